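# fixtures are built in code; sequences are random but seeded per test

rand_body <- function(n, disc = NULL, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  s <- paste(sample(c("A", "C", "G", "T"), n, TRUE), collapse = "")
  if (!is.null(disc)) s <- paste0(substr(s, 1, n - 1), disc)
  s
}

# small mixed reference set: one A-discriminator gene, one C-discriminator
# gene (CA-tail candidate), one plastid-derived gene, one spike-in
demo_refs <- function(seed = 42) {
  set.seed(seed)
  seqs <- c(gln1 = rand_body(72, "A"),
            met1 = rand_body(74, "C"),
            ile1 = rand_body(73, "G"),
            spike1 = rand_body(70, "T"))
  meta <- data.frame(
    id = names(seqs),
    origin = c("fungal_derived", "fungal_derived", "plastid_derived",
               "spike_in"),
    anticodon = c("TTG", "CAT", "GAT", "AAA"),
    amino_acid = c("Gln", "Met", "Ile", "X"),
    discriminator = c("A", "C", "G", "T"),
    cca_encoded = FALSE,
    is_spike_in = c(FALSE, FALSE, FALSE, TRUE),
    anticodon_start = c(33L, 34L, 33L, 32L),
    stringsAsFactors = FALSE)
  trnaReferenceSet(seqs, meta)
}

# three gene copies of one isoacceptor: two identical, one differing only
# at the discriminator base; all share a locus family
ile_family_refs <- function(seed = 7) {
  set.seed(seed)
  b <- rand_body(73, "A")
  variant <- paste0(substr(b, 1, 72), "G")  # substitution at the discriminator
  seqs <- c(ileA = b, ileB = b, ileC = variant)
  meta <- data.frame(
    id = names(seqs), origin = "plastid_derived", anticodon = "GAT",
    amino_acid = "Ile",
    discriminator = c("A", "A", "G"), cca_encoded = FALSE,
    is_spike_in = FALSE, locus_family = "plastid_tRNA-Ile",
    stringsAsFactors = FALSE)
  trnaReferenceSet(seqs, meta)
}

# independent full-matrix affine-gap DP ("fit" alignment: read global,
# reference ends free); gap of length k costs open + k * ext
gotoh_fit_score <- function(read, ref, match = 2, mismatch = -3,
                            open = 5, ext = 2) {
  r <- strsplit(read, "")[[1]]
  s <- strsplit(ref, "")[[1]]
  n <- length(r); m <- length(s)
  NEG <- -1e9
  H_prev <- c(0, -(open + ext * seq_len(n)))
  E_prev <- rep(NEG, n + 1)
  best <- H_prev[n + 1]
  for (j in seq_len(m)) {
    sub <- ifelse(r == s[j], match, mismatch)
    D <- H_prev[1:n] + sub
    E <- pmax(H_prev[2:(n + 1)] - open - ext, E_prev[2:(n + 1)] - ext)
    A <- c(0, pmax(D, E))
    cm <- cummax(A + ext * (0:n))
    Fv <- c(NEG, -ext * (1:n) + cm[1:n] - open)
    H <- pmax(A, Fv)
    best <- max(best, H[n + 1])
    H_prev <- H
    E_prev <- c(NEG, E)
  }
  best
}

# string-level tail-category oracle for reads constructed as
# (body + tail) minus `depth` 3' nucleotides, without errors
suffix_tail_oracle <- function(disc, tail, depth) {
  if (tail == "CCA") {
    if (depth == 0) "CCA_intact"
    else if (depth == 1) "CC_minus1"
    else sprintf("truncated_%d", depth)
  } else {                        # CA tail: endpoint sits one short of model
    if (depth == 0) {
      if (disc == "C") "CA_addition" else "CC_minus1"
    } else sprintf("truncated_%d", depth + 1)
  }
}

# sort-and-count percentile / top-5% oracle on raw depth vectors
percentile_oracle <- function(inter, region_sites) {
  m <- median(region_sites)
  s <- sort(inter)
  list(percentile = 100 * (sum(s < m) + 0.5 * sum(s == m)) / length(s),
       q95 = as.numeric(quantile(s, 0.95)),
       frac_top5 = mean(region_sites > as.numeric(quantile(s, 0.95))))
}

# exact binomial 99% acceptance bounds for an observed success count
binom99_bounds <- function(n, p) {
  c(qbinom(0.005, n, p), qbinom(0.995, n, p))
}
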