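#' @include AllClasses.R reference.R
#' @importFrom Biostrings BStringSet reverseComplement
#' @importFrom GenomicRanges GRanges strand start end width coverage
#' @importFrom stats rbinom runif setNames
NULL

.BASES <- c("A", "C", "G", "T")

# draw, for each element of `cur`, a uniformly random base different from it
.rand_other_base <- function(cur) {
  n <- length(cur)
  if (!n) return(character(0))
  k <- sample.int(3L, n, replace = TRUE)
  vapply(seq_len(n), function(i) setdiff(.BASES, cur[i])[k[i]], character(1))
}

.rand_bases <- function(n) {
  if (!n) return(character(0))
  .BASES[sample.int(4L, n, replace = TRUE)]
}

# run `expr` under a fixed seed without disturbing the caller's RNG state
.with_seed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Build simulator parameters for a charged tRNA-seq library
#'
#' Per-reference vectors are recycled from scalars and may be given
#' named (by reference id) or positional. Spike-in references are
#' forced to charging fraction 0: the spike-in is uncharged by
#' construction, which is what makes it a periodate-efficacy control.
#'
#' @param refs a \linkS4class{TrnaReferenceSet}.
#' @param abundance nonnegative sampling weights (default equal).
#' @param charging per-reference aminoacylated fraction in [0,1].
#' @param charging_ca aminoacylated fraction of CA-tailed molecules
#'   (default: same as \code{charging}); lets CA-tailed transcripts be
#'   charged at a different level than full CCA tails.
#' @param tail_ca_prob probability that the post-transcriptional tail is
#'   CA instead of CCA (default 0; only meaningful where the enzyme adds
#'   a short tail, but permitted anywhere — the truth table records it).
#' @param mod_sites data.frame(id, pos, mis_rate, del_rate) of
#'   modification-induced misincorporation/deletion sites; \code{pos} is
#'   0-based on the gene body.
#' @param trunc_probs probability vector over 0,1,2,... additional
#'   missing 3' nucleotides (3' exonucleolytic truncation). Default:
#'   no truncation.
#' @param p5_ext_rate probability of an untemplated 1-3 nt 5' extension
#'   (reverse-transcriptase terminal-transferase artifact).
#' @param seq_error_rate per-base substitution error rate.
#' @param periodate_efficiency probability that periodate treatment
#'   removes the terminal nucleotide of an unprotected (uncharged) 3'
#'   end. Default 0.98 ("near complete" removal).
#' @param n_reads reads per library.
#' @param seed mandatory RNG seed; output is byte-deterministic.
#' @return a validated \linkS4class{SimTrnaParams}.
#' @export
simTrnaParams <- function(refs, abundance = 1, charging = 0.8,
                          charging_ca = NULL,
                          tail_ca_prob = 0, mod_sites = NULL,
                          trunc_probs = 1, p5_ext_rate = 0,
                          seq_error_rate = 0, periodate_efficiency = 0.98,
                          n_reads = 10000L, seed) {
  stopifnot(is(refs, "TrnaReferenceSet"))
  if (missing(seed)) stop("seed is mandatory")
  ids <- refIds(refs)
  expand <- function(x, what) {
    if (!is.null(names(x))) {
      out <- setNames(rep(NA_real_, length(ids)), ids)
      unknown <- setdiff(names(x), ids)
      if (length(unknown))
        stop(what, " given for unknown reference id(s): ",
             paste(unknown, collapse = ", "))
      out[names(x)] <- x
      if (anyNA(out))
        stop(what, " missing for id(s): ", paste(ids[is.na(out)], collapse = ", "))
      out
    } else setNames(rep_len(as.numeric(x), length(ids)), ids)
  }
  ab <- expand(abundance, "abundance")
  ch <- expand(charging, "charging")
  ch[refMeta(refs)$is_spike_in] <- 0
  chca <- if (is.null(charging_ca)) ch else expand(charging_ca, "charging_ca")
  chca[refMeta(refs)$is_spike_in] <- 0
  ca <- expand(tail_ca_prob, "tail_ca_prob")
  if (is.null(mod_sites))
    mod_sites <- data.frame(id = character(0), pos = integer(0),
                            mis_rate = numeric(0), del_rate = numeric(0))
  if (n_reads <= 0) stop("n_reads must be positive")
  obj <- new("SimTrnaParams", abundance = ab, charging = ch,
             chargingCa = chca, tailCaProb = ca,
             modSites = mod_sites, truncProbs = trunc_probs / sum(trunc_probs),
             p5ExtRate = p5_ext_rate, seqErrorRate = seq_error_rate,
             periodateEfficiency = periodate_efficiency,
             nReads = as.integer(n_reads), seed = as.integer(seed))
  validObject(obj)
  obj
}

#' Simulate one charged tRNA-seq library
#'
#' Draws reads from the generative model: pick a reference by abundance;
#' append the post-transcriptional tail (CCA, or CA per the tail
#' profile; genes whose genomic copy already ends in CCA get no tail);
#' draw the aminoacylation state; in a periodate-treated library, remove
#' the terminal 3' nucleotide of each unprotected (uncharged) molecule
#' with probability \code{periodate_efficiency} — the beta-elimination
#' signature; then apply 3' exonucleolytic truncation,
#' modification-induced misincorporation/deletion, untemplated 5'
#' extension, and uniform base-call error.
#'
#' @param refs a \linkS4class{TrnaReferenceSet}.
#' @param params a \linkS4class{SimTrnaParams}.
#' @param treated logical; TRUE for the periodate-treated library,
#'   FALSE for the untreated control.
#' @param fastq_path optional path; when given, reads are written as
#'   FASTQ with constant quality 'I'.
#' @return list with \code{reads} (named \code{DNAStringSet}) and
#'   \code{truth}, a \code{DataFrame} with one row per read: read_id,
#'   ref_id, charged, tail_type (CCA/CA/genomic), periodate_removed,
#'   trunc_depth, treated.
#' @seealso \code{\link{truthSummary}}
#' @export
simulateTrnaSeq <- function(refs, params, treated, fastq_path = NULL) {
  stopifnot(is(refs, "TrnaReferenceSet"), is(params, "SimTrnaParams"))
  validObject(params)
  m <- refMeta(refs)
  body <- as.character(refSequences(refs))
  n <- params@nReads
  ab <- params@abundance
  if (sum(ab) <= 0) stop("total abundance is zero")
  .with_seed(params@seed, {
    idx <- sample.int(length(ab), n, replace = TRUE, prob = ab / sum(ab))
    ref_id <- refIds(refs)[idx]
    tail_type <- ifelse(m$cca_encoded[idx], "genomic",
                        ifelse(runif(n) < params@tailCaProb[idx], "CA", "CCA"))
    tail_str <- c(CCA = "CCA", CA = "CA", genomic = "")[tail_type]
    seqs <- paste0(body[idx], tail_str)
    charged <- runif(n) < ifelse(tail_type == "CA",
                                 params@chargingCa[idx],
                                 params@charging[idx])
    periodate_removed <- treated & !charged &
      (runif(n) < params@periodateEfficiency)
    trunc <- sample.int(length(params@truncProbs), n, replace = TRUE,
                        prob = params@truncProbs) - 1L
    cut <- pmin(as.integer(periodate_removed) + trunc, nchar(seqs) - 1L)
    seqs <- substr(seqs, 1L, nchar(seqs) - cut)
    # modification events, applied 3'->5' so deletions cannot shift later sites
    ms <- params@modSites
    if (nrow(ms)) {
      ms <- ms[order(-ms$pos), , drop = FALSE]
      for (k in seq_len(nrow(ms))) {
        sel <- which(ref_id == ms$id[k] & nchar(seqs) > ms$pos[k])
        if (!length(sel)) next
        u <- runif(length(sel))
        del <- u < ms$del_rate[k]
        mis <- !del & u < ms$del_rate[k] + ms$mis_rate[k]
        p <- ms$pos[k] + 1L
        if (any(mis)) {
          i <- sel[mis]
          substr(seqs[i], p, p) <- .rand_other_base(substr(seqs[i], p, p))
        }
        if (any(del)) {
          i <- sel[del]
          seqs[i] <- paste0(substr(seqs[i], 1L, p - 1L),
                            substr(seqs[i], p + 1L, nchar(seqs[i])))
        }
      }
    }
    # untemplated 5' extension of 1-3 nt
    ext <- ifelse(runif(n) < params@p5ExtRate,
                  sample.int(3L, n, replace = TRUE), 0L)
    if (any(ext > 0L)) {
      i <- which(ext > 0L)
      pre <- vapply(ext[i], function(e)
        paste(.rand_bases(e), collapse = ""), character(1))
      seqs[i] <- paste0(pre, seqs[i])
    }
    # uniform base-call error
    if (params@seqErrorRate > 0) {
      nerr <- rbinom(n, nchar(seqs), params@seqErrorRate)
      for (i in which(nerr > 0L)) {
        pos <- sample.int(nchar(seqs[i]), nerr[i])
        for (p in pos)
          substr(seqs[i], p, p) <- .rand_other_base(substr(seqs[i], p, p))
      }
    }
    read_id <- sprintf("read%06d", seq_len(n))
    reads <- DNAStringSet(seqs)
    names(reads) <- read_id
    truth <- DataFrame(read_id = read_id, ref_id = ref_id, charged = charged,
                       tail_type = tail_type,
                       periodate_removed = periodate_removed,
                       trunc_depth = trunc, treated = treated)
    if (!is.null(fastq_path))
      writeXStringSet(reads, fastq_path, format = "fastq",
                      qualities = BStringSet(strrep("I", width(reads))))
    list(reads = reads, truth = truth)
  })
}

#' Aggregate per-read simulation truth to per-reference summaries
#'
#' @param truth the per-read truth \code{DataFrame} from
#'   \code{\link{simulateTrnaSeq}}.
#' @return data.frame with ref_id, n_reads, true_abundance (read
#'   fraction) and true_charging_fraction (mean of per-read charged
#'   flags).
#' @export
truthSummary <- function(truth) {
  sp <- split(seq_len(nrow(truth)), truth$ref_id)
  data.frame(
    ref_id = names(sp),
    n_reads = lengths(sp),
    true_abundance = lengths(sp) / nrow(truth),
    true_charging_fraction = vapply(sp, function(i)
      mean(truth$charged[i]), numeric(1)),
    row.names = NULL)
}

#' Simulate a strand-specific mRNA-seq read set over a scaffold
#'
#' Reads are placed uniformly within each annotated feature at the
#' feature's depth, on the feature's strand, plus a uniform intergenic
#' background on both strands. Because placements are known, alignments
#' are emitted directly (optionally as SAM), letting coverage statistics
#' be tested independently of any aligner.
#'
#' @param scaffold scaffold sequence (character or \code{DNAString}).
#' @param annotations \code{GRanges} of features (1-based, closed) with
#'   strand; use \code{\link{readAnnotations}} for BED/GFF input.
#' @param expression numeric per-feature mean depth (recycled).
#' @param background_depth mean depth of the uniform background applied
#'   per strand across the whole scaffold.
#' @param read_len read length in nt.
#' @param seed mandatory RNG seed.
#' @param scaffold_name reference name used in the SAM output.
#' @param sam_path optional path to write a SAM file (FLAG 0/16 encodes
#'   the strand; "read1-forward" convention: alignment strand equals
#'   transcript strand).
#' @return list with \code{alignments} (read \code{GRanges}),
#'   \code{truth} (a \linkS4class{StrandedCoverage} computed exactly
#'   from the emitted reads) and \code{sam_path} (NULL if not written).
#' @export
simulateMrnaSeq <- function(scaffold, annotations, expression,
                            background_depth, read_len = 100L, seed,
                            scaffold_name = "scaffold_1", sam_path = NULL) {
  if (missing(seed)) stop("seed is mandatory")
  scaffold <- as.character(scaffold)
  L <- nchar(scaffold)
  if (length(annotations) && (min(start(annotations)) < 1L ||
                              max(end(annotations)) > L))
    stop("annotation interval outside scaffold bounds")
  if (any(width(annotations) < 1L)) stop("malformed interval")
  expression <- rep_len(expression, length(annotations))
  read_len <- as.integer(read_len)
  if (read_len < 1L || read_len > L) stop("read_len out of range")
  .with_seed(seed, {
    starts <- integer(0); strands <- character(0)
    for (i in seq_along(annotations)) {
      w <- width(annotations)[i]
      nr <- round(expression[i] * w / read_len)
      if (nr <= 0) next
      smin <- start(annotations)[i]
      smax <- max(smin, min(end(annotations)[i] - read_len + 1L,
                            L - read_len + 1L))
      smin <- min(smin, L - read_len + 1L)
      st <- smin + sample.int(smax - smin + 1L, nr, replace = TRUE) - 1L
      sd <- as.character(strand(annotations)[i])
      if (sd == "*") sd <- "+"
      starts <- c(starts, st)
      strands <- c(strands, rep(sd, nr))
    }
    if (background_depth > 0) {
      nb <- round(background_depth * L / read_len)
      for (sd in c("+", "-")) {
        st <- sample.int(L - read_len + 1L, nb, replace = TRUE)
        starts <- c(starts, st)
        strands <- c(strands, rep(sd, nb))
      }
    }
    if (!length(starts)) stop("no reads generated; increase depths")
    o <- order(starts, strands, method = "radix")
    starts <- starts[o]; strands <- strands[o]
    al <- GRanges(scaffold_name,
                  IRanges(start = starts, width = read_len),
                  strand = strands,
                  seqlengths = setNames(L, scaffold_name))
    names(al) <- sprintf("mread%07d", seq_along(al))
    cov_f <- coverage(al[strand(al) == "+"])[[1L]]
    cov_r <- coverage(al[strand(al) == "-"])[[1L]]
    truth <- new("StrandedCoverage", scaffold = scaffold_name,
                 forward = cov_f, reverse = cov_r)
    if (!is.null(sam_path))
      .write_sam(sam_path, scaffold, scaffold_name, al, read_len)
    list(alignments = al, truth = truth, sam_path = sam_path)
  })
}

.write_sam <- function(path, scaffold, scaffold_name, al, read_len) {
  seqs <- substring(scaffold, start(al), end(al))
  rev <- as.logical(strand(al) == "-")
  if (any(rev))
    seqs[rev] <- as.character(reverseComplement(DNAStringSet(seqs[rev])))
  lines <- c(
    "@HD\tVN:1.6\tSO:coordinate",
    sprintf("@SQ\tSN:%s\tLN:%d", scaffold_name, nchar(scaffold)),
    sprintf("%s\t%d\t%s\t%d\t60\t%dM\t*\t0\t0\t%s\t%s",
            names(al), ifelse(rev, 16L, 0L), scaffold_name, start(al),
            read_len, seqs, strrep("I", read_len)))
  writeLines(lines, path)
  invisible(path)
}
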