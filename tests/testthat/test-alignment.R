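test_that("perfect and near-perfect reads align as expected", {
  refs <- demo_refs()
  gr <- collapseIdentical(refs)
  models <- as.character(modelSeqs(gr))
  reads <- Biostrings::DNAStringSet(c(perfect = models[["gln1"]]))
  aln <- alignReads(reads, gr)
  expect_identical(aln$group_id, "gln1")
  expect_true(aln$unique)
  expect_equal(aln$ref_start, 0L)
  expect_equal(aln$ref_end, nchar(models[["gln1"]]))
  expect_equal(length(aln$mismatch_pos[[1]]), 0L)
  expect_equal(aln$score, 2 * nchar(models[["gln1"]]))

  # one substitution at a known internal position -> one mismatch event there
  set.seed(3)
  for (pos0 in c(10L, 30L, 55L)) {
    s <- models[["met1"]]
    base <- substr(s, pos0 + 1, pos0 + 1)
    sub <- setdiff(c("A", "C", "G", "T"), base)[1]
    substr(s, pos0 + 1, pos0 + 1) <- sub
    a <- alignReads(Biostrings::DNAStringSet(c(r = s)), gr)
    expect_identical(a$group_id, "met1")
    expect_identical(a$mismatch_pos[[1]], pos0)
    expect_identical(a$mismatch_base[[1]], sub)
  }
})

test_that("reads matching a multi-member group are unique at group level", {
  refs <- ile_family_refs()
  gr <- collapseIdentical(refs)
  shared <- paste0(as.character(representativeSeqs(gr))[["ileA"]], "CCA")
  aln <- alignReads(Biostrings::DNAStringSet(c(r1 = shared)), gr)
  expect_identical(aln$group_id, "ileA")
  expect_true(aln$unique)   # uniqueness is per collapse group, not per copy
})

test_that("score ties across distinct groups are reported ambiguous", {
  b <- rand_body(60, seed = 44)
  seqs <- c(g1 = paste0(b, "A"), g2 = paste0(b, "C"))
  meta <- data.frame(id = names(seqs), origin = "native_mito",
                     anticodon = "AAA", amino_acid = "Lys",
                     discriminator = c("A", "C"), cca_encoded = FALSE,
                     is_spike_in = FALSE)
  gr <- collapseIdentical(trnaReferenceSet(seqs, meta))
  # read ends in a base equidistant from both references
  read <- paste0(b, "G", "CCA")
  aln <- alignReads(Biostrings::DNAStringSet(c(r = read)), gr)
  expect_identical(aln$group_id, "ambiguous")
  expect_false(aln$unique)
  # garbage read is unmapped, not an error
  junk <- strrep("AC", 35)
  a2 <- alignReads(Biostrings::DNAStringSet(c(r = junk)), gr)
  expect_identical(a2$status, "unmapped")
})

test_that("error-free simulated reads all map uniquely to their true group", {
  refs <- demo_refs()
  gr <- collapseIdentical(refs)
  p <- simTrnaParams(refs, charging = 0.5, n_reads = 600, seed = 10)
  sim <- simulateTrnaSeq(refs, p, treated = TRUE)
  aln <- alignReads(sim$reads, gr)
  expect_true(all(aln$unique))
  expect_identical(aln$group_id, sim$truth$ref_id)  # singleton groups
  # reversing read order permutes but does not change assignments
  rev_aln <- alignReads(rev(sim$reads), gr)
  m <- match(aln$read_id, rev_aln$read_id)
  expect_identical(rev_aln$group_id[m], aln$group_id)
  expect_identical(rev_aln$ref_end[m], aln$ref_end)
})

test_that("5' untemplated extensions are absorbed by penalty-free clipping", {
  refs <- demo_refs()["gln1"]
  gr <- collapseIdentical(refs)
  model <- as.character(modelSeqs(gr))[[1]]
  read <- paste0("GGG", model)   # 3 nt terminal-transferase artifact
  aln <- alignReads(Biostrings::DNAStringSet(c(r = read)), gr)
  expect_identical(aln$group_id, "gln1")
  expect_equal(aln$soft_clip_5p, 3L)
  expect_equal(aln$score, 2 * nchar(model))
  expect_equal(length(aln$mismatch_pos[[1]]), 0L)
})

test_that("production scores equal the brute-force full-DP oracle", {
  set.seed(77)
  for (i in 1:40) {
    read <- rand_body(sample(20:120, 1))
    ref <- rand_body(sample(20:120, 1))
    expect_equal(semiGlobalScore(read, ref), gotoh_fit_score(read, ref))
  }
})

test_that("SAM ingestion reconstructs events from CIGAR and MD", {
  refs <- demo_refs()
  gr <- collapseIdentical(refs)
  model <- as.character(modelSeqs(gr))[["gln1"]]
  L <- nchar(model)
  sam <- tempfile(fileext = ".sam")
  hdr <- c("@HD\tVN:1.6\tSO:unknown",
           sprintf("@SQ\tSN:%s\tLN:%d", names(modelSeqs(gr)),
                   nchar(as.character(modelSeqs(gr)))))
  # deletion of reference base 51 (1-based): 50M1D(L-51)M
  delseq <- paste0(substr(model, 1, 50), substr(model, 52, L))
  delrec <- paste(c("d1", 0, "gln1", 1, 60, sprintf("50M1D%dM", L - 51L),
                    "*", 0, 0, delseq, strrep("I", nchar(delseq)),
                    sprintf("MD:Z:50^%s%d", substr(model, 51, 51), L - 51L)),
                  collapse = "\t")
  # mismatch at reference position 21 (1-based)
  mmseq <- model
  orig <- substr(mmseq, 21, 21)
  substr(mmseq, 21, 21) <- setdiff(c("A", "C", "G", "T"), orig)[1]
  mmrec <- paste(c("m1", 0, "gln1", 1, 60, sprintf("%dM", L), "*", 0, 0,
                   mmseq, strrep("I", L), sprintf("MD:Z:20%s%d", orig, L - 21L)),
                 collapse = "\t")
  # secondary-flagged copy of the perfect read
  sec <- paste(c("p2", 0, "gln1", 1, 60, sprintf("%dM", L), "*", 0, 0,
                 model, strrep("I", L), sprintf("MD:Z:%d", L)),
               collapse = "\t")
  sec2 <- paste(c("p2", 256, "met1", 1, 60, sprintf("%dM", L), "*", 0, 0,
                  model, strrep("I", L), sprintf("MD:Z:%d", L)),
                collapse = "\t")
  perfect <- paste(c("p1", 0, "gln1", 1, 60, sprintf("%dM", L), "*", 0, 0,
                     model, strrep("I", L), sprintf("MD:Z:%d", L)),
                   collapse = "\t")
  writeLines(c(hdr, perfect, delrec, mmrec, sec, sec2), sam)
  aln <- ingestSam(sam, gr)
  p <- aln[aln$read_id == "p1", ]
  expect_true(p$unique)
  expect_equal(p$ref_end, L)
  expect_equal(length(p$mismatch_pos[[1]]), 0L)
  expect_equal(p$score, 2 * L)
  d <- aln[aln$read_id == "d1", ]
  expect_identical(d$deletion_pos[[1]], 50L)      # 0-based
  expect_equal(d$ref_end, L)
  m1 <- aln[aln$read_id == "m1", ]
  expect_identical(m1$mismatch_pos[[1]], 20L)
  expect_identical(m1$mismatch_base[[1]], substr(mmseq, 21, 21))
  # secondary alignment marks the read non-unique
  p2 <- aln[aln$read_id == "p2", ]
  expect_false(p2$unique)
  # unknown reference is a hard error
  bad <- tempfile(fileext = ".sam")
  writeLines(c(hdr[1], "@SQ\tSN:ghost\tLN:80",
               paste(c("x1", 0, "ghost", 1, 60, "10M", "*", 0, 0,
                       strrep("A", 10), strrep("I", 10)), collapse = "\t")),
             bad)
  expect_error(ingestSam(bad, gr), "ghost")
})
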