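test_that("simulator is deterministic and truth aggregates exactly", {
  refs <- demo_refs()
  p <- simTrnaParams(refs, abundance = c(3, 3, 2, 1), charging = 0.6,
                     seq_error_rate = 0.01, trunc_probs = c(0.8, 0.1, 0.1),
                     p5_ext_rate = 0.1, n_reads = 500, seed = 21)
  a <- simulateTrnaSeq(refs, p, treated = TRUE)
  b <- simulateTrnaSeq(refs, p, treated = TRUE)
  expect_identical(as.character(a$reads), as.character(b$reads))
  expect_identical(as.data.frame(a$truth), as.data.frame(b$truth))
  # FASTQ output is byte-identical across runs too
  f1 <- tempfile(fileext = ".fastq"); f2 <- tempfile(fileext = ".fastq")
  simulateTrnaSeq(refs, p, treated = TRUE, fastq_path = f1)
  simulateTrnaSeq(refs, p, treated = TRUE, fastq_path = f2)
  expect_identical(readLines(f1), readLines(f2))
  # per-ref truth summary equals aggregation of per-read rows
  ts <- truthSummary(a$truth)
  for (g in ts$ref_id) {
    rows <- a$truth[a$truth$ref_id == g, ]
    expect_identical(ts$n_reads[ts$ref_id == g], nrow(rows))
    expect_equal(ts$true_charging_fraction[ts$ref_id == g],
                 mean(rows$charged))
  }
  # the caller's RNG stream is not disturbed
  set.seed(1); x1 <- runif(1)
  set.seed(1); invisible(simulateTrnaSeq(refs, p, treated = TRUE))
  expect_identical(runif(1), x1)
})

test_that("periodate chemistry acts only on unprotected 3' ends", {
  refs <- demo_refs()[c("gln1", "met1")]
  model_len <- nchar(as.character(refSequences(refs))) + 3L
  # full protection: every treated read retains the complete CCA tail
  p1 <- simTrnaParams(refs, charging = 1, periodate_efficiency = 1,
                      n_reads = 300, seed = 3)
  s1 <- simulateTrnaSeq(refs, p1, treated = TRUE)
  len1 <- nchar(as.character(s1$reads))
  expect_true(all(len1 == model_len[s1$truth$ref_id]))
  expect_true(all(endsWith(as.character(s1$reads), "CCA")))
  # no protection, complete removal: every read one nucleotide short
  p0 <- simTrnaParams(refs, charging = 0, periodate_efficiency = 1,
                      n_reads = 300, seed = 3)
  s0 <- simulateTrnaSeq(refs, p0, treated = TRUE)
  expect_true(all(nchar(as.character(s0$reads)) ==
                  model_len[s0$truth$ref_id] - 1L))
  # untreated control is untouched regardless of charging
  sc <- simulateTrnaSeq(refs, p0, treated = FALSE)
  expect_true(all(nchar(as.character(sc$reads)) ==
                  model_len[sc$truth$ref_id]))
})

test_that("observed intact-tail fraction follows the binomial law", {
  refs <- demo_refs()["gln1"]
  p <- simTrnaParams(refs, charging = 0.7, periodate_efficiency = 1,
                     n_reads = 10000, seed = 17)
  s <- simulateTrnaSeq(refs, p, treated = TRUE)
  intact <- endsWith(as.character(s$reads), "CCA") &
    nchar(as.character(s$reads)) == nchar(as.character(refSequences(refs))) + 3L
  se <- sqrt(0.7 * 0.3 / 10000)
  expect_lt(abs(mean(intact) - 0.7), 3 * se)
  expect_identical(unname(intact), s$truth$charged)  # protection <=> charged
})

test_that("simulator validates its inputs", {
  refs <- demo_refs()
  expect_error(simTrnaParams(refs, abundance = 0, seed = 1), "abundance")
  expect_error(simTrnaParams(refs, n_reads = 0, seed = 1), "n_reads")
  expect_error(simTrnaParams(refs, charging = 1.2, seed = 1), "charging")
  expect_error(simTrnaParams(refs, charging = 0.5), "seed")
  # spike-in forced uncharged
  p <- simTrnaParams(refs, charging = 1, seed = 1)
  expect_identical(unname(p@charging["spike1"]), 0)
})

test_that("mRNA simulator places reads per feature and records exact truth", {
  set.seed(8)
  scaf <- rand_body(4000)
  ann <- GenomicRanges::GRanges("s1",
    IRanges::IRanges(c(501, 2001), width = c(400, 600)),
    strand = c("+", "-"))
  # background off: all reads live inside the single forward gene
  ms <- simulateMrnaSeq(scaf, ann[1], expression = 30, background_depth = 0,
                        read_len = 100, seed = 5, scaffold_name = "s1")
  al <- ms$alignments
  expect_true(all(as.character(GenomicRanges::strand(al)) == "+"))
  expect_true(all(GenomicRanges::start(al) >= 501 &
                  GenomicRanges::end(al) <= 900))
  # truth track equals brute-force per-position interval stabbing
  d <- rep(0L, 4000)
  for (i in seq_along(al))
    d[GenomicRanges::start(al)[i]:GenomicRanges::end(al)[i]] <-
      d[GenomicRanges::start(al)[i]:GenomicRanges::end(al)[i]] + 1L
  expect_identical(as.integer(forwardDepth(ms$truth)), d)
  expect_true(all(as.integer(reverseDepth(ms$truth)) == 0L))
  expect_error(simulateMrnaSeq(scaf, ann, expression = 10,
                               background_depth = 0, read_len = 5000,
                               seed = 1), "read_len")
})

test_that("a feature simulated at background depth blends into background", {
  set.seed(12)
  scaf <- rand_body(6000)
  ann <- GenomicRanges::GRanges("s1", IRanges::IRanges(3001, 3800),
                                strand = "+")
  # feature depth equals the per-strand background: Poisson-compatible
  ms <- simulateMrnaSeq(scaf, ann, expression = 0, background_depth = 20,
                        read_len = 100, seed = 9, scaffold_name = "s1")
  d <- as.integer(forwardDepth(ms$truth)) + as.integer(reverseDepth(ms$truth))
  inner <- d[3101:3700]            # away from edge effects
  outer <- d[c(501:2500, 4101:5500)]
  # same generative process: means agree within sampling noise
  se <- sqrt(var(outer) / length(outer) * 100)  # ~100 bp correlation length
  expect_lt(abs(mean(inner) - mean(outer)), 4 * se)
})
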