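make_cov <- function(fwd, rev, name = "s1") {
  new("StrandedCoverage", scaffold = name,
      forward = S4Vectors::Rle(as.integer(fwd)),
      reverse = S4Vectors::Rle(as.integer(rev)))
}

test_that("coverage from SAM matches brute-force interval counting", {
  set.seed(41)
  scaf <- rand_body(2000)
  sam <- tempfile(fileext = ".sam")
  ann <- GenomicRanges::GRanges("s1", IRanges::IRanges(301, 700),
                                strand = "+")
  ms <- simulateMrnaSeq(scaf, ann, expression = 15, background_depth = 3,
                        read_len = 100, seed = 2, scaffold_name = "s1",
                        sam_path = sam)
  cov <- buildCoverage(sam, "s1", 2000)
  expect_identical(as.integer(forwardDepth(cov)),
                   as.integer(forwardDepth(ms$truth)))
  expect_identical(as.integer(reverseDepth(cov)),
                   as.integer(reverseDepth(ms$truth)))
  # protocol flip swaps the strands
  cov_r <- buildCoverage(sam, "s1", 2000, strand_protocol = "read1-reverse")
  expect_identical(as.integer(forwardDepth(cov_r)),
                   as.integer(reverseDepth(cov)))
  # name and length mismatches are errors
  expect_error(buildCoverage(sam, "nope", 2000), "not found")
  expect_error(buildCoverage(sam, "s1", 1999), "length mismatch")
  # single 100-nt forward read at the origin
  sam2 <- tempfile(fileext = ".sam")
  writeLines(c("@HD\tVN:1.6", "@SQ\tSN:s1\tLN:500",
               paste(c("r1", 0, "s1", 1, 60, "100M", "*", 0, 0,
                       strrep("A", 100), strrep("I", 100)), collapse = "\t")),
             sam2)
  cov2 <- buildCoverage(sam2, "s1", 500)
  expect_identical(as.integer(forwardDepth(cov2)),
                   c(rep(1L, 100), rep(0L, 400)))
  expect_true(all(as.integer(reverseDepth(cov2)) == 0L))
  # empty SAM: all-zero tracks
  sam3 <- tempfile(fileext = ".sam")
  writeLines(c("@HD\tVN:1.6", "@SQ\tSN:s1\tLN:500"), sam3)
  cov3 <- buildCoverage(sam3, "s1", 500)
  expect_equal(sum(as.integer(forwardDepth(cov3))), 0L)
})

test_that("window means average depth and conserve totals", {
  cov <- make_cov(rep(7L, 250), rep(0L, 250))
  w <- windowDepths(cov, 100)
  expect_equal(nrow(w), 3L)
  expect_true(all(w$forward == 7))
  expect_equal(w$n_sites, c(100L, 100L, 50L))   # final partial window
  # half-covered window averages to half
  cov2 <- make_cov(c(rep(10L, 50), rep(0L, 50)), rep(2L, 100))
  w2 <- windowDepths(cov2, 100)
  expect_equal(w2$forward, 5.0)
  expect_equal(w2$reverse, -2.0)                # reverse reported negative
  # conservation: sum(window mean x window length) = per-position total
  set.seed(3)
  covr <- make_cov(rpois(997, 4), rpois(997, 2))
  wr <- windowDepths(covr, 100)
  expect_equal(sum(wr$forward * wr$n_sites),
               sum(as.integer(forwardDepth(covr))))
})

test_that("intergenic percentile equals the sort-and-count oracle", {
  set.seed(77)
  for (i in 1:20) {
    L <- sample(2000:8000, 1)
    fwd <- rpois(L, sample(2:8, 1))
    rev <- rpois(L, sample(1:5, 1))
    cov <- make_cov(fwd, rev)
    g1 <- sort(sample(seq_len(L - 600), 2))
    ann <- GenomicRanges::GRanges("s1",
      IRanges::IRanges(g1, width = sample(100:300, 2)), strand = "+")
    r0 <- sample(seq_len(L - 500), 1)
    region <- c(r0 - 1, r0 + 399)               # 0-based half-open
    rep <- intergenicPercentile(cov, ann, region)
    # oracle on raw vectors
    d <- fwd + rev
    mask <- rep(FALSE, L)
    red <- GenomicRanges::reduce(ann)
    for (k in seq_along(red))
      mask[GenomicRanges::start(red)[k]:GenomicRanges::end(red)[k]] <- TRUE
    orc <- percentile_oracle(d[!mask], d[r0:(r0 + 399)])
    expect_equal(rep$region_percentile, orc$percentile)
    expect_equal(rep$frac_region_sites_in_top5, orc$frac_top5)
    expect_equal(rep$intergenic_q95, orc$q95)
  }
})

test_that("percentile edge cases follow the tie rule", {
  # region median 0, all intergenic positive -> percentile 0
  cov <- make_cov(c(rep(5L, 900), rep(0L, 100)), rep(0L, 1000))
  ann <- GenomicRanges::GRanges("s1", IRanges::IRanges(1, 1))[0]
  ann_region <- GenomicRanges::GRanges("s1", IRanges::IRanges(901, 1000))
  rep0 <- intergenicPercentile(cov, ann_region, c(900, 1000))
  expect_equal(rep0$region_percentile, 0)
  # region median equal to the unique intergenic maximum
  fwd <- c(rep(1L, 999), 50L)
  cov2 <- make_cov(fwd, rep(0L, 1000))
  rep2 <- intergenicPercentile(cov2, ann, c(999, 1000))
  expect_equal(rep2$region_percentile, 100 - 0.5 / 1000 * 100)
  # empty intergenic set is an error
  ann_all <- GenomicRanges::GRanges("s1", IRanges::IRanges(1, 1000))
  expect_error(intergenicPercentile(cov2, ann_all, c(0, 100)), "empty")
  expect_error(intergenicPercentile(cov2, ann, c(900, 2000)), "bounds")
})

test_that("replicate window correlation behaves at the limits", {
  w <- data.frame(start = c(0, 100), end = c(100, 200), n_sites = 100,
                  forward = c(3, 9), reverse = c(-1, -4))
  expect_equal(replicateCorrelation(w, w), 1.0)
  wc <- transform(w, forward = 5, reverse = -5)
  expect_message(r <- replicateCorrelation(wc, wc), "undefined")
  expect_true(is.na(r))
  # independent Poisson replicates of one truth track correlate strongly
  # (the truth track varies like real data: genes over background)
  set.seed(9)
  truth <- 50 * exp(rnorm(40, 0, 1))
  wa <- data.frame(start = (0:39) * 100, end = (1:40) * 100, n_sites = 100,
                   forward = rpois(40, truth), reverse = -rpois(40, truth))
  wb <- data.frame(start = (0:39) * 100, end = (1:40) * 100, n_sites = 100,
                   forward = rpois(40, truth), reverse = -rpois(40, truth))
  expect_gt(replicateCorrelation(wa, wb), 0.9)
})
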