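#' @include AllClasses.R align.R
#' @importFrom GenomicAlignments readGAlignments
#' @importFrom GenomicRanges reduce granges seqnames
#' @importFrom IRanges Views viewMeans viewSums
#' @importFrom rtracklayer import
#' @importFrom stats cor quantile sd
#' @importFrom GenomeInfoDb seqlengths
NULL

#' Build strand-specific coverage from an mRNA-seq SAM/BAM
#'
#' Per-position read-count depth over one scaffold, split by transcript
#' strand. With the \code{read1-forward} protocol the alignment strand
#' is the transcript strand; \code{read1-reverse} (dUTP-style) flips it.
#'
#' @param sam_path SAM or BAM aligned to the scaffold.
#' @param scaffold_name name of the scaffold to extract; must be present
#'   in the SAM header.
#' @param scaffold_length optional expected length; mismatch with the
#'   header is an error.
#' @param strand_protocol \code{"read1-forward"} or
#'   \code{"read1-reverse"}.
#' @return a \linkS4class{StrandedCoverage}.
#' @export
buildCoverage <- function(sam_path, scaffold_name, scaffold_length = NULL,
                          strand_protocol = c("read1-forward",
                                              "read1-reverse")) {
  strand_protocol <- match.arg(strand_protocol)
  bam <- .as_bam(sam_path)
  gal <- readGAlignments(bam)
  sl <- GenomeInfoDb::seqlengths(gal)
  if (!scaffold_name %in% names(sl))
    stop("scaffold '", scaffold_name, "' not found in alignment header")
  L <- sl[[scaffold_name]]
  if (!is.null(scaffold_length) && L != scaffold_length)
    stop("scaffold length mismatch: header ", L, " vs expected ",
         scaffold_length)
  gr <- granges(gal)
  gr <- gr[as.character(seqnames(gr)) == scaffold_name]
  sgn <- as.character(strand(gr))
  if (strand_protocol == "read1-reverse")
    sgn <- c("+" = "-", "-" = "+", "*" = "*")[sgn]
  fwd <- coverage(gr[sgn == "+"])[[scaffold_name]]
  rev <- coverage(gr[sgn == "-"])[[scaffold_name]]
  new("StrandedCoverage", scaffold = scaffold_name, forward = fwd,
      reverse = rev)
}

#' Mean depth in non-overlapping windows
#'
#' Averages per-position depth over fixed windows along the scaffold;
#' the final partial window is averaged over its true length.
#' Reverse-strand means are reported as negative values, the usual
#' plotting convention for stranded coverage.
#'
#' @param cov a \linkS4class{StrandedCoverage}.
#' @param window window width in bp (default 100).
#' @return data.frame with start, end (0-based half-open), n_sites,
#'   forward and reverse (reverse \eqn{\le} 0).
#' @export
windowDepths <- function(cov, window = 100L) {
  stopifnot(is(cov, "StrandedCoverage"), window >= 1L)
  L <- length(cov)
  starts <- seq.int(1L, L, by = window)
  ends <- pmin(starts + window - 1L, L)
  fwd <- viewMeans(Views(cov@forward, start = starts, end = ends))
  rev <- viewMeans(Views(cov@reverse, start = starts, end = ends))
  data.frame(start = starts - 1L, end = ends, n_sites = ends - starts + 1L,
             forward = fwd, reverse = -rev, row.names = NULL)
}

#' Read gene annotations into GRanges
#'
#' BED input (0-based half-open) and GFF/GTF input (1-based closed) are
#' both converted to the 1-based closed \code{GRanges} convention used
#' internally.
#'
#' @param path annotation file (.bed, .gff, .gff3, .gtf).
#' @return a \code{GRanges}.
#' @export
readAnnotations <- function(path) {
  rtracklayer::import(path)
}

#' Rank a region's coverage against the intergenic background
#'
#' Computes the median per-site depth of a query region and places it
#' within the empirical distribution of per-site depths at intergenic
#' positions (all positions outside annotated genes on either strand,
#' optionally with excluded flanks). The percentile uses the mid-rank
#' tie rule: ties count one half. Also reports the fraction of region
#' sites exceeding the intergenic 95th-percentile depth — an expressed
#' region should populate that top 5%; a silent one should not. Depth is
#' strand-summed by default (the question is total transcription of the
#' region); a single-strand mode is available.
#'
#' @param cov a \linkS4class{StrandedCoverage}.
#' @param annotations \code{GRanges} of annotated genes.
#' @param region \code{GRanges} (single range) or length-2 numeric
#'   \code{c(start, end)} in 0-based half-open coordinates.
#' @param flank bp excluded on each side of every gene when defining the
#'   intergenic set.
#' @param strand_mode \code{"summed"} (default), \code{"forward"} or
#'   \code{"reverse"}.
#' @return list with region bounds, region_median_depth,
#'   n_intergenic_sites, intergenic depth summary, intergenic_q95,
#'   region_percentile, frac_region_sites_in_top5 and strand_mode.
#' @export
intergenicPercentile <- function(cov, annotations, region, flank = 0L,
                                 strand_mode = c("summed", "forward",
                                                 "reverse")) {
  strand_mode <- match.arg(strand_mode)
  stopifnot(is(cov, "StrandedCoverage"))
  L <- length(cov)
  d <- switch(strand_mode,
              summed = as.integer(cov@forward) + as.integer(cov@reverse),
              forward = as.integer(cov@forward),
              reverse = as.integer(cov@reverse))
  if (is(region, "GRanges")) {
    stopifnot(length(region) == 1L)
    r1 <- start(region); r2 <- end(region)
  } else {
    stopifnot(length(region) == 2L, region[1L] < region[2L])
    r1 <- region[1L] + 1L; r2 <- region[2L]
  }
  if (r1 < 1L || r2 > L) stop("region outside scaffold bounds")
  mask <- rep(FALSE, L)
  if (length(annotations)) {
    red <- reduce(granges(annotations), ignore.strand = TRUE)
    if (min(start(red)) < 1L || max(end(red)) > L)
      stop("annotation outside scaffold bounds")
    for (i in seq_along(red)) {
      a <- max(1L, start(red)[i] - flank)
      b <- min(L, end(red)[i] + flank)
      mask[a:b] <- TRUE
    }
  }
  inter <- d[!mask]
  if (!length(inter)) stop("intergenic site set is empty")
  region_sites <- d[r1:r2]
  if (!length(region_sites)) stop("region overlaps zero sites")
  m <- median(region_sites)
  pct <- 100 * (sum(inter < m) + 0.5 * sum(inter == m)) / length(inter)
  q95 <- as.numeric(quantile(inter, 0.95))
  list(region_start0 = r1 - 1L, region_end = r2,
       region_median_depth = m,
       n_intergenic_sites = length(inter),
       intergenic_summary = summary(inter),
       intergenic_q95 = q95,
       region_percentile = pct,
       frac_region_sites_in_top5 = mean(region_sites > q95),
       # fraction of intergenic sites above their own 95th percentile:
       # the null expectation for frac_region_sites_in_top5 (< 0.05 when
       # integer depths tie at the threshold)
       intergenic_frac_above_q95 = mean(inter > q95),
       strand_mode = strand_mode)
}

#' Correlation of window depths between replicates
#'
#' Pearson correlation of log(depth + pseudocount) across windows, both
#' strands concatenated. Undefined (NA, with a message) when either
#' vector has zero variance.
#'
#' @param windows_a,windows_b window tables from
#'   \code{\link{windowDepths}} computed with identical windowing of the
#'   same scaffold.
#' @param pseudocount added before the log (default 1).
#' @return numeric correlation, or NA when undefined.
#' @export
replicateCorrelation <- function(windows_a, windows_b, pseudocount = 1) {
  stopifnot(nrow(windows_a) == nrow(windows_b),
            all(windows_a$start == windows_b$start))
  xa <- log(c(windows_a$forward, abs(windows_a$reverse)) + pseudocount)
  xb <- log(c(windows_b$forward, abs(windows_b$reverse)) + pseudocount)
  if (sd(xa) == 0 || sd(xb) == 0) {
    message("zero-variance window depths; correlation undefined")
    return(NA_real_)
  }
  cor(xa, xb)
}
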