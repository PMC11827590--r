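#' @include align.R
#' @importFrom IRanges coverage Views viewMeans
#' @importFrom stats median
NULL

#' Per-position coverage, misincorporation and deletion profiles
#'
#' Builds, for each collapse group, the per-position depth and the
#' mismatch/deletion rates of uniquely mapped reads along the gene body
#' (linear 0-based coordinates on the representative sequence; the CCA
#' extension is not profiled). Reads missing more than
#' \code{min_missing_3p_for_exclusion} 3' nucleotides are excluded
#' entirely — heavily truncated reads reflect degradation and distort
#' positional statistics. Positions are additionally annotated with the
#' offset from the anticodon's 3'-most base, so \code{+1} is the
#' canonical position-37 neighborhood where modification-induced
#' misincorporations concentrate.
#'
#' @param alignments unique-only alignment \code{DataFrame}.
#' @param groups a \linkS4class{TrnaCollapseGroups}.
#' @param min_missing_3p_for_exclusion exclude reads lacking more than
#'   this many 3' nucleotides (default 7).
#' @param min_depth minimum depth for rates to be reported (below it
#'   rates are NA).
#' @return data.frame with group_id, position, depth, mismatch_count,
#'   mismatch_rate, deletion_count, deletion_rate, anticodon_relative.
#' @export
buildProfile <- function(alignments, groups,
                         min_missing_3p_for_exclusion = 7L,
                         min_depth = 1L) {
  stopifnot(is(groups, "TrnaCollapseGroups"))
  if (!all(alignments$unique))
    stop("profiles require uniquely assigned reads")
  models <- modelSeqs(groups)
  L <- setNames(width(models), names(models))
  missing <- L[alignments$group_id] - alignments$ref_end
  keep <- missing <= min_missing_3p_for_exclusion
  aln <- alignments[keep, , drop = FALSE]
  reps <- representativeSeqs(groups)
  g_tab <- groups@groups
  out <- vector("list", length(models))
  for (g in seq_along(models)) {
    gid <- names(models)[g]
    L0 <- width(reps)[g]
    a <- aln[aln$group_id == gid, , drop = FALSE]
    if (!nrow(a)) next
    ir <- IRanges(start = a$ref_start + 1L,
                  end = pmin(a$ref_end, L0))
    ir <- ir[width(ir) > 0L]
    depth <- as.integer(coverage(ir, width = L0))
    mm <- unlist(a$mismatch_pos)
    mm <- mm[mm < L0]
    dl <- unlist(a$deletion_pos)
    dl <- dl[dl < L0]
    mm_count <- tabulate(mm + 1L, nbins = L0)
    dl_count <- tabulate(dl + 1L, nbins = L0)
    ac_start <- g_tab$anticodon_start[g]
    if (is.na(ac_start)) {
      warning("group '", gid, "' lacks anticodon coordinates; ",
              "anticodon_relative reported as NA")
      ac_rel <- rep(NA_integer_, L0)
    } else {
      ac_rel <- (seq_len(L0) - 1L) - (ac_start + 2L)
    }
    out[[g]] <- data.frame(
      group_id = gid, position = seq_len(L0) - 1L, depth = depth,
      mismatch_count = mm_count,
      mismatch_rate = ifelse(depth >= min_depth, mm_count / pmax(depth, 1L),
                             NA_real_),
      deletion_count = dl_count,
      deletion_rate = ifelse(depth >= min_depth, dl_count / pmax(depth, 1L),
                             NA_real_),
      anticodon_relative = ac_rel, stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out[!vapply(out, is.null, logical(1))])
  if (is.null(res))
    res <- data.frame(group_id = character(0), position = integer(0),
                      depth = integer(0), mismatch_count = integer(0),
                      mismatch_rate = numeric(0), deletion_count = integer(0),
                      deletion_rate = numeric(0),
                      anticodon_relative = integer(0))
  rownames(res) <- NULL
  res
}

#' Flag putative modification sites from positional variant rates
#'
#' Sites whose combined mismatch + deletion rate reaches
#' \code{rate_threshold} at depth \code{min_depth} are flagged. The
#' first three 5' positions are never flagged (untemplated
#' reverse-transcriptase additions produce artifactual 5' mismatches).
#' A site at anticodon offset +1 carries a known-hotspot tag — the
#' neighborhood immediately 3' of the anticodon.
#'
#' @param profiles output of \code{\link{buildProfile}}.
#' @param rate_threshold combined variant-rate threshold.
#' @param min_depth minimum depth for a site to be considered.
#' @return the flagged subset of \code{profiles} with extra columns
#'   combined_rate and known_hotspot.
#' @export
flagVariantSites <- function(profiles, rate_threshold = 0.10,
                             min_depth = 50L) {
  combined <- profiles$mismatch_rate + profiles$deletion_rate
  sel <- !is.na(combined) & combined >= rate_threshold &
    profiles$depth >= min_depth & profiles$position >= 3L
  out <- profiles[sel, , drop = FALSE]
  out$combined_rate <- combined[sel]
  out$known_hotspot <- !is.na(out$anticodon_relative) &
    out$anticodon_relative == 1L
  rownames(out) <- NULL
  out
}

#' Detect internal coverage cliffs (putative RT hard stops)
#'
#' A "hard-stop" modification blocks reverse transcription, so coverage
#' collapses 5' of the stop while staying high 3' of it. A position is
#' reported when its depth falls below \code{frac} of the running median
#' of the next \code{window} positions on its 3' side. The gradual 5'
#' decay produced by ordinary truncation does not trigger the criterion.
#' The three 5'-terminal positions are skipped.
#'
#' @param profiles output of \code{\link{buildProfile}}.
#' @param frac cliff fraction (default 0.5).
#' @param window 3'-side window width for the running median.
#' @return data.frame with group_id, position, depth and median_3p for
#'   every flagged position.
#' @export
detectHardStops <- function(profiles, frac = 0.5, window = 10L) {
  out <- list()
  for (gid in unique(profiles$group_id)) {
    p <- profiles[profiles$group_id == gid, , drop = FALSE]
    p <- p[order(p$position), , drop = FALSE]
    d <- p$depth
    n <- length(d)
    for (i in seq_len(n)) {
      if (p$position[i] < 3L || i >= n) next
      med3 <- median(d[(i + 1L):min(i + window, n)])
      if (med3 > 0 && d[i] < frac * med3)
        out[[length(out) + 1L]] <- data.frame(
          group_id = gid, position = p$position[i], depth = d[i],
          median_3p = med3, stringsAsFactors = FALSE)
    }
  }
  if (!length(out))
    return(data.frame(group_id = character(0), position = integer(0),
                      depth = integer(0), median_3p = numeric(0)))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
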