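#' @include tails.R
NULL

#' Estimate per-tRNA aminoacylation from a treated-library tail census
#'
#' In a periodate-treated library the fraction of reads retaining an
#' intact CCA is the aminoacylated (protected) fraction:
#' \code{charged_pct = 100 * CCA_intact / (CCA_intact + CC_minus1)}.
#' Reads lacking more than a single 3' nucleotide are excluded from both
#' numerator and denominator — they reflect degradation, not the
#' periodate readout. For C-discriminator genes, CA-tailed reads form a
#' separate cohort (\code{tail_class_context = "CA_cohort"}) whose
#' intact state is retention of the CA endpoint; its one-nucleotide-loss
#' class is taken from the endpoint-truncation-2 reads (a CA tail minus
#' its terminal A is indistinguishable from a doubly truncated CCA
#' tail — see the package vignette).
#'
#' @param census a tail census (from \code{\link{tailCensus}}) of one or
#'   more periodate-treated libraries.
#' @param min_reads per-library minimum post-exclusion denominator; a
#'   group passes only with strictly more than \code{min_reads} reads.
#' @return a data.frame with library_id, group_id, tail_class_context
#'   (CCA_cohort / CA_cohort), n_cca, n_cc, n_excluded_deeper,
#'   charged_pct (NA when the denominator is 0) and passes_threshold.
#' @export
estimateCharging <- function(census, min_reads = 30L) {
  if (min_reads < 0) stop("min_reads must be nonnegative")
  if (!nrow(census))
    return(data.frame(library_id = character(0), group_id = character(0),
                      tail_class_context = character(0), n_cca = integer(0),
                      n_cc = integer(0), n_excluded_deeper = integer(0),
                      charged_pct = numeric(0), passes_threshold = logical(0)))
  key <- interaction(census$library_id, census$group_id, drop = TRUE)
  rows <- lapply(split(seq_len(nrow(census)), key), function(i) {
    cs <- census[i, , drop = FALSE]
    cnt <- function(cat) sum(cs$count[cs$category == cat])
    k <- .census_missing(cs$category)
    deep <- sum(cs$count[!is.na(k) & k >= 2L &
                         !cs$category %in% c("CA_addition")])
    out <- data.frame(library_id = cs$library_id[1L],
                      group_id = cs$group_id[1L],
                      tail_class_context = "CCA_cohort",
                      n_cca = cnt("CCA_intact"), n_cc = cnt("CC_minus1"),
                      n_excluded_deeper = deep,
                      stringsAsFactors = FALSE)
    if (cnt("CA_addition") > 0L) {
      t2 <- sum(cs$count[cs$category == "truncated_2"])
      deeper_ca <- sum(cs$count[!is.na(k) & k >= 3L])
      out <- rbind(out, data.frame(
        library_id = cs$library_id[1L], group_id = cs$group_id[1L],
        tail_class_context = "CA_cohort",
        n_cca = cnt("CA_addition"), n_cc = t2,
        n_excluded_deeper = deeper_ca, stringsAsFactors = FALSE))
    }
    out
  })
  est <- do.call(rbind, rows)
  denom <- est$n_cca + est$n_cc
  est$charged_pct <- ifelse(denom > 0L, 100 * est$n_cca / denom, NA_real_)
  est$passes_threshold <- denom > min_reads
  rownames(est) <- NULL
  est
}

#' Average charging estimates across replicate libraries
#'
#' Unweighted mean of per-library charged percentages over libraries
#' that pass the read threshold. Groups (per cohort) with no qualifying
#' library are omitted.
#'
#' @param estimates data.frame from \code{\link{estimateCharging}} over
#'   one or more libraries.
#' @return data.frame with group_id, tail_class_context, mean_charged_pct
#'   and n_libraries_used.
#' @export
averageReplicates <- function(estimates) {
  keep <- estimates$passes_threshold & !is.na(estimates$charged_pct)
  est <- estimates[keep, , drop = FALSE]
  if (!nrow(est))
    return(data.frame(group_id = character(0),
                      tail_class_context = character(0),
                      mean_charged_pct = numeric(0),
                      n_libraries_used = integer(0)))
  key <- interaction(est$group_id, est$tail_class_context, drop = TRUE)
  out <- do.call(rbind, lapply(split(seq_len(nrow(est)), key), function(i)
    data.frame(group_id = est$group_id[i[1L]],
               tail_class_context = est$tail_class_context[i[1L]],
               mean_charged_pct = mean(est$charged_pct[i]),
               n_libraries_used = length(i), stringsAsFactors = FALSE)))
  out <- out[order(out$group_id, out$tail_class_context, method = "radix"), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Charging fold difference between CCA- and CA-tailed cohorts
#'
#' For groups with both cohorts, reports the ratio of replicate-averaged
#' charged percentages (CCA over CA), per-library ratios where both
#' cohorts qualify, and their mean. A CA-cohort percentage of 0 yields
#' an infinite ratio, flagged.
#'
#' @param estimates per-library estimates from
#'   \code{\link{estimateCharging}}.
#' @return data.frame with group_id, mean_pct_cca, mean_pct_ca,
#'   ratio_of_means, mean_of_library_ratios, n_libraries and infinite.
#' @export
compareTailCohorts <- function(estimates) {
  avg <- averageReplicates(estimates)
  cca <- avg[avg$tail_class_context == "CCA_cohort", , drop = FALSE]
  ca <- avg[avg$tail_class_context == "CA_cohort", , drop = FALSE]
  shared <- intersect(cca$group_id, ca$group_id)
  if (!length(shared))
    return(data.frame(group_id = character(0), mean_pct_cca = numeric(0),
                      mean_pct_ca = numeric(0), ratio_of_means = numeric(0),
                      mean_of_library_ratios = numeric(0),
                      n_libraries = integer(0), infinite = logical(0)))
  out <- do.call(rbind, lapply(shared, function(g) {
    p_cca <- cca$mean_charged_pct[cca$group_id == g]
    p_ca <- ca$mean_charged_pct[ca$group_id == g]
    e <- estimates[estimates$group_id == g & estimates$passes_threshold &
                   !is.na(estimates$charged_pct), , drop = FALSE]
    bylib <- split(e, e$library_id)
    ratios <- vapply(bylib, function(x) {
      a <- x$charged_pct[x$tail_class_context == "CCA_cohort"]
      b <- x$charged_pct[x$tail_class_context == "CA_cohort"]
      if (length(a) == 1L && length(b) == 1L) a / b else NA_real_
    }, numeric(1))
    ratios <- ratios[!is.na(ratios)]
    data.frame(group_id = g, mean_pct_cca = p_cca, mean_pct_ca = p_ca,
               ratio_of_means = if (p_ca > 0) p_cca / p_ca else Inf,
               mean_of_library_ratios =
                 if (length(ratios)) mean(ratios) else NA_real_,
               n_libraries = length(ratios),
               infinite = p_ca == 0 || any(is.infinite(ratios)),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Validate periodate efficacy with the spike-in control
#'
#' The spike-in is uncharged by construction, so in a treated library it
#' must show near-zero intact 3' ends. Any treated library whose
#' spike-in charged percentage exceeds \code{max_pct} fails validation
#' and its estimates should be treated as unreliable.
#'
#' @param estimates per-library estimates from
#'   \code{\link{estimateCharging}} (treated libraries).
#' @param groups the \linkS4class{TrnaCollapseGroups} (identifies
#'   spike-in groups).
#' @param max_pct maximum tolerated spike-in charged percentage.
#' @return data.frame with library_id, spike_in_group, charged_pct,
#'   n_reads, max_pct and pass; when no spike-in is present a one-row
#'   report with \code{pass = NA} is returned with a warning.
#' @export
validateSpikeIn <- function(estimates, groups, max_pct = 10) {
  spikes <- groupIds(groups)[groups@groups$is_spike_in]
  libs <- unique(estimates$library_id)
  sel <- estimates$group_id %in% spikes &
    estimates$tail_class_context == "CCA_cohort"
  if (!length(spikes) || !any(sel)) {
    warning("no spike-in estimates found; charging report is unvalidated")
    return(data.frame(library_id = NA_character_,
                      spike_in_group = NA_character_,
                      charged_pct = NA_real_, n_reads = NA_integer_,
                      max_pct = max_pct, pass = NA))
  }
  e <- estimates[sel, , drop = FALSE]
  out <- data.frame(library_id = e$library_id, spike_in_group = e$group_id,
                    charged_pct = e$charged_pct,
                    n_reads = e$n_cca + e$n_cc, max_pct = max_pct,
                    pass = !is.na(e$charged_pct) & e$charged_pct <= max_pct,
                    stringsAsFactors = FALSE)
  missing_libs <- setdiff(libs, out$library_id)
  if (length(missing_libs))
    warning("no spike-in reads in library(ies): ",
            paste(missing_libs, collapse = ", "))
  rownames(out) <- NULL
  out
}
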