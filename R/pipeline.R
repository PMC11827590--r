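#' @include reference.R simulate.R align.R tails.R charging.R profile.R
#'   expression.R coverage.R
#' @importFrom yaml read_yaml
#' @importFrom jsonlite write_json read_json
#' @importFrom utils packageVersion
NULL

.default_thresholds <- function() list(
  min_reads = 30L,            # per-library post-exclusion denominator
  truncation_exclusion = 7L,  # >7 missing 3' nt excluded from profiles
  variant_rate = 0.10,
  variant_min_depth = 50L,
  spike_max_pct = 10)

#' Read a pipeline run configuration
#'
#' Configurations are single YAML or JSON documents; any value absent
#' falls back to the documented default. Thresholds default to the
#' standard analysis settings (minimum 30 reads per library, exclusion
#' of reads lacking more than 7 3' nucleotides, 100-bp coverage
#' windows, top-5\% intergenic cutoff).
#'
#' @param path YAML or JSON config file.
#' @return the config as a named list.
#' @export
readRunConfig <- function(path) {
  if (!file.exists(path)) stop("config not found: ", path)
  cfg <- if (grepl("\\.json$", path, ignore.case = TRUE))
    read_json(path, simplifyVector = TRUE) else read_yaml(path)
  cfg
}

.merge_thresholds <- function(cfg) {
  th <- .default_thresholds()
  for (k in names(cfg$thresholds)) th[[k]] <- cfg$thresholds[[k]]
  th
}

.write_tsv <- function(x, path) {
  write.table(as.data.frame(x), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  path
}

#' Run the charged tRNA-seq analysis end to end
#'
#' Stages: load and validate references (optionally dropping entries
#' identical to competing-genome sequences), collapse identical copies,
#' align every library, call tails, census, estimate charging from
#' treated libraries (with spike-in validation and replicate
#' averaging), quantify expression from control libraries, and build
#' modification profiles. Per-stage read counts are logged and written
#' into a run manifest together with the configuration.
#'
#' @param config a list or a YAML/JSON path (see
#'   \code{\link{readRunConfig}}). Required fields: \code{refs_fasta},
#'   \code{refs_meta}, \code{libraries} (each with \code{id},
#'   \code{fastq} or \code{sam}, and \code{treated} = TRUE/FALSE),
#'   \code{out_dir}. Optional: \code{other_genome_fasta},
#'   \code{thresholds}, \code{scoring}.
#' @return (invisibly) a list with all stage results and the manifest.
#' @export
runChargedTrnaSeq <- function(config) {
  if (is.character(config)) config <- readRunConfig(config)
  for (f in c("refs_fasta", "refs_meta", "libraries", "out_dir"))
    if (is.null(config[[f]])) stop("config lacks required field '", f, "'")
  th <- .merge_thresholds(config)
  scoring <- do.call(alignScoring, as.list(config$scoring))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  refs <- loadTrnaReferences(config$refs_fasta, config$refs_meta)
  message("loaded ", length(refs), " references")
  if (!is.null(config$other_genome_fasta)) {
    other <- readDNAStringSet(config$other_genome_fasta)
    refs <- excludeAmbiguousWith(refs, other)
  }
  groups <- collapseIdentical(refs)
  message("collapsed into ", length(groups), " mapping groups")
  libs <- config$libraries
  if (is.data.frame(libs)) libs <- split(libs, seq_len(nrow(libs)))
  treated_flag <- vapply(libs, function(l) isTRUE(as.logical(l$treated)),
                         logical(1))
  all_calls <- list(); counters <- list(); est_list <- list()
  expr_list <- list(); aln_unique <- list()
  for (k in seq_along(libs)) {
    lib <- libs[[k]]
    lid <- as.character(lib$id)
    aln <- if (!is.null(lib$sam) && !is.na(lib$sam))
      ingestSam(lib$sam, groups, scoring)
    else alignReads(as.character(lib$fastq), groups, scoring)
    cnt <- table(factor(aln$status,
                        levels = c("unique", "ambiguous", "unmapped")))
    counters[[lid]] <- as.list(cnt)
    message(sprintf("[%s] reads in: %d  unique: %d  ambiguous: %d  unmapped: %d",
                    lid, nrow(aln), cnt[["unique"]], cnt[["ambiguous"]],
                    cnt[["unmapped"]]))
    u <- aln[aln$unique, , drop = FALSE]
    aln_unique[[lid]] <- u
    all_calls[[lid]] <- callTails(u, groups, library_id = lid)
    if (!treated_flag[k])
      expr_list[[lid]] <- quantifyExpression(u, groups, library_id = lid)
  }
  census <- tailCensus(do.call(rbind, unname(all_calls)))
  .write_tsv(census, file.path(config$out_dir, "tail_census.tsv"))
  results <- list(refs = refs, groups = groups, census = census,
                  counters = counters)
  treated_ids <- vapply(libs[treated_flag], function(l)
    as.character(l$id), character(1))
  if (length(treated_ids)) {
    est <- estimateCharging(census[census$library_id %in% treated_ids, ,
                                   drop = FALSE],
                            min_reads = th$min_reads)
    spike <- tryCatch(validateSpikeIn(est, groups, th$spike_max_pct),
                      warning = function(w) {
                        message("spike-in validation: ", conditionMessage(w))
                        suppressWarnings(
                          validateSpikeIn(est, groups, th$spike_max_pct))
                      })
    bad <- unique(spike$library_id[!is.na(spike$pass) & !spike$pass])
    if (length(bad))
      message("spike-in validation FAILED for: ",
              paste(bad, collapse = ", "), " - estimates flagged unreliable")
    est$reliable <- !est$library_id %in% bad
    summary_tab <- averageReplicates(est[est$reliable, , drop = FALSE])
    cohorts <- compareTailCohorts(est[est$reliable, , drop = FALSE])
    .write_tsv(est, file.path(config$out_dir, "charging_estimates.tsv"))
    .write_tsv(summary_tab, file.path(config$out_dir, "charging_summary.tsv"))
    .write_tsv(spike, file.path(config$out_dir, "spike_in_validation.tsv"))
    if (nrow(cohorts))
      .write_tsv(cohorts, file.path(config$out_dir, "tail_cohort_ratios.tsv"))
    results <- c(results, list(charging = est, charging_summary = summary_tab,
                               spike_in = spike, cohorts = cohorts))
  } else {
    message("no treated libraries; charging stage skipped")
  }
  if (length(expr_list)) {
    expr <- do.call(rbind, unname(expr_list))
    .write_tsv(expr, file.path(config$out_dir, "expression.tsv"))
    fam <- aggregateCopies(expr, groups)
    if (nrow(fam$families))
      .write_tsv(fam$families,
                 file.path(config$out_dir, "expression_families.tsv"))
    results <- c(results, list(expression = expr, families = fam))
  }
  control_ids <- setdiff(names(aln_unique), treated_ids)
  prof_src <- if (length(control_ids)) control_ids else names(aln_unique)
  prof_aln <- do.call(rbind, unname(aln_unique[prof_src]))
  profiles <- buildProfile(prof_aln, groups,
                           min_missing_3p_for_exclusion = th$truncation_exclusion)
  flagged <- flagVariantSites(profiles, th$variant_rate, th$variant_min_depth)
  .write_tsv(profiles, file.path(config$out_dir, "position_profiles.tsv"))
  .write_tsv(flagged, file.path(config$out_dir, "flagged_sites.tsv"))
  results <- c(results, list(profiles = profiles, flagged = flagged))
  manifest <- list(
    package_version = as.character(packageVersion("tRNAcharge")),
    config = config, thresholds = th,
    n_references = length(refs), n_groups = length(groups),
    stage_counters = counters,
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  write_json(manifest, file.path(config$out_dir, "run_manifest.json"),
             auto_unbox = TRUE, pretty = TRUE, digits = NA, force = TRUE)
  results$manifest <- manifest
  invisible(results)
}

#' Run the mRNA-coverage pseudogene assessment
#'
#' Builds strand-specific coverage from a SAM alignment, windows it,
#' and ranks a query region (e.g. a horizontally transferred fragment)
#' against the intergenic depth distribution. With a second replicate
#' SAM, the between-replicate window correlation is also reported.
#'
#' @param config list or YAML/JSON path with fields \code{sam},
#'   \code{scaffold_name}, \code{annotations} (BED/GFF path or GRanges),
#'   \code{region} = c(start, end) 0-based half-open, \code{out_dir};
#'   optional \code{scaffold_length}, \code{replicate_sam},
#'   \code{window} (default 100), \code{strand_protocol}, \code{flank}.
#' @return (invisibly) list with the coverage, window table, percentile
#'   report and (optionally) replicate correlation.
#' @export
runMrnaCoverage <- function(config) {
  if (is.character(config)) config <- readRunConfig(config)
  for (f in c("sam", "scaffold_name", "annotations", "region", "out_dir"))
    if (is.null(config[[f]])) stop("config lacks required field '", f, "'")
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  window <- if (is.null(config$window)) 100L else as.integer(config$window)
  protocol <- if (is.null(config$strand_protocol)) "read1-forward"
              else config$strand_protocol
  flank <- if (is.null(config$flank)) 0L else as.integer(config$flank)
  ann <- if (is.character(config$annotations))
    readAnnotations(config$annotations) else config$annotations
  cov <- buildCoverage(config$sam, config$scaffold_name,
                       config$scaffold_length, strand_protocol = protocol)
  win <- windowDepths(cov, window)
  rep_def <- intergenicPercentile(cov, ann, as.numeric(config$region),
                                  flank = flank)
  .write_tsv(win, file.path(config$out_dir, "window_depths.tsv"))
  out <- list(coverage = cov, windows = win, report = rep_def)
  if (!is.null(config$replicate_sam)) {
    cov2 <- buildCoverage(config$replicate_sam, config$scaffold_name,
                          config$scaffold_length, strand_protocol = protocol)
    win2 <- windowDepths(cov2, window)
    out$replicate_correlation <- replicateCorrelation(win, win2)
  }
  json <- rep_def
  json$intergenic_summary <- as.list(setNames(
    as.numeric(json$intergenic_summary), names(json$intergenic_summary)))
  if (!is.null(out$replicate_correlation))
    json$replicate_correlation <- out$replicate_correlation
  write_json(json, file.path(config$out_dir, "coverage_report.json"),
             auto_unbox = TRUE, digits = NA)
  invisible(out)
}
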