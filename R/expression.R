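#' @include align.R
NULL

#' Quantify tRNA expression as reads per million uniquely mapped
#'
#' Counts \code{unique = TRUE} alignments per collapse group and scales
#' to reads per million mapped to this reference set
#' (\code{tpm = 1e6 * unique_reads / total_unique_reads}). Ambiguous and
#' unmapped reads enter neither numerator nor denominator; a read tying
#' between two non-identical groups therefore contributes to nothing.
#' Spike-in reads are exogenous and excluded from the denominator (and
#' the report) by default.
#'
#' @param alignments alignment \code{DataFrame} from one library.
#' @param groups a \linkS4class{TrnaCollapseGroups}.
#' @param library_id label for the output.
#' @param include_spike_in include spike-in groups in counts and the
#'   per-million denominator.
#' @return data.frame with library_id, group_id, origin, unique_reads
#'   and tpm (all-NA tpm, with a warning, when the library has no
#'   unique reads).
#' @export
quantifyExpression <- function(alignments, groups, library_id = "library1",
                               include_spike_in = FALSE) {
  stopifnot(is(groups, "TrnaCollapseGroups"))
  g <- groups@groups
  gids <- as.character(g$group_id)
  keep_groups <- if (include_spike_in) gids else gids[!g$is_spike_in]
  m <- refMeta(groups@refs)
  first <- match(vapply(g$member_ids, `[`, character(1), 1L), m$id)
  origin <- setNames(as.character(m$origin[first]), gids)
  cnt <- table(factor(alignments$group_id[alignments$unique],
                      levels = keep_groups))
  total <- sum(cnt)
  tpm <- if (total > 0L) 1e6 * as.numeric(cnt) / total else {
    warning("no unique reads in library '", library_id, "'; tpm undefined")
    rep(NA_real_, length(cnt))
  }
  data.frame(library_id = library_id, group_id = names(cnt),
             origin = origin[names(cnt)],
             unique_reads = as.integer(cnt), tpm = tpm,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Aggregate expression over gene copies of a locus family
#'
#' Sums unique reads and tpm across collapse groups sharing a
#' \code{locus_family} annotation (e.g. several gene copies of one
#' plastid-derived isoacceptor) and reports each group's share of the
#' family total — e.g. the share carried by two identical copies versus
#' a third copy differing at the discriminator base.
#'
#' @param records output of \code{\link{quantifyExpression}}.
#' @param groups a \linkS4class{TrnaCollapseGroups} carrying
#'   \code{locus_family} metadata.
#' @return list with \code{families} (library_id, locus_family,
#'   n_groups, unique_reads, tpm) and \code{shares} (per-group rows with
#'   share_of_family).
#' @export
aggregateCopies <- function(records, groups) {
  g <- groups@groups
  fam <- setNames(as.character(g$locus_family), as.character(g$group_id))
  rec <- records
  rec$locus_family <- fam[rec$group_id]
  rec <- rec[!is.na(rec$locus_family), , drop = FALSE]
  if (!nrow(rec))
    return(list(
      families = data.frame(library_id = character(0),
                            locus_family = character(0),
                            n_groups = integer(0), unique_reads = integer(0),
                            tpm = numeric(0)),
      shares = data.frame()))
  key <- interaction(rec$library_id, rec$locus_family, drop = TRUE)
  families <- do.call(rbind, lapply(split(seq_len(nrow(rec)), key),
    function(i) data.frame(
      library_id = rec$library_id[i[1L]],
      locus_family = rec$locus_family[i[1L]],
      n_groups = length(i),
      unique_reads = sum(rec$unique_reads[i]),
      tpm = sum(rec$tpm[i]), stringsAsFactors = FALSE)))
  rownames(families) <- NULL
  tot <- setNames(families$unique_reads,
                  paste(families$library_id, families$locus_family))
  rec$share_of_family <- ifelse(
    tot[paste(rec$library_id, rec$locus_family)] > 0,
    rec$unique_reads / tot[paste(rec$library_id, rec$locus_family)],
    0)
  rownames(rec) <- NULL
  list(families = families, shares = rec)
}
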