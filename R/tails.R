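#' @include align.R
NULL

#' Classify the 3' tail status of uniquely aligned reads
#'
#' Classification is endpoint-based: with the reference extended by the
#' post-transcriptional CCA, the number of missing 3' nucleotides is the
#' model length minus the read's 3' alignment endpoint. An endpoint
#' flush with the model is an intact CCA; one nucleotide short is the
#' periodate signature (CC); two or more short is a deeper truncation.
#' For C-discriminator genes an endpoint one short whose terminal read
#' bases are \code{CCA} is instead a post-transcriptional CA addition:
#' both CA and CCA tails then read ...CCA, and only the endpoint (the
#' final A sitting on the model's second C) separates them.
#'
#' @param alignments a \code{DataFrame} from \code{\link{alignReads}} or
#'   \code{\link{ingestSam}}; all rows must be unique assignments
#'   (non-unique input is a hard error, mirroring the unique-mapping
#'   filter applied throughout).
#' @param groups the \linkS4class{TrnaCollapseGroups} aligned against.
#' @param library_id label recorded on every call.
#' @return a \code{DataFrame} with read_id, group_id, library_id,
#'   category (\code{CCA_intact}, \code{CC_minus1}, \code{CA_addition},
#'   \code{truncated_k}), missing_3p_nt and terminal_bases (the last
#'   aligned read bases, logged for diagnostics).
#' @export
callTails <- function(alignments, groups, library_id = "library1") {
  stopifnot(is(groups, "TrnaCollapseGroups"))
  if (!all(alignments$unique))
    stop("tail calls require uniquely assigned reads; got ",
         sum(!alignments$unique), " non-unique alignment(s)")
  if (!nrow(alignments))
    return(DataFrame(read_id = character(0), group_id = character(0),
                     library_id = character(0), category = character(0),
                     missing_3p_nt = integer(0),
                     terminal_bases = character(0)))
  models <- modelSeqs(groups)
  disc <- setNames(as.character(groups@groups$discriminator),
                   names(models))
  L <- setNames(width(models), names(models))
  missing <- as.integer(L[alignments$group_id] - alignments$ref_end)
  if (any(missing < 0L)) stop("alignment endpoint beyond the extended model")
  term <- alignments$read_3p_bases
  is_ca <- missing == 1L & disc[alignments$group_id] == "C" & term == "CCA"
  category <- ifelse(missing == 0L, "CCA_intact",
               ifelse(is_ca, "CA_addition",
                ifelse(missing == 1L, "CC_minus1",
                       sprintf("truncated_%d", missing))))
  DataFrame(read_id = alignments$read_id,
            group_id = alignments$group_id,
            library_id = library_id,
            category = category,
            missing_3p_nt = missing,
            terminal_bases = term,
            row.names = NULL)
}

#' Tabulate tail categories per group and library
#'
#' @param calls a \code{DataFrame} of tail calls (possibly concatenated
#'   across libraries).
#' @return a data.frame with columns library_id, group_id, category,
#'   count; row counts sum to the number of input calls.
#' @export
tailCensus <- function(calls) {
  if (!nrow(calls))
    return(data.frame(library_id = character(0), group_id = character(0),
                      category = character(0), count = integer(0)))
  tab <- as.data.frame(table(library_id = calls$library_id,
                             group_id = calls$group_id,
                             category = calls$category),
                       stringsAsFactors = FALSE)
  tab <- tab[tab$Freq > 0L, , drop = FALSE]
  names(tab)[names(tab) == "Freq"] <- "count"
  tab <- tab[order(tab$library_id, tab$group_id, tab$category,
                   method = "radix"), , drop = FALSE]
  rownames(tab) <- NULL
  tab
}

# missing-3'-nt depth encoded in a census category string
.census_missing <- function(category) {
  out <- rep(NA_integer_, length(category))
  out[category == "CCA_intact"] <- 0L
  out[category == "CC_minus1"] <- 1L
  out[category == "CA_addition"] <- 1L
  k <- grepl("^truncated_", category)
  out[k] <- as.integer(sub("^truncated_", "", category[k]))
  out
}
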