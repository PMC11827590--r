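#' @include AllClasses.R
NULL

#' @rdname TrnaReferenceSet-class
#' @param x,object a \code{TrnaReferenceSet}.
#' @export
setGeneric("refSequences", function(x) standardGeneric("refSequences"))

#' @rdname TrnaReferenceSet-class
#' @export
setGeneric("refMeta", function(x) standardGeneric("refMeta"))

#' @rdname TrnaReferenceSet-class
#' @export
setGeneric("refIds", function(x) standardGeneric("refIds"))

#' @rdname TrnaCollapseGroups-class
#' @param x,object a \code{TrnaCollapseGroups}.
#' @export
setGeneric("groupTable", function(x) standardGeneric("groupTable"))

#' @rdname TrnaCollapseGroups-class
#' @export
setGeneric("groupIds", function(x) standardGeneric("groupIds"))

#' @rdname TrnaCollapseGroups-class
#' @export
setGeneric("representativeSeqs", function(x) standardGeneric("representativeSeqs"))

#' Mature alignment models of collapse groups
#'
#' The representative gene-body sequence of each group extended with the
#' post-transcriptional \code{CCA} tail; references whose genomic copy
#' already ends in CCA are not re-extended. Reads are aligned against
#' these models so that tail status can be read off the 3' alignment
#' endpoint.
#'
#' @param x a \code{TrnaCollapseGroups}.
#' @return a named \code{DNAStringSet}.
#' @export
setGeneric("modelSeqs", function(x) standardGeneric("modelSeqs"))

#' @rdname StrandedCoverage-class
#' @param x,object a \code{StrandedCoverage}.
#' @export
setGeneric("forwardDepth", function(x) standardGeneric("forwardDepth"))

#' @rdname StrandedCoverage-class
#' @export
setGeneric("reverseDepth", function(x) standardGeneric("reverseDepth"))

#' @rdname StrandedCoverage-class
#' @export
setGeneric("scaffoldName", function(x) standardGeneric("scaffoldName"))

#' @export
#' @rdname TrnaReferenceSet-class
setMethod("refSequences", "TrnaReferenceSet", function(x) x@sequences)

#' @export
#' @rdname TrnaReferenceSet-class
setMethod("refMeta", "TrnaReferenceSet", function(x) x@meta)

#' @export
#' @rdname TrnaReferenceSet-class
setMethod("refIds", "TrnaReferenceSet", function(x) as.character(x@meta$id))

#' @export
#' @rdname TrnaReferenceSet-class
setMethod("length", "TrnaReferenceSet", function(x) length(x@sequences))

#' @export
#' @rdname TrnaReferenceSet-class
#' @param i index (id or position).
setMethod("[", "TrnaReferenceSet", function(x, i) {
  if (is.character(i)) i <- match(i, refIds(x))
  new("TrnaReferenceSet", sequences = x@sequences[i], meta = x@meta[i, ])
})

setMethod("show", "TrnaReferenceSet", function(object) {
  m <- object@meta
  cat("TrnaReferenceSet with", length(object), "references\n")
  if (length(object)) {
    tab <- table(m$origin)
    cat("  origins:", paste(sprintf("%s=%d", names(tab), tab), collapse = ", "), "\n")
    cat("  spike-ins:", sum(m$is_spike_in), "\n")
    cat("  body length range:", paste(range(width(object@sequences)), collapse = "-"), "nt\n")
  }
})

#' @export
#' @rdname TrnaCollapseGroups-class
setMethod("groupTable", "TrnaCollapseGroups", function(x) x@groups)

#' @export
#' @rdname TrnaCollapseGroups-class
setMethod("groupIds", "TrnaCollapseGroups", function(x)
  as.character(x@groups$group_id))

#' @export
#' @rdname TrnaCollapseGroups-class
setMethod("representativeSeqs", "TrnaCollapseGroups", function(x) x@representatives)

#' @export
#' @rdname TrnaCollapseGroups-class
setMethod("length", "TrnaCollapseGroups", function(x) nrow(x@groups))

#' @export
#' @rdname modelSeqs
setMethod("modelSeqs", "TrnaCollapseGroups", function(x) {
  reps <- as.character(x@representatives)
  ext <- ifelse(x@groups$cca_encoded, reps, paste0(reps, "CCA"))
  out <- DNAStringSet(ext)
  names(out) <- x@groups$group_id
  out
})

setMethod("show", "TrnaCollapseGroups", function(object) {
  cat("TrnaCollapseGroups:", length(object), "groups over",
      length(object@refs), "references\n")
  n <- object@groups$n_members
  if (length(n))
    cat("  group sizes:", paste(sprintf("%d x size %d", as.integer(table(n)),
        as.integer(names(table(n)))), collapse = ", "), "\n")
})

#' @export
#' @rdname StrandedCoverage-class
setMethod("forwardDepth", "StrandedCoverage", function(x) x@forward)

#' @export
#' @rdname StrandedCoverage-class
setMethod("reverseDepth", "StrandedCoverage", function(x) x@reverse)

#' @export
#' @rdname StrandedCoverage-class
setMethod("scaffoldName", "StrandedCoverage", function(x) x@scaffold)

#' @export
#' @rdname StrandedCoverage-class
setMethod("length", "StrandedCoverage", function(x) length(x@forward))

setMethod("show", "StrandedCoverage", function(object) {
  cat("StrandedCoverage for", object@scaffold, "(", length(object), "bp )\n")
  cat("  mean depth: forward", round(mean(object@forward), 2),
      "reverse", round(mean(object@reverse), 2), "\n")
})
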