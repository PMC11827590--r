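#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<- Rle
#' @importFrom Biostrings DNAStringSet DNAString readDNAStringSet writeXStringSet
NULL

setClassUnion("characterOrNULL", c("character", "NULL"))

#' Reference set of tRNA gene models
#'
#' Holds the mature gene-body sequences of a set of tRNA references
#' together with per-gene metadata. Sequences are stored WITHOUT the
#' post-transcriptional CCA tail unless the genomic copy itself ends in
#' CCA (\code{cca_encoded}).
#'
#' Metadata columns (one row per sequence, in sequence order):
#' \describe{
#'   \item{id}{unique gene/transcript label}
#'   \item{origin}{one of \code{native_mito}, \code{plastid_derived},
#'     \code{fungal_derived}, \code{bacterial_derived}, \code{nuclear},
#'     \code{spike_in}}
#'   \item{anticodon}{anticodon trimer (DNA alphabet)}
#'   \item{amino_acid}{amino-acid label for the isoacceptor family}
#'   \item{discriminator}{the final base of the gene body (the unpaired
#'     base immediately 5' of the post-transcriptional CCA)}
#'   \item{cca_encoded}{logical; TRUE when the genomic sequence already
#'     ends in CCA so no tail is appended to form the mature model}
#'   \item{is_spike_in}{logical; spike-in controls are uncharged by
#'     construction}
#'   \item{anticodon_start}{optional 0-based offset of the anticodon
#'     trimer on the gene body (NA when unknown)}
#'   \item{locus_family}{optional label grouping gene copies of one
#'     locus family for aggregated expression reporting}
#' }
#'
#' @slot sequences a \linkS4class{DNAStringSet} of gene-body sequences.
#' @slot meta a \linkS4class{DataFrame} of per-gene metadata.
#' @seealso \code{\link{loadTrnaReferences}}, \code{\link{collapseIdentical}}
#' @export
setClass("TrnaReferenceSet",
  representation(sequences = "DNAStringSet", meta = "DataFrame"))

.valid_origins <- c("native_mito", "plastid_derived", "fungal_derived",
                    "bacterial_derived", "nuclear", "spike_in")

setValidity("TrnaReferenceSet", function(object) {
  sq <- object@sequences
  m <- object@meta
  msgs <- character(0)
  if (length(sq) != nrow(m))
    return("number of sequences and metadata rows differ")
  need <- c("id", "origin", "anticodon", "amino_acid", "discriminator",
            "cca_encoded", "is_spike_in")
  miss <- setdiff(need, colnames(m))
  if (length(miss))
    return(paste("missing metadata columns:", paste(miss, collapse = ", ")))
  if (anyDuplicated(m$id))
    msgs <- c(msgs, paste("duplicate reference ids:",
                          paste(unique(m$id[duplicated(m$id)]), collapse = ", ")))
  if (!identical(names(sq), as.character(m$id)))
    msgs <- c(msgs, "sequence names do not match metadata ids")
  chars <- as.character(sq)
  bad <- grepl("[^ACGT]", chars)
  if (any(bad)) {
    i <- which(bad)[1L]
    pos <- regexpr("[^ACGT]", chars[i])
    msgs <- c(msgs, sprintf("sequence '%s' has non-ACGT character at position %d",
                            m$id[i], as.integer(pos)))
  }
  if (any(nchar(chars) == 0L))
    msgs <- c(msgs, "empty sequence present")
  if (!all(m$origin %in% .valid_origins))
    msgs <- c(msgs, paste("invalid origin value(s):",
                          paste(setdiff(m$origin, .valid_origins), collapse = ", ")))
  last <- substr(chars, nchar(chars), nchar(chars))
  ncc <- !m$cca_encoded & nchar(chars) > 0L
  if (any(ncc & m$discriminator != last))
    msgs <- c(msgs, sprintf(
      "discriminator does not equal last base of sequence for: %s",
      paste(m$id[ncc & m$discriminator != last], collapse = ", ")))
  enc <- m$cca_encoded & nchar(chars) >= 3L
  tail3 <- substr(chars, pmax(1L, nchar(chars) - 2L), nchar(chars))
  if (any(m$cca_encoded & (nchar(chars) < 3L | tail3 != "CCA")))
    msgs <- c(msgs, sprintf(
      "cca_encoded=TRUE but sequence does not end in CCA for: %s",
      paste(m$id[m$cca_encoded & (nchar(chars) < 3L | tail3 != "CCA")],
            collapse = ", ")))
  if (length(msgs)) msgs else TRUE
})

#' Collapse groups of sequence-identical references
#'
#' A partition of a \linkS4class{TrnaReferenceSet} into groups of
#' byte-identical sequences. Reads are mapped at group level because
#' identical gene copies are indistinguishable in mapping. The group id
#' is the lexicographically smallest member id.
#'
#' @slot groups a \linkS4class{DataFrame} with columns \code{group_id},
#'   \code{member_ids} (CharacterList), \code{n_members},
#'   \code{discriminator}, \code{cca_encoded}, \code{is_spike_in},
#'   \code{anticodon_start}, \code{locus_family}.
#' @slot representatives a \linkS4class{DNAStringSet} named by group id
#'   holding the shared gene-body sequence of each group.
#' @slot refs the originating \linkS4class{TrnaReferenceSet}.
#' @export
setClass("TrnaCollapseGroups",
  representation(groups = "DataFrame", representatives = "DNAStringSet",
                 refs = "TrnaReferenceSet"))

setValidity("TrnaCollapseGroups", function(object) {
  g <- object@groups
  msgs <- character(0)
  if (length(object@representatives) != nrow(g))
    return("representatives and group table differ in length")
  members <- unlist(g$member_ids)
  all_ids <- object@refs@meta$id
  if (!setequal(members, all_ids) || length(members) != length(all_ids))
    msgs <- c(msgs, "groups are not a partition of the reference set")
  if (anyDuplicated(g$group_id))
    msgs <- c(msgs, "duplicate group ids")
  if (length(msgs)) msgs else TRUE
})

#' Parameters of the charged tRNA-seq read simulator
#'
#' Encapsulates the generative model for one library: per-reference
#' abundance weights and charging fractions, the CCA-vs-CA tailing
#' profile, modification-induced misincorporation/deletion sites,
#' 3' exonucleolytic truncation, 5' terminal-transferase artifacts,
#' base-call error, and the periodate efficiency applied to unprotected
#' 3' termini in treated libraries.
#'
#' @slot abundance named nonnegative weights, one per reference id.
#' @slot charging named charging fractions in [0,1], one per reference.
#'   Spike-in references are forced to 0.
#' @slot chargingCa named charging fractions applied to CA-tailed
#'   molecules (defaults to \code{charging}); full-length CCA tails and
#'   CA-tailed molecules can be aminoacylated at different levels.
#' @slot tailCaProb named probabilities that the post-transcriptional
#'   tail is CA rather than CCA.
#' @slot modSites data.frame with columns \code{id}, \code{pos} (0-based
#'   on the gene body), \code{mis_rate}, \code{del_rate}.
#' @slot truncProbs probability vector over 0,1,2,... additional missing
#'   3' nucleotides (index 1 = 0 missing).
#' @slot p5ExtRate probability of an untemplated 1-3 nt 5' extension.
#' @slot seqErrorRate per-base substitution error probability.
#' @slot periodateEfficiency probability that an unprotected terminal
#'   nucleotide is removed under periodate treatment.
#' @slot nReads number of reads to draw.
#' @slot seed RNG seed (mandatory; the simulator is deterministic).
#' @seealso \code{\link{simTrnaParams}}, \code{\link{simulateTrnaSeq}}
#' @export
setClass("SimTrnaParams",
  representation(abundance = "numeric", charging = "numeric",
                 chargingCa = "numeric",
                 tailCaProb = "numeric", modSites = "data.frame",
                 truncProbs = "numeric", p5ExtRate = "numeric",
                 seqErrorRate = "numeric", periodateEfficiency = "numeric",
                 nReads = "integer", seed = "integer"))

setValidity("SimTrnaParams", function(object) {
  msgs <- character(0)
  pr01 <- function(x, what) {
    if (any(is.na(x)) || any(x < 0) || any(x > 1))
      sprintf("%s must be probabilities in [0,1]", what) else character(0)
  }
  if (any(object@abundance < 0) || sum(object@abundance) <= 0)
    msgs <- c(msgs, "abundance weights must be nonnegative with positive sum")
  msgs <- c(msgs, pr01(object@charging, "charging fractions"),
            pr01(object@chargingCa, "CA-cohort charging fractions"),
            pr01(object@tailCaProb, "tail CA probabilities"),
            pr01(object@p5ExtRate, "p5ExtRate"),
            pr01(object@seqErrorRate, "seqErrorRate"),
            pr01(object@periodateEfficiency, "periodateEfficiency"))
  if (length(object@truncProbs) < 1L || any(object@truncProbs < 0) ||
      abs(sum(object@truncProbs) - 1) > 1e-8)
    msgs <- c(msgs, "truncProbs must be a probability vector summing to 1")
  if (nrow(object@modSites) &&
      !all(c("id", "pos", "mis_rate", "del_rate") %in% colnames(object@modSites)))
    msgs <- c(msgs, "modSites needs columns id, pos, mis_rate, del_rate")
  if (object@nReads <= 0L) msgs <- c(msgs, "nReads must be positive")
  if (length(object@seed) != 1L || is.na(object@seed))
    msgs <- c(msgs, "seed is mandatory")
  if (length(msgs)) msgs else TRUE
})

#' Strand-specific per-position coverage of one scaffold
#'
#' Read-count depth at every position of a scaffold, split by transcript
#' strand, stored run-length encoded.
#'
#' @slot scaffold scaffold name.
#' @slot forward,reverse integer \linkS4class{Rle} of per-position depth
#'   (0-based positions; lengths equal the scaffold length).
#' @seealso \code{\link{buildCoverage}}, \code{\link{windowDepths}},
#'   \code{\link{intergenicPercentile}}
#' @export
setClass("StrandedCoverage",
  representation(scaffold = "character", forward = "Rle", reverse = "Rle"))

setValidity("StrandedCoverage", function(object) {
  msgs <- character(0)
  if (length(object@forward) != length(object@reverse))
    msgs <- c(msgs, "forward and reverse tracks differ in length")
  if (min(object@forward) < 0 || min(object@reverse) < 0)
    msgs <- c(msgs, "negative depth")
  if (length(msgs)) msgs else TRUE
})
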