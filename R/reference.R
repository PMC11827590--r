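#' @include AllClasses.R AllGenerics.R
#' @importFrom IRanges width IRanges CharacterList IntegerList
#' @importFrom utils read.delim write.table
NULL

#' Construct a TrnaReferenceSet from in-memory objects
#'
#' @param sequences named character vector or \code{DNAStringSet} of
#'   gene-body sequences (no post-transcriptional CCA unless genomically
#'   encoded).
#' @param meta data.frame of per-gene metadata; see
#'   \linkS4class{TrnaReferenceSet} for the required columns. Optional
#'   columns \code{anticodon_start} and \code{locus_family} are filled
#'   with \code{NA} when absent. When \code{anticodon_start} is missing
#'   for a gene, the anticodon trimer is searched for in the central
#'   portion of the sequence and used when it occurs there exactly once.
#' @return a validated \linkS4class{TrnaReferenceSet}.
#' @export
trnaReferenceSet <- function(sequences, meta) {
  if (!is(sequences, "DNAStringSet")) {
    nm <- names(sequences)
    sequences <- DNAStringSet(toupper(as.character(sequences)))
    names(sequences) <- nm
  }
  meta <- as.data.frame(meta, stringsAsFactors = FALSE)
  if (!"id" %in% colnames(meta)) stop("metadata must contain an 'id' column")
  meta$id <- as.character(meta$id)
  if (anyDuplicated(meta$id))
    stop("duplicate ids in metadata: ",
         paste(unique(meta$id[duplicated(meta$id)]), collapse = ", "))
  if (is.null(names(sequences)))
    stop("sequences must be named by reference id")
  missing_meta <- setdiff(names(sequences), meta$id)
  if (length(missing_meta))
    stop("no metadata row for sequence id(s): ",
         paste(missing_meta, collapse = ", "))
  extra <- setdiff(meta$id, names(sequences))
  if (length(extra))
    stop("metadata row without sequence for id(s): ",
         paste(extra, collapse = ", "))
  meta <- meta[match(names(sequences), meta$id), , drop = FALSE]
  meta$cca_encoded <- as.logical(meta$cca_encoded)
  meta$is_spike_in <- as.logical(meta$is_spike_in)
  if (is.null(meta$anticodon_start)) meta$anticodon_start <- NA_integer_
  meta$anticodon_start <- suppressWarnings(as.integer(meta$anticodon_start))
  if (is.null(meta$locus_family)) meta$locus_family <- NA_character_
  chars <- as.character(sequences)
  fill <- which(is.na(meta$anticodon_start) & !is.na(meta$anticodon) &
                nchar(meta$anticodon) == 3L)
  for (i in fill)
    meta$anticodon_start[i] <- .locate_anticodon(chars[i], meta$anticodon[i])
  obj <- new("TrnaReferenceSet", sequences = sequences,
             meta = DataFrame(meta, row.names = NULL))
  validObject(obj)
  obj
}

# The anticodon sits in the central loop; accept a hit only when the
# trimer occurs exactly once in the middle half of the gene body.
.locate_anticodon <- function(seq, anticodon) {
  n <- nchar(seq)
  lo <- floor(n / 4); hi <- ceiling(3 * n / 4)
  hits <- gregexpr(anticodon, seq, fixed = TRUE)[[1L]]
  hits <- hits[hits > 0L]
  hits <- hits[hits - 1L >= lo & hits - 1L + 3L <= hi]
  if (length(hits) == 1L) as.integer(hits - 1L) else NA_integer_
}

#' Load a tRNA reference set from FASTA plus a metadata table
#'
#' Reads gene-body sequences from FASTA and joins them with a
#' tab-separated metadata sidecar keyed by sequence id. Every FASTA
#' record must have a metadata row; extra or missing rows are hard
#' errors naming the offending ids, as are non-ACGT characters (with
#' position) and inconsistent discriminator / cca_encoded declarations.
#'
#' @param fasta_path path to the reference FASTA.
#' @param meta_path path to a tab-delimited metadata table with header
#'   \code{id origin anticodon amino_acid discriminator cca_encoded
#'   is_spike_in} (+ optional \code{anticodon_start}, \code{locus_family}).
#' @return a validated \linkS4class{TrnaReferenceSet}.
#' @examples
#' fa <- tempfile(fileext = ".fa"); tsv <- tempfile(fileext = ".tsv")
#' writeLines(c(">t1", "GGGCCCATAGCTCAGTGGTAGAGC"), fa)
#' write.table(data.frame(id = "t1", origin = "native_mito",
#'   anticodon = "CAT", amino_acid = "Met", discriminator = "C",
#'   cca_encoded = FALSE, is_spike_in = FALSE),
#'   tsv, sep = "\t", row.names = FALSE, quote = FALSE)
#' refs <- loadTrnaReferences(fa, tsv)
#' @export
loadTrnaReferences <- function(fasta_path, meta_path) {
  if (!file.exists(fasta_path)) stop("FASTA not found: ", fasta_path)
  if (!file.exists(meta_path)) stop("metadata table not found: ", meta_path)
  sq <- readDNAStringSet(fasta_path)
  names(sq) <- sub("\\s.*$", "", names(sq))
  meta <- read.delim(meta_path, stringsAsFactors = FALSE)
  trnaReferenceSet(sq, meta)
}

#' Collapse sequence-identical references into mapping groups
#'
#' Partitions a reference set by exact full-length sequence equality.
#' Identical gene copies are indistinguishable in mapping, so reads are
#' assigned at group level; a read hitting a multi-member group still
#' counts as uniquely mapped. Group ids are the lexicographically
#' smallest member id, making the partition invariant to input order.
#'
#' @param refs a \linkS4class{TrnaReferenceSet}.
#' @return a \linkS4class{TrnaCollapseGroups}.
#' @export
collapseIdentical <- function(refs) {
  stopifnot(is(refs, "TrnaReferenceSet"))
  chars <- as.character(refs@sequences)
  m <- refs@meta
  key <- factor(chars, levels = unique(chars[order(chars, method = "radix")]))
  members <- split(as.character(m$id), key)
  members <- lapply(members, function(x) sort(x, method = "radix"))
  names(members) <- NULL
  gid <- vapply(members, `[`, character(1), 1L)
  ord <- order(gid, method = "radix")
  members <- members[ord]; gid <- gid[ord]
  first <- match(vapply(members, `[`, character(1), 1L), m$id)
  cca_enc <- vapply(members, function(ids) {
    v <- m$cca_encoded[match(ids, m$id)]
    if (length(unique(v)) > 1L)
      stop("members of an identical-sequence group disagree on cca_encoded: ",
           paste(ids, collapse = ", "))
    v[1L]
  }, logical(1))
  g <- DataFrame(
    group_id = gid,
    member_ids = CharacterList(members),
    n_members = lengths(members),
    discriminator = as.character(m$discriminator[first]),
    cca_encoded = cca_enc,
    is_spike_in = vapply(members, function(ids)
      any(m$is_spike_in[match(ids, m$id)]), logical(1)),
    anticodon = as.character(m$anticodon[first]),
    anticodon_start = m$anticodon_start[first],
    locus_family = as.character(m$locus_family[first]),
    row.names = NULL)
  reps <- refs@sequences[first]
  names(reps) <- gid
  obj <- new("TrnaCollapseGroups", groups = g, representatives = reps,
             refs = refs)
  validObject(obj)
  obj
}

#' Map reference ids to their collapse group ids
#'
#' @param groups a \linkS4class{TrnaCollapseGroups}.
#' @return named character vector: reference id -> group id.
#' @export
refToGroupMap <- function(groups) {
  g <- groups@groups
  ids <- unlist(g$member_ids)
  out <- rep(as.character(g$group_id), g$n_members)
  names(out) <- ids
  out
}

#' Drop references identical to sequences from another genome
#'
#' Removes references whose gene-body sequence is byte-identical to any
#' sequence in \code{other_genome_seqs} (e.g. mitochondrial gene copies
#' identical to their plastid-encoded counterparts, which cannot be
#' attributed to either genome by mapping). Each exclusion is reported
#' via \code{message()}.
#'
#' @param refs a \linkS4class{TrnaReferenceSet}.
#' @param other_genome_seqs character vector or \code{DNAStringSet} of
#'   competing sequences.
#' @return the filtered \linkS4class{TrnaReferenceSet}.
#' @export
excludeAmbiguousWith <- function(refs, other_genome_seqs) {
  stopifnot(is(refs, "TrnaReferenceSet"))
  other <- toupper(as.character(other_genome_seqs))
  if (!length(other)) return(refs)
  hit <- as.character(refs@sequences) %in% other
  if (any(hit)) {
    for (id in refIds(refs)[hit])
      message("excluding '", id, "': identical to a competing genome sequence")
    refs <- refs[!hit]
  }
  refs
}
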