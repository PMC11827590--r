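#' @include AllClasses.R reference.R
#' @importFrom Biostrings pairwiseAlignment nucleotideSubstitutionMatrix
#'   mismatchTable indel subject
#' @importFrom IRanges narrow
#' @importFrom Rsamtools asBam scanBam ScanBamParam scanBamFlag
NULL

#' Alignment scoring parameters
#'
#' Defaults are strict enough to separate tRNA isoacceptors (60-90 nt,
#' typically well diverged) while tolerating modification-induced
#' errors. A gap of length k costs \code{gap_open + k * gap_ext}.
#' Up to \code{max_clip_5p} 5' bases may be clipped without penalty to
#' absorb untemplated reverse-transcriptase additions at the read 5'
#' end. Reads scoring below \code{min_score_frac * match * read_length}
#' are reported unmapped.
#'
#' @param match,mismatch,gap_open,gap_ext scoring values (penalties
#'   positive for \code{gap_open}/\code{gap_ext}).
#' @param min_score_frac fraction of the perfect score required to map.
#' @param max_clip_5p maximum penalty-free 5' soft clip.
#' @return a list of class \code{"alignScoring"}.
#' @export
alignScoring <- function(match = 2, mismatch = -3, gap_open = 5,
                         gap_ext = 2, min_score_frac = 0.6,
                         max_clip_5p = 3L) {
  stopifnot(match > 0, mismatch < 0, gap_open >= 0, gap_ext >= 0,
            min_score_frac >= 0, max_clip_5p >= 0)
  structure(list(match = match, mismatch = mismatch, gap_open = gap_open,
                 gap_ext = gap_ext, min_score_frac = min_score_frac,
                 max_clip_5p = as.integer(max_clip_5p)),
            class = "alignScoring")
}

.submat <- function(scoring)
  nucleotideSubstitutionMatrix(match = scoring$match,
                               mismatch = scoring$mismatch, baseOnly = TRUE)

#' Semi-global alignment score of one read against one reference
#'
#' The read is aligned end to end; reference overhangs at either end are
#' free ("fit" alignment), so the read's 3' endpoint on the reference is
#' faithfully located.
#'
#' @param read,ref character or \code{DNAString} sequences.
#' @param scoring an \code{\link{alignScoring}} object.
#' @return numeric alignment score.
#' @export
semiGlobalScore <- function(read, ref, scoring = alignScoring()) {
  pairwiseAlignment(DNAStringSet(as.character(read)),
                    DNAString(as.character(ref)),
                    substitutionMatrix = .submat(scoring),
                    gapOpening = scoring$gap_open,
                    gapExtension = scoring$gap_ext,
                    type = "global-local", scoreOnly = TRUE)
}

#' Align tRNA-seq reads to collapse-group models
#'
#' Each read is aligned to every group's CCA-extended representative
#' with end-aware semi-global alignment (read global, reference local),
#' trying penalty-free 5' clips of 0..\code{max_clip_5p} bases and
#' keeping the best score (smallest sufficient clip). The best-scoring
#' group wins; score ties across distinct groups are never broken
#' arbitrarily — the read is reported ambiguous (\code{unique = FALSE}).
#' Reads below the score threshold are reported unmapped.
#'
#' @param reads a named \code{DNAStringSet}, or a FASTQ file path.
#' @param groups a \linkS4class{TrnaCollapseGroups}.
#' @param scoring an \code{\link{alignScoring}} object.
#' @return a \code{DataFrame} with one row per read: read_id, group_id
#'   (or "ambiguous"/"unmapped"), status, unique, score, ref_start /
#'   ref_end (0-based half-open on the CCA-extended model),
#'   soft_clip_5p, read_len, read_3p_bases (last 3 read bases),
#'   mismatch_pos / mismatch_base / deletion_pos (0-based model
#'   coordinates; IntegerList/CharacterList) and n_insertion.
#' @export
alignReads <- function(reads, groups, scoring = alignScoring()) {
  stopifnot(is(groups, "TrnaCollapseGroups"))
  if (is.character(reads) && length(reads) == 1L && file.exists(reads))
    reads <- readDNAStringSet(reads, format = "fastq")
  stopifnot(is(reads, "DNAStringSet"), length(reads) > 0L)
  if (is.null(names(reads)))
    names(reads) <- sprintf("read%06d", seq_along(reads))
  models <- modelSeqs(groups)
  ng <- length(models)
  n <- length(reads)
  sm <- .submat(scoring)
  clips <- 0:scoring$max_clip_5p
  # score[read, group] maximised over penalty-free 5' clips
  best_score <- matrix(-Inf, n, ng)
  best_clip <- matrix(0L, n, ng)
  for (cl in clips) {
    ok <- width(reads) > cl + 1L
    if (!any(ok)) next
    sub <- narrow(reads[ok], start = cl + 1L)
    for (g in seq_len(ng)) {
      sc <- pairwiseAlignment(sub, models[[g]], substitutionMatrix = sm,
                              gapOpening = scoring$gap_open,
                              gapExtension = scoring$gap_ext,
                              type = "global-local", scoreOnly = TRUE)
      oki <- which(ok)
      better <- sc > best_score[oki, g] + 1e-9
      best_score[oki[better], g] <- sc[better]
      best_clip[oki[better], g] <- cl
    }
  }
  top <- apply(best_score, 1L, max)
  n_top <- rowSums(best_score >= top - 1e-9)
  threshold <- scoring$min_score_frac * scoring$match * width(reads)
  status <- ifelse(top < threshold, "unmapped",
                   ifelse(n_top > 1L, "ambiguous", "unique"))
  gsel <- max.col(best_score, ties.method = "first")
  empty_int <- IntegerList(rep(list(integer(0)), n))
  empty_chr <- CharacterList(rep(list(character(0)), n))
  out <- DataFrame(
    read_id = names(reads),
    group_id = ifelse(status == "unique", names(models)[gsel], status),
    status = status, unique = status == "unique", score = top,
    ref_start = NA_integer_, ref_end = NA_integer_,
    soft_clip_5p = NA_integer_, read_len = width(reads),
    read_3p_bases = substr(as.character(reads),
                           pmax(1L, width(reads) - 2L), width(reads)),
    mismatch_pos = empty_int, mismatch_base = empty_chr,
    deletion_pos = empty_int, n_insertion = NA_integer_,
    row.names = NULL)
  # full realignment of assigned reads to their winning group only
  for (g in seq_len(ng)) {
    idx <- which(status == "unique" & gsel == g)
    if (!length(idx)) next
    cl <- best_clip[cbind(idx, g)]
    for (c2 in unique(cl)) {
      i2 <- idx[cl == c2]
      sub <- narrow(reads[i2], start = c2 + 1L)
      al <- pairwiseAlignment(sub, models[[g]], substitutionMatrix = sm,
                              gapOpening = scoring$gap_open,
                              gapExtension = scoring$gap_ext,
                              type = "global-local")
      out$ref_start[i2] <- start(subject(al)) - 1L
      out$ref_end[i2] <- end(subject(al))
      out$soft_clip_5p[i2] <- c2
      mt <- mismatchTable(al)
      if (nrow(mt)) {
        mp <- split(as.integer(mt$SubjectStart) - 1L,
                    factor(mt$PatternId, levels = seq_along(i2)))
        mb <- split(as.character(mt$PatternSubstring),
                    factor(mt$PatternId, levels = seq_along(i2)))
        out$mismatch_pos[i2] <- IntegerList(mp)
        out$mismatch_base[i2] <- CharacterList(mb)
      }
      ind <- indel(al)
      dels <- ind@deletion
      ins <- ind@insertion
      out$n_insertion[i2] <- sum(width(ins))
      dl <- lapply(seq_along(i2), function(k) {
        d <- dels[[k]]
        if (!length(d)) return(integer(0))
        prior <- cumsum(c(0L, head(width(d), -1L)))
        first <- (start(subject(al))[k] - 1L) + start(d) + prior
        unlist(lapply(seq_along(d), function(j)
          first[j] + 0:(width(d)[j] - 1L))) - 1L
      })
      out$deletion_pos[i2] <- IntegerList(dl)
    }
  }
  out
}

#' Import alignments from a SAM file
#'
#' Converts externally produced alignments (CIGAR + MD tag) into the
#' same per-read event representation as \code{\link{alignReads}}. SAM
#' reference names must be collapse-group ids of the CCA-extended
#' models. Secondary-flagged records, or multiple records per read,
#' mark the read ambiguous.
#'
#' @param sam_path path to a SAM (or BAM) file.
#' @param groups a \linkS4class{TrnaCollapseGroups}.
#' @param scoring an \code{\link{alignScoring}} used to recompute scores
#'   from the recorded events.
#' @return a \code{DataFrame} as in \code{\link{alignReads}}.
#' @export
ingestSam <- function(sam_path, groups, scoring = alignScoring()) {
  stopifnot(is(groups, "TrnaCollapseGroups"))
  models <- modelSeqs(groups)
  bam <- .as_bam(sam_path)
  b <- scanBam(bam, param = ScanBamParam(
    what = c("qname", "flag", "rname", "pos", "cigar", "seq"),
    tag = "MD"))[[1L]]
  keep <- !is.na(b$pos)
  qname <- b$qname[keep]; flag <- b$flag[keep]
  rname <- as.character(b$rname[keep]); pos <- b$pos[keep]
  cigar <- b$cigar[keep]; seq <- as.character(b$seq[keep])
  md <- b$tag$MD[keep]
  unknown <- setdiff(unique(rname), names(models))
  if (length(unknown))
    stop("SAM record references unknown group(s): ",
         paste(unknown, collapse = ", "))
  secondary <- bitwAnd(flag, 256L) > 0L
  multi <- qname %in% c(qname[secondary], qname[duplicated(qname)])
  n <- length(qname)
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    ev <- .walk_cigar_md(cigar[i], md[i], pos[i], seq[i])
    amb <- multi[i] || secondary[i]
    score <- scoring$match * ev$n_match + scoring$mismatch * ev$n_mismatch -
      sum(scoring$gap_open + scoring$gap_ext * ev$del_lens) -
      sum(scoring$gap_open + scoring$gap_ext * ev$ins_lens)
    rows[[i]] <- list(
      read_id = qname[i],
      group_id = if (amb) "ambiguous" else rname[i],
      status = if (amb) "ambiguous" else "unique",
      unique = !amb, score = score,
      ref_start = pos[i] - 1L, ref_end = ev$ref_end,
      soft_clip_5p = ev$clip5, read_len = nchar(seq[i]),
      read_3p_bases = substr(seq[i], max(1L, nchar(seq[i]) - 2L),
                             nchar(seq[i])),
      mismatch_pos = ev$mismatch_pos, mismatch_base = ev$mismatch_base,
      deletion_pos = ev$deletion_pos, n_insertion = sum(ev$ins_lens))
  }
  prim <- !secondary
  rows <- rows[prim]
  DataFrame(
    read_id = vapply(rows, `[[`, character(1), "read_id"),
    group_id = vapply(rows, `[[`, character(1), "group_id"),
    status = vapply(rows, `[[`, character(1), "status"),
    unique = vapply(rows, `[[`, logical(1), "unique"),
    score = vapply(rows, `[[`, numeric(1), "score"),
    ref_start = vapply(rows, `[[`, integer(1), "ref_start"),
    ref_end = vapply(rows, `[[`, integer(1), "ref_end"),
    soft_clip_5p = vapply(rows, `[[`, integer(1), "soft_clip_5p"),
    read_len = vapply(rows, `[[`, integer(1), "read_len"),
    read_3p_bases = vapply(rows, `[[`, character(1), "read_3p_bases"),
    mismatch_pos = IntegerList(lapply(rows, `[[`, "mismatch_pos")),
    mismatch_base = CharacterList(lapply(rows, `[[`, "mismatch_base")),
    deletion_pos = IntegerList(lapply(rows, `[[`, "deletion_pos")),
    n_insertion = vapply(rows, function(r) as.integer(r$n_insertion),
                         integer(1)),
    row.names = NULL)
}

.as_bam <- function(path) {
  if (grepl("\\.bam$", path, ignore.case = TRUE)) return(path)
  dest <- tempfile(fileext = "")
  asBam(path, dest, overwrite = TRUE, indexDestination = FALSE)
}

# joint CIGAR + MD walk: per-position mismatch and deletion calls in
# 0-based reference coordinates, plus the reference end offset
.walk_cigar_md <- function(cigar, md, pos, seq) {
  toks <- regmatches(cigar, gregexpr("\\d+[MIDNSHP=X]", cigar))[[1L]]
  lens <- as.integer(sub("[A-Z=]$", "", toks))
  kind <- sub("^\\d+", "", toks)
  refpos <- pos                      # 1-based
  readpos <- 1L
  clip5 <- if (length(kind) && kind[1L] == "S") lens[1L] else 0L
  del_pos <- integer(0); del_lens <- integer(0); ins_lens <- integer(0)
  n_m_cols <- 0L
  # map reference positions covered by M/=/X onto read positions
  ref_of_m <- integer(0); read_of_m <- integer(0)
  for (k in seq_along(kind)) {
    w <- lens[k]
    switch(kind[k],
      "M" = , "=" = , "X" = {
        ref_of_m <- c(ref_of_m, refpos + 0:(w - 1L))
        read_of_m <- c(read_of_m, readpos + 0:(w - 1L))
        refpos <- refpos + w; readpos <- readpos + w; n_m_cols <- n_m_cols + w
      },
      "I" = { ins_lens <- c(ins_lens, w); readpos <- readpos + w },
      "D" = , "N" = {
        del_pos <- c(del_pos, refpos + 0:(w - 1L))
        del_lens <- c(del_lens, w); refpos <- refpos + w
      },
      "S" = { readpos <- readpos + w },
      "H" = , "P" = NULL)
  }
  mism_ref <- integer(0); mism_base <- character(0)
  if (!is.na(md) && nzchar(md)) {
    mtoks <- regmatches(md, gregexpr("\\d+|\\^[A-Z]+|[A-Z]", md))[[1L]]
    mcol <- 0L                       # index into the M columns
    for (t in mtoks) {
      if (grepl("^\\d+$", t)) {
        mcol <- mcol + as.integer(t)
      } else if (startsWith(t, "^")) {
        # deletion: already covered by CIGAR D ops; consumes no M column
      } else {
        mcol <- mcol + 1L
        mism_ref <- c(mism_ref, ref_of_m[mcol])
        mism_base <- c(mism_base, substr(seq, read_of_m[mcol],
                                         read_of_m[mcol]))
      }
    }
  }
  list(ref_end = refpos - 1L,        # 0-based half-open end
       clip5 = clip5,
       n_match = n_m_cols - length(mism_ref),
       n_mismatch = length(mism_ref),
       mismatch_pos = mism_ref - 1L,
       mismatch_base = mism_base,
       deletion_pos = del_pos - 1L,
       del_lens = del_lens, ins_lens = ins_lens)
}
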