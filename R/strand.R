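## Y-adapter strand deconvolution.
##
## Each read begins with one of two adapter arms; which one, combined
## with the alignment orientation, identifies the biological strand the
## molecule derived from: forward-group reads aligning reverse (flag 16)
## and reverse-group reads aligning forward (flag 0) come from the
## original top (OT) strand; the other two combinations come from the
## original bottom (OB) strand. After normalisation OT reads carry flag
## 0 and OB reads flag 16.

#' Classify reads by ligated adapter
#'
#' Matches the forward and reverse 5' adapter arms against the start of
#' each read by semi-global (free-end) edit-distance alignment; a match
#' requires edit distance <= floor(max_error_rate * adapter length).
#' When both arms match, the smaller edit distance wins and ties are
#' left unclassified. Classified reads are trimmed of their 5' arm and,
#' when found, their 3' arm; classification by the 5' arm alone is
#' accepted when the read does not reach the 3' adapter.
#'
#' @param reads data.frame with read_id, seq, qual (see [read_fastq()]).
#' @param adapters an [adapter_config()].
#' @return data.frame with read_id, group ("forward"/"reverse"/
#'   "unclassified"), seq and qual (trimmed for classified reads,
#'   untouched otherwise), ed5 and ed3 (adapter edit distances; NA when
#'   unmatched).
#' @export
classify_reads <- function(reads, adapters = adapter_config()) {
  n <- nrow(reads)
  if (!n) {
    return(data.frame(read_id = character(0), group = character(0),
                      seq = character(0), qual = character(0),
                      ed5 = integer(0), ed3 = integer(0),
                      stringsAsFactors = FALSE))
  }
  f5 <- adapter_hits_5p(reads$seq, adapters$forward_5p)
  r5 <- adapter_hits_5p(reads$seq, adapters$reverse_5p)
  max_f <- floor(adapters$max_error_rate * nchar(adapters$forward_5p))
  max_r <- floor(adapters$max_error_rate * nchar(adapters$reverse_5p))
  ok_f <- f5$ed <= max_f
  ok_r <- r5$ed <= max_r
  group <- rep("unclassified", n)
  group[ok_f & (!ok_r | f5$ed < r5$ed)] <- "forward"
  group[ok_r & (!ok_f | r5$ed < f5$ed)] <- "reverse"

  out <- data.frame(read_id = reads$read_id, group = group,
                    seq = reads$seq, qual = reads$qual,
                    ed5 = NA_integer_, ed3 = NA_integer_,
                    stringsAsFactors = FALSE)
  for (g in c("forward", "reverse")) {
    idx <- which(group == g)
    if (!length(idx)) next
    hit5 <- if (g == "forward") f5 else r5
    a3 <- if (g == "forward") adapters$forward_3p else adapters$reverse_3p
    from <- hit5$end[idx] + 1L
    trimmed <- substr(reads$seq[idx], from, nchar(reads$seq[idx]))
    tqual <- substr(reads$qual[idx], from, nchar(reads$qual[idx]))
    h3 <- adapter_hits_3p(trimmed, a3)
    max3 <- floor(adapters$max_error_rate * nchar(a3))
    cut <- ifelse(!is.na(h3$ed) & h3$ed <= max3, h3$start - 1L,
                  nchar(trimmed))
    out$seq[idx] <- substr(trimmed, 1L, cut)
    out$qual[idx] <- substr(tqual, 1L, cut)
    out$ed5[idx] <- hit5$ed[idx]
    out$ed3[idx] <- ifelse(!is.na(h3$ed) & h3$ed <= max3, h3$ed, NA_integer_)
  }
  out
}

#' Classify a single read
#'
#' Convenience wrapper around [classify_reads()] for one sequence.
#'
#' @param seq read sequence.
#' @param qual optional quality string (defaults to constant Q30).
#' @param adapters an [adapter_config()].
#' @return one-row data.frame as from [classify_reads()].
#' @export
classify_strand <- function(seq, qual = NULL, adapters = adapter_config()) {
  if (!nzchar(seq)) stop("empty read sequence")
  if (is.null(qual)) qual <- const_qual(nchar(seq))
  classify_reads(data.frame(read_id = "read", seq = seq, qual = qual,
                            stringsAsFactors = FALSE), adapters)
}

## Best semi-global match of `adapter` inside the first
## nchar(adapter) + 30 bases of each read. Returns per-read edit
## distance and 1-based end position of the match.
adapter_hits_5p <- function(seqs, adapter) {
  w <- pmin(nchar(seqs), nchar(adapter) + 30L)
  win <- substr(seqs, 1L, w)
  al <- edit_align(win, adapter)
  list(ed = al$ed, end = al$end)
}

adapter_hits_3p <- function(seqs, adapter) {
  len <- nchar(seqs)
  w <- pmin(len, nchar(adapter) + 30L)
  win <- substr(seqs, len - w + 1L, len)
  al <- edit_align(win, adapter)
  list(ed = al$ed, start = len - w + al$start)
}

## Edit-distance alignment of a single adapter (global) inside each
## window (local): score with match 0 / mismatch -1 / gap -1, so the
## score is minus the edit distance.
edit_align <- function(windows, adapter) {
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = 0, mismatch = -1,
                                                  baseOnly = FALSE)
  pat <- Biostrings::DNAStringSet(windows)
  al <- Biostrings::pairwiseAlignment(
    pattern = pat, subject = Biostrings::DNAString(adapter),
    type = "local-global", substitutionMatrix = mat,
    gapOpening = 0, gapExtension = 1)
  pr <- Biostrings::pattern(al)
  list(ed = as.integer(-Biostrings::score(al)),
       start = BiocGenerics::start(pr),
       end = BiocGenerics::end(pr))
}

#' Normalise alignment flags to biological strands
#'
#' Applies the strand rule: (forward group, flag 16) and (reverse group,
#' flag 0) derive from the OT strand and are rewritten to flag 0;
#' (reverse, 16) and (forward, 0) derive from OB and become flag 16.
#' The original flag is kept in `flag_raw`. Already-normalised input
#' (with a `bio_strand` column) is returned unchanged, making the
#' operation idempotent.
#'
#' @param aln alignment data.frame; strand group taken from `groups` or
#'   from an existing `group` column.
#' @param groups optional named character vector (read id -> group).
#' @return alignment data.frame with bio_strand, rewritten flag, and
#'   flag_raw columns.
#' @export
normalize_strand <- function(aln, groups = NULL) {
  if (!is.null(aln$bio_strand)) return(aln)
  g <- if (!is.null(groups)) unname(groups[aln$qname]) else aln$group
  if (is.null(g)) stop("no strand group available for normalisation")
  if (any(is.na(g) | !g %in% c("forward", "reverse"))) {
    stop("unclassified or unknown strand group; normalisation rejected")
  }
  rev_bit <- bitwAnd(aln$flag, 16L) != 0L
  ot <- (g == "forward" & rev_bit) | (g == "reverse" & !rev_bit)
  aln$flag_raw <- aln$flag
  aln$group <- g
  aln$bio_strand <- ifelse(ot, "OT", "OB")
  aln$flag <- ifelse(ot, 0L, 16L)
  aln
}

#' Mark PCR duplicates with coordinate tolerance
#'
#' Reads sharing contig and biological strand whose 5' and 3' reference
#' coordinates both lie within `pos_tolerance` of a duplicate group's
#' anchor are flagged; the highest-MAPQ member (ties: longest reference
#' span, then lexicographically smallest read id) stays unflagged.
#'
#' Coordinate-based duplicate detection is meaningless on an amplicon
#' contig where every genuine molecule shares both ends (the spike-in
#' control); such contigs can be excluded.
#'
#' @param aln coordinate-sorted, strand-normalised alignment data.frame.
#' @param pos_tolerance coordinate slack in bp (default 20).
#' @param exclude_contigs contigs whose reads are never flagged.
#' @return `aln` with a logical `is_dup` column.
#' @export
mark_duplicates <- function(aln, pos_tolerance = 20,
                            exclude_contigs = NULL) {
  if (is.null(aln$bio_strand)) stop("normalise strands before duplicate marking")
  for (cn in unique(aln$rname)) {
    p <- aln$pos[aln$rname == cn]
    if (is.unsorted(p)) stop("alignments must be coordinate-sorted")
  }
  ref_len <- cigar_ref_len(aln$cigar)
  end <- aln$pos + ref_len - 1L
  aln$is_dup <- FALSE
  idx_all <- seq_len(nrow(aln))
  if (!is.null(exclude_contigs)) {
    idx_all <- idx_all[!aln$rname %in% exclude_contigs]
  }
  groups <- split(idx_all,
                  paste(aln$rname[idx_all], aln$bio_strand[idx_all],
                        sep = "\r"))
  for (idx in groups) {
    if (length(idx) < 2L) next
    starts <- aln$pos[idx]; ends <- end[idx]
    anchors_s <- integer(0); anchors_e <- integer(0)
    members <- list()
    for (j in seq_along(idx)) {
      hit <- which(abs(anchors_s - starts[j]) <= pos_tolerance &
                     abs(anchors_e - ends[j]) <= pos_tolerance)
      if (length(hit)) {
        members[[hit[1]]] <- c(members[[hit[1]]], idx[j])
      } else {
        anchors_s <- c(anchors_s, starts[j])
        anchors_e <- c(anchors_e, ends[j])
        members[[length(members) + 1L]] <- idx[j]
      }
    }
    for (mem in members) {
      if (length(mem) < 2L) next
      o <- order(-aln$mapq[mem], -ref_len[mem], aln$qname[mem])
      aln$is_dup[mem[o[-1L]]] <- TRUE
    }
  }
  aln
}

#' Filter alignments by mapping quality and duplicate state
#'
#' Retains reads with MAPQ >= `min_mapq` (default 10, i.e. MAPQ 9 is
#' excluded and MAPQ 10 retained) whose duplicate flag is unset.
#'
#' @param aln alignment data.frame.
#' @param min_mapq minimum mapping quality.
#' @return filtered alignment data.frame.
#' @export
filter_alignments <- function(aln, min_mapq = 10) {
  keep <- aln$mapq >= min_mapq
  if (!is.null(aln$is_dup)) keep <- keep & !aln$is_dup
  out <- aln[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}
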