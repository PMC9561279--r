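## Strand-specific cytosine pileup with TAPS semantics.
##
## TAPS converts modified cytosines to T (the inverse of bisulfite), so
## the modification level of a site is the converted fraction:
## n_converted / (n_converted + n_unconverted). Reads contribute only to
## the strand they derive from: original-top (OT) reads to + strand
## cytosines, original-bottom (OB) reads to - strand cytosines (reference
## G on the + strand, where conversion shows as G->A in the aligned
## sequence). That inversion happens here, once, and nowhere else.

#' Enumerate reference cytosines with context
#'
#' Lists every cytosine of the requested contexts on both strands of a
#' contig. Contexts follow the usual convention (CpG: C followed by G;
#' CHG: CHG; CHH: everything else), mirrored on the minus strand.
#' Cytosines too close to the contig end for a full context default to
#' CHH.
#'
#' @param seqv contig sequence (character).
#' @param contexts subset of c("CpG", "CHG", "CHH").
#' @return data.frame with columns pos (0-based position on the + strand
#'   of the cytosine's C, i.e. the G position for - strand sites), strand,
#'   context, ordered by pos.
#' @export
cytosine_sites <- function(seqv, contexts = c("CpG", "CHG", "CHH")) {
  ch <- strsplit(seqv, "", fixed = TRUE)[[1]]
  L <- length(ch)
  pad <- function(i) {
    out <- rep("N", length(i))
    ok <- i >= 1L & i <= L
    out[ok] <- ch[i[ok]]
    out
  }

  cpos <- which(ch == "C")           # 1-based
  ctx_plus <- rep("CHH", length(cpos))
  ctx_plus[pad(cpos + 1L) == "G"] <- "CpG"
  ctx_plus[ctx_plus == "CHH" & pad(cpos + 2L) == "G"] <- "CHG"

  gpos <- which(ch == "G")
  ctx_minus <- rep("CHH", length(gpos))
  ctx_minus[pad(gpos - 1L) == "C"] <- "CpG"
  ctx_minus[ctx_minus == "CHH" & pad(gpos - 2L) == "C"] <- "CHG"

  out <- data.frame(pos = c(cpos - 1L, gpos - 1L),
                    strand = c(rep("+", length(cpos)),
                               rep("-", length(gpos))),
                    context = c(ctx_plus, ctx_minus),
                    stringsAsFactors = FALSE)
  out <- out[out$context %in% contexts, , drop = FALSE]
  out <- out[order(out$pos, out$strand), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' TAPS modification level
#'
#' The inverted counting rule: level = n_converted /
#' (n_converted + n_unconverted); `NA` when no informative bases cover
#' the site.
#'
#' @param n_converted,n_unconverted non-negative integer counts (T-like
#'   and C-like bases at the reference cytosine, respectively).
#' @return numeric level in `[0, 1]`, or `NA` for zero depth.
#' @export
modification_level <- function(n_converted, n_unconverted) {
  if (any(n_converted < 0) || any(n_unconverted < 0)) {
    stop("counts must be non-negative")
  }
  d <- n_converted + n_unconverted
  ifelse(d > 0, n_converted / d, NA_real_)
}

#' Per-cytosine pileup over normalised alignments
#'
#' CIGAR-aware column counts at reference cytosines. Only OT-strand reads
#' are counted at + strand cytosines and only OB-strand reads at - strand
#' cytosines; the complementary base is read for the latter (A converted,
#' G unconverted). Deletions spanning a site and unexpected bases count
#' as `n_other` and never enter the level denominator. Bases below
#' `min_base_qual` are skipped entirely.
#'
#' @param aln alignment data.frame (see [read_alignments()]) that has
#'   been strand-normalised ([normalize_strand()]) and filtered
#'   ([filter_alignments()]).
#' @param reference named character vector of contig sequences, a
#'   `Biostrings::DNAStringSet`, or a FASTA path.
#' @param contexts cytosine contexts to report (default CpG only).
#' @param min_base_qual minimum phred base quality (default 13).
#' @return data.frame of site calls: contig, pos (0-based), strand,
#'   context, n_converted, n_unconverted, n_other, level. Only covered
#'   sites are returned.
#' @export
pileup_cytosines <- function(aln, reference, contexts = "CpG",
                             min_base_qual = 13) {
  reference <- as_reference(reference)
  if (is.null(aln$bio_strand) || anyNA(aln$bio_strand)) {
    stop("alignments must be strand-normalised before pileup")
  }
  bad <- !(aln$rname %in% names(reference))
  if (any(bad)) {
    stop("contig absent from reference: ",
         paste(unique(aln$rname[bad]), collapse = ", "))
  }
  res <- list()
  for (cn in unique(aln$rname)) {
    sub <- aln[aln$rname == cn, , drop = FALSE]
    res[[cn]] <- pileup_one_contig(sub, cn, reference[[cn]], contexts,
                                   min_base_qual)
  }
  out <- do.call(rbind, c(res, list(make.row.names = FALSE)))
  rownames(out) <- NULL
  out
}

pileup_one_contig <- function(aln, contig, seqv, contexts, min_base_qual) {
  L <- nchar(seqv)
  if (any(aln$pos < 1L | aln$pos + cigar_ref_len(aln$cigar) - 1L > L)) {
    stop("alignment overhangs contig end on ", contig)
  }
  sites <- cytosine_sites(seqv, contexts)
  empty <- data.frame(contig = character(0), pos = integer(0),
                      strand = character(0), context = character(0),
                      n_converted = integer(0), n_unconverted = integer(0),
                      n_other = integer(0), level = numeric(0),
                      stringsAsFactors = FALSE)
  if (!nrow(sites) || !nrow(aln)) return(empty)

  ## split site lists by strand; positions kept 1-based internally
  sp <- sites$pos[sites$strand == "+"] + 1L
  sm <- sites$pos[sites$strand == "-"] + 1L

  acc_idx <- list(); acc_base <- list(); acc_strand <- list()
  k <- 0L
  for (i in seq_len(nrow(aln))) {
    want_plus <- aln$bio_strand[i] == "OT"
    spos <- if (want_plus) sp else sm
    if (!length(spos)) next
    blocks <- cigar_blocks(aln$cigar[i], aln$pos[i])
    for (b in seq_len(nrow(blocks))) {
      lo <- findInterval(blocks$ref_start[b] - 1L, spos) + 1L
      hi <- findInterval(blocks$ref_end[b], spos)
      if (hi < lo) next
      hitpos <- spos[lo:hi]
      if (blocks$op[b] == "D") {
        base <- rep("-", length(hitpos))
      } else {
        q <- blocks$q_start[b] + (hitpos - blocks$ref_start[b])
        base <- substring(aln$seq[i], q, q)
        if (min_base_qual > 0 && !is.na(aln$qual[i]) && nzchar(aln$qual[i]) &&
            aln$qual[i] != "*") {
          ph <- utf8ToInt(aln$qual[i])[q] - 33L
          keep <- ph >= min_base_qual
          hitpos <- hitpos[keep]; base <- base[keep]
          if (!length(hitpos)) next
        }
      }
      k <- k + 1L
      acc_idx[[k]] <- hitpos
      acc_base[[k]] <- base
      acc_strand[[k]] <- rep(if (want_plus) "+" else "-", length(hitpos))
    }
  }
  if (!k) return(empty)
  pos1 <- unlist(acc_idx); base <- unlist(acc_base)
  strand <- unlist(acc_strand)

  conv_base <- ifelse(strand == "+", "T", "A")
  unconv_base <- ifelse(strand == "+", "C", "G")
  cls <- ifelse(base == conv_base, 1L, ifelse(base == unconv_base, 2L, 3L))

  key <- paste0(pos1, strand)
  skey <- paste0(sites$pos + 1L, sites$strand)
  si <- match(key, skey)
  nsite <- nrow(sites)
  n_conv <- tabulate(si[cls == 1L], nsite)
  n_unconv <- tabulate(si[cls == 2L], nsite)
  n_other <- tabulate(si[cls == 3L], nsite)
  covered <- which(n_conv + n_unconv + n_other > 0L)
  data.frame(contig = contig,
             pos = sites$pos[covered],
             strand = sites$strand[covered],
             context = sites$context[covered],
             n_converted = n_conv[covered],
             n_unconverted = n_unconv[covered],
             n_other = n_other[covered],
             level = modification_level(n_conv[covered], n_unconv[covered]),
             stringsAsFactors = FALSE)
}

#' Merge CpG strand pairs
#'
#' Sums the + strand C at position p with its - strand partner at p+1
#' into one CpG-unit record keyed at p, recomputing the level from the
#' summed counts. Non-CpG sites are dropped.
#'
#' @param calls site-call data.frame from [pileup_cytosines()].
#' @return data.frame with strand `"."` and one row per covered CpG unit.
#' @export
merge_cpg_strands <- function(calls) {
  cg <- calls[calls$context == "CpG", , drop = FALSE]
  if (!nrow(cg)) {
    return(data.frame(contig = character(0), pos = integer(0),
                      strand = character(0), context = character(0),
                      n_converted = integer(0), n_unconverted = integer(0),
                      n_other = integer(0), level = numeric(0),
                      stringsAsFactors = FALSE))
  }
  unit <- ifelse(cg$strand == "+", cg$pos, cg$pos - 1L)
  key <- paste(cg$contig, unit, sep = ":")
  agg <- function(v) as.integer(rowsum(as.integer(v), key, reorder = TRUE))
  n_conv <- agg(cg$n_converted)
  n_unconv <- agg(cg$n_unconverted)
  n_other <- agg(cg$n_other)
  u <- sort(unique(key))
  parts <- strsplit(u, ":", fixed = TRUE)
  out <- data.frame(contig = vapply(parts, `[`, "", 1L),
                    pos = as.integer(vapply(parts, `[`, "", 2L)),
                    strand = ".",
                    context = "CpG",
                    n_converted = n_conv,
                    n_unconverted = n_unconv,
                    n_other = n_other,
                    stringsAsFactors = FALSE)
  out$level <- modification_level(out$n_converted, out$n_unconverted)
  out <- out[order(out$contig, out$pos), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write site calls as bedGraph or bedMethyl
#'
#' bedGraph columns follow the familiar methylation-caller order: contig,
#' start, end, level as a percentage, n_converted, n_unconverted; records
#' are sorted and 0-based half-open. Strand-merged calls (strand ".")
#' span 2 bp.
#'
#' @param calls site-call data.frame.
#' @param path output file.
#' @param min_depth minimum informative depth (n_converted +
#'   n_unconverted) for a site to be emitted (default 1).
#' @param format "bedGraph" or "bedmethyl".
#' @param header_info optional named character vector written as
#'   `#key=value` comment lines.
#' @return the path, invisibly.
#' @export
write_methylome <- function(calls, path, min_depth = 1,
                            format = c("bedGraph", "bedmethyl"),
                            header_info = NULL) {
  format <- match.arg(format)
  keep <- (calls$n_converted + calls$n_unconverted) >= min_depth
  calls <- calls[keep, , drop = FALSE]
  calls <- calls[order(calls$contig, calls$pos, calls$strand), , drop = FALSE]
  end <- calls$pos + ifelse(calls$strand == ".", 2L, 1L)
  lines <- character(0)
  if (!is.null(header_info)) {
    lines <- paste0("#", names(header_info), "=", header_info)
  }
  if (format == "bedGraph") {
    lines <- c(lines,
               'track type="bedGraph" description="TAPS modification level"')
    if (nrow(calls)) {
      lines <- c(lines, paste(calls$contig, calls$pos, end,
                              formatC(100 * calls$level, digits = 6,
                                      format = "fg"),
                              calls$n_converted, calls$n_unconverted,
                              sep = "\t"))
    }
  } else {
    depth <- calls$n_converted + calls$n_unconverted + calls$n_other
    strand <- ifelse(calls$strand == ".", "+", calls$strand)
    if (nrow(calls)) {
      lines <- c(lines, paste(calls$contig, calls$pos, end, "m",
                              pmin(depth, 1000L), strand,
                              calls$pos, end, "0,0,0", depth,
                              round(100 * calls$level),
                              sep = "\t"))
    }
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read a bedGraph methylome written by [write_methylome()]
#'
#' @param path bedGraph file.
#' @return site-call data.frame (strand "." for 2-bp merged records).
#' @export
read_bedgraph <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#") & !startsWith(lines, "track")]
  if (!length(lines)) {
    return(data.frame(contig = character(0), pos = integer(0),
                      strand = character(0), context = character(0),
                      n_converted = integer(0), n_unconverted = integer(0),
                      n_other = integer(0), level = numeric(0),
                      stringsAsFactors = FALSE))
  }
  f <- utils::read.table(text = lines, sep = "\t",
                         col.names = c("contig", "start", "end", "pct",
                                       "n_converted", "n_unconverted"),
                         colClasses = c("character", "integer", "integer",
                                        "numeric", "integer", "integer"))
  data.frame(contig = f$contig, pos = f$start,
             strand = ifelse(f$end - f$start == 2L, ".", "+"),
             context = "CpG",
             n_converted = f$n_converted, n_unconverted = f$n_unconverted,
             n_other = 0L,
             level = modification_level(f$n_converted, f$n_unconverted),
             stringsAsFactors = FALSE)
}

as_reference <- function(reference) {
  if (is.character(reference) && length(reference) == 1L &&
      is.null(names(reference)) && file.exists(reference)) {
    dss <- Biostrings::readDNAStringSet(reference)
    ref <- as.character(dss)
    names(ref) <- sub("\\s.*$", "", names(ref))
    return(ref)
  }
  if (methods::is(reference, "DNAStringSet")) {
    ref <- as.character(reference)
    names(ref) <- sub("\\s.*$", "", names(reference))
    return(ref)
  }
  if (is.character(reference) && !is.null(names(reference))) {
    return(reference)
  }
  if (is.list(reference) && !is.null(names(reference))) {
    return(unlist(reference))
  }
  stop("reference must be a named character vector, DNAStringSet, or FASTA path")
}
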