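## Dataset-level summaries: N50, CpG coverage overlap between call
## sets, binned methylation correlation, and structural-variant overlap
## with flank extension.

#' N50 of a read-length distribution
#'
#' The smallest length L such that reads of length >= L together contain
#' at least half of all sequenced bases.
#'
#' @param lengths positive read lengths in bp.
#' @return N50 in bp.
#' @export
read_n50 <- function(lengths) {
  if (!length(lengths)) stop("empty length vector")
  if (any(lengths <= 0)) stop("lengths must be positive")
  s <- sort(lengths, decreasing = TRUE)
  cs <- cumsum(as.numeric(s))
  s[which(cs >= sum(as.numeric(s)) / 2)[1]]
}

#' CpG coverage overlap between two call sets
#'
#' Counts sites covered at depth >= `min_depth` in one set only, in
#' both, or in the other only; sites are keyed by contig and (merged
#' CpG) coordinate.
#'
#' @param calls_a,calls_b site-call data.frames (same reference).
#' @param min_depth minimum informative depth for membership (default 5,
#'   the usual "at least five reads covered" rule).
#' @return named integer vector c(only_a, both, only_b).
#' @export
coverage_overlap <- function(calls_a, calls_b, min_depth = 5) {
  keys <- function(d) {
    depth <- d$n_converted + d$n_unconverted
    unique(paste(d$contig, d$pos, sep = ":")[depth >= min_depth])
  }
  ka <- keys(calls_a); kb <- keys(calls_b)
  c(only_a = length(setdiff(ka, kb)),
    both = length(intersect(ka, kb)),
    only_b = length(setdiff(kb, ka)))
}

#' Binned methylation correlation between two call sets
#'
#' Averages levels of sites with depth >= `min_depth` within fixed-width
#' genomic bins and returns the Pearson correlation over bins present in
#' both sets.
#'
#' @param calls_a,calls_b site-call data.frames.
#' @param bin_size bin width in bp.
#' @param min_depth minimum informative depth per site (default 5).
#' @return Pearson r.
#' @export
binned_correlation <- function(calls_a, calls_b, bin_size, min_depth = 5) {
  binned <- function(d) {
    depth <- d$n_converted + d$n_unconverted
    d <- d[depth >= min_depth & !is.na(d$level), , drop = FALSE]
    bin <- paste(d$contig, d$pos %/% bin_size, sep = ":")
    tapply(d$level, bin, mean)
  }
  ma <- binned(calls_a); mb <- binned(calls_b)
  common <- intersect(names(ma), names(mb))
  if (length(common) < 2L) stop("fewer than 2 bins shared between call sets")
  stats::cor(ma[common], mb[common])
}

#' Structural-variant overlap with flank extension
#'
#' Extends every interval by `flank` bp on both sides (clipped at 0) and
#' counts, per matching SV type, intervals of `svs_a` overlapping an
#' extended interval of `svs_b` and vice versa. `both` is the number of
#' `svs_a` records with at least one type-matched overlap; `matched_b`
#' is the analogous count for `svs_b`.
#'
#' @param svs_a,svs_b data.frames with contig, start, end (0-based
#'   half-open; insertions may have start == end) and type.
#' @param flank flank extension in bp (default 5; 0 gives plain
#'   intersection).
#' @return named integer vector c(only_a, both, only_b, matched_b).
#' @export
sv_overlap <- function(svs_a, svs_b, flank = 5) {
  stopifnot(all(svs_a$start <= svs_a$end), all(svs_b$start <= svs_b$end))
  matched <- function(x, y) {
    hit <- logical(nrow(x))
    for (tp in unique(x$type)) {
      xi <- which(x$type == tp)
      yi <- which(y$type == tp)
      if (!length(yi)) next
      for (cn in unique(x$contig[xi])) {
        xc <- xi[x$contig[xi] == cn]
        yc <- yi[y$contig[yi] == cn]
        if (!length(yc)) next
        ## extended, closed interval overlap on the integer lattice:
        ## [s - flank, e + flank) intersects when starts/ends cross
        rx <- IRanges::IRanges(start = pmax(x$start[xc] - flank, 0L) + 1L,
                               end = x$end[xc] + flank)
        ry <- IRanges::IRanges(start = pmax(y$start[yc] - flank, 0L) + 1L,
                               end = y$end[yc] + flank)
        ov <- IRanges::countOverlaps(rx, ry, minoverlap = 1L)
        hit[xc] <- hit[xc] | ov > 0L
      }
    }
    hit
  }
  ha <- matched(svs_a, svs_b)
  hb <- matched(svs_b, svs_a)
  c(only_a = sum(!ha), both = sum(ha), only_b = sum(!hb),
    matched_b = sum(hb))
}

#' Read SV intervals from BED
#'
#' Expects contig, start, end and (4th column) type; missing type
#' becomes "other".
#'
#' @param path BED path.
#' @return data.frame contig, start, end, type, length.
#' @export
read_sv_bed <- function(path) {
  f <- utils::read.table(path, sep = "\t", header = FALSE,
                         stringsAsFactors = FALSE)
  type <- if (ncol(f) >= 4) as.character(f[[4]]) else "other"
  data.frame(contig = as.character(f[[1]]), start = as.integer(f[[2]]),
              end = as.integer(f[[3]]), type = type,
              length = as.integer(f[[3]]) - as.integer(f[[2]]),
              stringsAsFactors = FALSE)
}

#' Read SV records from a VCF
#'
#' Minimal reader extracting SVTYPE and SVLEN from INFO; insertions get
#' start == end at the breakpoint, other types span `abs(SVLEN)` (or
#' END-POS when END is present).
#'
#' @param path VCF path.
#' @param min_size drop SVs shorter than this (default 50 bp, the usual
#'   operational SV definition).
#' @return data.frame contig, start, end, type, length.
#' @export
read_sv_vcf <- function(path, min_size = 50) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  info_field <- function(info, key) {
    m <- regmatches(info, regexpr(paste0("(^|;)", key, "=[^;]+"), info))
    out <- rep(NA_character_, length(info))
    hit <- lengths(regmatches(info, gregexpr(paste0("(^|;)", key, "=[^;]+"),
                                             info))) > 0
    out[hit] <- sub(paste0(".*", key, "="), "", m)
    out
  }
  svtype <- info_field(fix$INFO, "SVTYPE")
  svlen <- suppressWarnings(as.numeric(info_field(fix$INFO, "SVLEN")))
  endv <- suppressWarnings(as.numeric(info_field(fix$INFO, "END")))
  pos0 <- as.integer(fix$POS) - 1L
  type <- ifelse(svtype %in% c("INS", "DEL"), svtype, "other")
  len <- abs(svlen)
  len[is.na(len) & !is.na(endv)] <- (endv - pos0 - 1L)[is.na(len) & !is.na(endv)]
  len[is.na(len)] <- 0
  end <- ifelse(type == "INS", pos0, pos0 + as.integer(len))
  out <- data.frame(contig = fix$CHROM, start = pos0, end = as.integer(end),
                    type = type, length = as.integer(len),
                    stringsAsFactors = FALSE)
  out[!is.na(out$length) & out$length > min_size, , drop = FALSE]
}

#' Fraction of sites overlapping an annotation BED
#'
#' Generic site-vs-annotation overlap (e.g. repeat regions): the
#' fraction of call sites falling inside any annotated interval.
#'
#' @param calls site-call data.frame.
#' @param bed data.frame with contig, start, end (0-based half-open).
#' @return fraction in `[0, 1]`.
#' @export
annotation_overlap <- function(calls, bed) {
  if (!nrow(calls)) return(NA_real_)
  hit <- logical(nrow(calls))
  for (cn in unique(calls$contig)) {
    ci <- which(calls$contig == cn)
    bi <- which(bed$contig == cn)
    if (!length(bi)) next
    sites <- IRanges::IRanges(start = calls$pos[ci] + 1L, width = 1L)
    ann <- IRanges::IRanges(start = bed$start[bi] + 1L, end = bed$end[bi])
    hit[ci] <- IRanges::countOverlaps(sites, ann) > 0L
  }
  mean(hit)
}
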