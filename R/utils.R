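## Small shared helpers: sequence manipulation and CIGAR arithmetic.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Reverse complement of character DNA sequences
#'
#' Vectorised over a character vector; only A/C/G/T/N are handled.
#'
#' @param x character vector of DNA sequences.
#' @return character vector of reverse complements.
#' @export
revcomp <- function(x) {
  vapply(x, function(s) {
    rawToChar(rev(charToRaw(chartr("ACGTN", "TGCAN", s))))
  }, character(1), USE.NAMES = FALSE)
}

## Parse a CIGAR string into integer lengths and single-character ops.
parse_cigar <- function(cigar) {
  m <- gregexpr("\\d+[MIDNSHP=X]", cigar)[[1]]
  if (m[1] == -1L) stop("malformed CIGAR: ", cigar)
  toks <- regmatches(cigar, gregexpr("\\d+[MIDNSHP=X]", cigar))[[1]]
  n <- nchar(toks)
  list(len = as.integer(substr(toks, 1L, n - 1L)),
       op  = substr(toks, n, n))
}

cigar_ref_len <- function(cigar) {
  vapply(cigar, function(cg) {
    p <- parse_cigar(cg)
    sum(p$len[p$op %in% c("M", "D", "N", "=", "X")])
  }, integer(1), USE.NAMES = FALSE)
}

cigar_query_len <- function(cigar) {
  vapply(cigar, function(cg) {
    p <- parse_cigar(cg)
    sum(p$len[p$op %in% c("M", "I", "S", "=", "X")])
  }, integer(1), USE.NAMES = FALSE)
}

## Block decomposition of one alignment: for every reference-consuming
## CIGAR op, the covered reference interval (1-based, inclusive) and, for
## aligned blocks, the query offset of its first base. Deletion/skip
## blocks get qstart NA. Soft clips and insertions advance the query only.
cigar_blocks <- function(cigar, pos) {
  p <- parse_cigar(cigar)
  nb <- length(p$len)
  rs <- integer(0); re <- integer(0); qs <- integer(0); op <- character(0)
  rcur <- pos
  qcur <- 1L
  for (i in seq_len(nb)) {
    l <- p$len[i]; o <- p$op[i]
    if (o %in% c("M", "=", "X")) {
      rs <- c(rs, rcur); re <- c(re, rcur + l - 1L); qs <- c(qs, qcur)
      op <- c(op, "M")
      rcur <- rcur + l; qcur <- qcur + l
    } else if (o %in% c("D", "N")) {
      rs <- c(rs, rcur); re <- c(re, rcur + l - 1L); qs <- c(qs, NA_integer_)
      op <- c(op, "D")
      rcur <- rcur + l
    } else if (o %in% c("I", "S")) {
      qcur <- qcur + l
    } # H, P consume nothing we track
  }
  data.frame(ref_start = rs, ref_end = re, q_start = qs, op = op,
             stringsAsFactors = FALSE)
}

## iid or first-order-Markov random DNA. `cpg_tilt` multiplies the
## probability of G following C by exp(cpg_tilt) (0 = iid), so negative
## values give the CpG depletion typical of mammalian genomes.
random_dna <- function(length, gc = 0.5, cpg_tilt = 0) {
  bases <- c("A", "C", "G", "T")
  p0 <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  if (cpg_tilt == 0) {
    return(paste(sample(bases, length, replace = TRUE, prob = p0),
                 collapse = ""))
  }
  pc <- p0
  pc[3] <- pc[3] * exp(cpg_tilt)
  pc <- pc / sum(pc)
  cum0 <- cumsum(p0); cumc <- cumsum(pc)
  u <- stats::runif(length)
  out <- integer(length)
  prev_c <- FALSE
  for (i in seq_len(length)) {
    cm <- if (prev_c) cumc else cum0
    b <- findInterval(u[i], cm, left.open = TRUE) + 1L
    out[i] <- b
    prev_c <- (b == 2L)
  }
  paste(bases[out], collapse = "")
}

## Constant-quality string at the given phred score.
const_qual <- function(n, phred = 30L) {
  strrep(intToUtf8(phred + 33L), n)
}

## Apply iid substitution errors to a DNA string at the given per-base rate.
add_substitutions <- function(seq, rate) {
  if (rate <= 0) return(seq)
  n <- nchar(seq)
  hit <- which(stats::runif(n) < rate)
  if (!length(hit)) return(seq)
  ch <- strsplit(seq, "", fixed = TRUE)[[1]]
  bases <- c("A", "C", "G", "T")
  for (i in hit) {
    ch[i] <- sample(setdiff(bases, ch[i]), 1L)
  }
  paste(ch, collapse = "")
}
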