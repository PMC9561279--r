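## Haplotype tagging and allele-specific methylation.
##
## Long reads span several kilobases and therefore usually overlap at
## least one heterozygous variant, which lets each read be assigned to a
## parental haplotype. One TAPS-specific caveat: conversion mimics C->T
## (G->A on the opposite strand) changes, so variants whose two alleles
## are C/T or A/G are uninformative and must be skipped.

#' Assign reads to haplotypes at phased heterozygous SNPs
#'
#' Every read votes at each overlapped variant according to its observed
#' base (CIGAR-aware). Conversion-confounded variants are skipped
#' strand-awarely: C/T allele pairs are uninformative for OT-derived
#' reads (TAPS conversion shows as C->T there) and A/G pairs for
#' OB-derived reads (conversion shows as G->A in reference-forward
#' orientation). A read is assigned to the haplotype with
#' the majority of votes when the margin (supporting - conflicting) is
#' at least `min_votes` and the conflicting fraction is at most
#' `max_conflict_fraction`.
#'
#' @param aln alignment data.frame (normalised; SEQ in reference-forward
#'   orientation).
#' @param variants data.frame from [read_phased_vcf()] or the simulator
#'   truth: contig, pos (0-based), ref, alt, hap (haplotype of the alt).
#' @param min_votes minimum vote margin (default 1).
#' @param max_conflict_fraction maximum tolerated conflicting-vote
#'   fraction (default 0.2).
#' @return data.frame read_id, haplotype (1, 2 or NA), n_support,
#'   n_conflict.
#' @export
haplotag_reads <- function(aln, variants, min_votes = 1,
                           max_conflict_fraction = 0.2) {
  if (is.null(aln$bio_strand)) {
    stop("alignments must be strand-normalised before haplotagging")
  }
  v <- variants
  lo <- pmin(v$ref, v$alt); hi <- pmax(v$ref, v$alt)
  conf_ct <- lo == "C" & hi == "T"  # unreadable on OT reads
  conf_ag <- lo == "A" & hi == "G"  # unreadable on OB reads
  allele1 <- ifelse(v$hap == 1L, v$alt, v$ref)
  allele2 <- ifelse(v$hap == 1L, v$ref, v$alt)

  n <- nrow(aln)
  hap <- rep(NA_integer_, n)
  n_support <- integer(n); n_conflict <- integer(n)
  ref_len <- cigar_ref_len(aln$cigar)
  for (i in seq_len(n)) {
    conf <- if (aln$bio_strand[i] == "OT") conf_ct else conf_ag
    sel <- which(!conf & v$contig == aln$rname[i] &
                   v$pos >= aln$pos[i] - 1L &
                   v$pos < aln$pos[i] - 1L + ref_len[i])
    if (!length(sel)) next
    blocks <- cigar_blocks(aln$cigar[i], aln$pos[i])
    votes1 <- 0L; votes2 <- 0L
    for (s in sel) {
      p1 <- v$pos[s] + 1L
      b <- which(blocks$ref_start <= p1 & blocks$ref_end >= p1 &
                   blocks$op == "M")
      if (!length(b)) next
      q <- blocks$q_start[b[1]] + (p1 - blocks$ref_start[b[1]])
      base <- substr(aln$seq[i], q, q)
      if (base == allele1[s]) votes1 <- votes1 + 1L
      else if (base == allele2[s]) votes2 <- votes2 + 1L
      ## other bases: sequencing error or conversion artefact; no vote
    }
    tot <- votes1 + votes2
    if (!tot) next
    win <- max(votes1, votes2); lose <- min(votes1, votes2)
    n_support[i] <- win; n_conflict[i] <- lose
    if (win - lose >= min_votes && lose / tot <= max_conflict_fraction) {
      hap[i] <- if (votes1 >= votes2) 1L else 2L
    }
  }
  data.frame(read_id = aln$qname, haplotype = hap,
             n_support = n_support, n_conflict = n_conflict,
             stringsAsFactors = FALSE)
}

#' Per-haplotype methylomes
#'
#' Runs the cytosine pileup separately on each haplotype's reads;
#' unassigned reads are excluded. A haplotype with no assigned reads
#' yields an empty call set with a warning.
#'
#' @param haplotags output of [haplotag_reads()].
#' @param aln filtered, normalised alignment data.frame.
#' @param reference reference (see [pileup_cytosines()]).
#' @param ... passed on to [pileup_cytosines()].
#' @return list with elements `hap1` and `hap2` (site-call data.frames).
#' @export
allele_methylomes <- function(haplotags, aln, reference, ...) {
  hap <- haplotags$haplotype[match(aln$qname, haplotags$read_id)]
  one <- function(h) {
    sub <- aln[!is.na(hap) & hap == h, , drop = FALSE]
    if (!nrow(sub)) {
      warning("haplotype ", h, " has no assigned reads")
      return(data.frame(contig = character(0), pos = integer(0),
                        strand = character(0), context = character(0),
                        n_converted = integer(0), n_unconverted = integer(0),
                        n_other = integer(0), level = numeric(0),
                        stringsAsFactors = FALSE))
    }
    pileup_cytosines(sub, reference, ...)
  }
  list(hap1 = one(1L), hap2 = one(2L))
}

#' Test CpGs for allele-specific methylation
#'
#' For each CpG covered with at least `min_depth_per_allele` informative
#' bases on both haplotypes, a two-sided Fisher exact test compares the
#' converted/unconverted counts between alleles; p-values are
#' Benjamini-Hochberg adjusted across all tested CpGs.
#'
#' @param hap1_calls,hap2_calls site-call data.frames on shared
#'   coordinates (e.g. from [allele_methylomes()], optionally
#'   strand-merged).
#' @param min_depth_per_allele minimum informative depth per allele
#'   (default 5).
#' @return data.frame contig, pos, strand, per-allele counts and levels,
#'   level_diff (hap1 - hap2), p_value, q_value.
#' @export
test_asm <- function(hap1_calls, hap2_calls, min_depth_per_allele = 5) {
  key <- function(d) paste(d$contig, d$pos, d$strand, sep = "\r")
  k1 <- key(hap1_calls); k2 <- key(hap2_calls)
  common <- intersect(k1, k2)
  i1 <- match(common, k1); i2 <- match(common, k2)
  d1 <- hap1_calls$n_converted[i1] + hap1_calls$n_unconverted[i1]
  d2 <- hap2_calls$n_converted[i2] + hap2_calls$n_unconverted[i2]
  keep <- d1 >= min_depth_per_allele & d2 >= min_depth_per_allele
  i1 <- i1[keep]; i2 <- i2[keep]
  n <- length(i1)
  if (!n) {
    return(data.frame(contig = character(0), pos = integer(0),
                      strand = character(0),
                      h1_converted = integer(0), h1_unconverted = integer(0),
                      h2_converted = integer(0), h2_unconverted = integer(0),
                      level_hap1 = numeric(0), level_hap2 = numeric(0),
                      level_diff = numeric(0), p_value = numeric(0),
                      q_value = numeric(0), stringsAsFactors = FALSE))
  }
  a <- hap1_calls$n_converted[i1]; b <- hap1_calls$n_unconverted[i1]
  c_ <- hap2_calls$n_converted[i2]; d_ <- hap2_calls$n_unconverted[i2]
  p <- vapply(seq_len(n), function(j) {
    stats::fisher.test(matrix(c(a[j], b[j], c_[j], d_[j]), nrow = 2,
                              byrow = TRUE))$p.value
  }, numeric(1))
  lev1 <- modification_level(a, b)
  lev2 <- modification_level(c_, d_)
  out <- data.frame(contig = hap1_calls$contig[i1],
                    pos = hap1_calls$pos[i1],
                    strand = hap1_calls$strand[i1],
                    h1_converted = a, h1_unconverted = b,
                    h2_converted = c_, h2_unconverted = d_,
                    level_hap1 = lev1, level_hap2 = lev2,
                    level_diff = lev1 - lev2,
                    p_value = p,
                    q_value = stats::p.adjust(p, method = "BH"),
                    stringsAsFactors = FALSE)
  out[order(out$contig, out$pos), , drop = FALSE]
}
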