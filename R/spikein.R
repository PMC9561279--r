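## Spike-in conversion-rate QC.
##
## The control is a PCR amplicon methylated by HpaII methyltransferase,
## so exactly the internal C of every CCGG is modified. Reads mapped to
## it measure the conversion rate (at those Cs) and the false-positive
## rate (at the remaining, unmodified cytosines). CpG sites whose 4-mer
## context is TCGG, CCGT or ACGG are plausible HpaII off-targets and are
## excluded from the false-positive denominator.

OFFTARGET_4MERS <- c("TCGG", "CCGT", "ACGG")

#' Partition spike-in cytosines into QC categories
#'
#' Classifies every cytosine on both strands of the control sequence:
#' the internal C of each CCGG (context 4-mer CCGG, read on the site's
#' own strand) is HpaII-methylated; other CpG cytosines are unmodified
#' unless their 4-mer context is an off-target motif (TCGG/CCGT/ACGG),
#' in which case they are excluded; all non-CpG cytosines form the CpH
#' set. The 4-mer places the CpG's C at the position homologous to the
#' internal C of CCGG (one base of upstream context, one downstream of
#' the G); minus-strand sites use the reverse-complement context. CpGs
#' at the sequence boundary without a full 4-mer count as unmodified.
#'
#' @param seqv spike-in sequence.
#' @return list of data.frames (`methylated`, `unmod_cpg`, `cph`,
#'   `excluded`), each with pos (0-based) and strand; together they
#'   partition all cytosines of both strands.
#' @export
partition_spikein_sites <- function(seqv) {
  sites <- cytosine_sites(seqv, contexts = c("CpG", "CHG", "CHH"))
  ch <- strsplit(seqv, "", fixed = TRUE)[[1]]
  L <- length(ch)
  pad <- function(i) {
    out <- rep("N", length(i))
    ok <- i >= 1L & i <= L
    out[ok] <- ch[i[ok]]
    out
  }

  fourmer <- character(nrow(sites))
  p1 <- sites$pos + 1L  # 1-based
  plus <- sites$strand == "+"
  fourmer[plus] <- paste0(pad(p1[plus] - 1L), pad(p1[plus]),
                          pad(p1[plus] + 1L), pad(p1[plus] + 2L))
  ## minus-strand C at + position p: its 5'->3' context on the minus
  ## strand is revcomp of + strand [p-2, p+1]
  mm <- !plus
  fourmer[mm] <- revcomp(paste0(pad(p1[mm] - 2L), pad(p1[mm] - 1L),
                                pad(p1[mm]), pad(p1[mm] + 1L)))

  cat_of <- rep("cph", nrow(sites))
  is_cpg <- sites$context == "CpG"
  cat_of[is_cpg] <- "unmod_cpg"
  cat_of[is_cpg & fourmer == "CCGG"] <- "methylated"
  cat_of[is_cpg & fourmer %in% OFFTARGET_4MERS] <- "excluded"

  mk <- function(name) {
    d <- sites[cat_of == name, c("pos", "strand"), drop = FALSE]
    rownames(d) <- NULL
    d
  }
  list(methylated = mk("methylated"), unmod_cpg = mk("unmod_cpg"),
       cph = mk("cph"), excluded = mk("excluded"))
}

#' Spike-in conversion and false-positive report
#'
#' Pools per-base counts over each site category of
#' [partition_spikein_sites()] and reports the conversion rate at
#' HpaII-methylated CpGs, the false-positive rate at unmodified CpGs
#' (off-target motifs excluded), and the false-positive rate at CpH
#' sites. Rates are pooled over bases, not averaged over sites. A
#' category with no covered sites yields `NA` with a warning.
#'
#' @param calls per-strand site calls (all contexts) restricted to the
#'   spike-in contig, from [pileup_cytosines()].
#' @param partitions output of [partition_spikein_sites()].
#' @return a `spikein_report` list: conversion_rate, fpr_cpg, fpr_cph,
#'   counts (per-category converted/total bases), n_excluded_sites.
#' @export
spikein_report <- function(calls, partitions) {
  if (length(unique(calls$contig)) > 1L) {
    stop("site calls must be restricted to the spike-in contig")
  }
  pooled <- function(part, label) {
    key <- paste(part$pos, part$strand)
    sel <- paste(calls$pos, calls$strand) %in% key
    conv <- sum(calls$n_converted[sel])
    tot <- conv + sum(calls$n_unconverted[sel])
    if (tot == 0L) {
      warning("no covered bases in spike-in category '", label, "'")
      return(c(converted = 0L, total = 0L, rate = NA_real_))
    }
    c(converted = conv, total = tot, rate = conv / tot)
  }
  m <- pooled(partitions$methylated, "methylated CpG")
  u <- pooled(partitions$unmod_cpg, "unmodified CpG")
  h <- pooled(partitions$cph, "CpH")
  structure(list(conversion_rate = unname(m["rate"]),
                 fpr_cpg = unname(u["rate"]),
                 fpr_cph = unname(h["rate"]),
                 counts = data.frame(
                   category = c("methylated_cpg", "unmod_cpg", "cph"),
                   n_converted = c(m["converted"], u["converted"],
                                   h["converted"]),
                   n_total = c(m["total"], u["total"], h["total"]),
                   row.names = NULL),
                 n_excluded_sites = nrow(partitions$excluded)),
            class = "spikein_report")
}

#' @export
print.spikein_report <- function(x, ...) {
  fmt <- function(r) if (is.na(r)) "NA" else sprintf("%.2f%%", 100 * r)
  cat("Spike-in QC report\n")
  cat("  conversion rate (HpaII-methylated CpG):", fmt(x$conversion_rate), "\n")
  cat("  false-positive rate (unmodified CpG):  ", fmt(x$fpr_cpg), "\n")
  cat("  false-positive rate (CpH):             ", fmt(x$fpr_cph), "\n")
  cat("  off-target CpG sites excluded:", x$n_excluded_sites, "\n")
  invisible(x)
}

#' Write a spike-in report as TSV
#'
#' @param report a `spikein_report`.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_spikein_report <- function(report, path) {
  df <- report$counts
  df$rate <- ifelse(df$n_total > 0, df$n_converted / df$n_total, NA_real_)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
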