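## File-format plumbing: FASTQ, FASTA, SAM/BAM, phased VCF.

#' Write reads as FASTQ
#'
#' @param reads data.frame with read_id, seq, qual.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_fastq <- function(reads, path) {
  if (!nrow(reads)) { writeLines(character(0), path); return(invisible(path)) }
  lines <- as.vector(rbind(paste0("@", reads$read_id), reads$seq,
                           "+", reads$qual))
  writeLines(lines, path)
  invisible(path)
}

#' Read a FASTQ file into a data.frame
#'
#' @param path FASTQ path.
#' @return data.frame with read_id, seq, qual.
#' @export
read_fastq <- function(path) {
  x <- withCallingHandlers(
    Biostrings::readQualityScaledDNAStringSet(path),
    warning = function(w) {
      if (grepl("metadata columns", conditionMessage(w))) {
        invokeRestart("muffleWarning")
      }
    })
  data.frame(read_id = sub("\\s.*$", "", names(x)),
             seq = as.character(x),
             qual = as.character(Biostrings::quality(x)),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Write contigs as FASTA (with .fai index)
#'
#' @param contigs named character vector of sequences.
#' @param path output FASTA path.
#' @return the path, invisibly.
#' @export
write_fasta <- function(contigs, path) {
  dss <- Biostrings::DNAStringSet(contigs)
  Biostrings::writeXStringSet(dss, path, width = 80L)
  try(Rsamtools::indexFa(path), silent = TRUE)
  invisible(path)
}

#' Write alignments as a SAM file
#'
#' Emits a coordinate-sorted SAM with @HD/@SQ/@PG header. The strand
#' group, biological strand, raw flag and duplicate state, when present
#' as columns, are carried in XG/XB/XF/XD tags.
#'
#' @param aln alignment data.frame (qname, flag, rname, pos, mapq,
#'   cigar, seq, qual and optional group/bio_strand/flag_raw/is_dup).
#' @param contig_lengths named integer vector of reference lengths.
#' @param path output SAM path.
#' @param comments optional character vector of @CO comment lines.
#' @return the path, invisibly.
#' @export
write_sam <- function(aln, contig_lengths, path, comments = NULL) {
  hd <- c("@HD\tVN:1.6\tSO:coordinate",
          sprintf("@SQ\tSN:%s\tLN:%d", names(contig_lengths),
                  as.integer(contig_lengths)),
          sprintf("@PG\tID:lrtaps\tPN:lrtaps\tVN:%s",
                  as.character(utils::packageVersion("lrtaps"))))
  if (!is.null(comments)) hd <- c(hd, paste0("@CO\t", comments))
  o <- order(match(aln$rname, names(contig_lengths)), aln$pos)
  aln <- aln[o, , drop = FALSE]
  body <- paste(aln$qname, aln$flag, aln$rname, aln$pos, aln$mapq,
                aln$cigar, "*", 0L, 0L, aln$seq, aln$qual, sep = "\t")
  opt <- rep("", nrow(aln))
  add_tag <- function(opt, col, tag, fmt = "Z") {
    if (!is.null(aln[[col]])) {
      v <- aln[[col]]
      if (fmt == "i") v <- as.integer(v)
      paste0(opt, sprintf("\t%s:%s:%s", tag, fmt, v))
    } else opt
  }
  opt <- add_tag(opt, "group", "XG")
  opt <- add_tag(opt, "bio_strand", "XB")
  opt <- add_tag(opt, "flag_raw", "XF", "i")
  if (!is.null(aln$is_dup)) {
    opt <- paste0(opt, sprintf("\tXD:i:%d", as.integer(aln$is_dup)))
  }
  writeLines(c(hd, paste0(body, opt)), path)
  invisible(path)
}

#' Read alignments from SAM or BAM into a data.frame
#'
#' SAM input is converted through `Rsamtools::asBam()`. Unmapped records
#' are dropped. XG (strand group), XB (biological strand) and XD
#' (duplicate) tags, when present, populate the corresponding columns.
#'
#' @param path SAM or BAM file.
#' @return alignment data.frame with columns qname, flag, rname, pos
#'   (1-based), mapq, cigar, seq, qual and any tag-derived columns.
#' @export
read_alignments <- function(path) {
  bam <- path
  if (grepl("\\.sam$", path, ignore.case = TRUE)) {
    dest <- tempfile(fileext = "")
    bam <- Rsamtools::asBam(path, dest, overwrite = TRUE,
                            indexDestination = FALSE)
  }
  p <- Rsamtools::ScanBamParam(
    what = c("qname", "flag", "rname", "pos", "mapq", "cigar", "seq", "qual"),
    tag = c("XG", "XB", "XD"))
  res <- Rsamtools::scanBam(bam, param = p)[[1]]
  keep <- !is.na(res$pos)
  out <- data.frame(qname = res$qname[keep],
                    flag = as.integer(res$flag[keep]),
                    rname = as.character(res$rname[keep]),
                    pos = as.integer(res$pos[keep]),
                    mapq = as.integer(res$mapq[keep]),
                    cigar = res$cigar[keep],
                    seq = as.character(res$seq)[keep],
                    qual = as.character(res$qual)[keep],
                    stringsAsFactors = FALSE)
  tg <- res$tag
  if (!is.null(tg$XG)) out$group <- tg$XG[keep]
  if (!is.null(tg$XB)) out$bio_strand <- tg$XB[keep]
  if (!is.null(tg$XD)) out$is_dup <- as.logical(tg$XD[keep])
  out
}

#' Write phased heterozygous SNPs as a minimal VCF
#'
#' One sample ("sim") with phased GT: `1|0` when the alternate allele
#' sits on haplotype 1, `0|1` when on haplotype 2.
#'
#' @param het data.frame with contig, pos (0-based), ref, alt, hap.
#' @param contig_lengths named lengths for the header.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_phased_vcf <- function(het, contig_lengths, path) {
  hd <- c("##fileformat=VCFv4.2",
          sprintf("##contig=<ID=%s,length=%d>", names(contig_lengths),
                  as.integer(contig_lengths)),
          '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
          "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tsim")
  het <- het[order(het$contig, het$pos), , drop = FALSE]
  gt <- ifelse(het$hap == 1L, "1|0", "0|1")
  body <- paste(het$contig, het$pos + 1L, ".", het$ref, het$alt, ".",
                "PASS", ".", "GT", gt, sep = "\t")
  writeLines(c(hd, body), path)
  invisible(path)
}

#' Read a phased VCF of biallelic SNPs
#'
#' Requires a phased GT field (`|` separator) for the first sample;
#' unphased records are rejected, multiallelic records dropped.
#'
#' @param path VCF path.
#' @return data.frame with contig, pos (0-based), ref, alt, hap (the
#'   haplotype carrying the alternate allele; NA for hom records).
#' @export
read_phased_vcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  gt <- vcfR::extract.gt(v, element = "GT")[, 1]
  keep <- !grepl(",", fix$ALT, fixed = TRUE)
  fix <- fix[keep, , drop = FALSE]; gt <- gt[keep]
  if (any(grepl("/", gt, fixed = TRUE))) {
    stop("VCF genotypes are unphased; phased GT (|) required")
  }
  hap <- ifelse(gt == "1|0", 1L, ifelse(gt == "0|1", 2L, NA_integer_))
  het <- !is.na(hap)
  data.frame(contig = fix$CHROM[het], pos = as.integer(fix$POS[het]) - 1L,
             ref = fix$REF[het], alt = fix$ALT[het], hap = hap[het],
             stringsAsFactors = FALSE, row.names = NULL)
}
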