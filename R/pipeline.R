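## End-to-end pipeline: classify -> (align) -> normalise -> duplicates
## -> MAPQ filter -> pileup -> outputs, in the order the stages are run
## on real libraries. Alignment itself is delegated: either a SAM/BAM
## from an external long-read aligner is supplied, or (optionally)
## minimap2 is invoked when available; the simulator's truth SAM serves
## in tests.

#' Pipeline configuration
#'
#' @param reads FASTQ of raw adapter-carrying reads.
#' @param reference reference FASTA.
#' @param out_dir output directory (created).
#' @param alignments SAM/BAM of the trimmed reads; when `NULL` and
#'   `aligner` is set, the aligner is invoked on the classified reads.
#' @param vcf optional phased VCF of heterozygous SNPs; enables ASM.
#' @param spikein_name optional spike-in contig name; enables QC.
#' @param min_mapq MAPQ threshold (default 10).
#' @param min_depth site depth threshold for summary outputs (default 5).
#' @param flank SV flank extension in bp (default 5).
#' @param adapter_error adapter max error rate (default 0.1).
#' @param contexts pileup contexts (default "CpG").
#' @param pos_tolerance duplicate-marking coordinate slack (default 20).
#' @param aligner optional aligner executable (e.g. "minimap2").
#' @param seed seed recorded in output headers.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(reads, reference, out_dir, alignments = NULL,
                            vcf = NULL, spikein_name = NULL, min_mapq = 10,
                            min_depth = 5, flank = 5, adapter_error = 0.1,
                            contexts = "CpG", pos_tolerance = 20,
                            aligner = NULL, seed = 1L) {
  thr <- c(min_mapq, min_depth, flank, adapter_error, pos_tolerance)
  if (any(thr < 0)) stop("thresholds must be non-negative")
  structure(list(reads = reads, reference = reference, out_dir = out_dir,
                 alignments = alignments, vcf = vcf,
                 spikein_name = spikein_name, min_mapq = min_mapq,
                 min_depth = min_depth, flank = flank,
                 adapter_error = adapter_error, contexts = contexts,
                 pos_tolerance = pos_tolerance, aligner = aligner,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Run the methylation-calling pipeline
#'
#' Executes classification, strand normalisation, duplicate marking,
#' MAPQ filtering, cytosine pileup and output writing. Fails with a
#' stage-named error and removes partial outputs.
#'
#' @param config a [pipeline_config()].
#' @param quiet suppress progress messages.
#' @return named list of output paths, invisibly.
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  for (f in c(config$reads, config$reference, config$alignments, config$vcf)) {
    if (!is.null(f) && !file.exists(f)) stop("missing input file: ", f)
  }
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  created <- character(0)
  note <- function(...) if (!quiet) message("[lrtaps] ", ...)
  stage <- "setup"
  tryCatch({
    hdr <- c(version = as.character(utils::packageVersion("lrtaps")),
             seed = config$seed, min_mapq = config$min_mapq,
             min_depth = config$min_depth)

    stage <- "classify"
    note("classify: adapter-based strand classification")
    reads <- read_fastq(config$reads)
    adapters <- adapter_config(max_error_rate = config$adapter_error)
    cls <- classify_reads(reads, adapters)
    out <- list()
    out$classification <- file.path(config$out_dir, "classification.tsv")
    utils::write.table(cls[, c("read_id", "group", "ed5", "ed3")],
                       out$classification, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    created <- c(created, out$classification)
    for (g in c("forward", "reverse")) {
      p <- file.path(config$out_dir, paste0(g, ".fastq"))
      write_fastq(cls[cls$group == g, c("read_id", "seq", "qual")], p)
      out[[paste0(g, "_fastq")]] <- p
      created <- c(created, p)
    }

    stage <- "align"
    aln_path <- config$alignments
    if (is.null(aln_path)) {
      if (is.null(config$aligner)) {
        stop("no alignments supplied and no aligner configured")
      }
      note("align: invoking ", config$aligner)
      aln_path <- run_external_aligner(config, out, cls)
      created <- c(created, aln_path)
    }
    aln <- read_alignments(aln_path)

    stage <- "normalize"
    note("normalize: OT/OB flag assignment")
    grp <- stats::setNames(cls$group, cls$read_id)
    aln <- aln[aln$qname %in% cls$read_id[cls$group != "unclassified"], ,
               drop = FALSE]
    aln <- normalize_strand(aln, grp)

    stage <- "duplicates"
    note("duplicates: coordinate-tolerant marking")
    aln <- aln[order(match(aln$rname, unique(aln$rname)), aln$pos), ,
               drop = FALSE]
    aln <- mark_duplicates(aln, config$pos_tolerance,
                           exclude_contigs = config$spikein_name)

    stage <- "filter"
    aln_f <- filter_alignments(aln, config$min_mapq)
    out$normalized_sam <- file.path(config$out_dir, "normalized.sam")
    ref <- as_reference(config$reference)
    write_sam(aln, nchar(ref), out$normalized_sam,
              comments = sprintf("seed=%d min_mapq=%d", config$seed,
                                 config$min_mapq))
    created <- c(created, out$normalized_sam)

    stage <- "pileup"
    note("pileup: strand-specific cytosine counting")
    contexts <- config$contexts
    if (!is.null(config$spikein_name)) {
      spike_aln <- aln_f[aln_f$rname == config$spikein_name, , drop = FALSE]
      aln_f_main <- aln_f[aln_f$rname != config$spikein_name, , drop = FALSE]
    } else {
      spike_aln <- NULL
      aln_f_main <- aln_f
    }
    calls <- if (nrow(aln_f_main)) {
      pileup_cytosines(aln_f_main, ref, contexts = contexts)
    } else {
      data.frame(contig = character(0), pos = integer(0),
                 strand = character(0), context = character(0),
                 n_converted = integer(0), n_unconverted = integer(0),
                 n_other = integer(0), level = numeric(0))
    }
    merged <- merge_cpg_strands(calls)
    out$methylome <- file.path(config$out_dir, "methylome.bedGraph")
    write_methylome(merged, out$methylome, min_depth = 1,
                    header_info = hdr)
    created <- c(created, out$methylome)

    if (!is.null(spike_aln) && nrow(spike_aln)) {
      stage <- "qc-spikein"
      note("qc-spikein: conversion-rate report")
      sp_calls <- pileup_cytosines(spike_aln, ref,
                                   contexts = c("CpG", "CHG", "CHH"))
      parts <- partition_spikein_sites(ref[[config$spikein_name]])
      rep_ <- spikein_report(sp_calls, parts)
      out$spikein_report <- file.path(config$out_dir, "spikein_report.tsv")
      write_spikein_report(rep_, out$spikein_report)
      created <- c(created, out$spikein_report)
    }

    if (!is.null(config$vcf)) {
      stage <- "phase"
      note("phase: haplotagging and ASM test")
      variants <- read_phased_vcf(config$vcf)
      tags <- haplotag_reads(aln_f_main, variants)
      out$haplotags <- file.path(config$out_dir, "haplotags.tsv")
      utils::write.table(tags, out$haplotags, sep = "\t", quote = FALSE,
                         row.names = FALSE)
      created <- c(created, out$haplotags)
      am <- allele_methylomes(tags, aln_f_main, ref,
                              contexts = contexts)
      for (h in 1:2) {
        p <- file.path(config$out_dir, sprintf("hap%d.bedGraph", h))
        write_methylome(merge_cpg_strands(am[[h]]), p, header_info = hdr)
        out[[sprintf("hap%d_methylome", h)]] <- p
        created <- c(created, p)
      }
      asm <- test_asm(merge_cpg_strands(am$hap1), merge_cpg_strands(am$hap2),
                      min_depth_per_allele = config$min_depth)
      out$asm <- file.path(config$out_dir, "asm.tsv")
      utils::write.table(asm, out$asm, sep = "\t", quote = FALSE,
                         row.names = FALSE)
      created <- c(created, out$asm)
    }

    stage <- "summarize"
    note("summarize: dataset summary")
    trimmed_len <- nchar(cls$seq[cls$group != "unclassified"])
    summary_df <- data.frame(
      metric = c("n_reads", "n_classified", "n_forward", "n_reverse",
                 "n_aligned_used", "n_duplicates", "read_n50",
                 "n_cpg_covered", "n_cpg_min_depth"),
      value = c(nrow(reads), sum(cls$group != "unclassified"),
                sum(cls$group == "forward"), sum(cls$group == "reverse"),
                nrow(aln_f), sum(aln$is_dup),
                if (length(trimmed_len)) read_n50(trimmed_len) else NA,
                nrow(merged),
                sum(merged$n_converted + merged$n_unconverted >=
                      config$min_depth)))
    out$summary <- file.path(config$out_dir, "summary.tsv")
    utils::write.table(summary_df, out$summary, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    created <- c(created, out$summary)
    invisible(out)
  }, error = function(e) {
    unlink(created)
    stop("pipeline failed at stage '", stage, "': ", conditionMessage(e),
         call. = FALSE)
  })
}

run_external_aligner <- function(config, out, cls) {
  trimmed <- file.path(config$out_dir, "trimmed.fastq")
  write_fastq(cls[cls$group != "unclassified", c("read_id", "seq", "qual")],
              trimmed)
  sam <- file.path(config$out_dir, "aligned.sam")
  status <- system2(config$aligner,
                    c("-a", "-x", "map-pb", shQuote(config$reference),
                      shQuote(trimmed)),
                    stdout = sam, stderr = FALSE)
  if (status != 0L) stop("aligner exited with status ", status)
  sam
}
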