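## TAPS long-read simulator.
##
## Molecule model: a genomic fragment is drawn (lognormal length, size
## selected), assigned a haplotype (diploid mode) and a biological strand
## of origin, OT (original top) or OB (original bottom), with p = 0.5.
## CpG modification states are realised per molecule by Bernoulli draws
## from the methylome, TAPS conversion rewrites modified (and, at the
## false-conversion rates, unmodified) cytosines of the biological strand
## as T, and the Y-shaped adapter arms are attached so that the
## forward-configuration strand is the complementary copy of the
## converted strand. Each molecule is emitted in a uniformly chosen
## sequencing orientation, which reproduces the adapter/flag bookkeeping
## of the real library: a forward-adapter read aligning to the minus
## strand (flag 16) derives from OT, and so on.

#' Y-shaped adapter configuration
#'
#' Defaults are the adapter arms of the long-read TAPS library: a read
#' beginning with `forward_5p` belongs to the forward group, one
#' beginning with `reverse_5p` to the reverse group. The pairs are
#' reverse complements of each other's opposite ends (reverse_5p =
#' revcomp(forward_3p), reverse_3p = revcomp(forward_5p)).
#'
#' @param forward_5p,forward_3p,reverse_5p,reverse_3p adapter sequences.
#' @param max_error_rate maximum edit distance per adapter base for a
#'   match (default 0.1).
#' @param min_overlap minimum matched adapter length in bp.
#' @return an `adapter_config` list.
#' @export
adapter_config <- function(
    forward_5p = "CCGAGATCTACACTCTTTCCCTACACGACGCTCTTCCGATCT",
    forward_3p = "AGATCGGAAGAGCACACGTCTGAACTCCAGTCACCGATGTATCTCGTA",
    reverse_5p = "TACGAGATACATCGGTGACTGGAGTTCAGACGTGTGCTCTTCCGATCT",
    reverse_3p = "AGATCGGAAGAGCGTCGTGTAGGGAAAGAGTGTAGATCTCGG",
    max_error_rate = 0.1, min_overlap = 10) {
  structure(list(forward_5p = forward_5p, forward_3p = forward_3p,
                 reverse_5p = reverse_5p, reverse_3p = reverse_3p,
                 max_error_rate = max_error_rate, min_overlap = min_overlap),
            class = "adapter_config")
}

#' Simulation parameters
#'
#' Defaults are the library conditions of a whole-genome long-read TAPS
#' run: 5-kb fragmentation with >3 kb size selection, spike-in at 0.5%
#' molar fraction, conversion rate 96.23% with false conversion 0.36%
#' (CpG) and 0.12% (CpH), and a HiFi-like 0.1% substitution error rate.
#'
#' @param n_reads number of molecules to emit (>= 1).
#' @param frag_median median fragment length in bp (lognormal).
#' @param frag_sigma lognormal sdlog of fragment lengths.
#' @param frag_min minimum fragment length retained by size selection.
#' @param conversion_rate probability a modified C reads as T.
#' @param false_conversion_cpg,false_conversion_cph probability an
#'   unmodified C in CpG / CpH context reads as T.
#' @param error_rate per-base substitution sequencing error.
#' @param spikein_fraction probability a molecule is a spike-in amplicon.
#' @param dup_fraction fraction of molecules re-emitted as PCR
#'   duplicates (default 0).
#' @param seed integer master seed; all randomness flows from it.
#' @return a `sim_params` list.
#' @export
sim_params <- function(n_reads = 2000, frag_median = 5000, frag_sigma = 0.4,
                       frag_min = 3000, conversion_rate = 0.9623,
                       false_conversion_cpg = 0.0036,
                       false_conversion_cph = 0.0012,
                       error_rate = 0.001, spikein_fraction = 0.005,
                       dup_fraction = 0, seed = 1L) {
  rates <- c(conversion_rate, false_conversion_cpg, false_conversion_cph,
             error_rate, spikein_fraction, dup_fraction)
  if (any(rates < 0 | rates > 1)) stop("all rates must lie in [0, 1]")
  if (n_reads < 1) stop("n_reads must be >= 1")
  structure(list(n_reads = as.integer(n_reads), frag_median = frag_median,
                 frag_sigma = frag_sigma, frag_min = frag_min,
                 conversion_rate = conversion_rate,
                 false_conversion_cpg = false_conversion_cpg,
                 false_conversion_cph = false_conversion_cph,
                 error_rate = error_rate,
                 spikein_fraction = spikein_fraction,
                 dup_fraction = dup_fraction, seed = as.integer(seed)),
            class = "sim_params")
}

#' Apply TAPS conversion to one strand sequence
#'
#' Each modified cytosine becomes T with probability `conversion_rate`;
#' each unmodified cytosine becomes T with the context-appropriate false
#' conversion rate (CpG context when the next base of the strand is G,
#' CpH otherwise). Non-C bases are untouched. Uses the current RNG
#' stream.
#'
#' @param sequence strand sequence (5'->3' of the strand being converted).
#' @param positions 1-based cytosine positions within `sequence`.
#' @param modified logical vector parallel to `positions`.
#' @param params a [sim_params()] list (only the three rates are used).
#' @return converted sequence, with attributes `n_converted_modified`
#'   and `n_false_converted` recording the changes made.
#' @export
taps_convert <- function(sequence, positions, modified, params) {
  stopifnot(length(positions) == length(modified))
  if (!length(positions)) {
    out <- sequence
    attr(out, "n_converted_modified") <- 0L
    attr(out, "n_false_converted") <- 0L
    return(out)
  }
  ch <- strsplit(sequence, "", fixed = TRUE)[[1]]
  if (any(ch[positions] != "C")) {
    stop("realized state at a non-cytosine position")
  }
  nxt <- c(ch[-1], "N")
  is_cpg <- nxt[positions] == "G"
  p <- ifelse(modified, params$conversion_rate,
              ifelse(is_cpg, params$false_conversion_cpg,
                     params$false_conversion_cph))
  hit <- stats::runif(length(positions)) < p
  ch[positions[hit]] <- "T"
  out <- paste(ch, collapse = "")
  attr(out, "n_converted_modified") <- sum(hit & modified)
  attr(out, "n_false_converted") <- sum(hit & !modified)
  out
}

#' Simulate adapter-ligated TAPS long reads with ground truth
#'
#' Draws molecules from the genome (spike-in amplicons with probability
#' `spikein_fraction` span the whole control contig), realises CpG
#' modification states from the methylome (haplotype-specific
#' `prob1`/`prob2` columns are honoured in diploid mode), converts the
#' biological strand, attaches the Y-adapter arms, emits each read in a
#' uniform sequencing orientation with substitution errors, and returns
#' the truth alignment (MAPQ 60, exact coordinates) together with
#' per-molecule and per-CpG truth tables.
#'
#' @param genome a `sim_genome` from [simulate_genome()].
#' @param methylome methylome data.frame.
#' @param params a [sim_params()] list.
#' @param adapters an [adapter_config()].
#' @param out_dir optional directory; when given, FASTQ, reference FASTA,
#'   truth SAM, truth tables, truth methylome BED and (diploid) a phased
#'   VCF are written there.
#' @return list with `reads` (data.frame read_id, seq, qual), `truth`
#'   (per molecule: read_id, contig, start, end (0-based half-open),
#'   bio_strand, haplotype, group, is_spikein, is_dup), `truth_cpgs`
#'   (read_id, contig, pos, strand, modified), `aln` (truth alignment
#'   data.frame with strand `group` column), and `files` (paths, when
#'   `out_dir` given).
#' @export
simulate_reads <- function(genome, methylome, params,
                           adapters = adapter_config(), out_dir = NULL) {
  stopifnot(inherits(genome, "sim_genome"), inherits(params, "sim_params"))
  set.seed(params$seed)
  contigs <- genome$contigs
  spikein <- genome$spikein_name
  gnames <- setdiff(names(contigs), spikein)
  glen <- nchar(contigs[gnames])
  if (!length(gnames)) stop("genome has no non-spike-in contig")
  probs <- methylome_lookup(methylome, contigs)
  diploid <- genome$ploidy == 2L
  has_hap_probs <- !is.null(methylome$prob1)

  n <- params$n_reads
  mol <- vector("list", n)
  inserts <- character(n)
  for (i in seq_len(n)) {
    is_spike <- !is.null(spikein) && stats::runif(1) < params$spikein_fraction
    if (is_spike) {
      cn <- spikein; L <- nchar(contigs[[cn]])
      start0 <- 0L; fraglen <- L
      hap <- NA_integer_
    } else {
      cn <- if (length(gnames) == 1L) gnames else
        sample(gnames, 1L, prob = glen)
      clen <- nchar(contigs[[cn]])
      fraglen <- draw_fragment_length(params, clen)
      start0 <- sample.int(clen - fraglen + 1L, 1L) - 1L
      hap <- if (diploid) sample(c(1L, 2L), 1L) else NA_integer_
    }
    mol[[i]] <- list(contig = cn, start = start0, len = fraglen, hap = hap,
                     is_spike = is_spike)
  }

  acc <- emit_env(n)
  realized <- vector("list", n)
  for (i in seq_len(n)) {
    realized[[i]] <- realize_molecule(mol[[i]], contigs, genome, probs,
                                      params, has_hap_probs)
    emit_read(acc, sprintf("mol%05d", i), mol[[i]], realized[[i]], params,
              adapters, is_dup = FALSE)
  }
  if (params$dup_fraction > 0) {
    ndup <- round(params$dup_fraction * n)
    if (ndup > 0) {
      ## a PCR duplicate is the same converted molecule sequenced again:
      ## identical strand and modification states, fresh orientation/errors
      picks <- sample.int(n, ndup, replace = FALSE)
      for (i in picks) {
        emit_read(acc, sprintf("mol%05dd", i), mol[[i]], realized[[i]],
                  params, adapters, is_dup = TRUE)
      }
    }
  }
  out <- collect_emitted(acc)

  files <- NULL
  if (!is.null(out_dir)) {
    files <- write_simulation(out, genome, methylome, params, out_dir)
  }
  c(out, list(files = files))
}

draw_fragment_length <- function(params, contig_len) {
  for (t in 1:100) {
    l <- round(stats::rlnorm(1, meanlog = log(params$frag_median),
                             sdlog = params$frag_sigma))
    if (l >= params$frag_min && l <= contig_len) return(as.integer(l))
  }
  as.integer(min(contig_len, max(params$frag_min, 1L)))
}

## Fast per-contig modification-probability lookup: numeric vectors
## indexed by 1-based position, one per strand (and per haplotype when
## allele-specific columns are present).
methylome_lookup <- function(methylome, contigs) {
  has_hap <- !is.null(methylome$prob1)
  out <- list()
  for (cn in names(contigs)) {
    L <- nchar(contigs[[cn]])
    sub <- methylome[methylome$contig == cn, , drop = FALSE]
    mk <- function(col) {
      p <- numeric(L); m <- numeric(L)
      pl <- sub$strand == "+"
      p[sub$pos[pl] + 1L] <- sub[[col]][pl]
      m[sub$pos[!pl] + 1L] <- sub[[col]][!pl]
      list(plus = p, minus = m)
    }
    out[[cn]] <- if (has_hap) {
      list(h1 = mk("prob1"), h2 = mk("prob2"), shared = mk("prob"))
    } else {
      list(shared = mk("prob"))
    }
  }
  out
}

emit_env <- function(n) {
  e <- new.env(parent = emptyenv())
  e$reads <- list(); e$truth <- list(); e$cpgs <- list(); e$aln <- list()
  e$k <- 0L
  e
}

## Realise one molecule: haplotype-resolved fragment, biological strand,
## per-cytosine modification states, TAPS-converted strand sequence.
realize_molecule <- function(m, contigs, genome, probs, params,
                             has_hap_probs) {
  cn <- m$contig; start0 <- m$start; L <- m$len
  ref <- contigs[[cn]]
  frag <- substr(ref, start0 + 1L, start0 + L)
  if (!is.na(m$hap) && nrow(genome$het_variants)) {
    hv <- genome$het_variants
    hv <- hv[hv$contig == cn & hv$pos >= start0 & hv$pos < start0 + L &
               hv$hap == m$hap, , drop = FALSE]
    if (nrow(hv)) {
      ch <- strsplit(frag, "", fixed = TRUE)[[1]]
      ch[hv$pos - start0 + 1L] <- hv$alt
      frag <- paste(ch, collapse = "")
    }
  }
  ot <- stats::runif(1) < 0.5
  bio <- if (ot) "OT" else "OB"
  bseq <- if (ot) frag else revcomp(frag)

  bch <- strsplit(bseq, "", fixed = TRUE)[[1]]
  cpos <- which(bch == "C")
  if (length(cpos)) {
    gpos0 <- if (ot) start0 + cpos - 1L else start0 + (L - cpos)
    gstrand <- if (ot) "+" else "-"
    pr <- probs[[cn]]
    tab <- if (has_hap_probs && !is.na(m$hap)) {
      if (m$hap == 1L) pr$h1 else pr$h2
    } else pr$shared
    vec <- if (ot) tab$plus else tab$minus
    p <- vec[gpos0 + 1L]
    modified <- stats::runif(length(cpos)) < p
    ## truth CpG status comes from the genome annotation (defined even at
    ## fragment edges): a + strand C at g is CpG iff ref[g+1] is G, a -
    ## strand C at g iff ref[g-1] is C
    is_cpg <- if (ot) {
      substring(ref, gpos0 + 2L, gpos0 + 2L) == "G"
    } else {
      gpos0 > 0L & substring(ref, gpos0, gpos0) == "C"
    }
  } else {
    gpos0 <- integer(0); gstrand <- "+"; modified <- logical(0)
    is_cpg <- logical(0)
  }
  conv <- taps_convert(bseq, cpos, modified, params)
  list(bio = bio, conv = conv, gpos0 = gpos0, gstrand = gstrand,
       modified = modified, is_cpg = is_cpg)
}

## Emit one sequenced read of a realised molecule. The forward-
## configuration strand of the library molecule is revcomp(converted
## biological strand); forward-group reads are that strand,
## reverse-group reads its reverse complement.
emit_read <- function(acc, read_id, m, rz, params, adapters, is_dup) {
  cn <- m$contig; start0 <- m$start; L <- m$len
  bio <- rz$bio; conv <- rz$conv
  group_fwd <- stats::runif(1) < 0.5
  insert <- if (group_fwd) revcomp(as.character(conv)) else as.character(conv)
  read <- if (group_fwd) {
    paste0(adapters$forward_5p, insert, adapters$forward_3p)
  } else {
    paste0(adapters$reverse_5p, insert, adapters$reverse_3p)
  }
  read <- add_substitutions(read, params$error_rate)

  ## truth alignment: the insert recovered from the (errored) read
  a5 <- nchar(if (group_fwd) adapters$forward_5p else adapters$reverse_5p)
  ins_err <- substr(read, a5 + 1L, a5 + L)
  flag16 <- xor(group_fwd, bio == "OB")
  ## SAM stores the sequence in reference-forward orientation
  sam_seq <- if (flag16) revcomp(ins_err) else ins_err

  acc$k <- acc$k + 1L; k <- acc$k
  acc$reads[[k]] <- data.frame(read_id = read_id, seq = read,
                               qual = const_qual(nchar(read)),
                               stringsAsFactors = FALSE)
  acc$truth[[k]] <- data.frame(
    read_id = read_id, contig = cn, start = start0, end = start0 + L,
    bio_strand = bio, haplotype = m$hap,
    group = if (group_fwd) "forward" else "reverse",
    is_spikein = m$is_spike, is_dup = is_dup,
    n_converted_modified = attr(conv, "n_converted_modified"),
    n_false_converted = attr(conv, "n_false_converted"),
    stringsAsFactors = FALSE)
  if (any(rz$is_cpg)) {
    acc$cpgs[[k]] <- data.frame(
      read_id = read_id, contig = cn, pos = rz$gpos0[rz$is_cpg],
      strand = rz$gstrand, modified = rz$modified[rz$is_cpg],
      stringsAsFactors = FALSE)
  }
  acc$aln[[k]] <- data.frame(
    qname = read_id, flag = if (flag16) 16L else 0L, rname = cn,
    pos = start0 + 1L, mapq = 60L, cigar = paste0(L, "M"),
    seq = sam_seq, qual = const_qual(L),
    group = if (group_fwd) "forward" else "reverse",
    stringsAsFactors = FALSE)
  invisible(NULL)
}

collect_emitted <- function(acc) {
  rb <- function(l) do.call(rbind, c(l, list(make.row.names = FALSE)))
  cpgs <- acc$cpgs[!vapply(acc$cpgs, is.null, logical(1))]
  list(reads = rb(acc$reads), truth = rb(acc$truth),
       truth_cpgs = if (length(cpgs)) rb(cpgs) else
         data.frame(read_id = character(0), contig = character(0),
                    pos = integer(0), strand = character(0),
                    modified = logical(0), stringsAsFactors = FALSE),
       aln = rb(acc$aln))
}

write_simulation <- function(out, genome, methylome, params, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  f <- list(
    fastq = file.path(out_dir, "reads.fastq"),
    reference = file.path(out_dir, "reference.fa"),
    truth_sam = file.path(out_dir, "truth.sam"),
    truth = file.path(out_dir, "truth.tsv"),
    truth_cpgs = file.path(out_dir, "truth_cpgs.tsv"),
    truth_methylome = file.path(out_dir, "truth_methylome.bed"))
  write_fastq(out$reads, f$fastq)
  write_fasta(genome$contigs, f$reference)
  write_sam(out$aln, nchar(genome$contigs), f$truth_sam,
            comments = sim_header(params))
  utils::write.table(out$truth, f$truth, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(out$truth_cpgs, f$truth_cpgs, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  bed <- methylome[order(methylome$contig, methylome$pos), , drop = FALSE]
  writeLines(paste(bed$contig, bed$pos, bed$pos + 1L,
                   formatC(bed$prob, digits = 6, format = "fg"),
                   bed$strand, bed$context, sep = "\t"),
             f$truth_methylome)
  if (genome$ploidy == 2L && nrow(genome$het_variants)) {
    f$vcf <- file.path(out_dir, "variants.vcf")
    write_phased_vcf(genome$het_variants, nchar(genome$contigs), f$vcf)
  }
  f
}

sim_header <- function(params) {
  sprintf("lrtaps simulation seed=%d conversion=%g fpr_cpg=%g fpr_cph=%g error=%g",
          params$seed, params$conversion_rate, params$false_conversion_cpg,
          params$false_conversion_cph, params$error_rate)
}
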