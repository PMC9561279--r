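# Shared fixtures, built in code and cached for the session.

.fx_cache <- new.env(parent = emptyenv())

fx <- function(name, builder) {
  if (!exists(name, envir = .fx_cache)) {
    assign(name, builder(), envir = .fx_cache)
  }
  get(name, envir = .fx_cache)
}

# Noiseless library: perfect conversion, no false conversion, no
# sequencing error. The workhorse for exact round-trip checks.
fx_noiseless <- function() {
  fx("noiseless", function() {
    sim <- simulate_genome(genome_size = 200000, seed = 401)
    pars <- sim_params(n_reads = 2000, conversion_rate = 1,
                       false_conversion_cpg = 0, false_conversion_cph = 0,
                       error_rate = 0, spikein_fraction = 0.005, seed = 402)
    rr <- simulate_reads(sim$genome, sim$methylome, pars)
    list(sim = sim, pars = pars, rr = rr)
  })
}

# Noiseless library pushed through classify -> normalise -> dedup ->
# filter, with per-strand CpG calls.
fx_noiseless_calls <- function() {
  fx("noiseless_calls", function() {
    z <- fx_noiseless()
    aln <- normalize_strand(z$rr$aln)
    aln <- aln[order(match(aln$rname, unique(aln$rname)), aln$pos), ]
    aln <- mark_duplicates(aln, exclude_contigs = z$sim$genome$spikein_name)
    aln <- filter_alignments(aln)
    calls <- pileup_cytosines(aln, z$sim$genome$contigs, contexts = "CpG")
    c(z, list(aln = aln, calls = calls))
  })
}

# Build an alignment data.frame row directly (truth-SAM-like).
toy_aln <- function(qname, rname, pos, seq, flag = 0L, mapq = 60L,
                    cigar = NULL, bio_strand = NULL, qual = NULL) {
  if (is.null(cigar)) cigar <- paste0(nchar(seq), "M")
  df <- data.frame(qname = qname, flag = flag, rname = rname, pos = pos,
                   mapq = mapq, cigar = cigar, seq = seq,
                   qual = qual %||% strrep("?", nchar(seq)),
                   stringsAsFactors = FALSE)
  if (!is.null(bio_strand)) df$bio_strand <- bio_strand
  df
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Independent brute-force pileup: per-read, per-CIGAR-op, per-base walk
# with explicit loops, counting at every reference cytosine found by a
# naive substring scan. Deliberately shares no code with the package's
# block-wise pileup.
oracle_pileup <- function(aln, ref_seq, contig, contexts = "CpG",
                          min_base_qual = 13) {
  L <- nchar(ref_seq)
  site_list <- list()
  for (p in seq_len(L)) {
    b <- substr(ref_seq, p, p)
    if (b == "C") {
      nxt <- if (p < L) substr(ref_seq, p + 1, p + 1) else "N"
      nxt2 <- if (p + 2 <= L) substr(ref_seq, p + 2, p + 2) else "N"
      ctx <- if (nxt == "G") "CpG" else if (nxt2 == "G") "CHG" else "CHH"
      site_list[[length(site_list) + 1]] <- list(p = p, strand = "+", ctx = ctx)
    }
    if (b == "G") {
      prv <- if (p > 1) substr(ref_seq, p - 1, p - 1) else "N"
      prv2 <- if (p - 2 >= 1) substr(ref_seq, p - 2, p - 2) else "N"
      ctx <- if (prv == "C") "CpG" else if (prv2 == "C") "CHG" else "CHH"
      site_list[[length(site_list) + 1]] <- list(p = p, strand = "-", ctx = ctx)
    }
  }
  counts <- list()
  for (i in seq_len(nrow(aln))) {
    toks <- regmatches(aln$cigar[i],
                       gregexpr("\\d+[MIDNSHP=X]", aln$cigar[i]))[[1]]
    rp <- aln$pos[i]; qp <- 1
    for (tk in toks) {
      n <- as.integer(substr(tk, 1, nchar(tk) - 1))
      op <- substr(tk, nchar(tk), nchar(tk))
      if (op %in% c("M", "=", "X")) {
        for (j in seq_len(n)) {
          base <- substr(aln$seq[i], qp, qp)
          q <- utf8ToInt(substr(aln$qual[i], qp, qp)) - 33
          key <- paste0(rp)
          counts[[length(counts) + 1]] <- list(rp = rp, base = base,
                                               qual = q,
                                               strand = aln$bio_strand[i])
          rp <- rp + 1; qp <- qp + 1
        }
      } else if (op %in% c("D", "N")) {
        for (j in seq_len(n)) {
          counts[[length(counts) + 1]] <- list(rp = rp, base = "-",
                                               qual = Inf,
                                               strand = aln$bio_strand[i])
          rp <- rp + 1
        }
      } else if (op %in% c("I", "S")) {
        qp <- qp + n
      }
    }
  }
  out <- list()
  for (s in site_list) {
    if (!(s$ctx %in% contexts)) next
    want <- if (s$strand == "+") "OT" else "OB"
    nc <- 0; nu <- 0; no <- 0
    for (cc in counts) {
      if (cc$rp != s$p || cc$strand != want) next
      if (is.finite(cc$qual) && cc$qual < min_base_qual) next
      if (s$strand == "+") {
        if (cc$base == "T") nc <- nc + 1
        else if (cc$base == "C") nu <- nu + 1
        else no <- no + 1
      } else {
        if (cc$base == "A") nc <- nc + 1
        else if (cc$base == "G") nu <- nu + 1
        else no <- no + 1
      }
    }
    if (nc + nu + no > 0) {
      out[[length(out) + 1]] <- data.frame(
        contig = contig, pos = s$p - 1, strand = s$strand, context = s$ctx,
        n_converted = nc, n_unconverted = nu, n_other = no,
        stringsAsFactors = FALSE)
    }
  }
  if (!length(out)) {
    return(data.frame(contig = character(0), pos = integer(0),
                      strand = character(0), context = character(0),
                      n_converted = integer(0), n_unconverted = integer(0),
                      n_other = integer(0)))
  }
  res <- do.call(rbind, out)
  res[order(res$pos, res$strand), ]
}

# Random small alignment instance over a random reference, with mixed
# M/I/D/S CIGARs and mutated bases, for pileup property testing.
random_sam_instance <- function(seed, ref_len = 300, n_reads = 8) {
  set.seed(seed)
  ref <- paste(sample(c("A", "C", "G", "T"), ref_len, replace = TRUE),
               collapse = "")
  rows <- list()
  for (i in seq_len(n_reads)) {
    start <- sample.int(ref_len - 80, 1)
    rp <- start
    cig <- character(0)
    seqs <- character(0)
    n_ops <- sample(1:4, 1)
    lead_s <- sample(0:3, 1)
    if (lead_s > 0) {
      cig <- c(cig, paste0(lead_s, "S"))
      seqs <- c(seqs, paste(sample(c("A", "C", "G", "T"), lead_s, TRUE),
                            collapse = ""))
    }
    for (k in seq_len(n_ops)) {
      mlen <- sample(10:40, 1)
      if (rp + mlen - 1 > ref_len) mlen <- ref_len - rp + 1
      if (mlen < 1) break
      block <- substr(ref, rp, rp + mlen - 1)
      ch <- strsplit(block, "")[[1]]
      mut <- which(runif(mlen) < 0.3)
      for (m in mut) ch[m] <- sample(c("A", "C", "G", "T"), 1)
      cig <- c(cig, paste0(mlen, "M"))
      seqs <- c(seqs, paste(ch, collapse = ""))
      rp <- rp + mlen
      if (k < n_ops) {
        if (runif(1) < 0.5) {
          dlen <- sample(1:5, 1)
          if (rp + dlen <= ref_len) {
            cig <- c(cig, paste0(dlen, "D")); rp <- rp + dlen
          }
        } else {
          ilen <- sample(1:5, 1)
          cig <- c(cig, paste0(ilen, "I"))
          seqs <- c(seqs, paste(sample(c("A", "C", "G", "T"), ilen, TRUE),
                                collapse = ""))
        }
      }
    }
    if (!any(grepl("M", cig))) next
    # ensure the CIGAR ends on M (trim trailing D)
    while (grepl("D$", cig[length(cig)])) {
      dl <- as.integer(sub("D$", "", cig[length(cig)]))
      rp <- rp - dl
      cig <- cig[-length(cig)]
    }
    seqv <- paste(seqs, collapse = "")
    rows[[i]] <- toy_aln(sprintf("r%02d", i), "ref", start, seqv,
                         cigar = paste(cig, collapse = ""),
                         bio_strand = sample(c("OT", "OB"), 1))
  }
  list(ref = ref, aln = do.call(rbind, rows))
}

# Spike-in-dominated library for conversion-rate QC checks.
spikein_run <- function(conversion, f_cpg, f_cph, n_reads = 600, seed = 91) {
  sim <- simulate_genome(genome_size = 20000, spikein_length = 4000,
                         seed = seed)
  pars <- sim_params(n_reads = n_reads, conversion_rate = conversion,
                     false_conversion_cpg = f_cpg,
                     false_conversion_cph = f_cph, error_rate = 0,
                     spikein_fraction = 0.9, seed = seed + 1)
  rr <- simulate_reads(sim$genome, sim$methylome, pars)
  aln <- filter_alignments(normalize_strand(rr$aln))
  spike <- aln[aln$rname == "spikein", ]
  calls <- pileup_cytosines(spike, sim$genome$contigs,
                            contexts = c("CpG", "CHG", "CHH"))
  parts <- partition_spikein_sites(sim$genome$contigs[["spikein"]])
  list(report = spikein_report(calls, parts), n_spike = nrow(spike),
       parts = parts)
}

# Diploid imprinted-locus library for ASM tests: one contig, dense
# phased SNPs, an imprinted region (hap1/hap2 CpG levels as given).
fx_asm_sim <- function(level1 = 0.95, level2 = 0.05, n_reads = 300,
                       seed = 501) {
  sim <- simulate_genome(genome_size = 20000, ploidy = 2,
                         snp_density = 0.002, spikein_length = 0,
                         seed = seed)
  meth <- set_imprinted_region(sim$methylome, "chrS1", 0, 20000,
                               level1, level2)
  pars <- sim_params(n_reads = n_reads, frag_median = 4000, frag_min = 2500,
                     conversion_rate = 1, false_conversion_cpg = 0,
                     false_conversion_cph = 0, error_rate = 0,
                     spikein_fraction = 0, seed = seed + 1)
  rr <- simulate_reads(sim$genome, meth, pars)
  aln <- normalize_strand(rr$aln)
  aln <- aln[order(aln$pos), ]
  aln <- mark_duplicates(aln)
  aln <- filter_alignments(aln)
  list(sim = sim, meth = meth, rr = rr, aln = aln)
}
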