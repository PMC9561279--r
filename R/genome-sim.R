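## Synthetic genome and methylome generation.
##
## The generator emulates the input material of a whole-genome long-read
## TAPS experiment: mammalian-like genomic DNA (CpG-depleted, bimodally
## methylated at CpG sites), optionally diploid with phased heterozygous
## SNPs, plus a fully CCGG-methylated spike-in control contig used for
## conversion-rate QC.

#' Build a methylated spike-in control sequence
#'
#' Generates a random DNA sequence carrying at least `min_ccgg` CCGG
#' sites and a methylome slice in which the internal C of every CCGG is
#' modified with probability 1.0 on both strands (the product of HpaII
#' methyltransferase treatment) while every other cytosine has
#' probability 0.0.
#'
#' @param length sequence length in bp (>= 100; default 4000, a 4-kb
#'   amplicon-sized control).
#' @param seed optional integer seed; `NULL` uses the current RNG state.
#' @param min_ccgg minimum number of CCGG sites required (resampled up to
#'   `max_tries` times).
#' @param contig name given to the control contig in the methylome slice.
#' @param max_tries bounded number of resampling attempts.
#' @return list with `sequence` (character) and `methylome` (data.frame
#'   with columns contig, pos, strand, context, prob; pos is 0-based).
#' @export
make_spikein <- function(length = 4000, seed = NULL, min_ccgg = 5,
                         contig = "spikein", max_tries = 100) {
  if (length < 100) stop("spike-in length must be >= 100 bp")
  if (!is.null(seed)) set.seed(seed)
  seqv <- NULL
  for (i in seq_len(max_tries)) {
    cand <- random_dna(length, gc = 0.5, cpg_tilt = 0)
    if (count_motif(cand, "CCGG") >= min_ccgg) { seqv <- cand; break }
  }
  if (is.null(seqv)) {
    stop("could not place >= ", min_ccgg, " CCGG sites in ", length,
         " bp after ", max_tries, " tries")
  }
  meth <- spikein_methylome(seqv, contig)
  list(sequence = seqv, methylome = meth)
}

count_motif <- function(seq, motif) {
  m <- gregexpr(motif, seq, fixed = TRUE)[[1]]
  if (m[1] == -1L) 0L else length(m)
}

## Methylome slice for a spike-in contig: prob 1 at the internal C of
## every CCGG on both strands (CCGG is palindromic, so the + strand C at
## offset +1 pairs with the - strand C at offset +2), prob 0 elsewhere.
spikein_methylome <- function(seqv, contig) {
  sites <- cytosine_sites(seqv, contexts = c("CpG", "CHG", "CHH"))
  hits <- gregexpr("CCGG", seqv, fixed = TRUE)[[1]]
  meth_plus <- integer(0); meth_minus <- integer(0)
  if (hits[1] != -1L) {
    meth_plus <- as.integer(hits)        # 1-based start; internal C at start+1 -> 0-based start
    meth_minus <- as.integer(hits) + 1L  # 0-based start+2
  }
  prob <- rep(0, nrow(sites))
  prob[sites$strand == "+" & sites$pos %in% meth_plus] <- 1
  prob[sites$strand == "-" & sites$pos %in% meth_minus] <- 1
  data.frame(contig = contig, pos = sites$pos, strand = sites$strand,
             context = sites$context, prob = prob, stringsAsFactors = FALSE)
}

#' Simulate a genome and CpG methylome
#'
#' Draws contigs from a first-order base model with configurable GC
#' content and CpG tilt, assigns each CpG a modification probability from
#' a two-component Beta mixture (a high-methylation bulk component and a
#' low-methylation island-like component), appends a CCGG-methylated
#' spike-in contig, and (in diploid mode) plants phased heterozygous SNPs.
#'
#' `cpg_enrichment` is a log-scale tilt on the probability of G following
#' C: 0 leaves bases i.i.d., negative values deplete CpGs as in mammalian
#' genomes (default -1.4, roughly a quarter of the i.i.d. expectation).
#'
#' @param genome_size total genomic length in bp (split across contigs).
#' @param n_contigs number of contigs (each >= 1 kb).
#' @param gc GC fraction.
#' @param cpg_enrichment log-scale CpG tilt (0 = i.i.d. bases).
#' @param mix_weights weights of the (high, low) methylation components;
#'   must sum to 1.
#' @param meth_high,meth_low Beta shape pairs for the two components.
#' @param ploidy 1 or 2.
#' @param snp_density per-bp heterozygous SNP probability in diploid mode.
#' @param avoid_cpg_snps if TRUE (default) SNPs never hit the C or G of a
#'   truth CpG, so allele-specific methylation fixtures keep their sites.
#' @param spikein_length spike-in contig length in bp; 0 disables it.
#' @param spikein_name contig name for the spike-in.
#' @param seed integer seed; the run is fully deterministic given it.
#' @return list with `genome` (a `sim_genome`: contigs, ploidy,
#'   het_variants, spikein_name) and `methylome` (data.frame contig, pos,
#'   strand, context, prob; 0-based positions; cytosines absent from the
#'   table are unmodified).
#' @export
simulate_genome <- function(genome_size = 200000, n_contigs = 1, gc = 0.42,
                            cpg_enrichment = -1.4,
                            mix_weights = c(0.8, 0.2),
                            meth_high = c(8, 2), meth_low = c(1, 20),
                            ploidy = 1, snp_density = 0.001,
                            avoid_cpg_snps = TRUE,
                            spikein_length = 4000, spikein_name = "spikein",
                            seed = 1L) {
  if (abs(sum(mix_weights) - 1) > 1e-8 || any(mix_weights < 0)) {
    stop("mixture weights must be non-negative and sum to 1")
  }
  if (!ploidy %in% c(1L, 2L)) stop("ploidy must be 1 or 2")
  per <- floor(genome_size / n_contigs)
  if (per < 1000) stop("each contig must be >= 1 kb")
  set.seed(seed)

  sizes <- rep(per, n_contigs)
  sizes[n_contigs] <- genome_size - per * (n_contigs - 1L)
  names(sizes) <- sprintf("chrS%d", seq_len(n_contigs))

  contigs <- vapply(sizes, function(L) random_dna(L, gc, cpg_enrichment),
                    character(1))
  meth_list <- vector("list", n_contigs)
  for (i in seq_len(n_contigs)) {
    meth_list[[i]] <- draw_cpg_methylome(contigs[i], names(sizes)[i],
                                         mix_weights, meth_high, meth_low)
  }
  methylome <- do.call(rbind, meth_list)

  spike <- NULL
  if (spikein_length > 0) {
    spike <- make_spikein(spikein_length, contig = spikein_name)
    contigs <- c(contigs, stats::setNames(spike$sequence, spikein_name))
    methylome <- rbind(methylome, spike$methylome)
  }

  het <- data.frame(contig = character(0), pos = integer(0),
                    ref = character(0), alt = character(0),
                    hap = integer(0), stringsAsFactors = FALSE)
  if (ploidy == 2L && snp_density > 0) {
    het <- plant_het_snps(contigs, spikein_name, methylome, snp_density,
                          avoid_cpg_snps)
  }

  genome <- structure(list(contigs = contigs, ploidy = as.integer(ploidy),
                           het_variants = het,
                           spikein_name = if (spikein_length > 0) spikein_name
                                          else NULL),
                      class = "sim_genome")
  list(genome = genome, methylome = methylome)
}

## Per-contig CpG methylome from the Beta mixture; both strand cytosines
## of a CpG unit share one probability (symmetric maintenance methylation).
draw_cpg_methylome <- function(seqv, contig, w, high, low) {
  pos <- cpg_positions(seqv)  # 0-based position of the + strand C
  n <- length(pos)
  if (!n) {
    return(data.frame(contig = character(0), pos = integer(0),
                      strand = character(0), context = character(0),
                      prob = numeric(0), stringsAsFactors = FALSE))
  }
  comp <- sample(c(1L, 2L), n, replace = TRUE, prob = w)
  prob <- numeric(n)
  prob[comp == 1L] <- stats::rbeta(sum(comp == 1L), high[1], high[2])
  prob[comp == 2L] <- stats::rbeta(sum(comp == 2L), low[1], low[2])
  data.frame(contig = contig,
             pos = c(pos, pos + 1L),
             strand = rep(c("+", "-"), each = n),
             context = "CpG",
             prob = c(prob, prob),
             stringsAsFactors = FALSE)
}

## 0-based positions of the C of every CG dinucleotide.
cpg_positions <- function(seqv) {
  m <- gregexpr("CG", seqv, fixed = TRUE)[[1]]
  if (m[1] == -1L) integer(0) else as.integer(m) - 1L
}

plant_het_snps <- function(contigs, spikein_name, methylome, density,
                           avoid_cpg) {
  out <- list()
  for (cn in names(contigs)) {
    if (!is.null(spikein_name) && identical(cn, spikein_name)) next
    s <- contigs[[cn]]
    L <- nchar(s)
    pos <- which(stats::runif(L) < density) - 1L  # 0-based
    if (avoid_cpg) {
      cg <- cpg_positions(s)
      pos <- setdiff(pos, c(cg, cg + 1L))
    }
    if (!length(pos)) next
    ch <- strsplit(s, "", fixed = TRUE)[[1]]
    ref <- ch[pos + 1L]
    alt <- vapply(ref, function(r) sample(setdiff(c("A", "C", "G", "T"), r), 1L),
                  character(1), USE.NAMES = FALSE)
    hap <- sample(c(1L, 2L), length(pos), replace = TRUE)
    out[[cn]] <- data.frame(contig = cn, pos = pos, ref = ref, alt = alt,
                            hap = hap, stringsAsFactors = FALSE)
  }
  if (!length(out)) {
    return(data.frame(contig = character(0), pos = integer(0),
                      ref = character(0), alt = character(0),
                      hap = integer(0), stringsAsFactors = FALSE))
  }
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}

#' Impose allele-specific methylation on a region
#'
#' Replaces the CpG modification probabilities inside `[start, end)` of
#' `contig` with haplotype-specific levels, adding `prob1`/`prob2`
#' columns to the methylome (initialised to the shared `prob` elsewhere).
#' Used to build imprinted-locus fixtures.
#'
#' @param methylome methylome data.frame from [simulate_genome()].
#' @param contig,start,end region (0-based half-open).
#' @param level1,level2 modification probability on haplotype 1 / 2.
#' @return methylome with `prob1` and `prob2` columns.
#' @export
set_imprinted_region <- function(methylome, contig, start, end,
                                 level1, level2) {
  if (is.null(methylome$prob1)) {
    methylome$prob1 <- methylome$prob
    methylome$prob2 <- methylome$prob
  }
  sel <- methylome$contig == contig & methylome$pos >= start &
    methylome$pos < end & methylome$context == "CpG"
  methylome$prob1[sel] <- level1
  methylome$prob2[sel] <- level2
  methylome
}

#' @export
print.sim_genome <- function(x, ...) {
  cat("Simulated genome:", length(x$contigs), "contig(s),",
      sum(nchar(x$contigs)), "bp total, ploidy", x$ploidy, "\n")
  if (!is.null(x$spikein_name)) {
    cat("  spike-in contig:", x$spikein_name,
        sprintf("(%d bp)\n", nchar(x$contigs[[x$spikein_name]])))
  }
  if (nrow(x$het_variants)) {
    cat("  heterozygous SNPs:", nrow(x$het_variants), "\n")
  }
  invisible(x)
}

#' In-silico HpaII digestion
#'
#' HpaII cuts CCGG only when the internal C is unmodified. Returns the
#' 0-based positions of CCGG sites that would be cut given a methylome;
#' a fully HpaII-methylated spike-in yields an empty vector (the digest
#' leaves the control uncut).
#'
#' @param seqv contig sequence.
#' @param methylome methylome data.frame restricted to this contig.
#' @return integer vector of cut-site CCGG start positions (0-based).
#' @export
hpaii_cut_sites <- function(seqv, methylome) {
  hits <- gregexpr("CCGG", seqv, fixed = TRUE)[[1]]
  if (hits[1] == -1L) return(integer(0))
  starts0 <- as.integer(hits) - 1L
  internal_c <- starts0 + 1L  # + strand internal C
  plus <- methylome[methylome$strand == "+", , drop = FALSE]
  prob <- plus$prob[match(internal_c, plus$pos)]
  prob[is.na(prob)] <- 0
  starts0[prob < 1]
}
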