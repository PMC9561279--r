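test_that("reads vote for the haplotype carrying their observed allele", {
  # het A->G at 0-based 49, alt on haplotype 2
  variants <- data.frame(contig = "chr", pos = 49L, ref = "A", alt = "G",
                         hap = 2L, stringsAsFactors = FALSE)
  ref_read <- strrep("T", 100)
  g_read <- paste0(strrep("T", 49), "G", strrep("T", 50))
  a_read <- paste0(strrep("T", 49), "A", strrep("T", 50))
  aln <- rbind(toy_aln("rG", "chr", 1L, g_read, bio_strand = "OT"),
               toy_aln("rA", "chr", 1L, a_read, bio_strand = "OT"),
               toy_aln("far", "chr", 200L, ref_read, bio_strand = "OT"))
  tags <- haplotag_reads(aln, variants)
  expect_equal(tags$haplotype[tags$read_id == "rG"], 2L)
  expect_equal(tags$haplotype[tags$read_id == "rA"], 1L)
  expect_true(is.na(tags$haplotype[tags$read_id == "far"]))
})

test_that("conversion-confounded variants never contribute votes", {
  variants <- data.frame(contig = "chr",
                         pos = c(9L, 29L),
                         ref = c("C", "G"), alt = c("T", "A"),
                         hap = c(1L, 2L), stringsAsFactors = FALSE)
  read <- strrep("T", 60)  # would "support" both C/T and G/A alts
  aln <- toy_aln("r1", "chr", 1L, read, bio_strand = "OT")
  tags <- haplotag_reads(aln, variants)
  expect_true(is.na(tags$haplotype))
  expect_equal(tags$n_support, 0L)
})

test_that("haplotagging matches simulation truth with zero error", {
  z <- fx("asm_sim", function() fx_asm_sim())
  variants <- z$sim$genome$het_variants
  tags <- haplotag_reads(z$aln, variants)
  truth_hap <- z$rr$truth$haplotype[match(tags$read_id, z$rr$truth$read_id)]
  assigned <- !is.na(tags$haplotype)
  expect_gt(mean(assigned), 0.8)
  expect_true(all(tags$haplotype[assigned] == truth_hap[assigned]))
  # reads overlapping no usable variant stay unassigned
  expect_true(all(tags$n_support[!assigned] +
                    tags$n_conflict[!assigned] == 0))
})

test_that("swapping haplotype labels swaps assignments", {
  z <- fx("asm_sim", function() fx_asm_sim())
  variants <- z$sim$genome$het_variants
  swapped <- variants
  swapped$hap <- 3L - swapped$hap
  t1 <- haplotag_reads(z$aln, variants)
  t2 <- haplotag_reads(z$aln, swapped)
  assigned <- !is.na(t1$haplotype)
  expect_identical(t1$haplotype[assigned], 3L - t2$haplotype[assigned])
})

test_that("allele methylomes split and re-sum to the unphased pileup", {
  z <- fx("asm_sim", function() fx_asm_sim())
  tags <- haplotag_reads(z$aln, z$sim$genome$het_variants)
  am <- allele_methylomes(tags, z$aln, z$sim$genome$contigs)

  assigned_ids <- tags$read_id[!is.na(tags$haplotype)]
  both <- pileup_cytosines(z$aln[z$aln$qname %in% assigned_ids, ],
                           z$sim$genome$contigs)
  key <- function(d) paste(d$contig, d$pos, d$strand)
  tot <- rbind(am$hap1, am$hap2)
  agg <- tapply(tot$n_converted + tot$n_unconverted + tot$n_other, key(tot),
                sum)
  expect_setequal(names(agg), key(both))
  expect_equal(as.numeric(agg[key(both)]),
               both$n_converted + both$n_unconverted + both$n_other)

  # a one-sided input leaves the other haplotype empty, with a warning
  hap1_only <- tags
  hap1_only$haplotype[hap1_only$haplotype == 2L] <- NA_integer_
  expect_warning(am1 <- allele_methylomes(hap1_only, z$aln,
                                          z$sim$genome$contigs),
                 "haplotype 2")
  expect_equal(nrow(am1$hap2), 0)
})

test_that("identical allele counts give p = 1; extreme table matches the
          hypergeometric enumeration", {
  mk <- function(conv, unconv) {
    data.frame(contig = "chr", pos = 10L, strand = ".", context = "CpG",
               n_converted = conv, n_unconverted = unconv, n_other = 0L,
               level = conv / (conv + unconv), stringsAsFactors = FALSE)
  }
  same <- test_asm(mk(7L, 3L), mk(7L, 3L))
  expect_equal(same$p_value, 1)
  expect_equal(same$level_diff, 0)

  extreme <- test_asm(mk(20L, 0L), mk(0L, 20L))
  # enumeration over all tables with both margins 20/20
  p_obs <- stats::dhyper(20, 20, 20, 20)
  p_exact <- sum(stats::dhyper(0:20, 20, 20, 20)[
    stats::dhyper(0:20, 20, 20, 20) <= p_obs + 1e-12])
  expect_equal(extreme$p_value, p_exact, tolerance = 1e-10)
  expect_equal(extreme$level_diff, 1)
})

test_that("depth gating and BH ordering hold", {
  h1 <- data.frame(contig = "chr", pos = c(1L, 5L), strand = ".",
                   context = "CpG", n_converted = c(2L, 20L),
                   n_unconverted = c(1L, 0L), n_other = 0L,
                   level = c(2 / 3, 1), stringsAsFactors = FALSE)
  h2 <- data.frame(contig = "chr", pos = c(1L, 5L), strand = ".",
                   context = "CpG", n_converted = c(1L, 0L),
                   n_unconverted = c(1L, 20L), n_other = 0L,
                   level = c(0.5, 0), stringsAsFactors = FALSE)
  res <- test_asm(h1, h2, min_depth_per_allele = 5)
  expect_equal(res$pos, 5L)  # the depth-3 site is not tested
  expect_true(all(res$q_value >= res$p_value))
})

test_that("an imprinted locus is detected and its direction recovered", {
  z <- fx("asm_sim", function() fx_asm_sim())
  tags <- haplotag_reads(z$aln, z$sim$genome$het_variants)
  am <- allele_methylomes(tags, z$aln, z$sim$genome$contigs)
  m1 <- merge_cpg_strands(am$hap1)
  m2 <- merge_cpg_strands(am$hap2)
  # per-allele levels reproduce the programmed 0.95/0.05 imprint
  pool <- function(m) sum(m$n_converted) / sum(m$n_converted + m$n_unconverted)
  se <- function(p, n) sqrt(p * (1 - p) / n)
  n1 <- sum(m1$n_converted + m1$n_unconverted)
  n2 <- sum(m2$n_converted + m2$n_unconverted)
  expect_lt(abs(pool(m1) - 0.95), 3 * se(0.95, n1))
  expect_lt(abs(pool(m2) - 0.05), 3 * se(0.05, n2))

  res <- test_asm(m1, m2, min_depth_per_allele = 5)
  expect_gt(nrow(res), 20)
  expect_gte(mean(res$q_value < 0.05), 0.9)
  expect_true(all(res$level_diff[res$q_value < 0.05] > 0))
})
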