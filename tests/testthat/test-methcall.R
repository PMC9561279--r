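test_that("modification level follows the inverted TAPS formula", {
  expect_equal(modification_level(8, 2), 0.8)
  expect_equal(modification_level(0, 5), 0)
  expect_true(is.na(modification_level(0, 0)))
  expect_error(modification_level(-1, 2), "non-negative")
})

test_that("single-read pileup cases behave as specified", {
  ref <- c(chr = "AACGTT")  # CpG: + strand C at pos 2 (0-based), - at 3
  # OT read with T over the C: converted
  a <- toy_aln("r1", "chr", 1L, "AATGTT", bio_strand = "OT")
  calls <- pileup_cytosines(a, ref)
  plus <- calls[calls$strand == "+", ]
  expect_equal(plus$pos, 2L)
  expect_equal(plus$n_converted, 1L)
  expect_equal(plus$level, 1)

  # an OB read never contributes to a + strand C
  b <- toy_aln("r2", "chr", 1L, "AACGTT", flag = 16L, bio_strand = "OB")
  calls_b <- pileup_cytosines(b, ref)
  expect_false(any(calls_b$strand == "+"))
  # it reads the - strand C (G on +): G = unconverted
  minus <- calls_b[calls_b$strand == "-", ]
  expect_equal(minus$pos, 3L)
  expect_equal(minus$n_unconverted, 1L)
  expect_equal(minus$level, 0)

  # OB conversion appears as A at the reference G
  c_ <- toy_aln("r3", "chr", 1L, "AACATT", flag = 16L, bio_strand = "OB")
  minus_c <- pileup_cytosines(c_, ref)
  expect_equal(minus_c$n_converted[minus_c$strand == "-"], 1L)

  # a deletion spanning the site counts as other
  d <- toy_aln("r4", "chr", 1L, "AATT", cigar = "2M2D2M", bio_strand = "OT")
  calls_d <- pileup_cytosines(d, ref)
  expect_equal(calls_d$n_other[calls_d$strand == "+"], 1L)
  expect_true(is.na(calls_d$level[calls_d$strand == "+"]))
})

test_that("bases below the quality floor are excluded", {
  ref <- c(chr = "AACGTT")
  lowq <- paste0(strrep("I", 2), rawToChar(as.raw(33 + 5)), strrep("I", 3))
  a <- toy_aln("r1", "chr", 1L, "AATGTT", bio_strand = "OT", qual = lowq)
  calls <- pileup_cytosines(a, ref)
  expect_false(any(calls$strand == "+" & calls$pos == 2L))
  calls2 <- pileup_cytosines(a, ref, min_base_qual = 0)
  expect_equal(calls2$n_converted[calls2$strand == "+"], 1L)
})

test_that("pileup counts equal the brute-force recount on random instances", {
  for (seed in 1:25) {
    inst <- random_sam_instance(seed)
    got <- pileup_cytosines(inst$aln, c(ref = inst$ref),
                            contexts = c("CpG", "CHG", "CHH"))
    want <- oracle_pileup(inst$aln, inst$ref, "ref",
                          contexts = c("CpG", "CHG", "CHH"))
    got <- got[order(got$pos, got$strand), ]
    expect_equal(got$pos, want$pos, label = paste("seed", seed))
    expect_equal(got$n_converted, want$n_converted)
    expect_equal(got$n_unconverted, want$n_unconverted)
    expect_equal(got$n_other, want$n_other)
  }
})

test_that("alignments overhanging the contig end are rejected", {
  ref <- c(chr = "AACGTT")
  a <- toy_aln("r1", "chr", 4L, "AATGTT", bio_strand = "OT")
  expect_error(pileup_cytosines(a, ref), "overhangs")
  b <- toy_aln("r1", "nope", 1L, "AATGTT", bio_strand = "OT")
  expect_error(pileup_cytosines(b, ref), "absent")
})

test_that("caller levels equal realized truth exactly in the noiseless limit", {
  z <- fx_noiseless_calls()
  tc <- z$rr$truth_cpgs
  # restrict truth to reads that survived filtering
  tc <- tc[tc$read_id %in% z$aln$qname, ]
  truth_frac <- tapply(tc$modified, paste(tc$contig, tc$pos, tc$strand), mean)
  key <- paste(z$calls$contig, z$calls$pos, z$calls$strand)
  common <- intersect(names(truth_frac), key)
  expect_gt(length(common), 1000)
  expect_equal(as.numeric(truth_frac[common]),
               z$calls$level[match(common, key)])
})

test_that("CpG strand merging is additive", {
  calls <- data.frame(contig = "chr", pos = c(10L, 11L, 30L),
                      strand = c("+", "-", "-"), context = "CpG",
                      n_converted = c(3L, 1L, 2L),
                      n_unconverted = c(1L, 1L, 0L),
                      n_other = c(0L, 1L, 0L),
                      level = c(0.75, 0.5, 1),
                      stringsAsFactors = FALSE)
  m <- merge_cpg_strands(calls)
  expect_equal(nrow(m), 2)
  u1 <- m[m$pos == 10L, ]
  expect_equal(u1$n_converted, 4L)
  expect_equal(u1$n_unconverted, 2L)
  expect_equal(u1$level, 2 / 3)
  # one strand missing: merged record equals the present strand, keyed at
  # the + strand C position
  u2 <- m[m$pos == 29L, ]
  expect_equal(u2$n_converted, 2L)

  z <- fx_noiseless_calls()
  mm <- merge_cpg_strands(z$calls)
  expect_equal(sum(mm$n_converted + mm$n_unconverted + mm$n_other),
               sum(z$calls$n_converted + z$calls$n_unconverted +
                     z$calls$n_other))
})

test_that("strand isolation: OB reads never change + strand calls", {
  z <- fx_noiseless_calls()
  ot_only <- z$aln[z$aln$bio_strand == "OT", ]
  calls_ot <- pileup_cytosines(ot_only, z$sim$genome$contigs)
  plus_full <- z$calls[z$calls$strand == "+", ]
  plus_ot <- calls_ot[calls_ot$strand == "+", ]
  k_full <- paste(plus_full$contig, plus_full$pos)
  k_ot <- paste(plus_ot$contig, plus_ot$pos)
  expect_setequal(k_full, k_ot)
  ord <- match(k_full, k_ot)
  expect_identical(plus_full$n_converted, plus_ot$n_converted[ord])
  expect_identical(plus_full$n_unconverted, plus_ot$n_unconverted[ord])
  expect_equal(nrow(calls_ot[calls_ot$strand == "-", ]), 0)
})

test_that("a deeply covered uniform locus recovers the conversion rate", {
  sim <- simulate_genome(genome_size = 4000, spikein_length = 0, seed = 71)
  meth <- sim$methylome
  meth$prob <- 1  # uniformly methylated
  pars <- sim_params(n_reads = 400, frag_median = 2000, frag_sigma = 0.2,
                     frag_min = 1000, conversion_rate = 0.95,
                     false_conversion_cpg = 0, false_conversion_cph = 0,
                     error_rate = 0, spikein_fraction = 0, seed = 72)
  rr <- simulate_reads(sim$genome, meth, pars)
  aln <- filter_alignments(normalize_strand(rr$aln))
  calls <- pileup_cytosines(aln, sim$genome$contigs)
  n_bases <- sum(calls$n_converted + calls$n_unconverted)
  expect_gt(n_bases / nrow(calls), 100)  # deep coverage
  pooled <- sum(calls$n_converted) / n_bases
  expect_lt(abs(pooled - 0.95), 3 * sqrt(0.95 * 0.05 / n_bases))
})

test_that("bedGraph output respects min_depth and round-trips", {
  calls <- data.frame(contig = "chr", pos = c(5L, 9L), strand = ".",
                      context = "CpG", n_converted = c(4L, 2L),
                      n_unconverted = c(2L, 2L), n_other = 0L,
                      level = c(2 / 3, 0.5), stringsAsFactors = FALSE)
  f <- tempfile(fileext = ".bedGraph")
  write_methylome(calls, f, min_depth = 5)
  back <- read_bedgraph(f)
  expect_equal(nrow(back), 1)  # the depth-4 site is dropped
  expect_equal(back$pos, 5L)
  expect_equal(back$level, 2 / 3)

  write_methylome(calls[0, ], f)
  expect_equal(nrow(read_bedgraph(f)), 0)

  z <- fx_noiseless_calls()
  mm <- merge_cpg_strands(z$calls)
  f2 <- tempfile(fileext = ".bedGraph")
  write_methylome(mm, f2, min_depth = 5)
  n_expected <- sum(mm$n_converted + mm$n_unconverted >= 5)
  expect_equal(nrow(read_bedgraph(f2)), n_expected)
})
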