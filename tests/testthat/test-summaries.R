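test_that("N50 matches hand-computed and brute-force values", {
  expect_equal(read_n50(c(2, 2, 2, 3, 3)), 3)
  expect_equal(read_n50(7), 7)
  expect_error(read_n50(numeric(0)), "empty")
  expect_error(read_n50(c(5, -1)), "positive")

  # largest length whose ">= L" tail still holds half of all bases
  n50_oracle <- function(lens) {
    half <- sum(lens) / 2
    for (l in sort(unique(lens), decreasing = TRUE)) {
      if (sum(lens[lens >= l]) >= half) return(l)
    }
  }
  set.seed(101)
  for (k in 1:10) {
    lens <- sample(100:10000, 1000, replace = TRUE)
    expect_equal(read_n50(lens), n50_oracle(lens))
  }
  # order invariance and scaling
  lens <- sample(100:5000, 500, replace = TRUE)
  expect_equal(read_n50(lens), read_n50(rev(sort(lens))))
  expect_equal(read_n50(lens * 3), 3 * read_n50(lens))
})

mk_calls <- function(pos, depth, level = 0.5, contig = "chr") {
  conv <- round(level * depth)
  lev <- conv / depth
  lev[depth == 0] <- NA_real_
  data.frame(contig = contig, pos = as.integer(pos), strand = ".",
             context = "CpG", n_converted = as.integer(conv),
             n_unconverted = as.integer(depth - conv), n_other = 0L,
             level = lev, stringsAsFactors = FALSE)
}

test_that("coverage overlap counts sites by depth threshold", {
  a <- mk_calls(c(10, 20, 30), c(5, 6, 4))
  b <- mk_calls(c(20, 30, 40), c(9, 5, 5))
  ov <- coverage_overlap(a, b, min_depth = 5)
  # a has {10,20}, b has {20,30,40}
  expect_equal(unname(ov), c(1, 1, 2))
  # symmetry
  vo <- coverage_overlap(b, a, min_depth = 5)
  expect_equal(ov[["only_a"]], vo[["only_b"]])
  expect_equal(ov[["both"]], vo[["both"]])

  same <- coverage_overlap(a, a)
  expect_equal(unname(same), c(0, 2, 0))
  disj <- coverage_overlap(mk_calls(1:3, 9), mk_calls(11:13, 9))
  expect_equal(disj[["both"]], 0)
})

test_that("coverage overlap equals the set-algebra oracle on simulated runs", {
  z <- fx_noiseless_calls()
  m <- merge_cpg_strands(z$calls)
  set.seed(102)
  # two random downsamples of the read set
  ids <- unique(z$aln$qname)
  sub_calls <- function(frac, seed) {
    set.seed(seed)
    keep <- sample(ids, round(frac * length(ids)))
    merge_cpg_strands(pileup_cytosines(z$aln[z$aln$qname %in% keep, ],
                                       z$sim$genome$contigs))
  }
  a <- sub_calls(0.5, 103); b <- sub_calls(0.5, 104)
  ov <- coverage_overlap(a, b, min_depth = 5)
  keys <- function(d) paste(d$contig, d$pos)[d$n_converted + d$n_unconverted >= 5]
  ka <- keys(a); kb <- keys(b)
  expect_equal(unname(ov), c(length(setdiff(ka, kb)),
                             length(intersect(ka, kb)),
                             length(setdiff(kb, ka))))
})

test_that("binned correlation behaves at the trivial limits", {
  set.seed(105)
  a <- mk_calls(seq(0, 99999, by = 97), 10,
                level = round(runif(1031), 1))
  expect_equal(binned_correlation(a, a, bin_size = 5000), 1)
  anti <- a
  anti$n_converted <- a$n_unconverted
  anti$n_unconverted <- a$n_converted
  anti$level <- 1 - a$level
  expect_equal(binned_correlation(a, anti, bin_size = 5000), -1)
  expect_error(binned_correlation(a[1, ], a[1, ], bin_size = 5000),
               "fewer than 2")
})

test_that("independent replicates of one methylome correlate in bins", {
  sim <- simulate_genome(genome_size = 100000, spikein_length = 0,
                         seed = 106)
  rep_calls <- function(seed) {
    pars <- sim_params(n_reads = 120, error_rate = 0, spikein_fraction = 0,
                       seed = seed)
    rr <- simulate_reads(sim$genome, sim$methylome, pars)
    aln <- filter_alignments(normalize_strand(rr$aln))
    merge_cpg_strands(pileup_cytosines(aln, sim$genome$contigs))
  }
  r <- binned_correlation(rep_calls(107), rep_calls(108), bin_size = 2500,
                          min_depth = 3)
  expect_gt(r, 0.8)
})

test_that("SV overlap applies the flank-extension rule", {
  del <- function(s, e) data.frame(contig = "chr", start = s, end = e,
                                   type = "DEL", stringsAsFactors = FALSE)
  ins <- function(p) data.frame(contig = "chr", start = p, end = p,
                                type = "INS", stringsAsFactors = FALSE)
  # DEL [100,150) vs DEL [154,200): only joined by the 5 bp flanks
  ov <- sv_overlap(del(100, 150), del(154, 200), flank = 5)
  expect_equal(ov[["both"]], 1)
  expect_equal(sv_overlap(del(100, 150), del(154, 200), flank = 0)[["both"]],
               0)
  # INS 12 bp apart: beyond reach of two 5 bp flanks
  expect_equal(sv_overlap(ins(100), ins(112), flank = 5)[["both"]], 0)
  expect_equal(sv_overlap(ins(100), ins(109), flank = 5)[["both"]], 1)
  # type mismatch never matches
  expect_equal(sv_overlap(del(100, 150), ins(120), flank = 5)[["both"]], 0)
})

test_that("SV overlap equals the quadratic pairwise oracle", {
  rand_svs <- function(n, seed) {
    set.seed(seed)
    type <- sample(c("INS", "DEL"), n, replace = TRUE)
    start <- sample.int(5000, n)
    len <- ifelse(type == "INS", 0L, sample.int(100, n, replace = TRUE))
    data.frame(contig = sample(c("c1", "c2"), n, replace = TRUE),
               start = start, end = start + len, type = type,
               stringsAsFactors = FALSE)
  }
  oracle <- function(a, b, flank) {
    hits <- logical(nrow(a))
    for (i in seq_len(nrow(a))) {
      for (j in seq_len(nrow(b))) {
        if (a$contig[i] != b$contig[j] || a$type[i] != b$type[j]) next
        s1 <- max(a$start[i] - flank, 0); e1 <- a$end[i] + flank
        s2 <- max(b$start[j] - flank, 0); e2 <- b$end[j] + flank
        if (max(s1, s2) < min(e1, e2)) hits[i] <- TRUE
      }
    }
    hits
  }
  for (seed in 1:8) {
    a <- rand_svs(100, seed)
    b <- rand_svs(100, seed + 50)
    got <- sv_overlap(a, b, flank = 5)
    ha <- oracle(a, b, 5); hb <- oracle(b, a, 5)
    expect_equal(got[["both"]], sum(ha))
    expect_equal(got[["only_a"]], sum(!ha))
    expect_equal(got[["only_b"]], sum(!hb))
    # flank 0 equals plain intersection
    got0 <- sv_overlap(a, b, flank = 0)
    expect_equal(got0[["both"]], sum(oracle(a, b, 0)))
  }
})

test_that("SV readers extract type and size", {
  bed <- tempfile(fileext = ".bed")
  writeLines(c("chr1\t100\t200\tDEL", "chr1\t500\t500\tINS"), bed)
  svs <- read_sv_bed(bed)
  expect_equal(svs$type, c("DEL", "INS"))
  expect_equal(svs$length, c(100L, 0L))

  vcf <- tempfile(fileext = ".vcf")
  writeLines(c("##fileformat=VCFv4.2",
               "##contig=<ID=chr1,length=10000>",
               "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO",
               "chr1\t1000\t.\tN\t<DEL>\t.\tPASS\tSVTYPE=DEL;SVLEN=-120",
               "chr1\t2000\t.\tN\t<INS>\t.\tPASS\tSVTYPE=INS;SVLEN=80",
               "chr1\t3000\t.\tN\t<INS>\t.\tPASS\tSVTYPE=INS;SVLEN=30"),
             vcf)
  svs2 <- read_sv_vcf(vcf, min_size = 50)
  expect_equal(nrow(svs2), 2)  # the 30 bp INS is below the size floor
  expect_equal(svs2$type, c("DEL", "INS"))
  expect_equal(svs2$start[1], 999L)
  expect_equal(svs2$end[1], 999L + 120L)
  expect_equal(svs2$start[2], svs2$end[2])
})

test_that("annotation overlap fraction is exact on a hand-built case", {
  calls <- mk_calls(c(10, 60, 110), 9)
  bed <- data.frame(contig = "chr", start = c(0L, 100L), end = c(20L, 120L),
                    stringsAsFactors = FALSE)
  expect_equal(annotation_overlap(calls, bed), 2 / 3)
})
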