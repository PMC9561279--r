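---
title: "Strand-aware methylation calling for long-read TAPS libraries"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Strand-aware methylation calling for long-read TAPS libraries}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lrtaps)
```

## The chemistry and the counting rule

TAPS (TET-assisted pyridine borane sequencing) detects cytosine
modification directly: 5mC and 5hmC are oxidised to 5caC and reduced to
dihydrouracil, which amplifies and sequences as T. Unmodified cytosines
are untouched. This is the inverse of bisulfite chemistry, and because
the reaction is mild, multi-kilobase fragments survive and can be
sequenced on a long-read (CCS/HiFi) platform.

The consequence for calling is a single inverted formula. At a
reference cytosine covered by $n_T$ reads showing T and $n_C$ reads
showing C, the modification level is

$$\hat{m} = \frac{n_T}{n_T + n_C}.$$

`lrtaps` applies this inversion exactly once, in
`modification_level()`, and every other component speaks in
converted/unconverted vocabulary. This localises the classic
double-inversion bug to one audited line.

Bases that are neither C nor T at the site (alignment errors, deletions)
are tallied as `n_other` and never enter the denominator, mirroring the
C/T-only ratio of the counting rule.

## Strand deconvolution

The library carries a Y-shaped adapter whose two arms differ, so the
arm found at a read's 5' end, combined with the alignment orientation,
identifies the biological strand of the source molecule:

| adapter group | SAM flag | origin strand | normalised flag |
|---|---|---|---|
| forward | 16 | OT (original top) | 0 |
| reverse | 0  | OT | 0 |
| reverse | 16 | OB (original bottom) | 16 |
| forward | 0  | OB | 16 |

After normalisation, OT reads are counted only at + strand cytosines
and OB reads only at − strand cytosines (where conversion appears as
G→A in reference-forward orientation). `pileup_cytosines()` enforces
this strand isolation; permuting OB reads can never change a + strand
call.

Adapter matching is a semi-global edit-distance alignment (match 0,
mismatch/gap −1) of each arm against the first `length(arm) + 30` bases
of the read, accepting a match at edit distance ≤ ⌊0.1 × arm length⌋.
The trimming tool this emulates processes the two adapter sets
sequentially, which makes the outcome for a read matching both sets
order-dependent; we instead make the rule symmetric — the smaller edit
distance wins and ties stay unclassified — and accept classification by
the 5' arm alone when the read does not reach into the 3' adapter.
Partial arm matches hanging off the read end are not attempted; with
full-length arms ligated on both ends this only matters for severely
truncated reads, which are left unclassified.

## Tunable parameters that matter

* `min_mapq` (default 10): alignments below this mapping quality are
  excluded before pileup.
* `min_base_qual` (default 13): per-base floor for a read base to be
  counted at a site. The pipeline this reimplements does not state a
  floor; 13 (1 in 20 error) is a conventional caller default and is
  configurable.
* `min_depth` (default 5): informative depth ($n_T + n_C$) required for
  a CpG to enter coverage and correlation summaries.
* `pos_tolerance` (default 20 bp): duplicate-marking coordinate slack.
  Long-read 5'/3' coordinates jitter by indel errors, so exact-position
  duplicate detection under-calls; 20 bp is of the order of the
  per-read indel displacement at HiFi accuracy. Reads on an amplicon
  contig (the spike-in), where all genuine molecules share both ends,
  are excluded from duplicate marking — coordinate identity carries no
  duplicate information there.
* `flank` (default 5 bp): structural-variant intervals are extended by
  this much on both sides before overlap comparison, and overlap
  additionally requires matching SV type.
* ASM gates: `min_votes` (default 1) net haplotype votes to assign a
  read, `max_conflict_fraction` (default 0.2), and
  `min_depth_per_allele` (default 5) per-haplotype depth for a CpG to
  be tested.

## The simulator: what it emulates, and what it does not

`simulate_genome()` + `simulate_reads()` generate a complete synthetic
experiment so that every pipeline stage can be verified against ground
truth:

* **Genome** — contigs from a first-order base model with configurable
  GC (default 0.42) and a CpG tilt (default −1.4, i.e. roughly
  four-fold CpG depletion, as in mammalian genomes). Diploid mode
  plants phased heterozygous SNPs (default 1/kb); by default SNPs never
  hit the C or G of an annotated CpG, so methylation truth sites
  survive on both haplotypes.
* **Methylome** — each CpG unit draws its modification probability from
  a two-component mixture: Beta(8, 2) "bulk" with weight 0.8 and
  Beta(1, 20) "island-like" with weight 0.2. The source experiment
  gives no genome model; these defaults simply make the methylome
  bimodal in the mammalian way and are fully overridable.
  `set_imprinted_region()` overlays haplotype-specific levels for
  allele-specific methylation fixtures.
* **Spike-in** — a 4-kb random amplicon containing ≥ 5 CCGG sites,
  modified at probability exactly 1.0 at the internal C of every CCGG
  on both strands (the HpaII methyltransferase product) and 0.0
  elsewhere. The realised completeness of the real enzymatic reaction
  after two rounds is not published; 1.0 is assumed and exposed as the
  methylome slice, so incomplete methylation can be emulated by
  scaling it.
* **Library** — lognormal fragment lengths (median 5 kb, σ 0.4)
  truncated below 3 kb, emulating shearing plus size selection;
  spike-in molecules are full-length amplicons drawn with probability
  0.005; strand of origin OT/OB with p = 0.5; TAPS conversion with
  rate 0.9623 and false conversion 0.0036 (CpG) / 0.0012 (CpH) — the
  rates the spike-in QC of the real library reports; Y-adapter arms
  attached so that a forward-arm read aligning reverse derives from
  OT; uniform sequencing orientation; i.i.d. substitution errors at
  0.1% (HiFi-like).
* **Truth** — FASTQ with adapters, a coordinate-sorted truth SAM
  (MAPQ 60, pure-match CIGARs), per-molecule and per-CpG realised
  modification tables, a truth methylome BED, and a phased VCF in
  diploid mode.

Not modelled: indel sequencing errors (HiFi indel rates in homopolymers
are non-trivial; the pileup is CIGAR-aware and tested on indel-bearing
alignments, but simulated reads are substitution-only), PCR
amplification bias, polymerase kinetics, chimeras, and subread-level
CCS structure. Passing round-trip tests therefore demonstrates
correctness of the counting and bookkeeping, not robustness to every
artefact of real data; the MAPQ, base-quality and duplicate filters
exist for those artefacts but are exercised here only on synthetic
cases.

## Spike-in QC

Conversion rate is measured at the internal C of CCGG sites of the
control contig; the CpG false-positive rate at the remaining CpGs after
excluding sites whose 4-mer context is TCGG, CCGT or ACGG (plausible
off-targets of HpaII methyltransferase); the CpH false-positive rate at
all non-CpG cytosines. Two conventions had to be fixed because the
method description names the motifs but not the geometry:

* the 4-mer places the CpG's C at the position homologous to the
  internal C of CCGG (one base of 5' context, one base 3' of the G),
  read on the site's own strand — minus-strand sites use the
  reverse-complement context;
* rates are pooled over bases (read-level counts), not averaged over
  sites, matching the per-base ratio formula of the caller.

A CpG at the sequence boundary without a full 4-mer is kept in the
unmodified set. Categories with zero covered bases report `NA`, never a
fabricated 0.

## Haplotagging and the ASM test

Reads vote at overlapped phased SNPs by their observed base. TAPS
conversion mimics C→T changes on OT-derived reads and G→A changes on
OB-derived reads, so C/T variant pairs are skipped for OT reads and A/G
pairs for OB reads; the variant stays usable on the other strand. This
masking is essential — without it converted reads systematically vote
for T-carrying or A-carrying alleles.

The experiment this implements demonstrates allelic methylation
visually; the statistical test is this package's own choice: per CpG, a
two-sided Fisher exact test on the 2×2 converted/unconverted ×
haplotype table, Benjamini–Hochberg corrected across tested CpGs. An
exact conditional test is mildly conservative at these depths (its null
rejection rate sits at or below the nominal level), which we prefer
over asymptotic alternatives at per-allele depths as low as 5.
Indel-based haplotype markers are supported only as simulator-planted
exact-representation variants; real indel tagging requires realignment
machinery that is out of scope.

## Numerical and bookkeeping choices

* Coordinates are 0-based half-open everywhere internally and in
  bedGraph/BED output; 1-based only inside SAM and VCF records.
* Strand-merged CpG records are keyed at the + strand C and span 2 bp.
* Duplicate groups keep the highest-MAPQ member, ties broken by longer
  reference span, then lexicographically smallest read id — fully
  deterministic.
* All simulator randomness flows from one master seed; identical seeds
  give byte-identical output files. Derived seeds are plain offsets of
  the master seed.
* `read_n50()` returns the largest length whose ≥-tail still contains
  half of all bases (the conventional N50), which also satisfies the
  sorted-cumulative-sum construction.
* Degenerate inputs: zero-depth levels are `NA`, empty call sets write
  header-only files, a haplotype with no reads yields an empty call set
  with a warning, and the pipeline removes partial outputs on stage
  failure.

## Problem sizes used in the checks

The test-suite and the acceptance script work at desk scale: 200-kb
genomes with ~2000 5-kb reads for round-trip and strand checks (about
50× coverage), a 4-kb spike-in at ~540 reads for QC recovery, 20-kb
diploid loci at ~30–75 reads per allele for ASM, and hundreds of small
randomised alignment instances for the pileup-versus-brute-force
property. These sizes give the binomial standard errors the checks
assert against while keeping a full run in minutes on one core.

## Known limitations

* Substitution-only error model in the simulator (see above).
* The external aligner is delegated (`minimap2` via the pipeline's
  `aligner` option, or any SAM/BAM you supply); alignment artefacts
  such as supplementary/secondary records are dropped rather than
  reconciled.
* CHG/CHH calls are reported but carry no biological interpretation
  here; TAPS reports the 5mC+5hmC sum and this package does not attempt
  to separate the two marks.
* Read-based phasing of unphased VCFs is out of scope; the phased GT
  field is required.
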