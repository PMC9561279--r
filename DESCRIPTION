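Package: lrtaps
Title: Strand-Aware Methylation Calling for Long-Read TAPS Sequencing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for base-resolution DNA methylation calling from
    TAPS-converted (TET-assisted pyridine borane sequencing) long reads,
    in which modified cytosines are read as thymine. Includes Y-adapter
    based strand classification of CCS-like reads, original-top/bottom
    strand normalisation of alignment flags, coordinate-tolerant duplicate
    marking, a CIGAR-aware strand-specific cytosine pileup with the
    TAPS-inverted modification-level formula, spike-in conversion-rate and
    false-positive-rate QC with HpaII off-target exclusion, haplotype
    tagging and allele-specific methylation testing, dataset summaries
    (N50, CpG coverage overlap, binned correlation, structural-variant
    overlap), and a full TAPS chemistry simulator that generates genomes,
    methylomes, adapter-ligated reads and ground truth so that every stage
    is testable without real sequencing data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    BiocGenerics,
    Biostrings,
    methods,
    IRanges,
    Rsamtools,
    stats,
    utils,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
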