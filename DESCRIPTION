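Package: multigwas
Title: Multi-Strategy Genome-Wide Association for Quantitative Traits
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: SNP-, haplotype- and gene-based genome-wide association
    scans for quantitative traits such as average daily gain in beef
    cattle. Provides a mixed-linear-model core (VanRaden genomic
    relationships, EMMA-style REML variance components, an EMMAX/P3D
    single-marker scan and per-marker variance explained), Gabriel-style
    haplotype block partitioning with EM phasing and a two-step
    block-level variance-explained statistic, a gene-based test built on
    principal components of intragenic genotypes regressed against GBLUP
    breeding values with permutation-derived significance thresholds,
    marker and sample quality control, and a seeded synthetic-data
    generator that emulates LD-block-structured genotype panels with
    planted causal signals for calibration and power studies.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    methods,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    vcfR,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
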