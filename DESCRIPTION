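Package: HapMET
Title: Haplotype-Based GWAS, Yield Stability and Genomic Prediction for
    Multi-Environment Trials
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Analysis pipeline for grain-yield multi-environment trials in
    inbred crop panels: check-based adjustment of alpha-lattice plot data,
    factorial ANOVA and broad-sense heritability, Lin-Binns and
    Eberhart-Russell yield-stability indices, linkage-disequilibrium
    haplotype-block construction from D-prime confidence intervals,
    mixed-linear-model association scans for single SNPs and haplotype
    blocks with VanRaden kinship, two- and three-locus epistasis scans,
    and G-BLUP / Gaussian-kernel (RKHS) genomic prediction with
    GWAS-derived loci as fixed effects, evaluated by repeated
    cross-validation. Includes a synthetic-data generator that reproduces
    the assumed statistical structure (LD blocks, alpha-lattice designs
    with repeated checks, genotype-by-environment interaction) so the
    whole pipeline is testable without field data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    yaml,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
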