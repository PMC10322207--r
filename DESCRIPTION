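Package: IonMut
Title: Screening and Characterization of Heavy-Ion-Beam Induced Mutations
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for identifying and characterizing induced mutations in
    whole-genome-sequenced mutagenized plant populations, built around
    carbon-ion-beam (CIB) rice mutagenesis. Implements multi-sample variant
    screening from per-site allele-count tables (callability, focal and
    background variant-allele-frequency thresholds, zygosity, removal of
    parental and cross-plant shared variants), mutation-spectrum statistics
    (six-class substitution typing, Ts/Tv, InDel size bins, per-dose
    summaries), panicle-lineage sharing analysis, variant-effect annotation
    with candidate-gene selection, single-hit multi-target (SHMT)
    dose-response fitting with shoulder-dose and LD50 derivation, and a
    seeded synthetic-cohort generator (miniature genome, gene models,
    dose-dependent truth mutations with Mendelian segregation and panicle
    lineage, noisy read counts) so the whole pipeline is testable without
    raw sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3.0)
Imports:
    methods,
    stats,
    utils,
    BiocGenerics,
    S4Vectors,
    IRanges,
    SummarizedExperiment,
    GenomicRanges,
    GenomeInfoDb,
    Biostrings,
    rtracklayer,
    VariantAnnotation,
    minpack.lm,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
biocViews: Sequencing, VariantDetection, VariantAnnotation, Genetics
RoxygenNote: 7.3.3
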