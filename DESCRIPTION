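Package: cdmv
Title: Commonly Variable DNA Methylation Analysis for EWAS Target Selection
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for studying inter-individual DNA methylation variability
    from whole-genome bisulfite sequencing (WGBS) methylation calls and for
    selecting epigenome-wide association study (EWAS) target CpG sites by
    common variability. Reads Bismark-style per-CpG coverage files, applies
    read-depth, variant-masking and call-rate quality filters, and assembles a
    CpG-by-sample methylation matrix. Quantifies per-CpG variability with the
    reference interval (difference between the 95th and 5th percentiles of
    methylation levels across individuals), classifies CpGs by methylation
    status, and builds commonly-variable target sets outside repetitive
    regions. Evaluates target sets against catalogs of previously reported
    EWAS CpGs via biomarker likelihoods, Fisher exact tests and odds ratios
    with Woolf confidence intervals, including decile profiles and
    design-stratified comparisons. Also provides promoter and CpG-island
    shore derivation, regulatory-element enrichment, per-CpG smoking and
    quantitative-trait regression with age and sex adjustment, Monte-Carlo
    power estimation for Fisher-exact efficacy comparisons, and a synthetic
    WGBS cohort generator with known ground truth for end-to-end validation.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    methods,
    data.table,
    jsonlite,
    IRanges,
    GenomicRanges,
    Biostrings,
    vcfR
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
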