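Package: scMitoHet
Title: Single-Cell Mitochondrial DNA Somatic Heteroplasmy Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantifies somatic mitochondrial DNA heteroplasmy in single
    cells from per-position allele counts. Provides a circular rCRS genome
    model with locus annotation and low-complexity masks, a count-based
    substitution caller with heteroplasmic-fraction thresholds and coverage
    quality control, consensus- and privacy-based somatic variant
    identification, strand-aware synonymous/non-synonymous annotation under
    the vertebrate mitochondrial genetic code, pathogenicity classification
    from score tables, locus-length-normalized burden statistics with
    many-to-one Dunnett comparisons, and a Wright-Fisher drift simulator of
    single-cell allele-count data with ground truth for recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Biostrings,
    IRanges,
    mvtnorm,
    e1071
Suggests:
    testthat (>= 3.0.0),
    multcomp,
    VariantAnnotation,
    SummarizedExperiment,
    ggplot2,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
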