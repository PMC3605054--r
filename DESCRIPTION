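Package: transfine
Title: Trans-Ethnic Fine-Mapping of Quantitative Trait Loci
Version: 0.1.0
Authors@R: person("Maintainer", "Transfine", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for fine-mapping quantitative trait loci across ancestry
    groups with divergent linkage disequilibrium: per-study single-variant
    association under an additive linear model, inverse-variance fixed-effect
    meta-analysis with Cochran's Q and I-squared heterogeneity statistics,
    sequential conditional analysis with an annotation-aware stopping rule,
    two-locus and multilocus EM haplotype-frequency estimation with haplotype
    regression, variance-explained decomposition, association-region
    refinement across ancestries, and analytic power calculation. A bundled
    synthetic-data generator produces multi-ancestry genotype panels with
    block-structured, ancestry-divergent linkage disequilibrium and additive
    quantitative traits so the full pipeline can be exercised end to end
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    stats,
    utils,
    VariantAnnotation,
    SummarizedExperiment,
    BiocGenerics,
    GenomeInfoDb
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
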