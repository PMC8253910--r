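Package: miprot
Title: Multiple-Imputation Differential Expression for Label-Free Proteomics
Version: 0.1.0
Authors@R: person("miprot", "developers", role = c("aut", "cre"),
    email = "miprot@example.org")
Description: Analysis pipeline for label-free quantitative tissue proteomics
    with left-censored (missing-not-at-random) intensities. Implements the
    MaxQuant proteinGroups filter cascade, QRILC truncated-normal imputation
    with a multiple-imputation ensemble, per-replicate two-way ANOVA with
    Tukey HSD contrasts and Benjamini-Hochberg adjustment pooled across
    replicates by geometric mean, plus principal component analysis,
    hierarchical cluster profiles, hypergeometric cross-study signature
    overlap with directional concordance, over-representation analysis, and
    urine-endpoint statistics. Includes a synthetic-data generator emulating
    a two-arm, three-timepoint porcine kidney preservation design with
    intensity-dependent censoring for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
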