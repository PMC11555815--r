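Package: dcornet
Title: Differential Spearman Correlation Networks for Longitudinal Biomarker Panels
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds and compares group-wise Spearman correlation networks from
    longitudinal immunoassay panels, as used to characterise serum cytokine and
    growth-factor signatures of neonatal morbidities in extremely preterm
    infants. Covers the full analysis path: limit-of-detection imputation
    (LOD/8), log transformation, log-linear interpolation of missing samples,
    sparse-analyte exclusion, first-month AUC/time summarisation,
    gestational-age residualization, per-group Spearman networks with
    edge-difference testing (Fisher z with the Fieller variance factor,
    permutation, or bootstrap rank-sum), hub ranking by summed z-scores,
    confounder stratification of differential edges, and per-analyte level
    comparisons. Includes a seeded Gaussian-copula cohort simulator with
    gestational-age-dependent log-normal analyte levels, group-specific
    planted correlation structure, left-censoring and missingness, so the
    whole pipeline is testable without access to restricted patient data.
License: MIT
Encoding: UTF-8
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    igraph
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
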