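Package: druggable
Title: Multi-Omics Druggability Inference for Cancer Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Infers potentially druggable alterations in tumor cohorts by
    matching somatic mutations against a curated variant/drug knowledgebase
    with evidence tiers and cancer-type specificity, scoring mRNA and
    (phospho)protein expression outliers with Tukey-style IQR fences,
    nominating putative drug-response mutations by recursive 3D proximity
    clustering on protein structures, integrating calls across data levels
    into per-tumor multi-omics druggability and co-occurrence reports,
    quantifying demographic enrichment of druggable genes, and validating
    biomarkers against cell-line drug screens (Mann-Whitney LN(IC50)
    comparisons and outlier-score regressions). Includes a synthetic-cohort
    generator with ground-truth tables so every stage is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    igraph,
    stats,
    utils
Suggests:
    bio3d,
    jsonlite,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
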