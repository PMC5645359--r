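Package: hgscompare
Title: Comparative Molecular Analysis of High-Grade Serous Carcinoma With
    and Without Tubal Precursor Lesions
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A tested pipeline for the multi-platform comparison of
    high-grade serous carcinoma (HGSC) tumors with and without serous tubal
    intra-epithelial carcinoma (STIC) lesions, and for matching tumors to
    their most likely normal tissue of origin. Provides two-group class
    comparison of expression under Benjamini-Hochberg false discovery rate
    control, a correlation-based nearest-prototype subtype classifier with
    an ambiguity-rejection rule, a tissue-of-origin signature built from
    one-versus-rest marker genes with Spearman matching and an exact
    binomial confidence interval on the origin call, region-level somatic
    copy-number frequency comparison, and power-by-simulation for
    FDR-controlled differential expression designs. A synthetic-cohort
    generator emulates the statistical structure of such a study so every
    stage is testable without access to protected data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    withr,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    DESeq2
Config/testthat/edition: 3
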