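Package: proteoconcord
Title: Cross-Platform Proteomics Concordance, QC and Reproducibility Scoring
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for head-to-head comparison of affinity proteomics
    platforms (aptamer- and antibody-based panels) on shared samples:
    readers for wide RFU and long NPX tables, log2 + z-score
    harmonization, UniProt-set reagent pairing, PCA-based structure
    checks with IQR outlier removal, intra- and inter-assay coefficient
    of variation for linear- and log2-scale readouts, Spearman-based
    intra- and inter-platform correlation with a combined 1-9/A-C
    reproducibility and reliability score, covariate-adjusted phenotype
    association screens with Bonferroni control, LASSO
    variance-explained reports, and a bootstrap null for top-K ranking
    overlap.  Includes a synthetic two-platform study generator with
    known ground truth for validating every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    glmnet,
    stats,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
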