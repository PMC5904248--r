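Package: ehrgenval
Title: Genetic Validation of EHR-Derived Case-Control Phenotypes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for validating rule-based and classifier-based phenotypes
    derived from longitudinal electronic health records (EHR) with genome-wide
    genetic data, exercised end-to-end on synthetic data. Includes a synthetic
    EHR generator with latent diagnostic truth, bipolar-disorder phenotyping
    algorithms (coded rules and an adaptive-LASSO note-feature classifier),
    a liability-threshold genotype and summary-statistic simulator with block
    LD, a genotype quality-control cascade (missingness, heterozygosity,
    Hardy-Weinberg exact test, batch effects, PCA ancestry selection,
    relatedness pruning), per-SNP case-control association, LD score
    regression for SNP-based heritability and genetic correlation with
    observed-to-liability scale conversion and block-jackknife standard
    errors, and a genome-wide Cochran's Q heterogeneity scan.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    glmnet,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    vcfR,
    withr
Config/testthat/edition: 3
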