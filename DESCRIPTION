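Package: cnngwas
Title: Convolutional Neural Network Classification of Case-Control Genotypes
    with GWAS-Guided Feature Selection
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates case-control genotype cohorts with known per-SNP effect
    sizes and linkage-disequilibrium structure, selects SNP features from
    external genome-wide association summary statistics at p-value thresholds,
    encodes genotypes as additive minor-allele counts, and classifies disease
    status with a small one-dimensional convolutional neural network trained
    with early stopping and dropout. Includes Grad-CAM per-SNP saliency
    attribution, per-SNP logistic association scans, linkage-disequilibrium
    clumping with polygenic risk scoring, negative-control validations
    (null-SNP subsets and index-parity pseudo-labels), propensity-score
    matching, and a panel of classification metrics aggregated over repeated
    stratified train/validation/test splits.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    glmnet,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
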