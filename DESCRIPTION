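Package: impactmodes
Title: Imaging Genetics of Polygenic Disposition: Mass-Univariate Association
    and Impact-Mode Decomposition
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: An imaging-genetics analysis pipeline: variant quality control
    (minor allele frequency, imputation quality, Hardy-Weinberg equilibrium),
    kinship-based relatedness pruning, greedy linkage-disequilibrium clumping,
    clumping-and-thresholding polygenic scores optimized against
    imaging-derived phenotypes, mass-univariate general linear models of
    voxel- or fixel-wise brain measures with max-statistic permutation
    inference for brain-wide family-wise error control, and spatial
    independent component analysis of variant-wise t-statistic maps into
    "impact modes" (spatially independent brain components with per-variant
    weight z-scores). Includes a synthetic-data module that plants a known
    low-rank modes-by-loadings structure in simulated genotypes and brain
    maps so every stage can be validated against ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    data.table,
    jsonlite,
    RNifti
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
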