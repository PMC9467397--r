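Package: ironherit
Title: Pedigree-Based Variance-Components Analysis of Regional Brain Iron
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Univariate and bivariate polygenic variance-components models
    for family studies of quantitative MRI phenotypes. Parses PED/FAM
    pedigrees, computes kinship matrices by the recursive tabular method,
    classifies relative pairs, estimates heritability of regional R2*
    brain-iron measures by maximum likelihood with boundary likelihood-ratio
    tests, screens covariates, attributes covariate variance, partitions
    phenotypic correlations into genetic and environmental components, and
    applies grouped false-discovery-rate correction. Includes a synthetic
    family-cohort generator emulating a two- and three-member family design
    so the whole inference chain is testable without access to the original
    cohort.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
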