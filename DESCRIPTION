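Package: grazediv
Title: Diversity Responses of Soil Food Webs to Cessation of Grazing
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Analysis pipeline for paired grazed/ungrazed plot studies of
    soil organism communities across multiple sites. Computes alpha-diversity
    (taxon richness) and within-site beta-diversity (mean pairwise
    Bray-Curtis dissimilarity on presence-absence data), their response
    ratios to cessation of grazing, occupancy-based rare/common/widespread
    cohort analyses, Gaussian linear mixed models with a random site
    intercept, and AICc-based multimodel inference with conditional model
    averaging of candidate driver models. Includes a synthetic multi-site
    community generator that emulates the paired-exclosure study design so
    every estimator can be validated by parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    vegan,
    jsonlite
Suggests:
    lme4,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
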