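Package: rrmforage
Title: Random Regression Models for Multi-Harvest Forage Trials
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Two-stage analysis of longitudinal dry-matter-yield data from
    multi-harvest perennial forage breeding trials. Stage one estimates
    per-harvest genotype BLUEs and Smith weights from plot-level data under
    common field designs; stage two fits a weighted random regression model
    on normalized Legendre polynomials by restricted maximum likelihood,
    with BIC-guided choice of the random polynomial order and a loess rule
    for the fixed order. From a fitted model the package derives the genetic
    covariance function across harvest times, heritability trajectories,
    eigenfunctions of the coefficient covariance, genotypic-value reaction
    norms, and the area-under-curve adaptability and curve
    coefficient-of-variation stability statistics used to rank genotypes.
    A seeded synthetic-trial generator with known truth supports testing
    and parameter-recovery studies.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    lme4
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    jsonlite,
    knitr,
    rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
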