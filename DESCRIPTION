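Package: emmpat
Title: Evolutionary Mixed Model for Pooled Association Testing
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Association testing for sequenced candidate genes that pools
    information across rare variants using population-genetic theory.  A
    distribution of fitness effects and a demographic model are used to
    predict, from each variant's observed allele count, the mean and variance
    of its selection coefficient; these predictions structure both the mean
    and the variance of per-variant phenotype effects in a Gaussian
    two-moment mixed model.  The package provides the fitness-prior
    machinery (a per-site Wright-Fisher forward simulator and an equilibrium
    Poisson Random Field oracle), quasi-likelihood model fitting with BLUP
    effect estimates, permutation-calibrated likelihood-ratio tests,
    attributable-variance decompositions, the standard burden-test
    competitors (minimum-p, CAST, CMC, Madsen-Browning weighted sum,
    optimal-mean regression), and a synthetic-cohort generator plus power
    study driver.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    pracma
Suggests:
    testthat (>= 3.0.0),
    vcfR,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
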