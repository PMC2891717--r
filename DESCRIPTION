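Package: tailassoc
Title: Selective-Genotyping Association and Single-Locus Heritability for
    Dose-Mortality Traits
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for quantifying the contribution of a single bi-allelic
    locus to a binary dose-mortality trait, as in insecticide-resistance
    association studies that genotype only the phenotypic extremes
    (survivors of a near-LC95 dose and dead at a near-LC5 dose).
    Provides maximum-likelihood log-dose probit modelling with LC-quantile
    estimation, extreme-tails association statistics (dead-count scaling,
    Cochran-Armitage trend test, exact tests, odds ratios, allele
    frequencies with exact binomial confidence intervals), a
    threshold-trait quantitative-genetic chain (gene action a and k,
    average allelic effect, additive variance, observed- and
    liability-scale heritability), and a Hardy-Weinberg cohort simulator
    so every stage can be validated on synthetic data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
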