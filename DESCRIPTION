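Package: wqbench
Title: Benchmarking Inference Methods for Water-Quality Status Classification
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates high-frequency nutrient-concentration populations,
    sub-samples them under regulatory monitoring schemes (Water Framework
    Directive operational and surveillance monitoring), and benchmarks
    statistical inference of the mean and 95th percentile. Implements
    maximum-likelihood fitting of unimodal and two-component mixture
    distributions (lognormal, gamma, Weibull) by EM, Bayesian inference of
    water-quality statistics via a lognormal model with uniform priors and
    via the Bayesian bootstrap, second-order uncertainty metrics (hit rate,
    highest density interval width, relative mean bias error), and
    physicochemical status classification by face-value, one-sided t-test
    and Bayesian posterior class probabilities against configurable class
    boundaries.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    fitdistrplus,
    jsonlite,
    yaml,
    withr
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
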