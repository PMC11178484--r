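Package: invadeGO
Title: Genomic Offset as a Predictor of Invasion Establishment Probability
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Forward-in-time simulation and statistical toolkit for asking whether
    genomic offset statistics predict the establishment probability of invasive
    populations. Provides a Wright-Fisher stepping-stone simulator of polygenic
    local adaptation on an environmental grid, a non-Wright-Fisher invasion
    simulator with overlapping generations yielding establishment probabilities,
    four genomic-offset estimators (latent-factor geometric offset, univariate and
    multivariate covariance-whitened GLS analogues, and a gradient-forest turnover
    offset) plus a squared Euclidean baseline, population-genetic summaries (f2,
    genome-wide FST, heterozygosity), and the evaluation pipelines relating offset
    to log establishment probability and to the f2 statistic.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    yaml,
    withr,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    ggplot2
Config/testthat/edition: 3
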