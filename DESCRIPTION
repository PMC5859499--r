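Package: cqmix
Title: Design and Measurement Assurance of Mixture-Based RT-qPCR Reference Samples
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for designing pairs of cell-based reference samples with
    built-in microRNA abundance differences and for assessing the performance
    of an RT-qPCR measurement process against those designs. Provides in-silico
    prediction of mixture quantification-cycle (Cq) values from component
    profiles under the additive linear-abundance model, grid search over
    mixture-fraction designs with Bland-Altman scoring, delta-Cq and
    delta-delta-Cq difference statistics, full-factorial variance decomposition
    of inter-laboratory crossover designs, and Bayesian mixed-effects bias
    assessment via normalized marginal-likelihood curves fitted with a
    Gibbs-within-Metropolis sampler. A synthetic-data generator emulates the
    seven measurement scenarios of a two-laboratory crossover study so that
    every analysis is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    ggplot2
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr,
    lme4
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
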