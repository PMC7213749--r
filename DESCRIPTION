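Package: clonexpand
Title: Bayesian Detection of Clonal Expansion from Immune Repertoire Sequencing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Disentangles true clonal dynamics from measurement noise in
    T-cell receptor repertoire sequencing. Learns a power-law clone-size
    distribution together with an explicit noise model (Poisson, negative
    binomial, or a two-step negative-binomial-to-Poisson law) from same-day
    replicate samples by maximum likelihood conditioned on observed clones;
    learns an empirical-Bayes prior on log fold-changes from two time points
    under an equal-repertoire-size constraint; and computes per-clone
    posteriors of log fold-change to identify responding clones. Includes
    Hill-diversity estimation with uncertainty propagation and an exact
    synthetic-data generator (quadrant-conditioned sampling of observed
    clones) so the whole pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    MASS,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
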