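Package: megmultiplex
Title: Multilayer Network Analysis of MEG Frequency-Band Connectivity
Version: 0.1.0
Authors@R: person("Multinet", "Maintainer", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: A pipeline from multichannel oscillatory time series to
    frequency-band phase-lag-index (PLI) connectivity, per-band minimum
    spanning tree backbones, a multiplex supra-adjacency network,
    multilayer eigenvector centrality averaged over a frontoparietal node
    set, and cohort-level statistics (impairment classification, paired
    change tests, covariate screening, backward-elimination regression
    with Bonferroni correction). Includes a synthetic-data module that
    generates coupled band-limited oscillators and two-timepoint cohorts
    with known effect sizes, so every stage is testable without patient
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    igraph
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
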