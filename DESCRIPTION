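Package: grud
Title: Gated Recurrent Units with Trainable Decay for Multivariate Time
    Series with Missing Values
Version: 0.1.0
Authors@R:
    person("Artifact", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Classification of irregularly sampled multivariate time series
    with missing values, as found in ICU and other clinical cohorts.
    Implements the GRU-D recurrent cell, which augments a gated recurrent
    unit with trainable input decay (stale measurements relax toward the
    training mean) and hidden-state decay, both driven by per-variable
    elapsed time since the last observation.  Also provides the standard
    masking/interval data model, mean- and forward-imputation GRU baselines,
    the mask-and-interval concatenation baseline, exact backpropagation
    through time with Adam and early stopping, stratified cross-validated
    AUC evaluation, online (truncated-prefix) prediction curves, decay
    interpretation reports, and a synthetic-data generator with a tunable
    correlation between per-sample missing rates and class labels.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
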