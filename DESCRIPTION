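Package: fanotime
Title: Fano Factor Analysis of Spike Trains in Operational Time
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for measuring spike-count variability with the Fano
    factor while accounting for its dependence on the firing rate.
    Provides parametric interspike-interval models (gamma, inverse
    Gaussian, exponential with rate-scaled refractory period, pacemaker)
    and two-state Markov renewal models, exact windowed Fano-factor
    curves F(w) via numerical Laplace-transform inversion, equilibrium
    (time-stationary) spike-train simulators, the intensity-invariant
    operational Fano-factor estimator with its shifted-window variant,
    and a Monte-Carlo harness for comparing Fano-factor ratio estimators
    across experiments with different firing rates.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
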