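Package: glyrisk
Title: Risk-Scale Glucose Forecasting for Continuous Glucose Monitor Data
Version: 0.1.0
Authors@R:
    person("glyrisk", "developers", email = "glyrisk@example.org", role = c("aut", "cre"))
Description: Tools for short-horizon forecasting of continuous glucose
    monitor (CGM) time series on the Kovatchev blood-glucose risk scale.
    Provides CGM cleaning and floor-mean gap imputation, the symmetrizing
    glucose-to-risk transform and its inverse, supervised window
    construction for recurrent and lattice (convolutional) model families,
    small neural forecasters (RNN, GRU, LSTM, CNN) trained by
    backpropagation with an Adam optimizer, a sample-and-hold
    last-measurement baseline, and evaluation via plain, risk-weighted and
    Clarke-error-grid metrics.  A synthetic CGM cohort generator emulates
    the right-skewed distribution, sensor artifacts and gap structure of
    real CGM exports so that the whole pipeline is testable without access
    to restricted clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
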