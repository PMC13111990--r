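Package: boldhmm
Title: Variational Bayesian Hidden Markov Brain States from Parcellated BOLD
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Decomposes parcellated resting-state fMRI time series into a small
    number of recurring whole-brain activity states with a variational Bayesian
    Gaussian-observation hidden Markov model. Provides free-energy model
    selection over the number of states, fractional-occupancy and state-map
    summaries, nonparametric group and clinical statistics with
    Benjamini-Hochberg false-discovery-rate control, ROI time-series extraction
    from NIfTI volumes (atlas merging, truncation, band-pass filtering,
    nuisance regression, standardization), and a synthetic two-group cohort
    generator with analytic Markov-chain oracles for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    signal,
    RNifti,
    jsonlite,
    withr,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    ggplot2,
    optparse,
    yaml
Config/testthat/edition: 3
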