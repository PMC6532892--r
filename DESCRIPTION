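Package: onglide
Title: Attractor-Landscape Modelling of Pitch Accent Onglides
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for modelling the choice and realisation of nuclear pitch
    accents as a tilted double-well dynamical system. Provides exact algebra
    and numerics for one-dimensional potential landscapes (fixed points,
    bifurcation analysis, stationary densities), stochastic Euler-Maruyama
    simulation of accent production, a sign-preserving log normalisation for
    tonal onglide data in semitones, descriptive fall/rise summaries, a
    simulation-based grid search that fits the landscape tilt per focus
    condition and speaker group, a two-component Gaussian mixture analysis
    with bootstrap contrasts, and a synthetic-data generator emulating a
    production experiment with multiple speakers, focus conditions and
    target words.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    grDevices,
    graphics,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    mclust,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
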