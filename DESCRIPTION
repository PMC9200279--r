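Package: swarmaggr
Title: Quantifying the Swarm-to-Biofilm Transition from Time-Lapse Microscopy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for the terminal stages of bacterial swarming,
    where motile Bacillus subtilis cells coexist with stationary aggregates
    nucleated by immotile, matrix-producing (EPS-secreting) cells. Provides
    dense optical-flow velocimetry (Farneback polynomial expansion) with
    coarse-grained velocity and speed fields, speed-threshold segmentation of
    stationary aggregates with persistence filtering, maximum-likelihood
    fitting of aggregate-size distributions (power law, exponential, and
    power law with exponential cutoff) with AIC model selection, single-cell
    trajectory linking with mean-square-displacement exponent classification
    (sub-/super-/normal diffusion and transitive tracks), local surface
    coverage and speed-versus-coverage statistics inside and outside
    aggregates, radial colony profiles, and quantification of the
    EPS-secreting subpopulation from a second fluorescence channel. Includes
    an agent-based simulator of swarming cells with trapping by immotile
    seeds that generates calibrated two-channel image stacks with ground
    truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    EBImage,
    tiff,
    yaml,
    jsonlite,
    pracma,
    e1071,
    stats,
    utils,
    graphics
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
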