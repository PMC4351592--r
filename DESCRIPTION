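Package: spikedecoder
Title: Spatiotemporal Decoding of Directional Choice from Motor Cortical Ensembles
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing small ensembles of simultaneously recorded
    motor cortical single units while an animal learns a two-alternative
    directional choice task. Provides an inhomogeneous-Poisson spike-train
    simulator with session-wise learning structure, peri-event firing-rate
    estimation with sliding boxcar windows, ensemble rate statistics
    (per-unit and ensemble class means and absolute rate differences), a
    resampled linear-classifier protocol that decodes the directional
    choice from concatenated spike-count vectors (including label-shuffle
    chance controls, single-unit, bin-size, single-bin and ensemble-size
    analyses), and session-trend statistics, i.e. Z-scored linear regression
    against normalized session number with confidence-interval based slope
    sign calls, learning-stage summaries and slope-comparison tests.
    Sessions are exchanged as plain CSV/JSON bundles and the stages can be
    driven from a small command-line front end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    e1071,
    MASS,
    jsonlite
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
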