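Package: freeview
Title: Eye Calibration, Saccade Detection, and Receptive/Motor Field
    Mapping for Free-Viewing Oculomotor Electrophysiology
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.com", role = c("aut", "cre"))
Description: Analysis toolkit for oculomotor electrophysiology sessions
    recorded while a subject freely views a screen.  Provides
    dispersion-based fixation detection on smoothed gaze traces,
    fixation-cluster eye-tracker calibration (per-axis Gaussian fits of
    fixation clusters around salient stimuli, gain/offset by least
    squares), velocity/acceleration threshold saccade detection with
    amplitude-direction description, reverse-correlation visual
    receptive-field mapping over a patch-stimulus grid, peri-saccadic
    motor-field mapping over a polar amplitude-direction binning, and a
    seedable synthetic-session simulator (minimum-jerk saccades,
    inhomogeneous Poisson spiking) whose latent parameters support
    end-to-end recovery tests.  Includes a command-line interface with
    stable CSV/JSON file contracts.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    graphics,
    jsonlite,
    minpack.lm,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
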