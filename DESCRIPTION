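Package: phosim
Title: Biologically Plausible Simulation of Cortical Prosthetic Vision
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A stateful, frame-based simulator of the visual percepts
    ('phosphenes') elicited by intracortical microstimulation of primary
    visual cortex. Electrode positions on a flattened cortical map are
    related to visual-field locations through a wedge-dipole visuotopic
    model with cortical magnification; per-electrode stimulation parameters
    (amplitude, pulse width, frequency) drive a leaky-integrator model of
    tissue activation with normally distributed detection thresholds, a
    sigmoidal brightness response, and a slow memory trace that reproduces
    brightness accommodation under repeated stimulation. Percepts are
    rendered as Gaussian (or Gabor) profiles in a differentiable-by-design
    pipeline. Includes synthetic psychometric data generators and fitting
    routines (detection-threshold distribution, brightness sigmoid,
    strength-duration curve) with cross-validation, plus readers and
    writers for electrode layouts, stimulation sequences, and rendered
    frames.
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
    jsonlite,
    minpack.lm,
    png,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
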