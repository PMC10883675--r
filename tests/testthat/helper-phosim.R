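# small rendering window used throughout the tests
test_cfg <- function(...) {
  phosim_config(resolution = c(64, 64), fov_deg = 16, ...)
}

# single electrode at a mid-eccentricity cortical site
single_electrode_map <- function(cfg) {
  make_grid_layout(1, 1, 0.4, origin = c(20, 0), cfg)
}

# amplitude (uA) whose train reaches a given target activation, by bisection
amplitude_for_activation <- function(target, pulse_width_us, frequency_hz,
                                     duration_ms, cfg) {
  stats::uniroot(
    function(a) train_activation(a, pulse_width_us, frequency_hz,
                                 duration_ms, cfg) - target,
    interval = c(cfg$I0 * 1e6, 5000), tol = 1e-10)$root
}

# detection conditions spanning the psychometric range under defaults
detection_conditions <- function(n_conditions, cfg) {
  lo <- amplitude_for_activation(max(cfg$theta50 - 2.5 * cfg$sigma,
                                     cfg$theta50 / 20),
                                 170, 300, 166, cfg)
  hi <- amplitude_for_activation(cfg$theta50 + 2.5 * cfg$sigma,
                                 170, 300, 166, cfg)
  tibble::tibble(
    amplitude_uA = seq(lo, hi, length.out = n_conditions),
    pulse_width_us = 170, frequency_hz = 300, duration_ms = 166)
}

# brightness conditions sampling the sigmoid transition around A50 (the
# transition has width ~10/lambda, a narrow amplitude band)
brightness_conditions <- function(n_conditions, cfg) {
  targets <- cfg$A50 + seq(-20, 20, length.out = n_conditions) / cfg$lambda
  tibble::tibble(
    amplitude_uA = vapply(targets, amplitude_for_activation, numeric(1),
                          pulse_width_us = 170, frequency_hz = 300,
                          duration_ms = 166, cfg = cfg),
    pulse_width_us = 170, frequency_hz = 300, duration_ms = 166)
}
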