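#' Simulator configuration with fitted default parameters
#'
#' Builds the full parameter registry of the simulator. Defaults are the
#' fitted values for intracortical stimulation of human V1: the wedge-dipole
#' visuotopic constants, the cortical excitability constant of the
#' current-spread size model, the rheobase and leaky-integrator constants of
#' the tissue-activation model, the brightness sigmoid, the detection
#' threshold distribution, and the memory-trace (habituation) constants.
#'
#' Currents are stored internally in amperes and pulse widths in seconds;
#' the constructor and the configuration file accept microamperes
#' (`I0_uA`) and the rendered outputs use degrees of visual angle, because
#' all published values are quoted in those units. The excitability constant
#' `K` keeps its published unit (uA mm^-2) since the size model is defined on
#' currents in uA.
#'
#' @param a,b Dipole singularity parameters of the visuotopic map (deg);
#'   `0 < a < b`.
#' @param k Cortical scaling factor of the visuotopic map (mm).
#' @param alpha Shear of the wedge map, in `(0, 1]`.
#' @param hemisphere `"left"` or `"right"`: the cortical hemisphere carrying
#'   the electrodes. A right-hemisphere map renders phosphenes in the left
#'   visual hemifield and vice versa.
#' @param K Cortical excitability constant (uA mm^-2) of the current-spread
#'   model for phosphene size.
#' @param I0_uA Rheobase current (uA): the ineffective component subtracted
#'   from the stimulation amplitude.
#' @param tau_act Decay time constant of the tissue-activation leaky
#'   integrator (s).
#' @param d Duration scale of stimulation relative to the frame duration,
#'   in `(0, 1]`.
#' @param lambda Slope of the sigmoidal brightness curve (per activation
#'   unit).
#' @param A50 Activation at which a phosphene reaches half its maximum
#'   brightness.
#' @param theta50 Mean of the per-electrode detection-threshold
#'   distribution (activation units).
#' @param sigma Standard deviation of the detection-threshold distribution.
#' @param tau_trace Decay time constant of the memory trace (s).
#' @param kappa Input gain of the memory trace (dimensionless).
#' @param dt Frame duration (s); must satisfy `dt < tau_act` for the
#'   explicit-Euler update to be stable.
#' @param fov_deg Angular width of the rendered window (deg).
#' @param resolution Integer vector `c(rows, cols)` of the rendered frame.
#' @param seed Integer seed used when thresholds are sampled and no explicit
#'   seed is given.
#' @param gating_mode `"hard"` (phosphenes appear only when activation
#'   reaches the sampled threshold) or `"smooth"` (a steep sigmoid gate, for
#'   gradient-based use).
#' @param clip_mode `"clip"` (summed frames clipped to `[0, 1]`) or
#'   `"none"`.
#' @param gate_sharpness Slope of the smooth threshold gate (per activation
#'   unit); only used when `gating_mode = "smooth"`.
#' @param rectify_sharpness Sharpness of the softplus surrogate of the
#'   rectifier in the effective-current model (per ampere); only used when
#'   `gating_mode = "smooth"`.
#' @param interaction_mode `"none"` (independent electrodes, the default
#'   model), `"coactivation"` (current of active electrodes leaks to nearby
#'   active electrodes), or `"costim_loss"` (independent model, but the
#'   co-stimulation penalty is evaluated each frame and stored in the
#'   state trace).
#' @param leak_constant Distance scaling of the coactivation leak kernel
#'   (mm^-2).
#'
#' @return An object of class `phosim_config`: a named list of resolved,
#'   validated parameters (currents in amperes).
#' @seealso [read_config()], [write_config()]
#' @export
#' @examples
#' cfg <- phosim_config()
#' cfg$I0      # rheobase, stored in amperes
#' cfg$theta50 # mean detection threshold
phosim_config <- function(a = 0.75,
                          b = 120,
                          k = 17.3,
                          alpha = 0.95,
                          hemisphere = "right",
                          K = 675,
                          I0_uA = 23.9,
                          tau_act = 0.111,
                          d = 1,
                          lambda = 19.2e7,
                          A50 = 1.06e-6,
                          theta50 = 9.14e-8,
                          sigma = 6.72e-8,
                          tau_trace = 1.97e3,
                          kappa = 14.0,
                          dt = 1 / 30,
                          fov_deg = 16,
                          resolution = c(256L, 256L),
                          seed = 42L,
                          gating_mode = c("hard", "smooth"),
                          clip_mode = c("clip", "none"),
                          gate_sharpness = 1e9,
                          rectify_sharpness = 1e7,
                          interaction_mode = c("none", "coactivation", "costim_loss"),
                          leak_constant = 100) {
  cfg <- list(
    a = a, b = b, k = k, alpha = alpha,
    hemisphere = match.arg(hemisphere, c("left", "right")),
    K = K,
    I0 = I0_uA * 1e-6,
    tau_act = tau_act, d = d,
    lambda = lambda, A50 = A50,
    theta50 = theta50, sigma = sigma,
    tau_trace = tau_trace, kappa = kappa,
    dt = dt, fov_deg = fov_deg,
    resolution = as.integer(resolution),
    seed = as.integer(seed),
    gating_mode = match.arg(gating_mode),
    clip_mode = match.arg(clip_mode),
    gate_sharpness = gate_sharpness,
    rectify_sharpness = rectify_sharpness,
    interaction_mode = match.arg(interaction_mode),
    leak_constant = leak_constant
  )
  class(cfg) <- "phosim_config"
  validate_config(cfg)
}

check_that <- function(ok, param, bound) {
  if (!isTRUE(ok)) {
    stop(sprintf("invalid configuration: `%s` must satisfy %s", param, bound),
         call. = FALSE)
  }
}

#' Validate a simulator configuration
#'
#' Checks every invariant of the parameter registry and returns the
#' configuration unchanged. Called by [phosim_config()] and [read_config()];
#' exported so that manually edited configurations can be re-checked.
#'
#' @param cfg A `phosim_config` object.
#' @return `cfg`, invisibly unchanged, if all invariants hold.
#' @export
validate_config <- function(cfg) {
  num1 <- function(x) is.numeric(x) && length(x) == 1 && is.finite(x)
  check_that(num1(cfg$a) && cfg$a > 0, "a", "a > 0")
  check_that(num1(cfg$b) && cfg$b > cfg$a, "b", "b > a")
  check_that(num1(cfg$k) && cfg$k > 0, "k", "k > 0")
  check_that(num1(cfg$alpha) && cfg$alpha > 0 && cfg$alpha <= 1,
             "alpha", "0 < alpha <= 1")
  check_that(num1(cfg$K) && cfg$K > 0, "K", "K > 0")
  check_that(num1(cfg$I0) && cfg$I0 > 0, "I0_uA", "I0 > 0")
  check_that(num1(cfg$tau_act) && cfg$tau_act > 0, "tau_act", "tau_act > 0")
  check_that(num1(cfg$d) && cfg$d > 0 && cfg$d <= 1, "d", "0 < d <= 1")
  check_that(num1(cfg$lambda) && cfg$lambda > 0, "lambda", "lambda > 0")
  check_that(num1(cfg$A50) && cfg$A50 > 0, "A50", "A50 > 0")
  check_that(num1(cfg$theta50) && cfg$theta50 > 0, "theta50", "theta50 > 0")
  check_that(num1(cfg$sigma) && cfg$sigma >= 0, "sigma", "sigma >= 0")
  check_that(num1(cfg$tau_trace) && cfg$tau_trace > 0,
             "tau_trace", "tau_trace > 0")
  check_that(num1(cfg$kappa) && cfg$kappa > 0, "kappa", "kappa > 0")
  check_that(num1(cfg$dt) && cfg$dt > 0, "dt", "dt > 0")
  check_that(cfg$dt < cfg$tau_act, "dt",
             "dt < tau_act (explicit-Euler stability guard)")
  check_that(length(cfg$resolution) == 2 && all(cfg$resolution >= 8),
             "resolution", "both components >= 8")
  check_that(num1(cfg$fov_deg) && cfg$fov_deg > 0, "fov_deg", "fov_deg > 0")
  check_that(cfg$gating_mode %in% c("hard", "smooth"),
             "gating_mode", "one of {hard, smooth}")
  check_that(cfg$clip_mode %in% c("clip", "none"),
             "clip_mode", "one of {clip, none}")
  check_that(cfg$interaction_mode %in% c("none", "coactivation", "costim_loss"),
             "interaction_mode", "one of {none, coactivation, costim_loss}")
  check_that(num1(cfg$leak_constant) && cfg$leak_constant > 0,
             "leak_constant", "leak_constant > 0")
  invisible(cfg)
}

# keys accepted in configuration files, in the units users quote
config_file_keys <- c(
  "a", "b", "k", "alpha", "hemisphere", "K", "I0_uA", "tau_act", "d",
  "lambda", "A50", "theta50", "sigma", "tau_trace", "kappa", "dt",
  "fov_deg", "resolution", "seed", "gating_mode", "clip_mode",
  "gate_sharpness", "rectify_sharpness", "interaction_mode",
  "leak_constant", "n_frames"
)

#' Read a simulator configuration file
#'
#' Reads a YAML configuration file whose keys are named after the model
#' symbols (`a`, `b`, `k`, `alpha`, `K`, `I0_uA`, `tau_act`, `d`, `lambda`,
#' `A50`, `theta50`, `sigma`, `tau_trace`, `kappa`, `dt`, `fov_deg`,
#' `resolution`, `seed`, ...). Missing keys are filled with the package
#' defaults; unknown keys raise an error naming the offending key. The fully
#' resolved parameter set is echoed as a message when `quiet = FALSE`.
#'
#' @param path Path to a YAML configuration file.
#' @param quiet Suppress the log echo of resolved parameters.
#' @return A validated `phosim_config` object.
#' @export
read_config <- function(path, quiet = TRUE) {
  if (!file.exists(path)) {
    stop(sprintf("configuration file not found: %s", path), call. = FALSE)
  }
  vals <- tryCatch(
    yaml::read_yaml(path),
    error = function(e) {
      stop(sprintf("could not parse configuration file %s: %s",
                   path, conditionMessage(e)), call. = FALSE)
    }
  )
  if (is.null(vals)) vals <- list()
  unknown <- setdiff(names(vals), config_file_keys)
  if (length(unknown) > 0) {
    stop(sprintf("unknown configuration key(s): %s",
                 paste(unknown, collapse = ", ")), call. = FALSE)
  }
  vals$n_frames <- NULL # scenario metadata, not a model parameter
  cfg <- do.call(phosim_config, vals)
  if (!quiet) {
    message("resolved configuration:\n",
            paste(sprintf("  %s = %s", names(unclass(cfg)),
                          vapply(unclass(cfg), function(v)
                            paste(format(v), collapse = " "), "")),
                  collapse = "\n"))
  }
  cfg
}

#' Write a simulator configuration file
#'
#' Serializes a configuration back to YAML in user-facing units
#' (microamperes for `I0_uA`). `read_config(write_config(cfg, path))`
#' reproduces every resolved value exactly.
#'
#' @param cfg A `phosim_config` object.
#' @param path Output file path.
#' @param extra Optional named list of extra keys (e.g. `n_frames` for a
#'   bundled scenario).
#' @return `path`, invisibly.
#' @export
write_config <- function(cfg, path, extra = list()) {
  validate_config(cfg)
  out <- list(
    a = cfg$a, b = cfg$b, k = cfg$k, alpha = cfg$alpha,
    hemisphere = cfg$hemisphere, K = cfg$K,
    I0_uA = cfg$I0 * 1e6,
    tau_act = cfg$tau_act, d = cfg$d, lambda = cfg$lambda, A50 = cfg$A50,
    theta50 = cfg$theta50, sigma = cfg$sigma,
    tau_trace = cfg$tau_trace, kappa = cfg$kappa,
    dt = cfg$dt, fov_deg = cfg$fov_deg,
    resolution = cfg$resolution, seed = cfg$seed,
    gating_mode = cfg$gating_mode, clip_mode = cfg$clip_mode,
    gate_sharpness = cfg$gate_sharpness,
    rectify_sharpness = cfg$rectify_sharpness,
    interaction_mode = cfg$interaction_mode,
    leak_constant = cfg$leak_constant
  )
  out <- c(out, extra)
  yaml::write_yaml(out, path, precision = 17)
  invisible(path)
}

#' @export
print.phosim_config <- function(x, ...) {
  cat("<phosim_config>\n")
  cat(sprintf("  visuotopic map : a=%g deg, b=%g deg, k=%g mm, alpha=%g (%s hemisphere)\n",
              x$a, x$b, x$k, x$alpha, x$hemisphere))
  cat(sprintf("  size model     : K=%g uA/mm^2\n", x$K))
  cat(sprintf("  dynamics       : I0=%g uA, tau_act=%g s, d=%g\n",
              x$I0 * 1e6, x$tau_act, x$d))
  cat(sprintf("  brightness     : lambda=%g, A50=%g\n", x$lambda, x$A50))
  cat(sprintf("  thresholds     : theta50=%g, sigma=%g\n", x$theta50, x$sigma))
  cat(sprintf("  memory trace   : tau_trace=%g s, kappa=%g\n",
              x$tau_trace, x$kappa))
  cat(sprintf("  rendering      : %dx%d px, fov=%g deg, dt=%g s, gating=%s, clip=%s\n",
              x$resolution[1], x$resolution[2], x$fov_deg, x$dt,
              x$gating_mode, x$clip_mode))
  invisible(x)
}
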