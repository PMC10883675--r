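#' Effective stimulation current of a pulse train
#'
#' Subtracts from the stimulation amplitude the rheobase current `I0` (the
#' ineffective component of the input) and the memory trace `B` (reduced
#' excitability after prior stimulation), rectifies, and multiplies by the
#' duty cycle `Pw * f` (the fraction of each period in which the biphasic
#' square pulse is active):
#' \deqn{I_{eff} = \max(0,\; (I_{stim} - I_0 - B)) \cdot P_w f.}
#' In smooth mode the rectifier is replaced by a softplus surrogate so the
#' output is differentiable in the amplitude.
#'
#' All currents are in amperes and pulse widths in seconds.
#'
#' @param Istim Stimulation amplitude (A), non-negative; vectorized.
#' @param I0 Rheobase current (A).
#' @param B Memory trace (activation units, same scale as current here).
#' @param Pw Pulse width (s).
#' @param f Pulse frequency (Hz). The duty cycle `Pw * f` must lie in
#'   `(0, 1]`.
#' @param mode `"hard"` (exact rectifier) or `"smooth"` (softplus).
#' @param sharpness Softplus sharpness (per ampere), smooth mode only.
#' @return Effective current (A).
#' @export
#' @examples
#' cfg <- phosim_config()
#' # 100 uA, 170 us pulses at 300 Hz: duty cycle 0.051
#' effective_current(100e-6, cfg$I0, 0, 170e-6, 300)
effective_current <- function(Istim, I0, B, Pw, f,
                              mode = c("hard", "smooth"),
                              sharpness = 1e7) {
  mode <- match.arg(mode)
  stopifnot(all(Istim >= 0), all(B >= 0), all(Pw >= 0), all(f >= 0))
  duty <- Pw * f
  if (any(duty > 1 + 1e-12)) {
    stop(sprintf("duty cycle Pw*f must not exceed 1 (got %g)", max(duty)),
         call. = FALSE)
  }
  margin <- Istim - I0 - B
  rectified <- if (mode == "hard") {
    pmax(0, margin)
  } else {
    # softplus: log(1 + exp(s*x))/s, computed stably for large |s*x|
    sx <- sharpness * margin
    ifelse(sx > 30, margin, log1p(exp(pmin(sx, 30))) / sharpness)
  }
  rectified * duty
}

#' Leaky-integrator update of cortical tissue activation
#'
#' One explicit-Euler step of the first-order tissue-activation model:
#' \deqn{A_{t} = A_{t-\Delta t} + \left(-\frac{A_{t-\Delta t}}{\tau_{act}}
#'   + I_{eff}\, d\right)\Delta t.}
#' The decay constant `tau_act` produces the delayed on- and offset of
#' phosphene perception; `d` scales the stimulation duration relative to the
#' frame duration. Stability requires `dt < tau_act`, which the
#' configuration enforces.
#'
#' @param A_prev Activation at the previous frame; vectorized.
#' @param Ieff Effective current (A) for this frame.
#' @param dt Frame duration (s).
#' @param tau_act Activation decay time constant (s).
#' @param d Duration scale in `(0, 1]`.
#' @return Activation at the current frame.
#' @export
update_activation <- function(A_prev, Ieff, dt, tau_act, d = 1) {
  if (dt >= tau_act) {
    stop(sprintf("dt (%g s) must be smaller than tau_act (%g s)", dt, tau_act),
         call. = FALSE)
  }
  A_prev + (-A_prev / tau_act + Ieff * d) * dt
}

#' Leaky-integrator update of the memory trace
#'
#' The memory trace `B` accumulates past effective current and decays
#' slowly, modeling the accommodation (habituation) of phosphene brightness
#' under prolonged or repeated stimulation:
#' \deqn{B_{t} = B_{t-\Delta t} + \left(-\frac{B_{t-\Delta t}}{\tau_{trace}}
#'   + I_{eff}\, \kappa\right)\Delta t.}
#' The trace feeds back into the effective current (reducing it) and hence
#' affects phosphene brightness only, never phosphene size.
#'
#' @param B_prev Trace at the previous frame; vectorized.
#' @param Ieff Effective current (A) for this frame.
#' @param dt Frame duration (s).
#' @param tau_trace Trace decay time constant (s).
#' @param kappa Trace input gain (dimensionless).
#' @return Trace at the current frame.
#' @export
update_trace <- function(B_prev, Ieff, dt, tau_trace, kappa) {
  stopifnot(dt > 0)
  B_prev + (-B_prev / tau_trace + Ieff * kappa) * dt
}

#' Sample per-electrode detection thresholds
#'
#' Detection thresholds introduce variability between electrodes: each
#' threshold is an independent draw from `N(theta50, sigma^2)`, redrawn
#' until positive (a non-positive detection threshold is physically
#' meaningless). Thresholds are sampled once at simulator initialization and
#' then held constant, but can be re-initialized explicitly (see
#' [sim_reset_thresholds()]).
#'
#' @param n Number of electrodes.
#' @param theta50 Mean detection threshold (activation units).
#' @param sigma Threshold standard deviation (`>= 0`; `0` gives all
#'   thresholds equal to `theta50`).
#' @param seed Integer seed, or `NULL` to use the current RNG stream.
#' @return Numeric vector of `n` positive thresholds.
#' @export
sample_thresholds <- function(n, theta50, sigma, seed = NULL) {
  stopifnot(n >= 1, sigma >= 0)
  draw <- function() {
    if (sigma == 0) return(rep(theta50, n))
    x <- rnorm(n, theta50, sigma)
    while (any(x <= 0)) {
      bad <- x <= 0
      x[bad] <- rnorm(sum(bad), theta50, sigma)
    }
    x
  }
  if (is.null(seed)) draw() else withr::with_seed(seed, draw())
}

#' Phosphene brightness from tissue activation
#'
#' A phosphene is generated only when the tissue activation reaches the
#' electrode's detection threshold; its brightness then follows the
#' sigmoidal response
#' \deqn{\frac{1}{1 + e^{-\lambda (A - A_{50})}},}
#' where `lambda` is the slope and `A50` the activation at half-maximum
#' brightness. In hard mode sub-threshold activation yields exactly zero;
#' smooth mode replaces the step with a steep sigmoid gate for
#' gradient-based use.
#'
#' @param A Tissue activation, non-negative; vectorized.
#' @param Athr Per-electrode detection threshold(s).
#' @param cfg A [phosim_config()] (uses `lambda`, `A50`, `gating_mode`,
#'   `gate_sharpness`).
#' @return Brightness in `[0, 1]`.
#' @export
#' @examples
#' cfg <- phosim_config()
#' brightness_value(cfg$A50, cfg$theta50, cfg) # 0.5 at the sigmoid midpoint
brightness_value <- function(A, Athr, cfg) {
  stopifnot(all(A >= 0))
  base <- plogis(cfg$lambda * (A - cfg$A50))
  if (cfg$gating_mode == "hard") {
    ifelse(A >= Athr, base, 0)
  } else {
    base * plogis(cfg$gate_sharpness * (A - Athr))
  }
}
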