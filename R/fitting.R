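#' Peak tissue activation reached by a pulse train
#'
#' Simulates a single electrode from a quiescent state through a pulse
#' train of the given duration and returns the largest activation reached
#' (including the decay tail after stimulation offset, the peak occurs at
#' the last stimulated frame). Used by the psychometric data generators and
#' fitting routines to link stimulation conditions to the activation
#' variable of the threshold and brightness models.
#'
#' @param amplitude_uA Stimulation amplitude (uA).
#' @param pulse_width_us Pulse width (us).
#' @param frequency_hz Pulse frequency (Hz).
#' @param duration_ms Train duration (ms); realized as
#'   `ceiling(duration / dt)` stimulated frames.
#' @param cfg A [phosim_config()].
#' @return Peak activation (scalar); vectorized over conditions when the
#'   first four arguments are equal-length vectors.
#' @export
train_activation <- function(amplitude_uA, pulse_width_us, frequency_hz,
                             duration_ms, cfg) {
  m <- max(length(amplitude_uA), length(pulse_width_us),
           length(frequency_hz), length(duration_ms))
  amplitude_uA <- rep(amplitude_uA, length.out = m)
  pulse_width_us <- rep(pulse_width_us, length.out = m)
  frequency_hz <- rep(frequency_hz, length.out = m)
  duration_ms <- rep(duration_ms, length.out = m)
  vapply(seq_len(m), function(i) {
    n_frames <- ceiling(duration_ms[i] / 1000 / cfg$dt)
    A <- 0
    B <- 0
    peak <- 0
    for (t in seq_len(n_frames)) {
      Ieff <- effective_current(amplitude_uA[i] * 1e-6, cfg$I0, B,
                                pulse_width_us[i] * 1e-6, frequency_hz[i])
      A <- update_activation(A, Ieff, cfg$dt, cfg$tau_act, cfg$d)
      B <- update_trace(B, Ieff, cfg$dt, cfg$tau_trace, cfg$kappa)
      peak <- max(peak, A)
    }
    peak
  }, numeric(1))
}

detection_probability <- function(A, theta50, sigma) {
  ifelse(A <= 0, 0, pnorm((A - theta50) / sigma))
}

#' Generate synthetic phosphene-detection data
#'
#' For each stimulation condition, simulates the activation reached by the
#' train and draws Bernoulli detections with probability
#' `Phi((A - theta50) / sigma)` — the closed form implied by normally
#' distributed per-electrode detection thresholds. Conditions whose
#' amplitude never exceeds the rheobase produce zero activation and a
#' detection probability of exactly zero (thresholds are strictly
#' positive). Deterministic given `seed`.
#'
#' @param conditions A data frame with columns `amplitude_uA`,
#'   `pulse_width_us`, `frequency_hz`, `duration_ms` (one condition per
#'   row).
#' @param n_trials Trials per condition (scalar or per-condition vector).
#' @param cfg A [phosim_config()].
#' @param seed Integer seed, or `NULL`.
#' @return The conditions tibble with added columns `activation`,
#'   `p_detect`, `n_trials`, `n_detected`.
#' @export
#' @examples
#' cfg <- phosim_config()
#' cond <- tibble::tibble(amplitude_uA = seq(10, 100, by = 10),
#'                        pulse_width_us = 170, frequency_hz = 300,
#'                        duration_ms = 166)
#' generate_detection_data(cond, n_trials = 50, cfg, seed = 1)
generate_detection_data <- function(conditions, n_trials, cfg, seed = NULL) {
  out <- tibble::as_tibble(conditions)
  out$activation <- train_activation(out$amplitude_uA, out$pulse_width_us,
                                     out$frequency_hz, out$duration_ms, cfg)
  out$p_detect <- detection_probability(out$activation, cfg$theta50, cfg$sigma)
  out$n_trials <- rep(n_trials, length.out = nrow(out))
  draw <- function() rbinom(nrow(out), out$n_trials, out$p_detect)
  out$n_detected <- if (is.null(seed)) draw() else withr::with_seed(seed, draw())
  out
}

#' Generate synthetic phosphene-brightness data
#'
#' For each condition, simulates the activation reached by the train and
#' reports the mean of `n_repeats` noisy brightness responses around the
#' sigmoidal brightness curve. Deterministic given `seed`.
#'
#' @inheritParams generate_detection_data
#' @param n_repeats Repeats per condition.
#' @param noise_sd Gaussian response noise on each repeat (brightness
#'   units); responses are not clipped so the condition mean stays
#'   unbiased.
#' @return The conditions tibble with added columns `activation`,
#'   `n_trials` (the repeat count) and `mean_brightness`.
#' @export
generate_brightness_data <- function(conditions, n_repeats, noise_sd, cfg,
                                     seed = NULL) {
  out <- tibble::as_tibble(conditions)
  out$activation <- train_activation(out$amplitude_uA, out$pulse_width_us,
                                     out$frequency_hz, out$duration_ms, cfg)
  true_b <- plogis(cfg$lambda * (out$activation - cfg$A50))
  draw <- function() {
    vapply(true_b, function(b) mean(b + rnorm(n_repeats, 0, noise_sd)),
           numeric(1))
  }
  out$n_trials <- n_repeats
  out$mean_brightness <- if (is.null(seed)) draw()
                         else withr::with_seed(seed, draw())
  out
}

new_phosim_fit <- function(method, estimate, r.squared, data, fitted) {
  structure(
    list(method = method, estimate = estimate, r.squared = r.squared,
         data = data, fitted = fitted),
    class = "phosim_fit")
}

r_squared <- function(obs, pred) {
  ss_tot <- sum((obs - mean(obs))^2)
  if (ss_tot == 0) return(NA_real_)
  1 - sum((obs - pred)^2) / ss_tot
}

#' Fit the detection-threshold distribution to psychometric data
#'
#' Recovers the mean `theta50` and standard deviation `sigma` of the
#' per-electrode detection-threshold distribution by weighted nonlinear
#' least squares on per-condition detection proportions: each condition's
#' activation is simulated from its stimulation parameters, and the
#' predicted detection probability `Phi((A - theta50) / sigma)` is matched
#' to the observed rate. Conditions with zero activation (amplitude at or
#' below the rheobase) carry no information about the threshold
#' distribution and are excluded from the fit.
#'
#' @param data A detection dataset (see [generate_detection_data()] or
#'   [read_psychometric_csv()]): columns `amplitude_uA`, `pulse_width_us`,
#'   `frequency_hz`, `duration_ms`, `n_trials`, `n_detected`.
#' @param cfg A [phosim_config()] supplying the simulation constants
#'   (rheobase, time constants) used to compute activations.
#' @return A `phosim_fit` object; `tidy()` gives the estimates, `glance()`
#'   the goodness of fit.
#' @export
fit_threshold_distribution <- function(data, cfg) {
  data <- tibble::as_tibble(data)
  if (!("activation" %in% names(data))) {
    data$activation <- train_activation(data$amplitude_uA,
                                        data$pulse_width_us,
                                        data$frequency_hz,
                                        data$duration_ms, cfg)
  }
  fitdat <- data[data$activation > 0, ]
  if (nrow(fitdat) < 2) {
    stop("threshold fit needs at least two conditions with nonzero activation",
         call. = FALSE)
  }
  prop <- fitdat$n_detected / fitdat$n_trials
  if (all(prop >= 1) || all(prop <= 0)) {
    stop(paste("threshold distribution is not identifiable:",
               "data must span sub- and supra-threshold conditions"),
         call. = FALSE)
  }
  # work on a unit scale so the optimizer sees O(1) parameters
  scale <- stats::median(fitdat$activation)
  As <- fitdat$activation / scale
  lo <- As[prop < 0.5]
  hi <- As[prop >= 0.5]
  th0 <- if (length(lo) > 0 && length(hi) > 0) (max(lo) + min(hi)) / 2
         else stats::median(As)
  sd0 <- max(diff(range(As)) / 6, 1e-3)
  w <- sqrt(fitdat$n_trials)
  fit <- minpack.lm::nls.lm(
    par = c(th = th0, sg = sd0),
    fn = function(p) w * (prop - pnorm((As - p[1]) / p[2])),
    lower = c(1e-8, 1e-8),
    control = minpack.lm::nls.lm.control(maxiter = 500)
  )
  theta50 <- unname(fit$par["th"]) * scale
  sigma <- unname(fit$par["sg"]) * scale
  pred <- detection_probability(fitdat$activation, theta50, sigma)
  new_phosim_fit(
    "threshold_distribution",
    tibble::tibble(term = c("theta50", "sigma"),
                   estimate = c(theta50, sigma)),
    r_squared(prop, pred),
    data, pred)
}

#' Fit the sigmoidal brightness curve
#'
#' Recovers the slope `lambda` and half-brightness activation `A50` of the
#' brightness sigmoid by least squares on per-condition mean brightness
#' responses, with the activation of each condition simulated from its
#' stimulation parameters.
#'
#' @param data A brightness dataset (see [generate_brightness_data()]):
#'   columns `amplitude_uA`, `pulse_width_us`, `frequency_hz`,
#'   `duration_ms`, `mean_brightness`.
#' @param cfg A [phosim_config()].
#' @return A `phosim_fit` object with terms `lambda` and `A50`.
#' @export
fit_brightness_sigmoid <- function(data, cfg) {
  data <- tibble::as_tibble(data)
  if (nrow(data) < 2) {
    stop("brightness fit is underdetermined: need at least 2 conditions",
         call. = FALSE)
  }
  if (!("activation" %in% names(data))) {
    data$activation <- train_activation(data$amplitude_uA,
                                        data$pulse_width_us,
                                        data$frequency_hz,
                                        data$duration_ms, cfg)
  }
  scale <- stats::median(data$activation[data$activation > 0])
  As <- data$activation / scale
  b <- data$mean_brightness
  lo <- As[b < 0.5]
  hi <- As[b >= 0.5]
  a50_0 <- if (length(lo) > 0 && length(hi) > 0) (max(lo) + min(hi)) / 2
           else stats::median(As)
  fit <- minpack.lm::nls.lm(
    par = c(lam = 4 / max(diff(range(As)), 1e-6), a50 = a50_0),
    fn = function(p) b - plogis(p[1] * (As - p[2])),
    lower = c(1e-6, 0),
    control = minpack.lm::nls.lm.control(maxiter = 500)
  )
  lambda <- unname(fit$par["lam"]) / scale
  A50 <- unname(fit$par["a50"]) * scale
  pred <- plogis(lambda * (data$activation - A50))
  new_phosim_fit(
    "brightness_sigmoid",
    tibble::tibble(term = c("lambda", "A50"), estimate = c(lambda, A50)),
    r_squared(b, pred),
    data, pred)
}

#' Fit the strength-duration curve
#'
#' The minimal input charge needed to reach threshold grows linearly with
#' stimulation duration, `Q_thr = I0 (c + t)`: the slope of charge versus
#' duration is the rheobase `I0` and the intercept is `I0 * c` with
#' chronaxie `c`. Fitted by ordinary least squares.
#'
#' @param data A data frame with columns `duration_s` (total stimulation
#'   duration, s) and `charge_uC` (threshold charge, uC = uA s); at least 3
#'   distinct durations.
#' @return A `phosim_fit` object with terms `I0_uA` (rheobase, uA) and
#'   `chronaxie_s` (s; `Inf`, flagged degenerate, when the charge does not
#'   grow with duration).
#' @export
fit_strength_duration <- function(data) {
  data <- tibble::as_tibble(data)
  if (length(unique(data$duration_s)) < 3) {
    stop("strength-duration fit needs at least 3 distinct durations",
         call. = FALSE)
  }
  fit <- lm(charge_uC ~ duration_s, data = data)
  slope <- unname(coef(fit)["duration_s"])
  intercept <- unname(coef(fit)["(Intercept)"])
  degenerate <- slope <= 0 ||
    slope * mean(data$duration_s) < 1e-10 * abs(intercept)
  if (degenerate) {
    warning("strength-duration fit is degenerate: charge does not grow with duration (chronaxie -> Inf)",
            call. = FALSE)
  }
  I0 <- slope
  chronaxie <- if (degenerate) Inf else intercept / slope
  pred <- predict(fit)
  new_phosim_fit(
    "strength_duration",
    tibble::tibble(term = c("I0_uA", "chronaxie_s"),
                   estimate = c(I0, chronaxie)),
    r_squared(data$charge_uC, pred),
    data, pred)
}

#' Predict from a psychometric fit
#'
#' @param object A `phosim_fit` from [fit_threshold_distribution()] or
#'   [fit_brightness_sigmoid()].
#' @param newdata Conditions to predict (same columns as the fitting data).
#' @param cfg A [phosim_config()] for simulating activations.
#' @param ... Unused.
#' @return Predicted detection probabilities or brightness values.
#' @export
predict.phosim_fit <- function(object, newdata, cfg = NULL, ...) {
  newdata <- tibble::as_tibble(newdata)
  if (!("activation" %in% names(newdata))) {
    if (is.null(cfg)) {
      stop("`cfg` is required to simulate activations for new conditions",
           call. = FALSE)
    }
    newdata$activation <- train_activation(newdata$amplitude_uA,
                                           newdata$pulse_width_us,
                                           newdata$frequency_hz,
                                           newdata$duration_ms, cfg)
  }
  est <- setNames(object$estimate$estimate, object$estimate$term)
  switch(object$method,
    threshold_distribution =
      detection_probability(newdata$activation, est["theta50"], est["sigma"]),
    brightness_sigmoid =
      plogis(est["lambda"] * (newdata$activation - est["A50"])),
    strength_duration =
      est["I0_uA"] * (est["chronaxie_s"] + newdata$duration_s),
    stop("unknown fit method", call. = FALSE))
}

#' K-fold cross-validation of a psychometric fit
#'
#' Splits the conditions into `k` stratified folds (conditions are ordered
#' by simulated activation and dealt round-robin, so every fold spans the
#' psychometric range), fits on `k - 1` folds and evaluates the coefficient
#' of determination on the held-out conditions. Fold assignment is
#' deterministic given `seed`.
#'
#' @param data A psychometric dataset (one condition per row).
#' @param fitter A fitting function, e.g. [fit_threshold_distribution()].
#' @param k Number of folds (`>= 2`, at most the number of conditions;
#'   `k = nrow(data)` gives leave-one-condition-out).
#' @param cfg A [phosim_config()].
#' @param seed Integer seed for the within-block shuffle.
#' @param response Name of the observed response column (`"proportion"`
#'   uses `n_detected / n_trials`).
#' @return A list with `folds` (tibble of per-fold R^2 and sizes) and
#'   `mean_r_squared`.
#' @export
crossvalidate <- function(data, fitter, k = 3, cfg, seed = 1,
                          response = c("proportion", "mean_brightness")) {
  response <- match.arg(response)
  data <- tibble::as_tibble(data)
  n <- nrow(data)
  if (k < 2) stop("k must be at least 2", call. = FALSE)
  if (n < k) {
    stop(sprintf("cannot partition %d conditions into %d folds", n, k),
         call. = FALSE)
  }
  if (!("activation" %in% names(data))) {
    data$activation <- train_activation(data$amplitude_uA,
                                        data$pulse_width_us,
                                        data$frequency_hz,
                                        data$duration_ms, cfg)
  }
  # stratified assignment: order by activation, shuffle within blocks of k
  ord <- order(data$activation)
  fold <- integer(n)
  assign_folds <- function() {
    for (start in seq(1, n, by = k)) {
      idx <- ord[start:min(start + k - 1, n)]
      fold[idx] <<- sample(k)[seq_along(idx)]
    }
  }
  withr::with_seed(seed, assign_folds())
  obs <- if (response == "proportion") data$n_detected / data$n_trials
         else data$mean_brightness
  per_fold <- purrr::map(seq_len(k), function(f) {
    train <- data[fold != f, , drop = FALSE]
    test <- data[fold == f, , drop = FALSE]
    fit <- fitter(train, cfg)
    pred <- predict(fit, test, cfg)
    r2 <- r_squared(obs[fold == f], pred)
    tibble::tibble(fold = f, n_train = nrow(train), n_test = nrow(test),
                   r.squared = r2)
  })
  folds <- dplyr::bind_rows(per_fold)
  list(folds = folds, mean_r_squared = mean(folds$r.squared, na.rm = TRUE))
}

#' @export
print.phosim_fit <- function(x, ...) {
  cat(sprintf("<phosim_fit: %s>\n", x$method))
  for (i in seq_len(nrow(x$estimate))) {
    cat(sprintf("  %-12s %.6g\n", x$estimate$term[i], x$estimate$estimate[i]))
  }
  cat(sprintf("  R^2 = %.4f on %d conditions\n", x$r.squared, nrow(x$data)))
  invisible(x)
}

#' Tidy a psychometric fit
#'
#' @param x A `phosim_fit`.
#' @param ... Unused.
#' @return A tibble with one row per fitted term.
#' @export
tidy.phosim_fit <- function(x, ...) x$estimate

#' One-row fit summary
#'
#' @param x A `phosim_fit`.
#' @param ... Unused.
#' @return A tibble with the method, R^2 and condition count.
#' @export
glance.phosim_fit <- function(x, ...) {
  tibble::tibble(method = x$method, r.squared = x$r.squared,
                 n_conditions = nrow(x$data))
}

#' Plot a psychometric fit
#'
#' Observed per-condition responses against simulated activation with the
#' fitted curve overlaid.
#'
#' @param object A `phosim_fit` (threshold or brightness fit).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.phosim_fit <- function(object, ...) {
  data <- object$data
  obs <- switch(object$method,
    threshold_distribution = data$n_detected / data$n_trials,
    brightness_sigmoid = data$mean_brightness,
    strength_duration = data$charge_uC)
  xvar <- if (object$method == "strength_duration") data$duration_s
          else data$activation
  xlab <- if (object$method == "strength_duration") "duration (s)"
          else "tissue activation"
  est <- setNames(object$estimate$estimate, object$estimate$term)
  grid <- seq(min(xvar), max(xvar), length.out = 200)
  curve <- switch(object$method,
    threshold_distribution =
      detection_probability(grid, est["theta50"], est["sigma"]),
    brightness_sigmoid = plogis(est["lambda"] * (grid - est["A50"])),
    strength_duration = est["I0_uA"] * (est["chronaxie_s"] + grid))
  ggplot2::ggplot() +
    ggplot2::geom_point(ggplot2::aes(xvar, obs)) +
    ggplot2::geom_line(ggplot2::aes(grid, curve), color = "red") +
    ggplot2::labs(x = xlab,
                  y = switch(object$method,
                             threshold_distribution = "detection proportion",
                             brightness_sigmoid = "mean brightness",
                             strength_duration = "threshold charge (uC)")) +
    ggplot2::theme_minimal()
}
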