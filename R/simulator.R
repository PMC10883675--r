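#' Initialize a simulator session
#'
#' Creates the per-electrode dynamic state for a phosphene map: tissue
#' activation and memory trace start at zero, and each electrode's
#' detection threshold is sampled once from the configured normal
#' distribution. The session is deterministic given the seed; thresholds
#' remain constant for the lifetime of the session unless explicitly
#' re-initialized with [sim_reset_thresholds()].
#'
#' @param map A `phosphene_map` tibble (see [make_grid_layout()],
#'   [read_electrode_csv()]).
#' @param cfg A [phosim_config()].
#' @param seed Integer seed for the threshold draw; defaults to `cfg$seed`.
#' @return A `phosim_session` object.
#' @export
#' @examples
#' cfg <- phosim_config(resolution = c(64, 64))
#' map <- make_grid_layout(5, 5, 0.4, origin = c(20, 0), cfg)
#' session <- sim_init(map, cfg, seed = 1)
sim_init <- function(map, cfg, seed = cfg$seed) {
  validate_config(cfg)
  n <- nrow(map)
  if (n == 0) {
    stop("cannot initialize a session from an empty electrode map",
         call. = FALSE)
  }
  map$threshold <- sample_thresholds(n, cfg$theta50, cfg$sigma, seed = seed)
  xy <- field_xy(map$eccentricity_deg, map$azimuth_rad, cfg$hemisphere)
  structure(
    list(
      map = map,
      config = cfg,
      x_deg = xy$x_deg,
      y_deg = xy$y_deg,
      A = rep(0, n),
      B = rep(0, n),
      size_state = rep(0, n),
      Athr = map$threshold,
      clock = 0,
      frame_count = 0L,
      percept = NULL,
      last_costim = NA_real_
    ),
    class = "phosim_session")
}

#' Re-initialize the detection thresholds of a session
#'
#' Thresholds are fixed after initialization by default, but can be
#' re-drawn manually, e.g. to simulate a different virtual subject with the
#' same electrode layout.
#'
#' @param session A `phosim_session`.
#' @param seed Integer seed for the new draw, or `NULL` for the current RNG
#'   stream.
#' @return The session with fresh thresholds.
#' @export
sim_reset_thresholds <- function(session, seed = NULL) {
  cfg <- session$config
  session$Athr <- sample_thresholds(length(session$Athr), cfg$theta50,
                                    cfg$sigma, seed = seed)
  session$map$threshold <- session$Athr
  session
}

# recycle a per-electrode stimulation field to length n, validating NaNs
stim_field <- function(x, n, name, frame = NULL) {
  x <- rep(x, length.out = n)
  if (any(!is.finite(x))) {
    where <- which(!is.finite(x))
    stop(sprintf("non-finite %s for electrode(s) %s%s", name,
                 paste(where, collapse = ", "),
                 if (is.null(frame)) "" else sprintf(" at frame %d", frame)),
         call. = FALSE)
  }
  x
}

#' Advance the simulator by one stimulation frame
#'
#' Applies one frame of per-electrode stimulation: the effective current is
#' computed from the amplitude, the rheobase, the memory trace and the duty
#' cycle; the tissue activation and memory trace take one leaky-integrator
#' step; brightness is evaluated against the sampled detection thresholds;
#' phosphene size follows from the instantaneous stimulation current and
#' the local cortical magnification (after stimulation offset a phosphene
#' keeps its most recent size while its brightness decays, so percepts fade
#' rather than vanish); and (optionally) the phosphenes are
#' rendered and summed into a percept frame. Dropped electrodes contribute
#' nothing. With `interaction_mode = "coactivation"`, current of active
#' electrodes leaks to nearby active electrodes before the effective-current
#' stage.
#'
#' @param session A `phosim_session`.
#' @param stim A list or one-row-per-electrode data frame with fields
#'   `amplitude_uA`, `pulse_width_us`, `frequency_hz` (scalars are recycled
#'   across electrodes).
#' @param render Render the percept frame (set `FALSE` for state-only
#'   runs, e.g. long habituation protocols).
#' @return The updated session; the rendered frame (or `NULL`) is in
#'   `$percept`, and per-electrode brightness/size of the frame in
#'   `$last_specs`.
#' @export
sim_step <- function(session, stim, render = TRUE) {
  cfg <- session$config
  n <- nrow(session$map)
  amp_uA <- stim_field(stim$amplitude_uA, n, "amplitude_uA",
                       session$frame_count + 1L)
  pw_us <- stim_field(stim$pulse_width_us, n, "pulse_width_us",
                      session$frame_count + 1L)
  freq <- stim_field(stim$frequency_hz, n, "frequency_hz",
                     session$frame_count + 1L)
  if (any(amp_uA < 0)) {
    stop("stimulation amplitudes must be non-negative", call. = FALSE)
  }

  amp_uA[!session$map$active] <- 0
  if (cfg$interaction_mode == "coactivation") {
    pos <- cbind(session$map$x_cortex_mm, session$map$y_cortex_mm)
    amp_uA <- amp_uA + coactivation_currents(amp_uA, pos, cfg$leak_constant)
  }
  if (cfg$interaction_mode == "costim_loss") {
    pos <- cbind(session$map$x_cortex_mm, session$map$y_cortex_mm)
    session$last_costim <- costim_loss(amp_uA, pos)
  }

  Istim <- amp_uA * 1e-6
  Pw <- pw_us * 1e-6
  Ieff <- effective_current(Istim, cfg$I0, session$B, Pw, freq,
                            mode = if (cfg$gating_mode == "smooth") "smooth"
                                   else "hard",
                            sharpness = cfg$rectify_sharpness)
  session$A <- update_activation(session$A, Ieff, cfg$dt, cfg$tau_act, cfg$d)
  session$B <- update_trace(session$B, Ieff, cfg$dt, cfg$tau_trace, cfg$kappa)

  bright <- brightness_value(session$A, session$Athr, cfg)
  bright[!session$map$active] <- 0
  # size follows the instantaneous current while stimulating; after offset
  # the percept fades in place (brightness decays through the leaky
  # integrator) so the phosphene keeps its most recent size
  size <- ifelse(amp_uA > 0,
                 phosphene_size(amp_uA, session$map$eccentricity_deg, cfg),
                 session$size_state)
  session$size_state <- size

  specs <- tibble::new_tibble(
    list(
      electrode_id = session$map$electrode_id,
      x_deg = session$x_deg, y_deg = session$y_deg,
      size_deg = size, brightness = bright,
      Ieff = Ieff, A = session$A, B = session$B
    ),
    nrow = n)
  session$last_specs <- specs
  session$percept <- if (render) compose_frame(specs, cfg) else NULL
  session$frame_count <- session$frame_count + 1L
  session$clock <- session$frame_count * cfg$dt
  session
}

#' Run a stimulation sequence
#'
#' Drives [sim_step()] over a long-format stimulation table (`frame`,
#' `electrode_id`, `amplitude_uA`, `pulse_width_us`, `frequency_hz`).
#' Electrodes without a row in a given frame receive zero stimulation, so
#' quiescent frames need not be listed; `n_frames` extends the run beyond
#' the last listed frame.
#'
#' @param session A `phosim_session`.
#' @param stim_tbl Long-format stimulation tibble (see
#'   [read_stimulation_csv()]).
#' @param n_frames Total number of frames to simulate (default: the largest
#'   `frame` index in `stim_tbl`).
#' @param render Render every frame (`TRUE`) or track state only
#'   (`FALSE`).
#' @param trace Record the per-frame, per-electrode state (`Ieff`, `A`,
#'   `B`, `brightness`).
#' @return A list with elements `session` (final state), `frames` (list of
#'   `percept_frame` objects, or `NULL` when `render = FALSE`) and `trace`
#'   (long tibble, or `NULL`).
#' @export
run_sequence <- function(session, stim_tbl, n_frames = NULL,
                         render = TRUE, trace = FALSE) {
  cfg <- session$config
  n <- nrow(session$map)
  if (nrow(stim_tbl) > 0) {
    required <- c("frame", "electrode_id", "amplitude_uA",
                  "pulse_width_us", "frequency_hz")
    missing <- setdiff(required, names(stim_tbl))
    if (length(missing) > 0) {
      stop(sprintf("stimulation table is missing required column(s): %s",
                   paste(missing, collapse = ", ")), call. = FALSE)
    }
  }
  if (is.null(n_frames)) {
    n_frames <- if (nrow(stim_tbl) == 0) 0L else max(stim_tbl$frame)
  }
  if (n_frames == 0) {
    return(list(session = session, frames = list(), trace = NULL))
  }

  # dense frames x electrodes matrices for a lean inner loop
  amp <- matrix(0, n_frames, n)
  pw <- matrix(0, n_frames, n)
  fq <- matrix(0, n_frames, n)
  if (nrow(stim_tbl) > 0) {
    eidx <- match(stim_tbl$electrode_id, session$map$electrode_id)
    if (any(is.na(eidx))) {
      stop("stimulation table refers to electrode ids absent from the map",
           call. = FALSE)
    }
    if (any(stim_tbl$frame < 1 | stim_tbl$frame > n_frames)) {
      stop("stimulation frame indices must lie in [1, n_frames]",
           call. = FALSE)
    }
    ij <- cbind(stim_tbl$frame, eidx)
    amp[ij] <- stim_tbl$amplitude_uA
    pw[ij] <- stim_tbl$pulse_width_us
    fq[ij] <- stim_tbl$frequency_hz
  }

  frames <- if (render) vector("list", n_frames) else NULL
  if (trace) {
    tr_Ieff <- matrix(0, n_frames, n)
    tr_A <- matrix(0, n_frames, n)
    tr_B <- matrix(0, n_frames, n)
    tr_bright <- matrix(0, n_frames, n)
    tr_costim <- rep(NA_real_, n_frames)
  }
  for (t in seq_len(n_frames)) {
    session <- sim_step(session,
                        list(amplitude_uA = amp[t, ],
                             pulse_width_us = pw[t, ],
                             frequency_hz = fq[t, ]),
                        render = render)
    if (render) frames[[t]] <- session$percept
    if (trace) {
      s <- session$last_specs
      tr_Ieff[t, ] <- s$Ieff
      tr_A[t, ] <- s$A
      tr_B[t, ] <- s$B
      tr_bright[t, ] <- s$brightness
      tr_costim[t] <- session$last_costim
    }
  }
  trace_tbl <- NULL
  if (trace) {
    trace_tbl <- tibble::tibble(
      frame = rep(seq_len(n_frames), times = n),
      electrode_id = rep(session$map$electrode_id, each = n_frames),
      Ieff = as.vector(tr_Ieff),
      A = as.vector(tr_A),
      B = as.vector(tr_B),
      brightness = as.vector(tr_bright),
      costim_loss = rep(tr_costim, times = n)
    )
    trace_tbl <- dplyr::arrange(trace_tbl, .data$frame, .data$electrode_id)
  }
  list(session = session, frames = frames, trace = trace_tbl)
}

#' Export / import resumable session state
#'
#' `sim_state()` extracts the plain dynamic state (activation, trace,
#' thresholds, clock); `sim_restore()` writes it back into a session built
#' on the same map. Splitting a stimulation sequence and resuming from the
#' saved state reproduces the unsplit output exactly.
#'
#' @param session A `phosim_session`.
#' @return `sim_state()`: a list with `A`, `B`, `Athr`, `clock`,
#'   `frame_count`.
#' @export
sim_state <- function(session) {
  session[c("A", "B", "Athr", "size_state", "clock", "frame_count")]
}

#' @rdname sim_state
#' @param state A state list from [sim_state()].
#' @export
sim_restore <- function(session, state) {
  stopifnot(length(state$A) == nrow(session$map))
  session$A <- state$A
  session$B <- state$B
  session$Athr <- state$Athr
  session$map$threshold <- state$Athr
  session$size_state <- state$size_state
  session$clock <- state$clock
  session$frame_count <- state$frame_count
  session
}

#' Quantize stimulation amplitudes to discrete levels
#'
#' Stimulator hardware typically supports only a small set of discrete
#' amplitudes; the default matches a safety-constrained encoder with 10
#' equally spaced levels between 0 and 128 uA (both endpoints included).
#' The forward value is the nearest level; [smooth_staircase()] provides
#' the differentiable surrogate used for straight-through gradient
#' estimation.
#'
#' @param x Amplitude(s) (uA), non-negative.
#' @param n_levels Number of levels (`>= 2`).
#' @param max_uA Largest level (uA).
#' @return Quantized amplitude(s) (uA).
#' @export
#' @examples
#' quantize_amplitude(20) # snaps to 128/9 = 14.22 uA
quantize_amplitude <- function(x, n_levels = 10, max_uA = 128) {
  stopifnot(all(x >= 0), n_levels >= 2, max_uA > 0)
  delta <- max_uA / (n_levels - 1)
  pmin(pmax(round(x / delta), 0), n_levels - 1) * delta
}

#' @rdname quantize_amplitude
#' @param sharpness Dimensionless steepness of each smooth step (per level
#'   spacing); the hard staircase is the large-sharpness limit.
#' @export
smooth_staircase <- function(x, n_levels = 10, max_uA = 128, sharpness = 25) {
  stopifnot(all(x >= 0), n_levels >= 2, max_uA > 0, sharpness > 0)
  delta <- max_uA / (n_levels - 1)
  steps <- seq_len(n_levels - 1) - 0.5
  out <- numeric(length(x))
  for (k in steps) {
    out <- out + plogis(sharpness * (x / delta - k))
  }
  delta * out
}

#' @export
print.phosim_session <- function(x, ...) {
  cat(sprintf(
    "<phosim_session> %d electrodes (%d active), frame %d, t = %.3f s\n",
    nrow(x$map), sum(x$map$active), x$frame_count, x$clock))
  cat(sprintf("  activation in [%.3g, %.3g], trace in [%.3g, %.3g]\n",
              min(x$A), max(x$A), min(x$B), max(x$B)))
  invisible(x)
}
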