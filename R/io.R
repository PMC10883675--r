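require_columns <- function(df, required, what) {
  missing <- setdiff(required, names(df))
  if (length(missing) > 0) {
    stop(sprintf("%s is missing required column(s): %s", what,
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  invisible(df)
}

#' Read / write a long-format stimulation sequence CSV
#'
#' A stimulation sequence lists, per frame and per electrode, the amplitude
#' (uA), pulse width (us) and frequency (Hz); electrodes without a row in a
#' frame are unstimulated. Columns: `frame, electrode_id, amplitude_uA,
#' pulse_width_us, frequency_hz`.
#'
#' @param path CSV file path.
#' @return A tibble suitable for [run_sequence()].
#' @export
read_stimulation_csv <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE)
  require_columns(df, c("frame", "electrode_id", "amplitude_uA",
                        "pulse_width_us", "frequency_hz"),
                  "stimulation CSV")
  df
}

#' @rdname read_stimulation_csv
#' @param stim_tbl A long-format stimulation tibble.
#' @export
write_stimulation_csv <- function(stim_tbl, path) {
  require_columns(stim_tbl, c("frame", "electrode_id", "amplitude_uA",
                              "pulse_width_us", "frequency_hz"),
                  "stimulation table")
  readr::write_csv(stim_tbl, path)
  invisible(path)
}

#' Read / write psychometric trial data CSV
#'
#' Detection data carry columns `amplitude_uA, pulse_width_us,
#' frequency_hz, duration_ms, n_trials, n_detected`; brightness data
#' replace the last with `mean_brightness`.
#'
#' @param path CSV file path.
#' @param type `"detection"` or `"brightness"`.
#' @return A tibble.
#' @export
read_psychometric_csv <- function(path, type = c("detection", "brightness")) {
  type <- match.arg(type)
  df <- readr::read_csv(path, show_col_types = FALSE)
  base <- c("amplitude_uA", "pulse_width_us", "frequency_hz", "duration_ms")
  extra <- if (type == "detection") c("n_trials", "n_detected")
           else "mean_brightness"
  require_columns(df, c(base, extra), sprintf("%s psychometric CSV", type))
  df
}

#' @rdname read_psychometric_csv
#' @param data A psychometric tibble.
#' @export
write_psychometric_csv <- function(data, path) {
  readr::write_csv(data, path)
  invisible(path)
}

#' Build a pulse-train stimulation sequence
#'
#' Expands a train recipe (duration, pulse width, frequency, amplitude,
#' inter-train interval, repetitions) into a long-format stimulation table.
#' Each train occupies `ceiling(train_ms / 1000 / dt)` consecutive frames;
#' train onsets are spaced by the inter-train interval. With a vector of
#' amplitudes, successive trains cycle through them.
#'
#' @param electrode_ids Electrode ids to stimulate (all with the same
#'   parameters).
#' @param amplitude_uA Amplitude (uA) per train (recycled over trains).
#' @param train_ms Train duration (ms).
#' @param pulse_width_us Pulse width (us).
#' @param frequency_hz Frequency (Hz).
#' @param interval_s Onset-to-onset interval between trains (s); scalar or
#'   length `n_trains` (interval following each train's onset).
#' @param n_trains Number of trains (`0` gives an empty, all-quiescent
#'   sequence).
#' @param dt Frame duration (s).
#' @return A list with `stim` (long tibble) and `n_frames` (total frames
#'   including the tail of the last train).
#' @export
build_train_sequence <- function(electrode_ids, amplitude_uA, train_ms,
                                 pulse_width_us, frequency_hz,
                                 interval_s, n_trains, dt) {
  frames_per_train <- ceiling(train_ms / 1000 / dt)
  if (n_trains == 0) {
    return(list(stim = tibble::tibble(frame = integer(), electrode_id = integer(),
                                      amplitude_uA = numeric(),
                                      pulse_width_us = numeric(),
                                      frequency_hz = numeric()),
                n_frames = 0L))
  }
  interval_s <- rep(interval_s, length.out = n_trains)
  onsets_s <- cumsum(c(0, interval_s[-n_trains]))
  amplitude_uA <- rep(amplitude_uA, length.out = n_trains)
  rows <- purrr::map(seq_len(n_trains), function(i) {
    start <- round(onsets_s[i] / dt) + 1L
    frames <- start:(start + frames_per_train - 1L)
    tidyr::expand_grid(frame = frames, electrode_id = electrode_ids) |>
      dplyr::mutate(amplitude_uA = amplitude_uA[i],
                    pulse_width_us = pulse_width_us,
                    frequency_hz = frequency_hz)
  })
  stim <- dplyr::bind_rows(rows)
  list(stim = stim, n_frames = max(stim$frame))
}

fixture_scenarios <- function() {
  list(
    fig1_arrays = list(
      description = paste("four 10x10 arrays (0.4 mm spacing) in the right",
                          "hemisphere; 166 ms trains at 170 us / 300 Hz,",
                          "one train each at 40, 80, 120 uA"),
      grids = list(c(12, 4), c(22, 4), c(32, 4), c(42, -4)),
      n_rows = 10, n_cols = 10, spacing_mm = 0.4,
      train_ms = 166, pulse_width_us = 170, frequency_hz = 300,
      amplitude_uA = c(40, 80, 120), interval_s = 1, n_trains = 3
    ),
    fig2_brightness = list(
      description = paste("single electrode; 166 ms trains at 170 us /",
                          "300 Hz over an amplitude sweep 10-120 uA"),
      grids = list(c(20, 0)),
      n_rows = 1, n_cols = 1, spacing_mm = 0.4,
      train_ms = 166, pulse_width_us = 170, frequency_hz = 300,
      amplitude_uA = seq(10, 120, by = 10), interval_s = 2, n_trains = 12
    ),
    fig4_habituation = list(
      description = paste("single electrode; 125 ms trains at 100 us /",
                          "200 Hz, 90 uA; 50 trains at 4 s intervals then",
                          "5 trains at 200 s intervals"),
      grids = list(c(20, 0)),
      n_rows = 1, n_cols = 1, spacing_mm = 0.4,
      train_ms = 125, pulse_width_us = 100, frequency_hz = 200,
      amplitude_uA = 90,
      interval_s = c(rep(4, 50), rep(200, 5)), n_trains = 55
    )
  )
}

#' Generate a named fixture scenario
#'
#' Emits the three run inputs (electrode layout CSV, stimulation sequence
#' CSV, configuration YAML) for one of the bundled worked scenarios:
#' `fig1_arrays` (four Utah-style arrays at three amplitudes),
#' `fig2_brightness` (single-electrode amplitude sweep) and
#' `fig4_habituation` (50 pulse trains at 4 s intervals followed by five at
#' 200 s intervals). Outputs are byte-identical given the same scenario,
#' configuration and seed.
#'
#' @param scenario Scenario name.
#' @param dir Output directory (created if needed).
#' @param cfg A [phosim_config()].
#' @param n_repetitions Repeat the whole train schedule this many times
#'   (`0` emits only quiescent frames).
#' @return A list with `electrodes`, `stimulation`, `config` (file paths),
#'   `n_frames` and the scenario spec, invisibly.
#' @export
make_fixture <- function(scenario, dir, cfg = phosim_config(),
                         n_repetitions = 1) {
  scenarios <- fixture_scenarios()
  if (!scenario %in% names(scenarios)) {
    stop(sprintf("unknown scenario `%s`; available scenarios: %s", scenario,
                 paste(names(scenarios), collapse = ", ")), call. = FALSE)
  }
  spec <- scenarios[[scenario]]
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)

  maps <- purrr::map(spec$grids, function(origin) {
    make_grid_layout(spec$n_rows, spec$n_cols, spec$spacing_mm, origin, cfg)
  })
  map <- dplyr::bind_rows(maps)
  map$electrode_id <- seq_len(nrow(map))
  map <- new_phosphene_map(map)

  if (n_repetitions == 0) {
    seq_out <- build_train_sequence(map$electrode_id, spec$amplitude_uA,
                                    spec$train_ms, spec$pulse_width_us,
                                    spec$frequency_hz, spec$interval_s,
                                    n_trains = 0, dt = cfg$dt)
    seq_out$n_frames <- 1L
  } else {
    n_trains <- spec$n_trains * n_repetitions
    seq_out <- build_train_sequence(
      map$electrode_id,
      rep(spec$amplitude_uA, length.out = n_trains),
      spec$train_ms, spec$pulse_width_us, spec$frequency_hz,
      rep(spec$interval_s, length.out = n_trains),
      n_trains = n_trains, dt = cfg$dt)
  }

  paths <- list(
    electrodes = file.path(dir, "electrodes.csv"),
    stimulation = file.path(dir, "stimulation.csv"),
    config = file.path(dir, "config.yaml")
  )
  write_electrode_csv(map, paths$electrodes)
  write_stimulation_csv(seq_out$stim, paths$stimulation)
  write_config(cfg, paths$config, extra = list(n_frames = seq_out$n_frames))
  invisible(c(paths, list(n_frames = seq_out$n_frames, spec = spec,
                          map = map, stim = seq_out$stim)))
}

#' Write rendered frames as PNG files with a manifest
#'
#' Writes each percept frame as an 8-bit grayscale PNG (linear mapping of
#' brightness `[0, 1]` to `[0, 255]`) with zero-padded indices, plus a JSON
#' sidecar manifest recording frame count, frame rate, resolution and field
#' of view. PNG frames are the canonical, diff-able output; video assembly
#' is left to external tools reading the manifest.
#'
#' @param frames A list of `percept_frame` objects (at least one).
#' @param dir Output directory (created if needed).
#' @param fps Frame rate recorded in the manifest (frames/s), positive;
#'   `1 / dt` reproduces simulation time.
#' @return The manifest path, invisibly.
#' @export
write_frames <- function(frames, dir, fps) {
  if (length(frames) < 1) stop("need at least one frame", call. = FALSE)
  stopifnot(fps > 0)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  width <- max(4, nchar(length(frames)))
  for (i in seq_along(frames)) {
    img <- pmin(pmax(frames[[i]]$image, 0), 1)
    png::writePNG(img, file.path(dir, sprintf(paste0("frame_%0", width, "d.png"), i)))
  }
  manifest <- file.path(dir, "manifest.json")
  jsonlite::write_json(
    list(n_frames = length(frames), fps = fps,
         resolution = frames[[1]]$resolution,
         fov_deg = frames[[1]]$fov_deg),
    manifest, auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}

#' Read one rendered PNG frame back as a matrix
#'
#' @param path PNG file path.
#' @return A numeric brightness matrix in `[0, 1]`.
#' @export
read_frame_png <- function(path) {
  img <- png::readPNG(path)
  if (length(dim(img)) == 3) img <- img[, , 1]
  img
}
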