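#' Plot a phosphene map in the visual field
#'
#' Shows the visual-field position of each electrode's phosphene, with
#' point size proportional to the phosphene size a reference current would
#' produce at that eccentricity (the cortical-magnification effect: equal
#' cortical spacing yields small foveal and large peripheral phosphenes).
#'
#' @param object A `phosphene_map` tibble.
#' @param amplitude_uA Reference current (uA) for the size scaling.
#' @param cfg A [phosim_config()]; defaults to the package defaults.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.phosphene_map <- function(object, amplitude_uA = 100,
                                   cfg = phosim_config(), ...) {
  xy <- field_xy(object$eccentricity_deg, object$azimuth_rad,
                 object$hemisphere[1])
  df <- tibble::tibble(
    x = xy$x_deg, y = xy$y_deg,
    size_deg = phosphene_size(amplitude_uA, object$eccentricity_deg, cfg),
    active = object$active
  )
  ggplot2::ggplot(df, ggplot2::aes(.data$x, .data$y, size = .data$size_deg,
                                   alpha = .data$active)) +
    ggplot2::geom_point(color = "white", fill = "white", shape = 21) +
    ggplot2::scale_alpha_manual(values = c(`TRUE` = 1, `FALSE` = 0.15),
                                guide = "none") +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = "azimuth (deg)", y = "elevation (deg)",
                  size = "phosphene size (deg)") +
    ggplot2::theme_minimal() +
    ggplot2::theme(panel.background = ggplot2::element_rect(fill = "black"))
}

#' Per-train peak brightness of a state trace
#'
#' Summarizes a `run_sequence()` state trace into per-train peaks: frames
#' are grouped into trains by the onsets of nonzero effective current, and
#' the maximum brightness (and activation) within each train is reported.
#' Useful for habituation protocols, where the peak brightness declines
#' across repeated identical trains.
#'
#' @param trace A trace tibble from [run_sequence()] (single electrode).
#' @param onset_frames Integer vector of train onset frames.
#' @param span_frames Number of frames per train window (defaults to the
#'   gap between onsets).
#' @return A tibble with `train`, `onset_frame`, `peak_A`,
#'   `peak_brightness`.
#' @export
train_peaks <- function(trace, onset_frames, span_frames = NULL) {
  if (is.null(span_frames)) {
    span_frames <- if (length(onset_frames) > 1) min(diff(onset_frames))
                   else max(trace$frame) - onset_frames[1] + 1
  }
  purrr::map_dfr(seq_along(onset_frames), function(i) {
    win <- trace[trace$frame >= onset_frames[i] &
                 trace$frame < onset_frames[i] + span_frames, ]
    tibble::tibble(train = i, onset_frame = onset_frames[i],
                   peak_A = max(win$A), peak_brightness = max(win$brightness))
  })
}
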