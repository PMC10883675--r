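#' Pixel-center coordinates of the rendered window
#'
#' The rendered window has square pixels, the fixation point at the exact
#' image center, azimuth 0 pointing right and positive azimuth up; row 1 is
#' the top of the image. The angular width is `fov_deg`, so each pixel
#' subtends `fov_deg / cols` degrees.
#'
#' @param cfg A [phosim_config()].
#' @return A list with `xs` (deg, one per column), `ys` (deg, one per row,
#'   decreasing), and `pix_deg` (pixel size, deg).
#' @keywords internal
frame_geometry <- function(cfg) {
  rows <- cfg$resolution[1]
  cols <- cfg$resolution[2]
  pix <- cfg$fov_deg / cols
  list(
    xs = (seq_len(cols) - (cols + 1) / 2) * pix,
    ys = ((rows + 1) / 2 - seq_len(rows)) * pix,
    pix_deg = pix
  )
}

new_percept_frame <- function(image, cfg) {
  structure(
    list(image = image, fov_deg = cfg$fov_deg,
         resolution = dim(image)),
    class = "percept_frame")
}

#' Render a single phosphene as a Gaussian blob
#'
#' Phosphenes are rendered as isotropic Gaussian profiles with two standard
#' deviations equal to the phosphene size `P` (so `sigma = P/2`), placing
#' about 95% of the 1-D profile mass within the reported size. The peak
#' amplitude equals the phosphene brightness, matching the brightness-in-
#' `[0, 1]` semantics of the percept. Pixel values are smooth functions of
#' center, size and brightness, so gradients through the rendering are well
#' defined.
#'
#' @param x_deg,y_deg Phosphene center (deg) in screen coordinates.
#' @param size_deg Phosphene size `P` (deg).
#' @param brightness Peak brightness in `[0, 1]`.
#' @param cfg A [phosim_config()].
#' @return A `rows x cols` numeric matrix (the additive image
#'   contribution); all zeros when brightness or size is zero.
#' @export
render_phosphene <- function(x_deg, y_deg, size_deg, brightness, cfg) {
  geom <- frame_geometry(cfg)
  rows <- cfg$resolution[1]
  cols <- cfg$resolution[2]
  if (brightness <= 0 || size_deg <= 0) {
    return(matrix(0, rows, cols))
  }
  s <- size_deg / 2
  gx <- exp(-((geom$xs - x_deg)^2) / (2 * s^2))
  gy <- exp(-((geom$ys - y_deg)^2) / (2 * s^2))
  brightness * outer(gy, gx)
}

#' Render a single phosphene as a Gabor patch
#'
#' The Gaussian envelope of [render_phosphene()] multiplied by a cosine
#' carrier of the given spatial frequency and orientation, mapped into
#' `[0, 1]` as `0.5 + 0.5 * cos(...)` under the envelope. In the zero-
#' frequency limit the carrier is constant 1 and the Gaussian blob is
#' recovered.
#'
#' @inheritParams render_phosphene
#' @param frequency Carrier spatial frequency (cycles/deg), `>= 0`.
#' @param orientation Carrier orientation (rad).
#' @param phase Carrier phase (rad); zero phase centers a bright stripe on
#'   the phosphene.
#' @return A `rows x cols` numeric matrix.
#' @export
render_gabor <- function(x_deg, y_deg, size_deg, brightness,
                         frequency, orientation = 0, phase = 0, cfg) {
  stopifnot(frequency >= 0)
  envelope <- render_phosphene(x_deg, y_deg, size_deg, brightness, cfg)
  if (all(envelope == 0)) return(envelope)
  geom <- frame_geometry(cfg)
  u <- outer(rep(1, length(geom$ys)), geom$xs - x_deg) * cos(orientation) +
    outer(geom$ys - y_deg, rep(1, length(geom$xs))) * sin(orientation)
  carrier <- 0.5 + 0.5 * cos(2 * pi * frequency * u + phase)
  envelope * carrier
}

#' Compose phosphene renderings into a percept frame
#'
#' Sums the individual phosphene contributions pixelwise (the default
#' independent-electrode model renders each phosphene separately and adds
#' them) and, in clip mode, clips the result to `[0, 1]` so overlapping
#' bright phosphenes saturate.
#'
#' @param specs A data frame with one phosphene per row and columns
#'   `x_deg`, `y_deg`, `size_deg`, `brightness` (e.g. built by
#'   [sim_step()]); an empty frame is rendered from zero rows.
#' @param cfg A [phosim_config()].
#' @param clip_mode Override of `cfg$clip_mode` (`"clip"` or `"none"`).
#' @return A `percept_frame` object: a list with the brightness `image`
#'   matrix, `fov_deg`, and `resolution`.
#' @export
compose_frame <- function(specs, cfg, clip_mode = cfg$clip_mode) {
  img <- matrix(0, cfg$resolution[1], cfg$resolution[2])
  if (nrow(specs) > 0) {
    for (i in seq_len(nrow(specs))) {
      if (specs$brightness[i] <= 0 || specs$size_deg[i] <= 0) next
      img <- img + render_phosphene(specs$x_deg[i], specs$y_deg[i],
                                    specs$size_deg[i], specs$brightness[i],
                                    cfg)
    }
  }
  if (clip_mode == "clip") img <- pmin(pmax(img, 0), 1)
  new_percept_frame(img, cfg)
}

#' @export
print.percept_frame <- function(x, ...) {
  cat(sprintf("<percept_frame> %d x %d px, fov %g deg, brightness [%.3g, %.3g]\n",
              x$resolution[1], x$resolution[2], x$fov_deg,
              min(x$image), max(x$image)))
  invisible(x)
}

#' @export
as.matrix.percept_frame <- function(x, ...) x$image

#' Plot a percept frame
#'
#' Renders the simulated prosthetic percept with a linear gray scale,
#' degrees of visual angle on the axes and fixation at the origin.
#'
#' @param object A `percept_frame`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.percept_frame <- function(object, ...) {
  rows <- object$resolution[1]
  cols <- object$resolution[2]
  pix <- object$fov_deg / cols
  df <- tidyr::expand_grid(
    row = seq_len(rows),
    col = seq_len(cols)
  )
  df$x <- (df$col - (cols + 1) / 2) * pix
  df$y <- ((rows + 1) / 2 - df$row) * pix
  df$brightness <- as.vector(t(object$image))
  ggplot2::ggplot(df, ggplot2::aes(.data$x, .data$y,
                                   fill = .data$brightness)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_gradient(low = "black", high = "white",
                                 limits = c(0, max(1, max(df$brightness)))) +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = "azimuth (deg)", y = "elevation (deg)",
                  fill = "brightness") +
    ggplot2::theme_minimal()
}
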