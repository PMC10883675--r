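#' Wedge-dipole map: visual field to flattened V1 cortex
#'
#' Maps polar visual-field coordinates (eccentricity `r` in degrees, azimuth
#' `theta` in radians, `-pi/2 <= theta <= pi/2` within one hemifield) to a
#' complex cortical position `w` (mm) on a flattened map of V1, using the
#' normalized wedge-dipole model
#' \deqn{w = k\,[\log(z' + a) - \log(z' + b) - \log(a/b)], \quad
#'       z' = r e^{i\alpha\theta}.}
#' The constant term normalizes the fovea to the cortical origin, making the
#' map the exact inverse of [cortical_to_visual()].
#'
#' @param r Eccentricity (deg), non-negative; vectorized.
#' @param theta Azimuth (rad) within `[-pi/2, pi/2]`; vectorized.
#' @param cfg A [phosim_config()].
#' @return Complex vector of cortical positions (mm); the real part grows
#'   with eccentricity along the horizontal meridian.
#' @export
#' @examples
#' cfg <- phosim_config()
#' visual_to_cortical(0, 0, cfg)      # fovea maps to the origin
#' visual_to_cortical(5, pi / 4, cfg)
visual_to_cortical <- function(r, theta, cfg) {
  if (!all(is.finite(r)) || !all(is.finite(theta))) {
    stop("visual-field coordinates must be finite", call. = FALSE)
  }
  if (any(r < 0)) {
    stop("eccentricity `r` must be non-negative", call. = FALSE)
  }
  if (any(abs(theta) > pi / 2 + 1e-12)) {
    stop("azimuth `theta` must lie within [-pi/2, pi/2] (one hemifield)",
         call. = FALSE)
  }
  zp <- r * exp(1i * cfg$alpha * theta)
  cfg$k * (log(zp + cfg$a) - log(zp + cfg$b) - log(cfg$a / cfg$b))
}

#' Wedge-dipole map: flattened V1 cortex to visual field
#'
#' Inverts [visual_to_cortical()]:
#' \deqn{z = \Lambda^{-1}\!\left(\frac{ab\,(e^{w/k} - 1)}{b - a\,e^{w/k}}\right),
#'       \quad \Lambda^{-1}(r e^{i\theta}) = r e^{i\theta/\alpha},}
#' returning eccentricity `|z|` and azimuth `arg(z)`. Cortical positions at
#' (or numerically near) the map singularity `e^{w/k} = b/a` are rejected.
#'
#' @param w Complex cortical position(s) (mm).
#' @param cfg A [phosim_config()].
#' @return A tibble with columns `eccentricity_deg` and `azimuth_rad`.
#' @export
cortical_to_visual <- function(w, cfg) {
  if (!all(is.finite(Re(w))) || !all(is.finite(Im(w)))) {
    stop("cortical coordinates must be finite", call. = FALSE)
  }
  ew <- exp(w / cfg$k)
  if (any(Mod(ew - cfg$b / cfg$a) < 1e-9)) {
    stop("cortical position at the wedge-dipole map singularity (e^{w/k} = b/a)",
         call. = FALSE)
  }
  z_sheared <- cfg$a * cfg$b * (ew - 1) / (cfg$b - cfg$a * ew)
  tibble::tibble(
    eccentricity_deg = Mod(z_sheared),
    azimuth_rad = ifelse(Mod(z_sheared) == 0, 0, Arg(z_sheared) / cfg$alpha)
  )
}

#' Cortical magnification factor
#'
#' Millimetres of cortical surface per degree of visual angle at
#' eccentricity `r`, the derivative of the wedge-dipole map along the
#' horizontal meridian:
#' \deqn{M(r) = \frac{k (b - a)}{(r + a)(r + b)}.}
#' Largest at the fovea and strictly decreasing with eccentricity.
#'
#' @param r Eccentricity (deg), non-negative; vectorized.
#' @param cfg A [phosim_config()].
#' @return Magnification (mm/deg).
#' @export
#' @examples
#' cortical_magnification(0, phosim_config()) # ~22.9 mm/deg at the fovea
cortical_magnification <- function(r, cfg) {
  stopifnot(all(r >= 0))
  cfg$k * (cfg$b - cfg$a) / ((r + cfg$a) * (r + cfg$b))
}

# screen coordinates (deg) of a phosphene; the hemifield is opposite to the
# hemisphere carrying the electrodes
field_xy <- function(r, theta, hemisphere) {
  sgn <- if (hemisphere == "right") -1 else 1
  list(x_deg = sgn * r * cos(theta), y_deg = r * sin(theta))
}

new_phosphene_map <- function(df) {
  df <- tibble::as_tibble(df)
  class(df) <- c("phosphene_map", class(df))
  df
}

#' Regular electrode grid on the flattened cortical map
#'
#' Places an `n_rows x n_cols` grid of electrodes with the given spacing on
#' the flattened cortical surface (a 'Utah array' is 10 x 10 at 0.4 mm
#' spacing) and derives, for each electrode, the visual-field phosphene
#' position and the local cortical magnification. Detection thresholds are
#' left unset until the simulator session is initialized.
#'
#' @param n_rows,n_cols Grid dimensions.
#' @param spacing_mm Electrode spacing (mm), positive.
#' @param origin Numeric `c(x, y)`: cortical position (mm) of the grid
#'   center.
#' @param cfg A [phosim_config()]; supplies the map constants and the
#'   hemisphere label.
#' @return A `phosphene_map` tibble with one row per electrode and columns
#'   `electrode_id`, `x_cortex_mm`, `y_cortex_mm`, `eccentricity_deg`,
#'   `azimuth_rad`, `hemisphere`, `magnification_mm_per_deg`, `active`,
#'   `threshold`.
#' @export
#' @examples
#' cfg <- phosim_config()
#' utah <- make_grid_layout(10, 10, 0.4, origin = c(20, 0), cfg)
#' nrow(utah)
make_grid_layout <- function(n_rows, n_cols, spacing_mm, origin = c(0, 0), cfg) {
  stopifnot(n_rows >= 1, n_cols >= 1)
  if (spacing_mm <= 0 && (n_rows > 1 || n_cols > 1)) {
    stop("electrode spacing must be positive", call. = FALSE)
  }
  gx <- origin[1] + (seq_len(n_cols) - (n_cols + 1) / 2) * spacing_mm
  gy <- origin[2] + (seq_len(n_rows) - (n_rows + 1) / 2) * spacing_mm
  pos <- expand.grid(y = gy, x = gx)[, c("x", "y")]
  w <- complex(real = pos$x, imaginary = pos$y)
  ew <- exp(w / cfg$k)
  bad <- Mod(ew - cfg$b / cfg$a) < 1e-9
  vf <- cortical_to_visual(w[!bad], cfg)
  # the map is only valid within one hemifield; electrodes that land outside
  # it (or at the singularity) cannot be placed
  out_of_range <- rep(TRUE, length(w))
  out_of_range[!bad] <- abs(vf$azimuth_rad) > pi / 2 + 1e-9
  if (any(bad) || any(out_of_range)) {
    stop(sprintf(
      "grid placement failed: electrode(s) %s fall beyond the admissible cortical range",
      paste(which(bad | out_of_range), collapse = ", ")), call. = FALSE)
  }
  new_phosphene_map(tibble::tibble(
    electrode_id = seq_along(w),
    x_cortex_mm = Re(w),
    y_cortex_mm = Im(w),
    eccentricity_deg = vf$eccentricity_deg,
    azimuth_rad = vf$azimuth_rad,
    hemisphere = cfg$hemisphere,
    magnification_mm_per_deg = cortical_magnification(vf$eccentricity_deg, cfg),
    active = TRUE,
    threshold = NA_real_
  ))
}

#' Jitter electrode positions and drop electrodes
#'
#' Models imperfect knowledge of electrode locations and malfunctioning
#' electrodes: cortical positions receive zero-mean isotropic Gaussian noise
#' of scale `pos_noise_mm`, and each electrode is independently deactivated
#' with probability `dropout_p`. Visual-field coordinates and magnification
#' are recomputed from the perturbed positions. Deterministic given `seed`.
#'
#' @param map A `phosphene_map` tibble.
#' @param pos_noise_mm Gaussian positional noise scale (mm), `>= 0`.
#' @param dropout_p Dropout probability in `[0, 1]`.
#' @param seed Integer seed, or `NULL` to use the session RNG stream.
#' @param cfg A [phosim_config()].
#' @return The perturbed `phosphene_map`.
#' @export
perturb_layout <- function(map, pos_noise_mm = 0, dropout_p = 0, seed = NULL,
                           cfg) {
  stopifnot(pos_noise_mm >= 0, dropout_p >= 0, dropout_p <= 1)
  n <- nrow(map)
  do_perturb <- function() {
    if (pos_noise_mm > 0) {
      map$x_cortex_mm <<- map$x_cortex_mm + rnorm(n, 0, pos_noise_mm)
      map$y_cortex_mm <<- map$y_cortex_mm + rnorm(n, 0, pos_noise_mm)
    }
    if (dropout_p > 0) {
      map$active <<- map$active & (runif(n) >= dropout_p)
    }
  }
  if (is.null(seed)) do_perturb() else withr::with_seed(seed, do_perturb())
  w <- complex(real = map$x_cortex_mm, imaginary = map$y_cortex_mm)
  vf <- cortical_to_visual(w, cfg)
  map$eccentricity_deg <- vf$eccentricity_deg
  map$azimuth_rad <- vf$azimuth_rad
  map$magnification_mm_per_deg <-
    cortical_magnification(vf$eccentricity_deg, cfg)
  map
}

#' Read an electrode layout CSV
#'
#' Accepts either cortical coordinates (`electrode_id, x_cortex_mm,
#' y_cortex_mm, hemisphere`) or visual-field phosphene coordinates
#' (`electrode_id, eccentricity_deg, azimuth_rad`); whichever triple is
#' present is detected automatically and the missing coordinate system plus
#' the cortical magnification are derived from the wedge-dipole map.
#'
#' @param path CSV file path.
#' @param cfg A [phosim_config()].
#' @return A `phosphene_map` tibble (see [make_grid_layout()]).
#' @export
read_electrode_csv <- function(path, cfg) {
  df <- readr::read_csv(path, show_col_types = FALSE)
  has_cortex <- all(c("x_cortex_mm", "y_cortex_mm") %in% names(df))
  has_visual <- all(c("eccentricity_deg", "azimuth_rad") %in% names(df))
  if (!("electrode_id" %in% names(df))) {
    stop("electrode CSV is missing required column `electrode_id`",
         call. = FALSE)
  }
  if (!has_cortex && !has_visual) {
    stop(paste("electrode CSV must contain either columns",
               "`x_cortex_mm`, `y_cortex_mm` or",
               "`eccentricity_deg`, `azimuth_rad`"), call. = FALSE)
  }
  hemi <- if ("hemisphere" %in% names(df)) df$hemisphere else cfg$hemisphere
  if (has_cortex) {
    w <- complex(real = df$x_cortex_mm, imaginary = df$y_cortex_mm)
    vf <- cortical_to_visual(w, cfg)
    ecc <- vf$eccentricity_deg
    azi <- vf$azimuth_rad
    xc <- df$x_cortex_mm
    yc <- df$y_cortex_mm
  } else {
    w <- visual_to_cortical(df$eccentricity_deg, df$azimuth_rad, cfg)
    ecc <- df$eccentricity_deg
    azi <- df$azimuth_rad
    xc <- Re(w)
    yc <- Im(w)
  }
  new_phosphene_map(tibble::tibble(
    electrode_id = df$electrode_id,
    x_cortex_mm = xc,
    y_cortex_mm = yc,
    eccentricity_deg = ecc,
    azimuth_rad = azi,
    hemisphere = hemi,
    magnification_mm_per_deg = cortical_magnification(ecc, cfg),
    active = if ("active" %in% names(df)) as.logical(df$active) else TRUE,
    threshold = if ("threshold" %in% names(df)) df$threshold else NA_real_
  ))
}

#' Write an electrode layout CSV
#'
#' Emits both coordinate systems (cortical mm and visual-field polar
#' degrees/radians) plus the cortical magnification, so the file can be
#' re-read with either convention.
#'
#' @param map A `phosphene_map` tibble.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_electrode_csv <- function(map, path) {
  readr::write_csv(
    map[, c("electrode_id", "x_cortex_mm", "y_cortex_mm", "hemisphere",
            "eccentricity_deg", "azimuth_rad", "magnification_mm_per_deg",
            "active", "threshold")],
    path)
  invisible(path)
}
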