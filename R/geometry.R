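#' Diameter of activated cortical tissue
#'
#' Current-spread model of intracortical microstimulation: the current
#' needed to activate neurons grows with the square of the distance from the
#' electrode tip, so a stimulation current `I` (uA) with excitability
#' constant `K` (uA mm^-2) activates a disc of cortical tissue of diameter
#' \deqn{D = 2\sqrt{I / K} \; \mathrm{mm}.}
#'
#' @param I_uA Stimulation current (uA), non-negative; vectorized.
#' @param cfg A [phosim_config()] (uses `K`).
#' @return Activated cortical diameter (mm).
#' @export
#' @examples
#' activation_diameter(675, phosim_config()) # 2 mm at I = K
activation_diameter <- function(I_uA, cfg) {
  stopifnot(all(I_uA >= 0))
  2 * sqrt(I_uA / cfg$K)
}

#' Phosphene size from current and eccentricity
#'
#' Converts the activated cortical diameter into degrees of visual angle by
#' dividing by the local cortical magnification:
#' \deqn{P = D / M(r).}
#' At fixed current the phosphene grows with eccentricity (M falls); at
#' fixed eccentricity it grows with the square root of the current. Only the
#' instantaneous stimulation current enters the size: neither the memory
#' trace nor pulse width/frequency affect it.
#'
#' @param I_uA Stimulation current (uA), non-negative; vectorized.
#' @param r Eccentricity (deg), non-negative; vectorized.
#' @param cfg A [phosim_config()].
#' @return Phosphene size (deg).
#' @export
#' @examples
#' cfg <- phosim_config()
#' phosphene_size(675, 0, cfg)  # ~0.0873 deg at the fovea
#' phosphene_size(675, 10, cfg) # larger in the periphery
phosphene_size <- function(I_uA, r, cfg) {
  activation_diameter(I_uA, cfg) / cortical_magnification(r, cfg)
}
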