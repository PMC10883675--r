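#' Co-stimulation penalty for neighboring electrodes
#'
#' A scalar loss discouraging simultaneous activation of nearby electrode
#' pairs,
#' \deqn{L = \frac{1}{n} \sum_i \sum_{j \ne i}
#'   \frac{I_i I_j}{1 + \lVert p_j - p_i \rVert^2},}
#' with distances in mm on the flattened cortical map. Self-pairs are
#' excluded. The penalty is symmetric under electrode relabeling and
#' invariant under rigid translation of all positions.
#'
#' @param currents Per-electrode stimulation currents (non-negative; any
#'   consistent unit — the loss is quadratic in it).
#' @param positions `n x 2` matrix of cortical electrode positions (mm).
#' @return The scalar penalty.
#' @export
#' @examples
#' costim_loss(c(1, 1), rbind(c(0, 0), c(1, 0))) # 0.5
costim_loss <- function(currents, positions) {
  stopifnot(all(currents >= 0))
  positions <- as.matrix(positions)
  n <- length(currents)
  stopifnot(nrow(positions) == n, ncol(positions) == 2)
  if (n < 2) return(0)
  d2 <- as.matrix(stats::dist(positions))^2
  w <- outer(currents, currents) / (1 + d2)
  diag(w) <- 0
  sum(w) / n
}

#' Coactivation leak currents between active electrodes
#'
#' Models current of active electrodes 'leaking' to neighboring active
#' electrodes: each electrode with nonzero stimulation receives the added
#' current
#' \deqn{I_{coact,i} = \sum_{j \ne i,\; I_j > 0}
#'   \frac{I_j}{1 + c \lVert p_j - p_i \rVert^2}}
#' (leak constant `c = 100` mm^-2 by default), which is added to its
#' stimulation amplitude before the effective-current stage. Inactive
#' electrodes receive nothing, and with all pairwise distances large the
#' model reduces to the independent-electrode case.
#'
#' @param currents Per-electrode stimulation currents (non-negative).
#' @param positions `n x 2` matrix of cortical electrode positions (mm).
#' @param leak_constant Distance scaling of the leak kernel (mm^-2).
#' @return Per-electrode added current, in the unit of `currents`.
#' @export
#' @examples
#' coactivation_currents(c(10, 10), rbind(c(0, 0), c(0.1, 0))) # 5 uA each
coactivation_currents <- function(currents, positions, leak_constant = 100) {
  stopifnot(all(currents >= 0), leak_constant > 0)
  positions <- as.matrix(positions)
  n <- length(currents)
  stopifnot(nrow(positions) == n, ncol(positions) == 2)
  if (n < 2) return(numeric(n))
  active <- currents > 0
  d2 <- as.matrix(stats::dist(positions))^2
  kern <- 1 / (1 + leak_constant * d2)
  diag(kern) <- 0
  out <- as.vector(kern %*% (currents * active))
  out[!active] <- 0
  out
}
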