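#' DPD force-field and integration parameters
#'
#' Bundles the Groot-Warren parameter set used throughout the package. Units
#' are the customary DPD reduced units: the pair cutoff `r_c = 1` is the
#' length unit, the bead mass `m = 1`, the thermal energy `k_B T = 1`, and
#' the time unit is `tau = sqrt(m r_c^2 / k_B T) = 1`.
#'
#' The random-force amplitude is tied to the dissipative coefficient by the
#' fluctuation-dissipation relation `sigma^2 = 2 gamma k_B T`; supplying a
#' `sigma` that violates it is an error. The repulsion between like species
#' is `a_ii = 25` and the rod-strand repulsion `a_rp` defaults to the same
#' value, so that the rod-network interplay is purely entropic; `a_rp` can be
#' lowered (attraction) or raised (extra repulsion).
#'
#' @param a_ii repulsion amplitude between like species (k_B T / r_c).
#' @param a_rp rod-strand (and rod-crosslink) repulsion amplitude.
#' @param gamma_dpd dissipative friction coefficient (m / tau).
#' @param sigma random-force amplitude; default `sqrt(2 * gamma_dpd * kT)`.
#' @param kT thermal energy (energy unit, 1).
#' @param rc pair-force cutoff (length unit, 1).
#' @param dt integration time step (tau).
#' @param lambda_vv velocity-prediction factor of the modified
#'   velocity-Verlet scheme.
#' @param rho total bead number density (r_c^-3).
#' @param bond_k harmonic spring constant of strand bonds (k_B T / r_c^2).
#' @param bond_r0 spring rest length (r_c).
#' @return An object of class `dpd_params`: a validated list with an
#'   `aij` repulsion matrix over the species
#'   (solvent, strand, crosslink, rod).
#' @export
#' @examples
#' p <- dpd_params()
#' p$sigma^2 / (2 * p$gamma_dpd * p$kT)  # fluctuation-dissipation: exactly 1
dpd_params <- function(a_ii = 25, a_rp = a_ii, gamma_dpd = 4.5, sigma = NULL,
                       kT = 1, rc = 1, dt = 0.02, lambda_vv = 0.65, rho = 3,
                       bond_k = 100, bond_r0 = 0.7) {
  stopifnot(a_ii > 0, gamma_dpd > 0, kT > 0, rc > 0, dt > 0, rho > 0,
            bond_k >= 0, bond_r0 >= 0, lambda_vv > 0, lambda_vv <= 1)
  sigma_fd <- sqrt(2 * gamma_dpd * kT)
  if (is.null(sigma)) {
    sigma <- sigma_fd
  } else if (abs(sigma^2 - 2 * gamma_dpd * kT) > 1e-8 * max(1, sigma^2)) {
    stop("sigma^2 must equal 2 * gamma_dpd * kT (fluctuation-dissipation); ",
         "got sigma = ", sigma, ", expected ", sigma_fd)
  }
  aij <- matrix(a_ii, 4, 4,
                dimnames = list(species_levels(), species_levels()))
  aij["rod", c("strand", "crosslink")] <- a_rp
  aij[c("strand", "crosslink"), "rod"] <- a_rp
  structure(list(a_ii = a_ii, a_rp = a_rp, aij = aij,
                 gamma_dpd = gamma_dpd, sigma = sigma, kT = kT, rc = rc,
                 dt = dt, lambda_vv = lambda_vv, rho = rho,
                 bond_k = bond_k, bond_r0 = bond_r0),
            class = "dpd_params")
}

species_levels <- function() c("solvent", "strand", "crosslink", "rod")

#' @export
print.dpd_params <- function(x, ...) {
  cat("DPD parameters: a_ii =", x$a_ii, " a_rp =", x$a_rp,
      " gamma =", x$gamma_dpd, " dt =", x$dt, "\n")
  cat("  rho =", x$rho, " kT =", x$kT, " sigma =", round(x$sigma, 4),
      " lambda =", x$lambda_vv, "\n")
  cat("  bonds: k =", x$bond_k, " r0 =", x$bond_r0, "\n")
  invisible(x)
}

#' Kinetic temperature of a configuration
#'
#' Returns the instantaneous kinetic temperature `<m |v - v_drift|^2> / 3`
#' per bead, with the centre-of-mass drift removed. For systems containing a
#' rigid rod the rod beads are excluded by default (their velocities are
#' slaved to six rigid degrees of freedom, not 3N thermal ones).
#'
#' @param state a `dpd_state`, or a numeric matrix of velocities (N x 3).
#' @param include_rod include rod beads in the average.
#' @return kinetic temperature in units of k_B T.
#' @export
measure_temperature <- function(state, include_rod = FALSE) {
  v <- if (is.matrix(state)) state else state$velocities
  if (!is.matrix(state) && !include_rod && !is.null(state$rod)) {
    v <- v[state$species != 4L, , drop = FALSE]
  }
  if (nrow(v) == 0) return(NA_real_)
  drift <- colMeans(v)
  v <- sweep(v, 2, drift)
  mean(rowSums(v^2)) / 3
}
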