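#' Pairwise DPD forces of a configuration
#'
#' Evaluates the Groot-Warren pair forces at cutoff `r_c`: the soft
#' conservative repulsion `a_ij (1 - r/r_c) rhat`, the dissipative force
#' `-gamma (1 - r/r_c)^2 (rhat . v_ij) rhat` and the random force
#' `sigma (1 - r/r_c) theta_ij rhat / sqrt(dt)` with symmetric zero-mean
#' unit-variance pair noise. Newton's third law holds pairwise for every
#' component, so momentum is conserved exactly. Coincident beads (r = 0)
#' are separated along a seeded random direction, the documented convention
#' for this degenerate input.
#'
#' @param state a `dpd_state`.
#' @param params a [dpd_params()].
#' @param components subset of `c("conservative", "dissipative", "random")`.
#' @param method `"cell"` (linked cells, automatic brute-force fallback for
#'   boxes below 3 cutoffs) or `"brute"` (all pairs; reference path).
#' @return N x 3 matrix of forces (k_B T / r_c).
#' @export
pair_forces <- function(state, params,
                        components = c("conservative", "dissipative", "random"),
                        method = c("cell", "brute")) {
  method <- match.arg(method)
  components <- match.arg(components, several.ok = TRUE)
  if (any(!is.finite(state$positions))) stop("non-finite positions")
  cpp_pair_forces(state$positions, state$velocities, state$species,
                  state$species == 4L, params$aij, state$box, params$rc,
                  params$gamma_dpd, params$sigma, params$dt,
                  "conservative" %in% components,
                  "dissipative" %in% components,
                  "random" %in% components,
                  method == "brute")
}

#' Harmonic strand-bond forces
#'
#' `-bond_k (r - bond_r0) rhat` on each partner of every bonded pair; equal
#' and opposite by construction. A bond stretched beyond half the box signals
#' broken topology and is a hard failure.
#'
#' @inheritParams pair_forces
#' @return N x 3 matrix of forces.
#' @export
bond_forces <- function(state, params) {
  cpp_bond_forces(state$positions, state$bonds, state$box,
                  params$bond_k, params$bond_r0)
}

#' Run the DPD simulation
#'
#' Integrates the system with the modified velocity-Verlet scheme (velocity
#' prediction factor `lambda_vv`, one force evaluation per step). Free beads
#' follow the standard update; rod beads move rigidly: the net force and
#' torque about the rod centre of mass drive the COM velocity and angular
#' momentum, the orientation quaternion is advanced and renormalised every
#' step, and bead positions are regenerated from the pose, keeping intra-rod
#' distances exact. Any bead displacing more than `r_c / 2` in one step is a
#' hard failure (unstable step).
#'
#' @param state a `dpd_state`.
#' @param params a [dpd_params()].
#' @param n_steps number of time steps.
#' @param record_every store the rod pose and kinetic temperature every this
#'   many steps (0 = record nothing).
#' @param seed optional integer seed (restores the caller's RNG stream).
#' @param thermostat logical; FALSE switches off the dissipative and random
#'   forces (pure conservative dynamics, useful for conservation tests).
#' @return list with the updated `state`, a `trajectory` data frame
#'   (time, unwrapped rod COM, rod axis, kinetic temperature of free beads)
#'   and the total `momentum`.
#' @export
#' @examples
#' st <- solvent_box(125, dpd_params(), seed = 1)
#' out <- run_dpd(st, dpd_params(), n_steps = 50, record_every = 10, seed = 2)
#' out$trajectory$temperature
run_dpd <- function(state, params, n_steps, record_every = 10, seed = NULL,
                    thermostat = TRUE) {
  rodL <- if (is.null(state$rod)) list() else
    list(idx = state$rod$idx, body = state$rod$spec$body,
         mass = state$rod$mass, inertia = state$rod$inertia,
         com = state$rod$com, com_un = state$rod$com_un,
         quat = state$rod$quat, vel = state$rod$vel,
         angmom = state$rod$angmom)
  res <- with_seed(seed,
    cpp_dpd_run(state$positions, state$velocities, state$species,
                state$species == 4L, state$bonds, params$aij, state$box,
                params$rc, params$gamma_dpd, params$sigma, params$dt,
                params$lambda_vv, params$bond_k, params$bond_r0, rodL,
                state$time, as.integer(n_steps), as.integer(record_every),
                thermostat, thermostat, FALSE))
  rod <- state$rod
  if (!is.null(rod)) {
    rod$com <- res$rod$com; rod$com_un <- res$rod$com_un
    rod$quat <- res$rod$quat; rod$vel <- res$rod$vel
    rod$angmom <- res$rod$angmom
  }
  new_state <- new_dpd_state(res$pos, res$vel, state$species, state$box,
                             state$bonds, rod = rod, time = res$time)
  traj <- as.data.frame(res$traj)
  names(traj) <- c("time", "x", "y", "z", "ux", "uy", "uz", "temperature")
  class(traj) <- c("rod_trajectory", "data.frame")
  list(state = new_state, trajectory = traj, momentum = res$momentum)
}

#' Advance the system by a single step
#' @inheritParams run_dpd
#' @return the updated `dpd_state`.
#' @export
integrate_step <- function(state, params, seed = NULL, thermostat = TRUE) {
  run_dpd(state, params, n_steps = 1, record_every = 0, seed = seed,
          thermostat = thermostat)$state
}

#' Equilibrated pure-solvent box
#'
#' Builds a cubic box of `n` solvent beads at density `params$rho` with
#' uniform random positions and Maxwell-Boltzmann velocities.
#'
#' @param n number of beads.
#' @param params a [dpd_params()].
#' @param seed integer seed.
#' @return a `dpd_state`.
#' @export
solvent_box <- function(n, params = dpd_params(), seed = NULL) {
  edge <- (n / params$rho)^(1 / 3)
  with_seed(seed, {
    pos <- matrix(runif(3 * n, 0, edge), ncol = 3)
    vel <- maxwell_velocities(n, params$kT)
    new_dpd_state(pos, vel, rep(1L, n), rep(edge, 3),
                  matrix(integer(0), 0, 2))
  })
}

#' Append one run's trajectory to another
#'
#' Utility for chaining equilibration and production segments.
#' @param ... `rod_trajectory` data frames in time order.
#' @return a single `rod_trajectory`.
#' @export
bind_trajectories <- function(...) {
  out <- do.call(rbind, lapply(list(...), as.data.frame))
  class(out) <- c("rod_trajectory", "data.frame")
  out
}
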