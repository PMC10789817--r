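#' Specification of a hexa-functional network
#'
#' The network is realised as a simple-cubic lattice of crosslinks
#' (functionality 6 under periodic closure), each lattice edge carried by a
#' strand of bonded beads. Mesh-size polydispersity is controlled through the
#' coefficient of variation `cv` of the strand rest lengths: strand bead
#' counts are drawn from a rounded lognormal whose log-variance is calibrated
#' so the realised rest-length CV matches the target.
#'
#' @param cells_per_side number of lattice cells along each box edge (>= 2).
#' @param a_x target mesh size, i.e. lattice constant (r_c).
#' @param beads_per_strand mean number of beads per strand (excluding the
#'   two crosslinks).
#' @param cv target coefficient of variation of strand rest lengths
#'   (sigma_ax / a_x); 0 gives a monodisperse network.
#' @param seed integer seed for the strand-length draw and solvent placement.
#' @return An object of class `network_spec`.
#' @export
network_spec <- function(cells_per_side, a_x = 3.35, beads_per_strand = 7,
                         cv = 0, seed = NULL) {
  stopifnot(cells_per_side >= 2, a_x > 0, beads_per_strand >= 1, cv >= 0)
  structure(list(cells_per_side = as.integer(cells_per_side), a_x = a_x,
                 beads_per_strand = as.integer(beads_per_strand), cv = cv,
                 seed = seed),
            class = "network_spec")
}

# calibrate the lognormal log-SD so that the rounded draw k = max(1,
# round(Y - 1)), Y ~ LN(mean = m + 1), gives rest lengths (k + 1) * r0 with
# the requested CV.  Deterministic: works on the rounded-lognormal pmf.
calibrate_sdlog <- function(mean_beads, cv) {
  if (cv == 0) return(0)
  mu <- mean_beads + 1
  kmax <- max(200, ceiling(mu * (1 + 12 * cv)))
  cv_of <- function(s) {
    meanlog <- log(mu) - s^2 / 2
    k <- seq_len(kmax)
    upper <- plnorm(k + 1.5, meanlog, s)
    lower <- plnorm(pmax(k + 0.5, 0), meanlog, s)
    p <- upper - lower
    p[1] <- plnorm(2.5, meanlog, s) # k = 1 absorbs all Y < 2.5
    p <- p / sum(p)
    x <- k + 1
    m1 <- sum(p * x)
    sqrt(sum(p * (x - m1)^2)) / m1
  }
  hi <- 2.5
  if (cv_of(hi) < cv)
    stop("cv = ", cv, " beyond the feasible range of the strand-length ",
         "distribution")
  uniroot(function(s) cv_of(s) - cv, c(1e-6, hi), tol = 1e-6)$root
}

#' Draw per-strand bead counts for a target rest-length CV
#'
#' @param n number of strands.
#' @param beads_per_strand mean bead count.
#' @param cv target CV of the rest lengths `(k + 1) * bond_r0`.
#' @return integer vector of bead counts (>= 1). Uses the current RNG state.
#' @export
strand_bead_counts <- function(n, beads_per_strand, cv) {
  if (cv == 0) return(rep.int(beads_per_strand, n))
  s <- calibrate_sdlog(beads_per_strand, cv)
  mu <- beads_per_strand + 1
  y <- stats::rlnorm(n, log(mu) - s^2 / 2, s)
  pmax(1L, as.integer(round(y - 1)))
}

#' Build the cross-linked network with solvent fill
#'
#' Places `cells_per_side^3` crosslinks on a simple-cubic lattice of spacing
#' `a_x` (hexa-functional under periodic closure), realises each of the
#' `3 n^3` lattice edges as a bonded bead chain, fills the box with solvent
#' beads to the global density `params$rho`, and relaxes the solvent with a
#' capped-displacement descent so no residual hard overlaps remain.
#'
#' @param spec a [network_spec()].
#' @param params a [dpd_params()].
#' @param relax_iter capped-displacement relaxation sweeps for the solvent.
#' @return list with `topology` (crosslink positions, strand table,
#'   functionality) and `state` (a `dpd_state`).
#' @export
#' @examples
#' net <- build_network(network_spec(3, seed = 1), dpd_params(), relax_iter = 20)
#' nrow(net$topology$strands)  # 81 = 3 * 27 strands
build_network <- function(spec, params, relax_iter = 1000) {
  n <- spec$cells_per_side
  a_x <- spec$a_x
  box <- rep(n * a_x, 3)
  idx3 <- expand.grid(i = 0:(n - 1), j = 0:(n - 1), k = 0:(n - 1))
  cross_pos <- as.matrix(idx3) * a_x
  M <- nrow(cross_pos)
  node_id <- function(i, j, k) {
    1L + (i %% n) + (j %% n) * n + (k %% n) * n^2
  }
  dirs <- rbind(c(1, 0, 0), c(0, 1, 0), c(0, 0, 1))

  counts <- with_seed(spec$seed, strand_bead_counts(3L * M, spec$beads_per_strand, spec$cv))
  strands <- vector("list", 3L * M)
  bead_pos <- vector("list", 3L * M)
  bonds <- vector("list", 3L * M)
  next_bead <- M + 1L
  si <- 0L
  for (m in seq_len(M)) {
    ii <- idx3$i[m]; jj <- idx3$j[m]; kk <- idx3$k[m]
    for (d in 1:3) {
      si <- si + 1L
      nb <- node_id(ii + dirs[d, 1], jj + dirs[d, 2], kk + dirs[d, 3])
      kbeads <- counts[si]
      p1 <- cross_pos[m, ]
      ends <- p1 + dirs[d, ] * a_x # unwrapped endpoint
      frac <- seq_len(kbeads) / (kbeads + 1)
      bp <- t(sapply(frac, function(f) p1 + f * (ends - p1)))
      ids <- seq.int(next_bead, length.out = kbeads)
      chain <- c(m, ids, nb)
      bonds[[si]] <- cbind(chain[-length(chain)], chain[-1])
      bead_pos[[si]] <- bp
      strands[[si]] <- c(i = m, j = nb, dir = d, first_bead = next_bead,
                         n_beads = kbeads)
      next_bead <- next_bead + kbeads
    }
  }
  strand_tab <- as.data.frame(do.call(rbind, strands))
  strand_beads <- do.call(rbind, bead_pos)
  n_strand <- nrow(strand_beads)

  n_total <- round(params$rho * prod(box))
  n_solv <- n_total - M - n_strand
  if (n_solv < 0) stop("network beads alone exceed the target density")
  solv <- with_seed(if (is.null(spec$seed)) NULL else spec$seed + 1L,
                    matrix(runif(3 * n_solv, 0, box[1]), ncol = 3))

  positions <- rbind(cross_pos, strand_beads, solv)
  positions <- positions %% box[1]
  species <- c(rep(3L, M), rep(2L, n_strand), rep(1L, n_solv))
  bonds <- do.call(rbind, bonds)
  storage.mode(bonds) <- "integer"

  movable <- species == 1L
  if (relax_iter > 0 && n_solv > 0) {
    positions <- with_seed(if (is.null(spec$seed)) NULL else spec$seed + 2L,
      cpp_relax(positions, species, movable, bonds, params$aij, box,
                params$rc, as.integer(relax_iter), 0.05, 5e-4,
                params$bond_k, params$bond_r0))
  }
  velocities <- with_seed(if (is.null(spec$seed)) NULL else spec$seed + 3L,
                          maxwell_velocities(nrow(positions), params$kT))
  state <- new_dpd_state(positions, velocities, species, box, bonds,
                         rod = NULL, time = 0)
  topology <- structure(list(crosslink_positions = cross_pos,
                             strands = strand_tab, functionality = 6L,
                             a_x = a_x, cells_per_side = n, cv = spec$cv,
                             beads_per_strand = spec$beads_per_strand,
                             seed = spec$seed),
                        class = "network_topology")
  list(topology = topology, state = state)
}

maxwell_velocities <- function(n, kT) {
  v <- matrix(rnorm(3 * n, sd = sqrt(kT)), ncol = 3)
  sweep(v, 2, colMeans(v)) # zero total momentum
}

#' Mesh-size statistics of a network
#'
#' The mesh size of a strand is the distance between its two crosslinks. Two
#' measures are available: `"geometric"` uses the current crosslink positions
#' in `state` (minimum image), `"rest"` uses the strand rest lengths
#' `(n_beads + 1) * bond_r0` implied by the topology.
#'
#' @param topology a `network_topology`.
#' @param state a `dpd_state` (required for `use = "geometric"`).
#' @param use `"geometric"` or `"rest"`.
#' @param params a [dpd_params()] (for `bond_r0` when `use = "rest"`).
#' @return list with `mean`, `sd`, `cv` and the per-strand `sizes`.
#' @export
measure_mesh_sizes <- function(topology, state = NULL,
                               use = c("geometric", "rest"),
                               params = dpd_params()) {
  use <- match.arg(use)
  if (use == "rest") {
    sizes <- (topology$strands$n_beads + 1) * params$bond_r0
  } else {
    stopifnot(!is.null(state))
    M <- nrow(topology$crosslink_positions)
    pos <- state$positions[seq_len(M), , drop = FALSE]
    box <- state$box
    d <- pos[topology$strands$i, , drop = FALSE] -
      pos[topology$strands$j, , drop = FALSE]
    d <- d - sweep(round(sweep(d, 2, box, "/")), 2, box, "*")
    sizes <- sqrt(rowSums(d^2))
  }
  m <- mean(sizes)
  s <- stats::sd(sizes)
  list(mean = m, sd = s, cv = if (m > 0) s / m else NA_real_, sizes = sizes)
}

#' Insert a rigid rod into a built system
#'
#' Places the rod at `center` with its axis along `axis`, deletes solvent
#' beads within 0.5 r_c of any rod bead, restores the global bead density by
#' removing (or adding) solvent far from the rod, and re-relaxes the solvent.
#'
#' @param state a `dpd_state` from [build_network()].
#' @param rod a [build_rod()] spec.
#' @param center rod centre of mass (r_c, lab frame).
#' @param axis rod axis direction (defaults to the z lattice vector).
#' @param params a [dpd_params()].
#' @param seed seed for density-restoring insertions and the relaxation.
#' @param relax_iter relaxation sweeps after insertion.
#' @return the updated `dpd_state` with a `rod` component.
#' @export
place_rod <- function(state, rod, center, axis = c(0, 0, 1),
                      params = dpd_params(), seed = NULL, relax_iter = 200) {
  box <- state$box
  quat <- quat_from_axis(axis)
  R <- quat_to_matrix(quat)
  lab <- sweep(rod$body %*% t(R), 2, center, "+")
  if (any(lab < -box[1] | lab > 2 * box[1]))
    stop("rod does not fit near the primary box")
  # DPD cores are soft and bounded, so shallow initial overlap with network
  # beads is relaxed away after insertion; only a crosslink buried deep in
  # the rod body (beyond what slack strands can accommodate) is a geometry
  # error. For thick rods (d/a_x > sqrt 2) the lattice corner columns
  # necessarily graze the rod surface.
  cl <- state$positions[state$species == 3L, , drop = FALSE]
  if (nrow(cl) > 0) {
    axis_u <- R[, 3]
    rel <- sweep(cl, 2, center %% box[1])
    rel <- rel - sweep(round(sweep(rel, 2, box, "/")), 2, box, "*")
    zc <- as.numeric(rel %*% axis_u)
    half_seg <- max(0, (rod$length_L - rod$diameter_d) / 2)
    dz <- pmax(0, abs(zc) - half_seg)
    r2 <- pmax(rowSums(rel^2) - zc^2, 0)
    depth <- rod$diameter_d / 2 - sqrt(r2 + dz^2)
    if (any(depth > 1.5))
      stop("rod overlaps a crosslink bead; choose another pose")
  }
  keep <- rep(TRUE, nrow(state$positions))
  solv_idx <- which(state$species == 1L)
  if (length(solv_idx) > 0) {
    dmin <- min_pair_distance_to_set(state$positions[solv_idx, , drop = FALSE],
                                     lab, box)
    keep[solv_idx[dmin < 0.5]] <- FALSE
  }
  pos <- state$positions[keep, , drop = FALSE]
  spec <- state$species[keep]
  vel <- state$velocities[keep, , drop = FALSE]
  old_id <- which(keep)
  remap <- integer(length(keep)); remap[old_id] <- seq_along(old_id)
  bonds <- matrix(remap[state$bonds], ncol = 2)

  # density bookkeeping: total beads (network + solvent + rod) -> rho * V
  n_target <- round(params$rho * prod(box))
  n_now <- nrow(pos) + nrow(lab)
  res <- with_seed(seed, {
    if (n_now > n_target) {
      solv <- which(spec == 1L)
      dmin <- min_pair_distance_to_set(pos[solv, , drop = FALSE], lab, box)
      drop <- solv[order(dmin, decreasing = TRUE)][seq_len(n_now - n_target)]
      keep2 <- setdiff(seq_len(nrow(pos)), drop)
      remap2 <- integer(nrow(pos)); remap2[keep2] <- seq_along(keep2)
      list(pos = pos[keep2, , drop = FALSE], spec = spec[keep2],
           vel = vel[keep2, , drop = FALSE],
           bonds = matrix(remap2[bonds], ncol = 2))
    } else if (n_now < n_target) {
      add <- n_target - n_now
      newp <- matrix(numeric(0), 0, 3)
      while (nrow(newp) < add) {
        cand <- matrix(runif(3 * 2 * add, 0, box[1]), ncol = 3)
        dmin <- min_pair_distance_to_set(cand, lab, box)
        cand <- cand[dmin > 1.0, , drop = FALSE]
        newp <- rbind(newp, cand)
      }
      newp <- newp[seq_len(add), , drop = FALSE]
      list(pos = rbind(pos, newp), spec = c(spec, rep(1L, add)),
           vel = rbind(vel, matrix(rnorm(3 * add, sd = sqrt(params$kT)),
                                   ncol = 3)),
           bonds = bonds)
    } else list(pos = pos, spec = spec, vel = vel, bonds = bonds)
  })
  pos <- rbind(res$pos, lab %% box[1])
  spec <- c(res$spec, rep(4L, nrow(lab)))
  rod_idx <- seq.int(nrow(res$pos) + 1L, length.out = nrow(lab))
  vel <- rbind(res$vel, matrix(0, nrow(lab), 3))
  storage.mode(res$bonds) <- "integer"
  if (relax_iter > 0) {
    # all non-rod beads may move: strands and crosslinks grazing the rod
    # surface are pushed out by the soft repulsion
    pos <- cpp_relax(pos, spec, spec != 4L, res$bonds, params$aij, box,
                     params$rc, as.integer(relax_iter), 0.05, 5e-4,
                     params$bond_k, params$bond_r0)
  }
  rod_state <- with_seed(if (is.null(seed)) NULL else seed + 1L, list(
    spec = rod, idx = as.integer(rod_idx), com = center %% box[1],
    com_un = center, quat = quat,
    vel = rnorm(3, sd = sqrt(params$kT / rod$mass)),
    angmom = rnorm(3, sd = sqrt(pmax(rod$inertia, 0) * params$kT)),
    mass = rod$mass, inertia = rod$inertia))
  new_dpd_state(pos, vel, spec, box, res$bonds, rod = rod_state,
                time = state$time)
}

# minimum image distance from each row of A to the nearest row of B
min_pair_distance_to_set <- function(A, B, box, chunk = 512L) {
  if (nrow(A) == 0) return(numeric(0))
  out <- numeric(nrow(A))
  for (start in seq(1L, nrow(A), by = chunk)) {
    idx <- start:min(start + chunk - 1L, nrow(A))
    d2 <- matrix(0, length(idx), nrow(B))
    for (a in 1:3) {
      dd <- outer(A[idx, a], B[, a], "-")
      dd <- dd - box[a] * round(dd / box[a])
      d2 <- d2 + dd^2
    }
    out[idx] <- sqrt(apply(d2, 1, min))
  }
  out
}

min_cross_distance <- function(A, B, box) min(min_pair_distance_to_set(A, B, box))
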