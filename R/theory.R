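#' Gaussian-chain network model for the rod free energy
#'
#' The rod-network partition function is evaluated over an ideal
#' simple-cubic lattice of crosslinks with spacing `a_x = b sqrt(N)` (the
#' theory's unit length), each lattice edge carried by a Gaussian chain of
#' `N` bonds of Kuhn length `b` pinned at its two crosslinks. The
#' rod-monomer interaction is a hard-core capped cylinder of length `L` and
#' diameter `d`: any chain configuration with a monomer inside the cylinder
#' is forbidden, so the free energy is purely entropic,
#' `F = -k_B T ln Z` with `Z` the fraction of chain configurations that
#' avoid the rod.
#'
#' The crosslink integration of the partition function is approximated by
#' independent Gaussian smearing of the strand endpoints with SD
#' `crosslink_smear` (default `a_x / 4 = b sqrt(N) / 4`); setting it to 0
#' quenches the crosslinks exactly on the lattice.
#'
#' @param N bonds per strand (discretisation of the chain path integral).
#' @param a_x mesh size; the theory's unit of length (default 1).
#' @param beta inverse thermal energy.
#' @param crosslink_smear endpoint smearing SD (same units as `a_x`).
#' @return an object of class `theory_model` (with `b = a_x / sqrt(N)`).
#' @export
theory_model <- function(N = 32, a_x = 1, beta = 1,
                         crosslink_smear = a_x / 4) {
  stopifnot(N >= 1, a_x > 0, beta > 0, crosslink_smear >= 0)
  structure(list(N = as.integer(N), a_x = a_x, b = a_x / sqrt(N),
                 beta = beta, crosslink_smear = crosslink_smear),
            class = "theory_model")
}

#' Rod geometry for the free-energy theory
#'
#' @param length_L,diameter_d rod dimensions in units of `a_x`.
#' @param z position of the rod centre along the lattice axis, measured from
#'   the cell centre (`z = 0` at the cell centre, `z = 0.5` at the cell
#'   edge), in units of `a_x`.
#' @return an object of class `rod_geometry` (axis along z through the cell
#'   centres; arbitrary orientations are out of scope).
#' @export
rod_geometry <- function(length_L, diameter_d, z = 0) {
  stopifnot(length_L > 0, diameter_d > 0)
  structure(list(length_L = length_L, diameter_d = diameter_d, z = z),
            class = "rod_geometry")
}

#' Confinement free energy of a single strand
#'
#' Monte Carlo estimate of `-ln(fraction of allowed bridges)` for one
#' strand: discretised Gaussian bridges (N steps of per-dimension variance
#' `b^2/3`, endpoint-pinned by the standard bridge construction) are
#' sampled and rejected whenever a vertex falls inside the rod's hard-core
#' cylinder. With endpoint smearing the (annealed) endpoints are tested
#' too; without it an endpoint inside the rod is an invalid geometry and
#' returns a flagged infinity, as does zero acceptance.
#'
#' @param model a [theory_model()].
#' @param ep1,ep2 strand endpoints (crosslink positions, units of `a_x`).
#' @param rod a [rod_geometry()]; the cylinder axis runs along z through
#'   `(x0, y0)`.
#' @param n_samples Monte Carlo sample count (>= 1000 recommended).
#' @param x0,y0 lateral position of the rod axis.
#' @param seed optional seed.
#' @return list with `dF` (k_B T), `se` (delta-method standard error),
#'   `acceptance`, and `flag` (`"ok"`, `"zero_acceptance"` or
#'   `"endpoint_inside"`).
#' @export
strand_free_energy <- function(model, ep1, ep2, rod, n_samples = 2000,
                               x0 = 0.5, y0 = 0.5, seed = NULL) {
  zc <- 0.5 + rod$z # lattice coordinate of the rod centre (cell centre 0.5)
  if (model$crosslink_smear == 0) {
    for (ep in list(ep1, ep2)) {
      inside <- (ep[1] - x0)^2 + (ep[2] - y0)^2 < (rod$diameter_d / 2)^2 &&
        abs(ep[3] - zc) < rod$length_L / 2
      if (inside)
        return(list(dF = Inf, se = NA_real_, acceptance = 0,
                    flag = "endpoint_inside"))
    }
  }
  acc <- with_seed(seed,
    cpp_bridge_mc(as.numeric(ep1), as.numeric(ep2), model$N, model$b,
                  as.integer(n_samples), rod$length_L, rod$diameter_d,
                  x0, y0, zc, model$crosslink_smear))[1]
  if (acc == 0)
    return(list(dF = Inf, se = NA_real_, acceptance = 0,
                flag = "zero_acceptance"))
  p <- acc / n_samples
  list(dF = -log(p), se = sqrt((1 - p) / (n_samples * p)),
       acceptance = p, flag = "ok")
}

# strands of a finite lattice patch around the rod, as an endpoint-pair list
lattice_patch_strands <- function(x_range, y_range, z_range) {
  nodes <- expand.grid(x = x_range, y = y_range, z = z_range)
  key <- function(x, y, z) paste(x, y, z)
  have <- key(nodes$x, nodes$y, nodes$z)
  out <- list()
  dirs <- rbind(c(1, 0, 0), c(0, 1, 0), c(0, 0, 1))
  for (i in seq_len(nrow(nodes))) {
    p <- as.numeric(nodes[i, ])
    for (d in 1:3) {
      q <- p + dirs[d, ]
      if (key(q[1], q[2], q[3]) %in% have)
        out[[length(out) + 1]] <- list(ep1 = p, ep2 = q)
    }
  }
  out
}

# distance from point p to the z-aligned segment x=(x0,y0), z in [z1,z2]
point_segment_distance <- function(p, x0, y0, z1, z2) {
  dz <- if (p[3] < z1) z1 - p[3] else if (p[3] > z2) p[3] - z2 else 0
  sqrt((p[1] - x0)^2 + (p[2] - y0)^2 + dz^2)
}

#' Free-energy profile of the rod along the lattice axis
#'
#' Evaluates `F(z) = sum over strands of -ln(acceptance)` on a grid of rod
#' centre positions and returns `dF(z) = F(z) - min F` together with the
#' barrier `U_b = max dF - min dF`. Strands whose endpoints both lie
#' farther than `L/2 + d/2 + shell * a_x` from the rod axis segment are
#' skipped (their acceptance is 1 to numerical accuracy at these chain
#' lengths). Every strand's bridge samples are shared across the whole z
#' grid (common random numbers), which suppresses sampling noise in the
#' profile differences that set `U_b`.
#'
#' @param model a [theory_model()].
#' @param rod a [rod_geometry()] template (its `z` is ignored).
#' @param z_grid rod centre positions relative to the cell centre (a_x);
#'   should span at least one period.
#' @param n_samples bridges per strand.
#' @param shell interaction-shell radius beyond `L/2 + d/2`, in a_x.
#' @param seed integer seed.
#' @return a `free_energy_profile`: list with `z`, `deltaF`, `Ub`, `Ub_se`
#'   (block standard error of the barrier, CRN-aware), `mc_error`
#'   (per-point block SE), `F_raw` and `n_strands`.
#' @export
free_energy_profile <- function(model, rod, z_grid, n_samples = 2000,
                                shell = 3, seed = NULL) {
  a <- model$a_x
  L <- rod$length_L; d <- rod$diameter_d
  zc <- 0.5 + z_grid # lattice coordinates of rod centres
  reach <- L / 2 + d / 2 + shell * a
  x0 <- 0.5; y0 <- 0.5
  zlo <- min(zc) - L / 2; zhi <- max(zc) + L / 2
  xr <- floor(0.5 - reach):ceiling(0.5 + reach)
  zr <- floor(zlo - reach):ceiling(zhi + reach)
  strands <- lattice_patch_strands(xr, xr, zr)
  keep <- vapply(strands, function(s) {
    min(point_segment_distance(s$ep1, x0, y0, zlo, zhi),
        point_segment_distance(s$ep2, x0, y0, zlo, zhi)) <= reach
  }, TRUE)
  strands <- strands[keep]
  nz <- length(zc)
  n_blocks <- 8L
  Fz <- numeric(nz); unreachable <- logical(nz)
  Fblk <- matrix(0, nz, n_blocks) # per-block profiles for CRN-aware errors
  with_seed(seed, {
    for (s in strands) {
      if (model$crosslink_smear == 0) {
        for (ep in list(s$ep1, s$ep2)) {
          ins <- (ep[1] - x0)^2 + (ep[2] - y0)^2 < (d / 2)^2
          if (ins) {
            hit <- abs(ep[3] - zc) < L / 2
            unreachable <- unreachable | hit
          }
        }
      }
      acc <- cpp_bridge_mc_blocks(as.numeric(s$ep1), as.numeric(s$ep2),
                                  model$N, model$b, as.integer(n_samples),
                                  L, d, x0, y0, zc, model$crosslink_smear,
                                  n_blocks)
      tot <- rowSums(acc)
      p <- tot / n_samples
      zerop <- p == 0
      unreachable <- unreachable | zerop
      p[zerop] <- NA
      Fz <- Fz - log(p)
      # regularised block acceptances (error estimate only)
      per_blk <- n_samples / n_blocks
      Fblk <- Fblk - log((acc + 0.5) / (per_blk + 0.5))
    }
  })
  Fz[unreachable] <- Inf
  finite <- is.finite(Fz)
  if (!any(finite)) stop("no reachable rod position on the grid")
  dF <- Fz - min(Fz[finite])
  Ub <- max(dF[finite]) - min(dF[finite])
  # standard errors from the block spread: per-point, and for U_b itself
  # (the latter benefits from the common random numbers across the grid)
  mc_error <- apply(Fblk, 1, stats::sd) / sqrt(n_blocks)
  mc_error[unreachable] <- NA_real_
  ub_blocks <- apply(Fblk[finite, , drop = FALSE], 2,
                     function(f) max(f) - min(f))
  structure(list(z = z_grid, deltaF = dF, Ub = Ub,
                 Ub_se = stats::sd(ub_blocks) / sqrt(n_blocks),
                 mc_error = mc_error, F_raw = Fz,
                 n_strands = length(strands),
                 unreachable = unreachable),
            class = "free_energy_profile")
}

#' @export
print.free_energy_profile <- function(x, ...) {
  cat("Free-energy profile over", length(x$z), "positions;",
      x$n_strands, "strands in shell\n")
  cat("  U_b =", signif(x$Ub, 4), "k_BT  (max SE",
      signif(max(x$mc_error[is.finite(x$mc_error)]), 2), ")\n")
  invisible(x)
}

#' Barrier landscape over rod dimensions and the k_BT boundary
#'
#' Computes `U_b(d/a_x, L/a_x)` on a grid, labels each point `sliding`
#' (`U_b <= k_B T`) or `hopping` (`U_b > k_B T`), and extracts the
#' `U_b = k_B T` contour by linear interpolation. Grid points whose Monte
#' Carlo error exceeds `se_max` are flagged non-converged and excluded from
#' the contour.
#'
#' @param model a [theory_model()].
#' @param d_grid,L_grid rod diameters and lengths in units of a_x.
#' @param z_grid profile grid (defaults to one period in 13 points).
#' @param n_samples bridges per strand.
#' @param shell interaction-shell radius (a_x).
#' @param seed integer seed (one independent substream per grid point).
#' @param se_max convergence threshold on the barrier block SE (k_B T).
#' @return a `phase_diagram`: list with `d_grid`, `L_grid`, `Ub_map`,
#'   `labels`, `se_map`, `converged` and `boundary` (list of contour
#'   polylines with components `d` and `L`).
#' @export
phase_diagram <- function(model, d_grid, L_grid,
                          z_grid = seq(-0.5, 0.5, length.out = 13),
                          n_samples = 1500, shell = 2, seed = 1,
                          se_max = 0.2) {
  Ub <- matrix(NA_real_, length(d_grid), length(L_grid))
  se <- matrix(NA_real_, length(d_grid), length(L_grid))
  for (i in seq_along(d_grid)) for (j in seq_along(L_grid)) {
    prof <- free_energy_profile(model,
                                rod_geometry(L_grid[j], d_grid[i]),
                                z_grid, n_samples = n_samples, shell = shell,
                                seed = seed + 7919L * (i - 1L) + 104729L * (j - 1L))
    Ub[i, j] <- prof$Ub
    se[i, j] <- prof$Ub_se
  }
  conv <- is.finite(Ub) & se <= se_max
  labels <- matrix(ifelse(Ub > 1 / model$beta, "hopping", "sliding"),
                   nrow(Ub), ncol(Ub))
  Ub_c <- Ub
  Ub_c[!conv] <- NA
  boundary <- if (any(conv)) {
    tryCatch(
      suppressWarnings(contourLines(d_grid, L_grid, Ub_c,
                                    levels = 1 / model$beta)),
      error = function(e) list())
  } else list()
  boundary <- lapply(boundary, function(b) list(d = b$x, L = b$y))
  structure(list(d_grid = d_grid, L_grid = L_grid, Ub_map = Ub,
                 labels = labels, se_map = se, converged = conv,
                 boundary = boundary),
            class = "phase_diagram")
}

#' @export
print.phase_diagram <- function(x, ...) {
  cat("Barrier landscape:", length(x$d_grid), "x", length(x$L_grid),
      "grid, U_b in [", signif(min(x$Ub_map), 3), ",",
      signif(max(x$Ub_map), 3), "] k_BT\n")
  cat("  boundary segments at U_b = k_BT:", length(x$boundary), "\n")
  invisible(x)
}

#' Predicted regime from the barrier height
#'
#' Kramers picture: a barrier above the thermal energy makes cell-to-cell
#' transitions rare events (hopping); at or below it the rod slides.
#'
#' @param Ub barrier height (k_B T); must be non-negative.
#' @param kT thermal energy.
#' @return `"hopping"` if `Ub > kT`, else `"sliding"`.
#' @export
classify_by_barrier <- function(Ub, kT = 1) {
  if (any(Ub < 0)) stop("negative barrier")
  ifelse(Ub > kT, "hopping", "sliding")
}

#' Arrhenius estimate of the hopping time
#'
#' `tau_hop = tau_0 exp(beta U_b)`: the free waiting time amplified by the
#' Kramers barrier factor. A modelling convenience for choosing production
#' lengths and CTRW parameters; the prefactor is not derived.
#'
#' @param tau_0 free waiting time.
#' @param Ub barrier (k_B T).
#' @param beta inverse thermal energy.
#' @return estimated hopping time.
#' @export
hopping_time <- function(tau_0, Ub, beta = 1) tau_0 * exp(beta * Ub)
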