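#' Parameters of the continuous-time random-walk description
#'
#' Collects the scales entering the analytic displacement distributions of
#' the three dynamical regimes: the characteristic hopping time `tau_hop`
#' (cell-to-cell barrier crossings), the free waiting time `tau_0` (Brownian
#' dynamics in neat solvent), the periodic-potential amplitude `U0` that sets
#' the stationary in-cell Boltzmann comb, and the mesh size `a_x`. The
#' longitudinal friction of a rod is `gamma_rod = 2 pi eta L / ln(L/d)` and
#' the diffusivity `kappa` obeys `gamma_rod * kappa = k_B T`; either can be
#' supplied, the other is filled in. Only the Markovian case `alpha = 1` of
#' the generalized Fokker-Planck operator is implemented; other exponents
#' are rejected.
#'
#' @param tau_hop characteristic hopping time.
#' @param tau_0 characteristic waiting time in solvent.
#' @param U0 periodic free-energy amplitude (k_B T).
#' @param beta inverse thermal energy (1 by convention).
#' @param a_x mesh size (length unit of `z`).
#' @param alpha anomalous exponent; must be 1.
#' @param eta,L,d solvent viscosity and rod dimensions, used to derive
#'   `gamma_rod` when it is not given directly.
#' @param gamma_rod longitudinal friction coefficient.
#' @param kappa diffusivity, `k_B T / gamma_rod`.
#' @return an object of class `ctrw_params`.
#' @export
ctrw_params <- function(tau_hop = 150, tau_0 = 50, U0 = 1, beta = 1,
                        a_x = 1, alpha = 1, eta = NULL, L = NULL, d = NULL,
                        gamma_rod = NULL, kappa = NULL) {
  if (alpha != 1) stop("only the Markovian case alpha = 1 is implemented")
  stopifnot(tau_hop > 0, tau_0 > 0, beta > 0, a_x > 0)
  kT <- 1 / beta
  if (is.null(gamma_rod) && !is.null(eta) && !is.null(L) && !is.null(d)) {
    if (L <= d) stop("longitudinal friction needs L > d")
    gamma_rod <- 2 * pi * eta * L / log(L / d)
  }
  if (is.null(kappa) && !is.null(gamma_rod)) kappa <- kT / gamma_rod
  if (is.null(gamma_rod) && !is.null(kappa)) gamma_rod <- kT / kappa
  if (!is.null(gamma_rod) && !is.null(kappa) &&
      abs(gamma_rod * kappa - kT) > 1e-8 * kT)
    stop("gamma_rod * kappa must equal k_B T")
  structure(list(tau_hop = tau_hop, tau_0 = tau_0, U0 = U0, beta = beta,
                 a_x = a_x, alpha = alpha, gamma_rod = gamma_rod,
                 kappa = kappa, kT = kT),
            class = "ctrw_params")
}

#' Normalization constant of the stationary Boltzmann comb
#'
#' The in-cell stationary weights are `P(n) = exp(-4 betaU0 n^2)` on sites
#' `n = 0, 1, 2, ...`; `C` normalises `sum_n C P(n) = 1`. The series is
#' summed until the relative tail drops below 1e-12.
#'
#' @param betaU0 barrier amplitude in units of k_B T; must be positive
#'   (the comb diverges otherwise).
#' @return the constant `C`.
#' @export
#' @examples
#' comb_normalization(1) # 1 / (1 + e^-4 + e^-16 + ...) ~ 0.98201
comb_normalization <- function(betaU0) {
  if (betaU0 <= 0) stop("betaU0 must be positive (divergent comb)")
  total <- 0
  n <- 0
  repeat {
    term <- exp(-4 * betaU0 * n^2)
    total <- total + term
    if (term < 1e-12 * total) break
    n <- n + 1
  }
  1 / total
}

#' Hopping-regime displacement distribution (discrete comb)
#'
#' Large-time form for barriers above k_B T: a Gaussian envelope of variance
#' `2 a_x^2 t / tau_hop` carried by a delta comb on the lattice sites
#' `z = +- n a_x`, each site weighted by the Boltzmann factor `C P(n)` with
#' `P(n) = exp(-4 betaU0 n^2)`. The envelope-times-comb weights are
#' renormalised to unit total weight (the raw product is asymptotic, not
#' exactly normalised); the weight `C P(n)` of each `n >= 1` is split evenly
#' between the two signs.
#'
#' @param params a [ctrw_params()].
#' @param t lag time (> 0).
#' @param n_max largest site index (default: wide enough to exhaust the
#'   envelope and the comb).
#' @return a `dpdf_curve` data frame with site positions `z` and `weight`.
#' @export
dpdf_hopping <- function(params, t, n_max = NULL) {
  stopifnot(t > 0)
  a <- params$a_x
  sd_env <- a * sqrt(2 * t / params$tau_hop)
  C <- comb_normalization(params$beta * params$U0)
  if (is.null(n_max)) n_max <- max(3, ceiling(6 * sd_env / a) + 3)
  n <- 0:n_max
  envelope <- sqrt(params$tau_hop / (4 * pi * a^2 * t)) *
    exp(-params$tau_hop * (n * a)^2 / (4 * t * a^2))
  u <- envelope * C * exp(-4 * params$beta * params$U0 * n^2)
  z <- c(-rev(n[-1]), n) * a
  w <- c(rev(u[-1] / 2), u[1], u[-1] / 2)
  w <- w / sum(w)
  structure(data.frame(z = z, weight = w),
            class = c("dpdf_curve", "data.frame"),
            regime = "hopping", t = t, type = "comb")
}

#' Sliding-regime displacement distribution
#'
#' Low-barrier (0 < U_b < k_B T) form: the exponential-tailed density
#' `G_s(z, t) = 4 exp(-2|z|/a_x) exp(-2t/tau_hop) *
#'   integral_0^inf dx exp(-4x/a_x) I0(sqrt(8t(|z|+x)/(a_x tau_hop)))
#'   I0(sqrt(8tx/(a_x tau_hop)))`
#' with `I0` the modified Bessel function of the first kind, evaluated by
#' adaptive quadrature with overflow-safe exponential scaling of `I0`. At
#' `t = 0` it reduces to the Laplace density `exp(-2|z|/a_x)` (in units
#' where a_x = 1).
#'
#' @param params a [ctrw_params()].
#' @param t lag time (>= 0).
#' @param z_grid displacements at which to evaluate.
#' @return a `dpdf_curve` data frame with `z` and `density`.
#' @export
dpdf_sliding <- function(params, t, z_grid) {
  stopifnot(t >= 0)
  a <- params$a_x
  tau <- params$tau_hop
  dens <- vapply(z_grid, function(z) {
    az <- abs(z)
    integrand <- function(x) {
      y1 <- sqrt(8 * t * (az + x) / (a * tau))
      y2 <- sqrt(8 * t * x / (a * tau))
      expo <- -2 * az / a - 2 * t / tau - 4 * x / a + y1 + y2
      4 * exp(expo) * besselI(y1, 0, expon.scaled = TRUE) *
        besselI(y2, 0, expon.scaled = TRUE)
    }
    val <- tryCatch(
      stats::integrate(integrand, 0, Inf, rel.tol = 1e-10,
                       abs.tol = 1e-14)$value,
      error = function(e) stop("quadrature failed at z = ", z, ": ",
                               conditionMessage(e)))
    val
  }, 1)
  structure(data.frame(z = z_grid, density = dens),
            class = c("dpdf_curve", "data.frame"),
            regime = "sliding", t = t, type = "density")
}

#' Brownian displacement distribution
#'
#' Barrier-free Gaussian propagator
#' `G_s(z, t) = sqrt(tau_0 / (4 pi a_x^2 t)) exp(-tau_0 z^2 / (4 t a_x^2))`,
#' i.e. variance `2 a_x^2 t / tau_0`.
#'
#' @inheritParams dpdf_sliding
#' @return a `dpdf_curve` data frame with `z` and `density`.
#' @export
dpdf_brownian <- function(params, t, z_grid) {
  stopifnot(t > 0)
  a <- params$a_x
  dens <- sqrt(params$tau_0 / (4 * pi * a^2 * t)) *
    exp(-params$tau_0 * z_grid^2 / (4 * t * a^2))
  structure(data.frame(z = z_grid, density = dens),
            class = c("dpdf_curve", "data.frame"),
            regime = "brownian", t = t, type = "density")
}

#' Montroll-Weiss propagator in Fourier-Laplace space
#'
#' `S(k, s) = (1 - psi(s)) / (s [1 - phi(k) psi(s)])` for a waiting-time
#' density with Laplace transform `psi` and a jump-length distribution with
#' Fourier transform `phi`.
#'
#' @param psi_laplace function of `s`: Laplace transform of the waiting-time
#'   density (completely monotone, `psi(0) = 1`).
#' @param phi_fourier function of `k`: characteristic function of the jump
#'   length (`|phi| <= 1`).
#' @param k,s evaluation points (vectorised; a matrix over `k` x `s` is
#'   returned when both have length > 1).
#' @return `S(k, s)` values.
#' @export
montroll_weiss <- function(psi_laplace, phi_fourier, k, s) {
  ps <- psi_laplace(s)
  bad <- is.finite(Re(ps)) & Re(s) > 0 & Re(ps) >= 1
  if (any(bad)) stop("psi(s) >= 1 at positive s: invalid waiting density")
  pk <- phi_fourier(k)
  if (any(Mod(pk) > 1 + 1e-9)) stop("|phi(k)| > 1: invalid jump distribution")
  out <- matrix(0, length(k), length(s))
  for (j in seq_along(s)) out[, j] <- (1 - ps[j]) / (s[j] * (1 - pk * ps[j]))
  drop(out)
}

# fixed-Talbot numerical Laplace inversion (Abate-Valko), for the smooth
# transforms arising from Montroll-Weiss propagators
talbot_invert <- function(Fs, t, M = 48) {
  stopifnot(t > 0)
  r <- 2 * M / (5 * t)
  theta <- seq_len(M - 1) * pi / M
  cot_ <- cos(theta) / sin(theta)
  s <- r * theta * complex(real = cot_, imaginary = 1)
  sigma <- theta + (theta * cot_ - 1) * cot_
  total <- 0.5 * exp(r * t) * Fs(r) +
    sum(Re(exp(t * s) * Fs(s) * complex(real = 1, imaginary = sigma)))
  Re(total) * r / M
}

#' Invert the Montroll-Weiss propagator to real space and time
#'
#' Numerical Fourier-Laplace inversion of `S(k, s)`: fixed-Talbot Laplace
#' inversion at each wavenumber, then an inverse Fourier integral. Two
#' geometries are supported: `lattice = NULL` inverts over continuous `z`
#' (for continuous jump distributions), while a numeric `lattice` spacing
#' restricts the inversion to the first Brillouin zone and returns the
#' probability mass on each lattice site (for delta-comb jumps).
#'
#' @inheritParams montroll_weiss
#' @param t time at which to evaluate.
#' @param z_grid displacements (continuous case).
#' @param lattice lattice spacing (comb case) or NULL.
#' @param n_sites number of sites on each side of 0 in the comb case.
#' @param n_k wavenumber quadrature points.
#' @return data frame with `z` and `density` (continuous) or `weight`
#'   (lattice mass).
#' @export
mw_invert <- function(psi_laplace, phi_fourier, t, z_grid = NULL,
                      lattice = NULL, n_sites = 30, n_k = 256) {
  ft <- function(k) {
    vapply(k, function(k_) {
      talbot_invert(function(s) montroll_weiss(psi_laplace, phi_fourier,
                                               k_, s), t)
    }, 1)
  }
  if (is.null(lattice)) {
    stopifnot(!is.null(z_grid))
    kmax <- 30 / (diff(range(z_grid)) / length(z_grid) * 4 + 1e-9)
    kmax <- min(kmax, 60)
    kk <- seq(0, kmax, length.out = n_k)
    fk <- ft(kk)
    dens <- vapply(z_grid, function(z)
      sum(cos(kk * z) * fk) * (kk[2] - kk[1]) / pi, 1)
    data.frame(z = z_grid, density = dens)
  } else {
    a <- lattice
    kk <- seq(0, pi / a, length.out = n_k)
    wgt <- c(0.5, rep(1, n_k - 2), 0.5) # trapezoid
    fk <- ft(kk)
    n <- -n_sites:n_sites
    mass <- vapply(n, function(n_)
      (a / pi) * sum(wgt * cos(kk * n_ * a) * fk) * (kk[2] - kk[1]), 1)
    data.frame(z = n * a, weight = mass)
  }
}

#' Drift-diffusion (Smoluchowski) solver on a periodic free-energy profile
#'
#' Conservative finite-volume integration of
#' `dG/dt = d/dz [ (dF'(z)/gamma) G + kappa dG/dz ]`
#' on a periodic grid, with Scharfetter-Gummel exponential fluxes so the
#' discrete stationary state is exactly the Boltzmann density
#' `exp(-beta dF)`. Probability is conserved to round-off at every step;
#' the explicit sub-step obeys an internal CFL bound.
#'
#' @param deltaF free-energy profile: a function of z or a vector over
#'   `z_grid` (k_B T).
#' @param params a [ctrw_params()] providing `kappa` and `beta`.
#' @param t_grid output times (increasing, starting after 0).
#' @param z_grid uniform cell-centre grid; must resolve one period by at
#'   least 64 points when a nontrivial profile is given.
#' @param ic initial condition: `"delta"` (mass at the grid point nearest 0)
#'   or a density vector over `z_grid`.
#' @return list with `z`, `t`, and `dens` (matrix, one column per time).
#' @export
solve_fokker_planck <- function(deltaF, params, t_grid, z_grid,
                                ic = "delta") {
  stopifnot(!is.null(params$kappa))
  h <- diff(z_grid[1:2])
  if (any(abs(diff(z_grid) - h) > 1e-9 * h)) stop("z_grid must be uniform")
  nz <- length(z_grid)
  F_ <- if (is.function(deltaF)) deltaF(z_grid) else rep_len(deltaF, nz)
  if (any(F_ != 0) && nz < 64)
    stop("z_grid must resolve the profile by at least 64 points")
  kap <- params$kappa
  beta <- params$beta
  p <- if (identical(ic, "delta")) {
    v <- numeric(nz); v[which.min(abs(z_grid))] <- 1 / h; v
  } else rep_len(ic, nz)
  # Scharfetter-Gummel edge factors (periodic): edge i is between i and i+1
  ip <- c(2:nz, 1)
  w <- beta * (F_[ip] - F_)            # Peclet number per edge
  B <- function(x) ifelse(abs(x) < 1e-12, 1 - x / 2, x / expm1(x))
  Bp <- B(w); Bm <- B(-w)
  dt_cfl <- 0.25 * h^2 / (kap * max(Bp + Bm))
  out <- matrix(0, nz, length(t_grid))
  t_now <- 0
  for (j in seq_along(t_grid)) {
    t_target <- t_grid[j]
    while (t_now < t_target - 1e-15) {
      dt <- min(dt_cfl, t_target - t_now)
      flux <- (kap / h) * (Bp * p - Bm * p[ip]) # flux through edge i -> i+1
      p <- p - (dt / h) * (flux - flux[c(nz, 1:(nz - 1))])
      t_now <- t_now + dt
    }
    out[, j] <- p
  }
  list(z = z_grid, t = t_grid, dens = out)
}

ou_path <- function(n, sd_stat, tau) {
  rho <- exp(-1 / tau)
  innov <- rnorm(n, sd = sd_stat * sqrt(1 - rho^2))
  innov[1] <- rnorm(1, sd = sd_stat)
  as.numeric(stats::filter(innov, rho, method = "recursive"))
}

#' Seeded CTRW trajectory sampler
#'
#' Generates synthetic axial displacement series in each dynamical regime,
#' used as ground-truth fixtures for the analysis and classifier. Each
#' regime reproduces the trajectory phenomenology that defines it:
#' \itemize{
#' \item `brownian`: i.i.d. Gaussian increments with the variance rate
#'   `2 a_x^2 / tau_0` of the barrier-free propagator;
#' \item `hopping`: rare cell-to-cell jumps -- exponential waiting times
#'   (mean `tau_hop`, many frames) with `+-a_x` lattice jumps -- riding on
#'   Ornstein-Uhlenbeck in-cell confinement (`cell_sd`, `cell_tau`), which
#'   produces the intermediate MSD plateau and the a_x-spaced comb in
#'   G_s(z, t);
#' \item `trapped`: the in-cell Ornstein-Uhlenbeck confinement alone
#'   (stationary SD `trap_sd`, well below a_x): the MSD saturates;
#' \item `sliding_fast`: the low-barrier master-equation dynamics -- a
#'   Poisson jump kernel at rate `2 / tau_slide` with two-sided exponential
#'   jump lengths of scale `a_x / 2` (the tails of the sliding-regime
#'   propagator), plus small jitter. The MSD is Fickian with no plateau,
#'   but the displacements are strongly non-Gaussian ("anomalous yet
#'   Brownian"). A smooth sub-k_BT drift-diffusion path would wash the
#'   non-Gaussianity out once in-cell positions are averaged over; the
#'   jump-kernel form is the trajectory-level counterpart of the analytic
#'   sliding distribution.
#' }
#'
#' @param regime one of `"brownian"`, `"hopping"`, `"trapped"`,
#'   `"sliding_fast"`.
#' @param params a [ctrw_params()] (`tau_0` sets the Brownian rate; the
#'   hopping wait is `tau_hop_frames` below, in frames, since the fixtures
#'   are defined per frame).
#' @param n_steps frames per trajectory.
#' @param n_traj number of trajectories.
#' @param seed integer seed; fixed seeds give bit-identical output.
#' @param frame_dt frame interval (time units).
#' @param tau_hop_frames mean frames between cell-to-cell hops.
#' @param cell_sd,cell_tau in-cell confinement SD (units of a_x) and
#'   relaxation (frames) for the hopping regime.
#' @param trap_sd,trap_tau confinement of the trapped regime.
#' @param tau_slide mean frames between sliding-kernel jumps.
#' @param jitter_sd measurement-scale jitter SD (units of a_x).
#' @return list of `axial_series`.
#' @export
sample_ctrw <- function(regime, params = ctrw_params(), n_steps = 32768,
                        n_traj = 1, seed = NULL, frame_dt = 1,
                        tau_hop_frames = 2500, cell_sd = 0.2, cell_tau = 4,
                        trap_sd = 0.10, trap_tau = 20,
                        tau_slide = 100, jitter_sd = 0.05) {
  regime <- match.arg(regime, c("brownian", "hopping", "trapped",
                                "sliding_fast"))
  a <- params$a_x
  tt <- seq(0, by = frame_dt, length.out = n_steps)
  with_seed(seed, lapply(seq_len(n_traj), function(i) {
    z <- switch(regime,
      brownian = cumsum(c(0, rnorm(n_steps - 1,
                                   sd = a * sqrt(2 * frame_dt / params$tau_0)))),
      hopping = {
        waits <- rexp(ceiling(4 * n_steps / tau_hop_frames) + 20,
                      rate = 1 / tau_hop_frames)
        jump_t <- cumsum(waits)
        jump_t <- jump_t[jump_t < n_steps]
        jumps <- sample(c(-a, a), length(jump_t), replace = TRUE)
        base <- c(0, cumsum(jumps))[findInterval(seq_len(n_steps) - 1,
                                                 jump_t) + 1]
        base + a * ou_path(n_steps, cell_sd, cell_tau)
      },
      trapped = a * ou_path(n_steps, trap_sd, trap_tau),
      sliding_fast = {
        nj <- stats::rpois(n_steps, 1 / tau_slide)
        tot <- sum(nj)
        per_frame <- numeric(n_steps)
        if (tot > 0) {
          jumps <- sample(c(-1, 1), tot, TRUE) * rexp(tot, rate = 2 / a)
          s <- rowsum(jumps, rep.int(seq_len(n_steps), nj))
          per_frame[as.integer(rownames(s))] <- s
        }
        cumsum(per_frame) + rnorm(n_steps, sd = jitter_sd * a)
      })
    out <- data.frame(time = tt, z = z - z[1])
    attr(out, "a_x") <- a
    attr(out, "regime") <- regime
    class(out) <- c("axial_series", "data.frame")
    out
  }))
}

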