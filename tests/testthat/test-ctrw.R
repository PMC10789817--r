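# analytic displacement distributions, Montroll-Weiss and the FP solver

test_that("Boltzmann comb normalization matches direct summation", {
  expect_equal(comb_normalization(1),
               1 / sum(exp(-4 * (0:10)^2)), tolerance = 1e-12)
  expect_equal(comb_normalization(50), 1, tolerance = 1e-12)
  for (b in c(0.3, 1, 5)) {
    C <- comb_normalization(b)
    expect_equal(sum(C * exp(-4 * b * (0:60)^2)), 1, tolerance = 1e-12)
  }
  expect_error(comb_normalization(0), "positive")
  expect_error(comb_normalization(-1), "positive")
})

test_that("hopping comb lives on lattice sites with the printed weights", {
  p <- ctrw_params(tau_hop = 2, U0 = 1, a_x = 1)
  g <- dpdf_hopping(p, t = 4)
  expect_true(all(abs(g$z - round(g$z)) < 1e-12)) # delta comb on n a_x
  expect_equal(sum(g$weight), 1, tolerance = 1e-12)
  # site-weight ratio before renormalisation: envelope x C P(n)
  w1 <- g$weight[g$z == 1]
  w0 <- g$weight[g$z == 0]
  ratio_expected <- 0.5 * exp(-p$tau_hop * 1 / (4 * 4)) * exp(-4 * 1)
  expect_equal(w1 / w0, ratio_expected, tolerance = 1e-10)
  # t -> 0+: all weight collapses onto the origin
  g0 <- dpdf_hopping(p, t = 1e-6)
  expect_equal(g0$weight[g0$z == 0], 1, tolerance = 1e-9)
})

test_that("sliding distribution: Laplace limit, symmetry, unit integral", {
  p <- ctrw_params(tau_hop = 2, a_x = 1)
  z <- seq(-4, 4, by = 0.25)
  g0 <- dpdf_sliding(p, 0, z)
  expect_equal(g0$density, exp(-2 * abs(z)), tolerance = 1e-6)
  g <- dpdf_sliding(p, 3, z)
  expect_equal(g$density, rev(g$density), tolerance = 1e-10)
  for (t in c(0, 1, 5)) {
    I <- 2 * integrate(function(zz) dpdf_sliding(p, t, zz)$density,
                       0, Inf, rel.tol = 1e-10)$value
    expect_equal(I, 1, tolerance = 1e-8)
  }
  # alpha_1 of the t = 0 (Laplace) density is exactly 1
  m2 <- 2 * integrate(function(zz) zz^2 * exp(-2 * zz), 0, Inf,
                      rel.tol = 1e-12)$value
  m4 <- 2 * integrate(function(zz) zz^4 * exp(-2 * zz), 0, Inf,
                      rel.tol = 1e-12)$value
  expect_equal(m4 / (3 * m2^2) - 1, 1, tolerance = 1e-10)
})

test_that("Brownian distribution has the printed peak, norm and variance", {
  p <- ctrw_params(tau_0 = 4, a_x = 1)
  z <- seq(-50, 50, by = 0.01)
  for (t in c(0.5, 3)) {
    g <- dpdf_brownian(p, t, z)
    expect_equal(max(g$density), sqrt(4 / (4 * pi * t)), tolerance = 1e-12)
    I <- 2 * integrate(function(zz) dpdf_brownian(p, t, zz)$density, 0, Inf,
                       rel.tol = 1e-12)$value
    expect_equal(I, 1, tolerance = 1e-10)
    v <- 2 * integrate(function(zz) zz^2 * dpdf_brownian(p, t, zz)$density,
                       0, Inf, rel.tol = 1e-12)$value
    expect_equal(v, 2 * t / 4, tolerance = 1e-10)
  }
})

test_that("Montroll-Weiss propagator: conservation, diffusion limit, guards", {
  psi <- function(s) 1 / (1 + 2 * s)       # exponential waits, mean 2
  phi <- function(k) exp(-0.5 * 0.3^2 * k^2) # Gaussian jumps, sd 0.3
  expect_equal(montroll_weiss(psi, phi, 0, 0.7), 1 / 0.7, tolerance = 1e-12)
  # small (k, s): S -> 1 / (s + D k^2) with D = sigma^2 / (2 tau)
  D <- 0.3^2 / (2 * 2)
  for (k in c(0.01, 0.03)) for (s in c(1e-3, 1e-2)) {
    expect_equal(montroll_weiss(psi, phi, k, s), 1 / (s + D * k^2),
                 tolerance = 1e-3)
  }
  expect_error(montroll_weiss(function(s) 1 + s, phi, 0.1, 0.5), "psi")
  expect_error(montroll_weiss(psi, function(k) 2, 0.1, 0.5), "phi")
})

test_that("numerical MW inversion agrees with the hopping envelope", {
  tau <- 2; a <- 1
  # jumps of +-a at rate 2/tau reproduce the envelope diffusivity a^2/tau
  psi <- function(s) 1 / (1 + s * tau / 2)
  phi <- function(k) cos(k * a)
  t <- 20 * tau
  mw <- mw_invert(psi, phi, t = t, lattice = a, n_sites = 45)
  # a near-flat comb (betaU0 -> 0) isolates the Gaussian envelope
  hop <- dpdf_hopping(ctrw_params(tau_hop = tau, U0 = 1e-6, a_x = a), t = t,
                      n_max = 45)
  # the comb convention halves the +-n site weights relative to n = 0, so
  # compare shapes on the n >= 1 sites, renormalised over the window
  wt <- setNames(hop$weight, hop$z)
  sites <- 1:12 # within ~2 envelope SDs
  w_mw <- mw$weight[match(sites, mw$z)]
  w_hop <- wt[as.character(sites)]
  w_mw <- w_mw / sum(w_mw)
  w_hop <- w_hop / sum(w_hop)
  expect_lt(max(abs(w_mw - w_hop) / w_hop), 0.05)
})

test_that("Talbot Laplace inversion is accurate for smooth transforms", {
  expect_equal(rodnet:::talbot_invert(function(s) 1 / (s + 1), 2), exp(-2),
               tolerance = 1e-6)
  expect_equal(rodnet:::talbot_invert(function(s) 1 / s^2, 3), 3,
               tolerance = 1e-6)
})

test_that("Fokker-Planck solver reproduces the barrier-free Gaussian", {
  p <- ctrw_params(tau_0 = 20, kappa = 0.05, a_x = 1)
  z <- seq(-2, 2, by = 1 / 128)
  sol <- solve_fokker_planck(0, p, t_grid = c(0.3, 0.9), z_grid = z)
  h <- 1 / 128
  for (j in 1:2) {
    ref <- dpdf_brownian(p, sol$t[j], z)$density
    expect_lt(sum(abs(sol$dens[, j] - ref)) * h, 1e-4)
    expect_equal(sum(sol$dens[, j]) * h, 1, tolerance = 1e-10)
  }
})

test_that("Fokker-Planck stationary state is the Boltzmann density", {
  p <- ctrw_params(kappa = 0.05, a_x = 1)
  h <- 1 / 128
  z <- seq(-0.5, 0.5 - h, by = h)
  dF <- 0.8 * (1 + cos(2 * pi * z)) / 2
  sol <- solve_fokker_planck(dF, p, t_grid = 50, z_grid = z)
  boltz <- exp(-dF) / (sum(exp(-dF)) * h)
  expect_lt(sum(abs(sol$dens[, 1] - boltz)) * h, 1e-3)
  expect_equal(sum(sol$dens[, 1]) * h, 1, tolerance = 1e-10)
})

test_that("CTRW sampler is reproducible and regime parameters are honoured", {
  pars <- ctrw_params()
  s1 <- sample_ctrw("brownian", pars, n_steps = 2048, n_traj = 2, seed = 42)
  s2 <- sample_ctrw("brownian", pars, n_steps = 2048, n_traj = 2, seed = 42)
  expect_identical(s1, s2)
  s3 <- sample_ctrw("brownian", pars, n_steps = 2048, n_traj = 2, seed = 43)
  expect_false(identical(s1, s3))
  expect_error(sample_ctrw("ballistic", pars), "arg")
  expect_error(ctrw_params(alpha = 0.7), "alpha")
})

test_that("sampled hopping comb peaks are spaced by one mesh size", {
  pars <- ctrw_params()
  ss <- sample_ctrw("hopping", pars, n_traj = 4, seed = 91)
  g <- dpdf(ss, lags = 2500, bin_width = 0.1)
  pk <- find_peaks(g$z, g$gs[, 1])
  expect_gte(nrow(pk), 2)
  expect_equal(mean(diff(sort(pk$x))), 1, tolerance = 0.15)
})

test_that("sampled Brownian series are Fickian and Gaussian", {
  pars <- ctrw_params()
  ss <- sample_ctrw("brownian", pars, n_traj = 4, seed = 92)
  m <- axial_msd(ss)
  sel <- m$lags >= 10 & m$lags <= 1000
  fit <- lm(log(m$msd[sel]) ~ log(m$lags[sel]))
  expect_equal(unname(coef(fit)[2]), 1, tolerance = 0.05)
  a1 <- non_gaussian_alpha1(ss, lags = c(1, 10, 100))
  n_eff <- 4 * 32768 / c(1, 10, 100)
  expect_true(all(abs(a1$alpha1) < 4 * sqrt(24 / n_eff)))
})

test_that("alpha_1 orders the regimes: hopping > sliding > brownian", {
  pars <- ctrw_params()
  # pooled (ensemble) moments per replicate group; mid-lag window where the
  # rare-jump kurtosis of hopping dominates
  mean_a1 <- function(reg, groups = 12) {
    vals <- vapply(seq_len(groups), function(g) {
      ss <- sample_ctrw(reg, pars, n_traj = 5, seed = 93 + g)
      a <- non_gaussian_alpha1(ss)
      mean(a$alpha1[a$lags >= 300 & a$lags <= 1000], na.rm = TRUE)
    }, 1)
    c(mean = mean(vals), se = sd(vals) / sqrt(groups))
  }
  hop <- mean_a1("hopping"); sli <- mean_a1("sliding_fast")
  bro <- mean_a1("brownian")
  expect_gt(hop["mean"] - sli["mean"],
            4 * sqrt(hop["se"]^2 + sli["se"]^2))
  expect_gt(sli["mean"] - bro["mean"],
            4 * sqrt(sli["se"]^2 + bro["se"]^2))
  expect_lt(abs(bro["mean"]), 0.1)
})
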