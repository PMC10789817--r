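# trajectory observables: axial projection, MSD, G_s, alpha_1, hop detection

make_traj <- function(com, axis) {
  data.frame(time = seq_len(nrow(com)) - 1, x = com[, 1], y = com[, 2],
             z = com[, 3], ux = axis[, 1], uy = axis[, 2], uz = axis[, 3])
}

test_that("axial displacement projects on the instantaneous rod axis", {
  n <- 50
  ax <- matrix(rep(c(0, 0, 1), each = n), n, 3)
  com <- cbind(0, 0, 0.2 * (seq_len(n) - 1))
  ser <- axial_displacement(make_traj(com, ax))
  expect_equal(ser$z, 0.2 * (seq_len(n) - 1), tolerance = 1e-12)
  # pure rotation about the COM gives zero axial displacement
  th <- seq(0, 4 * pi, length.out = n)
  ax2 <- cbind(cos(th), sin(th), 0)
  ser2 <- axial_displacement(make_traj(matrix(1, n, 3), ax2))
  expect_equal(ser2$z, rep(0, n))
  # nematic symmetry: sign flips in the stored axis do not change z(t)
  flip <- rep(c(1, -1), length.out = n)
  ser3 <- axial_displacement(make_traj(com, ax * flip))
  expect_equal(ser3$z, ser$z)
  expect_error(axial_displacement(make_traj(com, ax)[c(1, 1, 2:n), ]),
               "non-monotonic")
})

test_that("MSD of deterministic and random walks matches closed forms", {
  n <- 2000
  ser <- axial_series(seq_len(n), 0.3 * seq_len(n))
  m <- axial_msd(ser)
  expect_equal(m$msd, 0.3^2 * m$lags^2, tolerance = 1e-10)
  expect_equal(m$local_exponent[2:(length(m$lags) - 1)],
               rep(2, length(m$lags) - 2), tolerance = 1e-6)
  expect_equal(axial_msd(axial_series(seq_len(200), rep(0, 200)))$msd,
               rep(0, length(axial_msd(axial_series(seq_len(200),
                                                    rep(0, 200)))$msd)))
  set.seed(61)
  s2 <- 0.5^2
  ser <- axial_series(seq_len(20000), cumsum(c(0, rnorm(19999, sd = 0.5))))
  m <- axial_msd(ser, lags = c(1, 2, 5, 10, 20))
  se <- sqrt(2 * c(1, 2, 5, 10, 20) / 20000) * m$msd # block-correlation bound
  expect_true(all(abs(m$msd - s2 * c(1, 2, 5, 10, 20)) < 3 * pmax(se, 0.01)))
})

test_that("time-averaged MSD agrees with the ensemble average for iid steps", {
  set.seed(62)
  reps <- lapply(1:20, function(i)
    axial_series(seq_len(2000), cumsum(c(0, rnorm(1999)))))
  m_ens <- axial_msd(reps, lags = c(2, 8, 32))
  m_ta <- axial_msd(reps[[1]], lags = c(2, 8, 32))
  se <- sqrt(2 * c(2, 8, 32) / 2000) * m_ens$msd
  expect_true(all(abs(m_ta$msd - m_ens$msd) < 3 * pmax(se, 3 * se[1])))
})

test_that("diffusion coefficient: exact slope, recovery, and trapped refusal", {
  m <- structure(list(lags = exp(seq(log(1), log(100), length.out = 30))),
                 class = "msd_result")
  m$msd <- 2 * 0.05 * m$lags
  m$lag_frames <- round(m$lags)
  m$local_exponent <- rep(1, 30)
  est <- diffusion_coefficient(m)
  expect_equal(est$D, 0.05, tolerance = 1e-12)
  expect_equal(est$status, "ok")
  # recovery from a sampled Brownian path with known D
  set.seed(63)
  D <- 0.7
  ser <- axial_series(seq_len(1e5), cumsum(c(0, rnorm(1e5 - 1,
                                                      sd = sqrt(2 * D)))))
  est <- diffusion_coefficient(axial_msd(ser))
  expect_equal(est$D, D, tolerance = 0.1 * D)
  # identical series as its own reference: D/D0 = 1
  est2 <- diffusion_coefficient(axial_msd(ser), reference = axial_msd(ser))
  expect_equal(est2$D_ratio, 1)
  # a saturating series has no Fickian window and returns no number
  set.seed(64)
  ou <- rodnet:::ou_path(5000, 0.3, 10)
  est3 <- diffusion_coefficient(axial_msd(axial_series(seq_len(5000), ou)))
  expect_equal(est3$status, "no_fickian_window")
  expect_true(is.na(est3$D))
})

test_that("displacement distribution is normalised and matches known forms", {
  # deterministic drift: single occupied bin at v * lag
  ser <- axial_series(seq_len(1000), 0.1 * seq_len(1000))
  g <- dpdf(ser, lags = 50, bin_width = 0.5)
  occupied <- which(g$gs[, 1] > 0)
  expect_length(occupied, 1)
  expect_equal(g$z[occupied], 5, tolerance = 0.5)
  # normalisation to machine-level accuracy at every lag
  set.seed(65)
  ser <- axial_series(seq_len(20000), cumsum(c(0, rnorm(19999))))
  g <- dpdf(ser, lags = c(5, 20, 80), bin_width = 0.25)
  sums <- colSums(g$gs) * g$bin_width
  expect_equal(sums, rep(1, 3), tolerance = 1e-6)
  # Gaussian increments reproduce the Gaussian density within binomial error
  gg <- g$gs[, 2]
  ref <- dnorm(g$z, sd = sqrt(20))
  n_inc <- g$n_increments[2]
  binom_se <- sqrt(pmax(ref, 1e-6) / (n_inc * g$bin_width))
  expect_true(all(abs(gg - ref) < 5 * binom_se + 0.01))
})

test_that("alpha_1 reproduces Gaussian, two-point and Laplace kurtosis", {
  set.seed(66)
  n <- 60000
  gauss <- axial_series(seq_len(n), cumsum(c(0, rnorm(n - 1))))
  a <- non_gaussian_alpha1(gauss, lags = 1)
  expect_equal(a$alpha1, 0, tolerance = 4 * sqrt(24 / n))
  twopoint <- axial_series(seq_len(n),
                           cumsum(c(0, sample(c(-1, 1), n - 1, TRUE))))
  a <- non_gaussian_alpha1(twopoint, lags = 1)
  expect_equal(a$alpha1, -2 / 3, tolerance = 0.01)
  lap <- axial_series(seq_len(n),
                      cumsum(c(0, sample(c(-1, 1), n - 1, TRUE) *
                                 rexp(n - 1, 2))))
  a <- non_gaussian_alpha1(lap, lags = 1)
  expect_equal(a$alpha1, 1, tolerance = 0.12)
})

test_that("wavelet smoothing recovers steps and avoids false positives", {
  # noiseless staircase: exact recovery, no spurious steps
  z <- rep(c(0, 4, 9), each = 400)
  sm <- smooth_trajectory(axial_series(seq_len(1200), z))
  expect_equal(nrow(sm$steps), 2)
  expect_equal(sort(sm$steps$frame), c(400, 800), tolerance = 1)
  # 5 sigma step in unit Gaussian noise: located within 3 frames
  set.seed(67)
  z <- c(rep(0, 512), rep(5, 512)) + rnorm(1024)
  sm <- smooth_trajectory(axial_series(seq_len(1024), z))
  expect_gte(nrow(sm$steps), 1)
  main <- sm$steps[which.max(abs(sm$steps$amplitude)), ]
  expect_lte(abs(main$frame - 512), 3)
  # noisy linear ramp: at most 1 spurious step per 1e3 frames
  set.seed(68)
  z <- 0.01 * seq_len(4096) + rnorm(4096, sd = 0.5)
  sm <- smooth_trajectory(axial_series(seq_len(4096), z))
  expect_lte(nrow(sm$steps), 4)
})

test_that("peak finder resolves a lattice comb and respects prominence", {
  x <- seq(-3, 3, by = 0.05)
  y <- dnorm(x, 0, 0.15) + 0.6 * dnorm(x, 1, 0.15) + 0.6 * dnorm(x, -1, 0.15)
  pk <- find_peaks(x, y)
  expect_equal(nrow(pk), 3)
  expect_equal(sort(pk$x), c(-1, 0, 1), tolerance = 0.06)
  expect_equal(mean(diff(sort(pk$x))), 1, tolerance = 0.06)
  # a tiny bump below the prominence floor is ignored
  y2 <- dnorm(x, 0, 0.15) + 0.02 * dnorm(x, 2, 0.1)
  expect_equal(nrow(find_peaks(x, y2)), 1)
})

test_that("classifier recovers each regime from its own generator", {
  pars <- ctrw_params()
  regs <- c("brownian", "hopping", "trapped", "sliding_fast")
  for (reg in regs) {
    ss <- sample_ctrw(reg, pars, n_traj = 2, seed = 100 + match(reg, regs))
    labs <- vapply(ss, function(s) classify_trajectory(s)$label, "")
    expect_true(all(labs == reg),
                info = paste(reg, "->", paste(labs, collapse = ",")))
  }
})

test_that("classifier precedence and evidence fields are populated", {
  pars <- ctrw_params()
  s <- sample_ctrw("hopping", pars, n_traj = 1, seed = 71)[[1]]
  lab <- classify_trajectory(s)
  expect_s3_class(lab, "regime_label")
  ev <- lab$evidence
  expect_true(all(c("sat_exponent", "fickian_window", "plateau",
                    "peak_spacing", "alpha1_peak", "z_range") %in% names(ev)))
  expect_equal(lab$evidence$peak_spacing, 1, tolerance = 0.2)
})
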