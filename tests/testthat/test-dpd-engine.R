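# Groot-Warren force field, integrator and thermostat

test_that("conservative pair force follows the soft linear form with cutoff", {
  p <- dpd_params()
  st <- two_bead_state(0.5)
  f <- pair_forces(st, p, components = "conservative", method = "brute")
  expect_equal(abs(f[1, 1]), 12.5) # a (1 - r/rc) = 25 * 0.5
  expect_equal(f[1, ], -f[2, ])    # Newton's third law
  st <- two_bead_state(1.0)
  expect_equal(pair_forces(st, p, components = "conservative",
                           method = "brute"),
               matrix(0, 2, 3))
  st <- two_bead_state(1.7)
  expect_equal(pair_forces(st, p, components = "conservative",
                           method = "brute"),
               matrix(0, 2, 3))
})

test_that("dissipative force damps relative motion along the pair axis", {
  p <- dpd_params()
  st <- two_bead_state(0.5, v1 = c(1, 0, 0), v2 = c(-1, 0, 0))
  f <- pair_forces(st, p, components = "dissipative", method = "brute")
  # -gamma w^2 (rhat . v12): w = 0.5, v12 along rhat = 2
  expect_equal(f[1, 1], -4.5 * 0.25 * 2)
  # perpendicular relative motion is not damped
  st <- two_bead_state(0.5, v1 = c(0, 1, 0), v2 = c(0, -1, 0))
  f <- pair_forces(st, p, components = "dissipative", method = "brute")
  expect_equal(f, matrix(0, 2, 3))
})

test_that("random pair force is symmetric and scales as sigma w / sqrt(dt)", {
  p <- dpd_params()
  st <- two_bead_state(0.5)
  set.seed(5)
  f <- pair_forces(st, p, components = "random", method = "brute")
  expect_equal(f[1, ], -f[2, ])
  expect_true(all(f[, 2:3] == 0)) # along the pair axis only
  # magnitude bounded by sigma * w * sqrt(3) / sqrt(dt)
  bound <- p$sigma * 0.5 * sqrt(3) / sqrt(p$dt)
  expect_lte(abs(f[1, 1]), bound + 1e-12)
})

test_that("cell-list forces equal brute-force forces exactly for small systems", {
  p <- dpd_params()
  set.seed(7)
  n <- 8
  st <- new_dpd_state(matrix(runif(3 * n, 0, 4), n, 3),
                      matrix(rnorm(3 * n), n, 3),
                      rep(1L, n), rep(4, 3), matrix(integer(0), 0, 2))
  fb <- pair_forces(st, p, components = c("conservative", "dissipative"),
                    method = "brute")
  fc <- pair_forces(st, p, components = c("conservative", "dissipative"),
                    method = "cell")
  expect_identical(fb, fc) # small box falls back to all pairs: bitwise equal
  # a box large enough for real cells must agree to round-off
  st2 <- new_dpd_state(st$positions * 2, st$velocities, st$species,
                      rep(8, 3), matrix(integer(0), 0, 2))
  expect_equal(pair_forces(st2, p, components = "conservative", method = "cell"),
               pair_forces(st2, p, components = "conservative", method = "brute"),
               tolerance = 1e-12)
})

test_that("coincident beads produce a finite force and non-finite input fails", {
  p <- dpd_params()
  st <- two_bead_state(0)
  set.seed(1)
  f <- pair_forces(st, p, components = "conservative", method = "brute")
  expect_true(all(is.finite(f)))
  expect_gt(max(abs(f)), 0)
  st$positions[1, 1] <- NaN
  expect_error(pair_forces(st, p), "non-finite")
})

test_that("harmonic bonds obey Hooke's law and reject broken topology", {
  p <- dpd_params(bond_k = 100, bond_r0 = 0.7)
  st <- two_bead_state(0.7)
  st$bonds <- matrix(c(1L, 2L), 1, 2)
  expect_equal(bond_forces(st, p), matrix(0, 2, 3))
  st <- two_bead_state(0.8)
  st$bonds <- matrix(c(1L, 2L), 1, 2)
  f <- bond_forces(st, p)
  expect_equal(f[1, 1], 10) # pulled back toward the partner
  expect_equal(f[1, ], -f[2, ])
  # a diagonal span beats the minimum image: clearly broken topology
  st <- new_dpd_state(matrix(c(0.3, 0.3, 0.3, 2.8, 2.8, 2.8), 2, 3,
                             byrow = TRUE), matrix(0, 2, 3), c(1L, 1L),
                      rep(5, 3), matrix(c(1L, 2L), 1, 2))
  expect_error(bond_forces(st, p), "half the box")
})

test_that("ballistic limit: isolated beads advance by v dt exactly", {
  p <- dpd_params()
  pos <- matrix(c(1, 1, 1, 6, 6, 6), 2, 3, byrow = TRUE)
  vel <- matrix(c(0.3, -0.1, 0.2, 0, 0.5, 0), 2, 3, byrow = TRUE)
  st <- new_dpd_state(pos, vel, c(1L, 1L), rep(12, 3),
                      matrix(integer(0), 0, 2))
  out <- run_dpd(st, p, n_steps = 10, record_every = 0, thermostat = FALSE)
  expect_equal(unname(out$state$positions), pos + 10 * p$dt * vel,
               tolerance = 1e-12)
  expect_equal(unname(out$state$velocities), vel)
})

test_that("conservative dynamics conserves momentum to machine precision", {
  p <- dpd_params()
  set.seed(11)
  st <- solvent_box(100, p, seed = 3)
  P0 <- unname(colSums(st$velocities))
  out <- run_dpd(st, p, n_steps = 200, record_every = 0, thermostat = FALSE)
  expect_equal(out$momentum, P0, tolerance = 1e-10)
})

test_that("thermostatted dynamics conserves momentum (symmetric pair noise)", {
  p <- dpd_params()
  st <- solvent_box(200, p, seed = 4)
  P0 <- unname(colSums(st$velocities))
  out <- run_dpd(st, p, n_steps = 1000, record_every = 0, seed = 5)
  expect_equal(out$momentum, P0, tolerance = 1e-8)
})

test_that("thermostat relaxes a cold start to the setpoint within 1e3 steps", {
  p <- dpd_params()
  st <- solvent_box(500, p, seed = 6)
  st$velocities[] <- 0
  out <- run_dpd(st, p, n_steps = 1000, record_every = 100, seed = 7)
  expect_equal(tail(out$trajectory$temperature, 1), 1, tolerance = 0.1)
})

test_that("fluctuation-dissipation holds: stationary temperature near 1 k_BT", {
  p <- dpd_params()
  st <- solvent_box(500, p, seed = 8)
  eq <- run_dpd(st, p, n_steps = 1500, record_every = 0, seed = 9)
  out <- run_dpd(eq$state, p, n_steps = 1500, record_every = 10, seed = 10)
  expect_equal(mean(out$trajectory$temperature), 1, tolerance = 0.05)
})

test_that("unstable steps are a hard failure", {
  p <- dpd_params()
  st <- solvent_box(50, p, seed = 12)
  st$velocities[1, 1] <- 1000 # would move > rc/2 in one step
  expect_error(run_dpd(st, p, n_steps = 1, record_every = 0), "unstable")
})

test_that("sigma inconsistent with fluctuation-dissipation is rejected", {
  expect_error(dpd_params(sigma = 2), "fluctuation-dissipation")
  expect_equal(dpd_params()$sigma^2, 2 * 4.5 * 1)
})

test_that("measure_temperature removes drift and matches Maxwell-Boltzmann", {
  v <- matrix(0, 200, 3)
  expect_equal(measure_temperature(v), 0)
  set.seed(13)
  n <- 4000
  v <- matrix(rnorm(3 * n), n, 3) + 5 # bulk drift must not count
  expect_equal(measure_temperature(v), 1, tolerance = 3 / sqrt(3 * n / 2))
})

test_that("rigid rod: free drift leaves the pose unchanged except COM motion", {
  p <- dpd_params()
  rod <- build_rod(3, 1, bead_spacing = 0.5)
  n <- nrow(rod$body)
  pos <- sweep(rod$body, 2, c(6, 6, 6), "+")
  st <- new_dpd_state(pos, matrix(0, n, 3), rep(4L, n), rep(12, 3),
                      matrix(integer(0), 0, 2),
                      rod = list(spec = rod, idx = seq_len(n),
                                 com = c(6, 6, 6), com_un = c(6, 6, 6),
                                 quat = c(1, 0, 0, 0), vel = c(0.2, 0, 0),
                                 angmom = c(0, 0, 0), mass = rod$mass,
                                 inertia = rod$inertia))
  out <- run_dpd(st, p, n_steps = 50, record_every = 0, thermostat = FALSE)
  expect_equal(out$state$rod$com_un, c(6, 6, 6) + 50 * p$dt * c(0.2, 0, 0),
               tolerance = 1e-12)
  expect_equal(out$state$rod$quat, c(1, 0, 0, 0))
})

test_that("rod beads stay rigid under thermostatted dynamics", {
  sys <- cached("rod_sys_short", {
    s <- small_rod_system(seed = 21, cells = 2, L_over_ax = 1.5,
                          relax_iter = 150)
    run_dpd(s$state, s$params, n_steps = 1500, record_every = 5, seed = 22)
  })
  st <- sys$state
  lab <- st$positions[st$rod$idx, ]
  R <- quat_to_matrix_exported(st$rod$quat)
  ref <- sweep(st$rod$spec$body %*% t(R), 2, st$rod$com, "+") %% st$box[1]
  expect_lt(max(abs(lab - ref)), 1e-8) # regenerated from the pose: exact
  # intra-rod distances equal the body-frame distances
  d_body <- dist(st$rod$spec$body[1:10, ])
  d_lab <- dist(minimg_coords(lab[1:10, ], st$box))
  expect_equal(as.numeric(d_lab), as.numeric(d_body), tolerance = 1e-8)
})

test_that("short-time rod motion in the network is ballistic (slope 2)", {
  sys <- cached("rod_sys_short", {
    s <- small_rod_system(seed = 21, cells = 2, L_over_ax = 1.5,
                          relax_iter = 150)
    run_dpd(s$state, s$params, n_steps = 1500, record_every = 5, seed = 22)
  })
  ser <- axial_displacement(sys$trajectory)
  m <- axial_msd(ser, lags = 1:10) # 0.1 tau to 1 tau at record_every = 5
  fit <- lm(log(m$msd) ~ log(m$lags))
  expect_equal(unname(coef(fit)[2]), 2, tolerance = 0.15)
})
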