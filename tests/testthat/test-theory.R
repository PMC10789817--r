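# Gaussian-bridge Monte Carlo free energy and the barrier phase diagram

test_that("a vanishing rod excludes nothing: strand free energy is 0", {
  m <- theory_model(crosslink_smear = 0)
  rod <- rod_geometry(1e-9, 1e-9)
  out <- strand_free_energy(m, c(0, 0, 0), c(0, 0, 1), rod,
                            n_samples = 500, seed = 1)
  expect_identical(out$dF, 0)
  expect_equal(out$acceptance, 1)
})

test_that("strands outside the interaction range contribute nothing", {
  m <- theory_model(crosslink_smear = 0)
  rod <- rod_geometry(2, 1.4)
  out <- strand_free_energy(m, c(8, 0.5, 0), c(8, 0.5, 1), rod,
                            n_samples = 2000, seed = 2)
  expect_identical(out$dF, 0)
})

test_that("N = 1 has no interior vertices: geometric endpoint rule only", {
  m <- theory_model(N = 1, crosslink_smear = 0)
  rod <- rod_geometry(2, 1.4)
  # both endpoints outside the cylinder: every bridge accepted
  out <- strand_free_energy(m, c(2, 0.5, 0.5), c(3, 0.5, 0.5), rod,
                            n_samples = 300, seed = 3)
  expect_identical(out$dF, 0)
  # an endpoint inside the hard core is flagged invalid geometry
  out2 <- strand_free_energy(m, c(0.5, 0.5, 0.5), c(1.5, 0.5, 0.5), rod,
                             n_samples = 300, seed = 3)
  expect_identical(out2$dF, Inf)
  expect_equal(out2$flag, "endpoint_inside")
})

test_that("N = 2 acceptance matches the single-vertex quadrature oracle", {
  m <- theory_model(N = 2, crosslink_smear = 0)
  L <- 1.0; d <- 1.0
  rod <- rod_geometry(L, d)
  ep1 <- c(1.0, 0.5, 0.0); ep2 <- c(1.0, 0.5, 1.0)
  out <- strand_free_energy(m, ep1, ep2, rod, n_samples = 40000, seed = 4)
  # oracle: interior vertex ~ N(midpoint, (b^2/3) * k(N-k)/N I) with k = 1
  mid <- (ep1 + ep2) / 2
  svar <- (m$b^2 / 3) * (1 * 1 / 2)
  s <- sqrt(svar)
  gx <- seq(-5, 5, length.out = 301) * s
  wx <- dnorm(gx, sd = s) * (gx[2] - gx[1])
  # lateral disc membership (x, y); axial slab membership (z)
  lat <- outer(gx + mid[1] - 0.5, gx + mid[2] - 0.5,
               function(x, y) x^2 + y^2 < (d / 2)^2)
  p_lat <- as.numeric(t(wx) %*% lat %*% wx)
  zc <- 0.5 + rod$z
  p_ax <- sum(wx[abs(gx + mid[3] - zc) < L / 2])
  p_inside <- p_lat * p_ax
  se <- sqrt(p_inside * (1 - p_inside) / 40000)
  expect_equal(1 - out$acceptance, p_inside, tolerance = 3.5 * se + 1e-4)
})

test_that("Monte Carlo error halves in variance when samples double", {
  m <- theory_model(crosslink_smear = 0)
  rod <- rod_geometry(1.5, 1.4)
  # transverse strand whose rest line clips the cylinder: partial acceptance
  ep1 <- c(0, 1.1, 0.5); ep2 <- c(1, 1.1, 0.5)
  vars <- sapply(c(400, 800, 1600), function(n) {
    est <- sapply(1:24, function(i)
      strand_free_energy(m, ep1, ep2, rod, n_samples = n,
                         seed = 1000 * n + i)$dF)
    var(est)
  })
  expect_gt(vars[1] / vars[2], 1.2)
  expect_lt(vars[1] / vars[2], 3.5)
  expect_gt(vars[1] / vars[3], 2.2)
  expect_lt(vars[1] / vars[3], 8)
})

test_that("free-energy profile: zero minimum, mirror symmetry, periodicity", {
  m <- theory_model()
  zg <- seq(-0.5, 0.5, length.out = 9)
  prof <- free_energy_profile(m, rod_geometry(1.5, 1.2), zg,
                              n_samples = 1500, shell = 1.5, seed = 5)
  expect_equal(min(prof$deltaF), 0)
  expect_gte(prof$Ub, 0)
  # lattice mirror symmetry about the cell centre
  sym_err <- abs(prof$deltaF - rev(prof$deltaF))
  tol <- 3 * (prof$mc_error + rev(prof$mc_error))
  expect_true(all(sym_err < pmax(tol, 0.35)))
  # periodicity over two periods
  zg2 <- seq(-0.5, 1.5, by = 0.25)
  prof2 <- free_energy_profile(m, rod_geometry(1.3, 0.9), zg2,
                               n_samples = 1500, shell = 1.5, seed = 6)
  pairs <- match(round(zg2 + 1, 9), round(zg2, 9))
  have <- !is.na(pairs)
  expect_true(all(abs(prof2$deltaF[have] - prof2$deltaF[pairs[have]]) < 0.4))
})

test_that("barrier grows with rod diameter and vanishes for a thin rod", {
  m <- theory_model()
  zg <- seq(-0.5, 0.5, length.out = 9)
  ubs <- sapply(c(1.0, 1.3, 1.6), function(d)
    free_energy_profile(m, rod_geometry(1.5, d), zg, n_samples = 1500,
                        shell = 1.5, seed = 7)$Ub)
  expect_true(all(diff(ubs) > -0.4)) # nondecreasing within MC noise
  expect_gt(ubs[3], ubs[1])
  thin <- free_energy_profile(m, rod_geometry(1.5, 0.05), zg,
                              n_samples = 1000, shell = 1, seed = 8)
  expect_lt(thin$Ub, 0.1)
})

test_that("barrier classification follows the Kramers k_BT criterion", {
  expect_equal(classify_by_barrier(0.5), "sliding")
  expect_equal(classify_by_barrier(3.0), "hopping")
  expect_equal(classify_by_barrier(0), "sliding")
  expect_error(classify_by_barrier(-0.1), "negative")
  expect_equal(hopping_time(10, 2), 10 * exp(2))
})

test_that("phase diagram labels are consistent with the barrier map", {
  m <- theory_model()
  pd <- phase_diagram(m, d_grid = c(1.2, 1.6), L_grid = c(1.5, 2.0),
                      z_grid = seq(-0.5, 0.5, length.out = 7),
                      n_samples = 600, shell = 1.5, seed = 9)
  expect_equal(dim(pd$Ub_map), c(2, 2))
  expect_identical(pd$labels,
                   matrix(ifelse(pd$Ub_map > 1, "hopping", "sliding"), 2, 2))
  expect_true(all(is.finite(pd$Ub_map)))
  expect_true(is.list(pd$boundary))
})
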