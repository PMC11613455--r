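test_that("MSD obeys closed forms for stationary and ballistic motion", {
  n_f <- 200
  times <- seq_len(n_f) * 0.1
  # stationary particle: MSD identically zero
  com <- array(5, c(n_f, 1, 3))
  tr <- trajectory(times, com, box_spec(100), wrapped = FALSE)
  expect_true(all(abs(compute_msd(tr)$values) < 1e-6)) # FFT roundoff only
  # deterministic drift v: MSD(t) = v^2 t^2
  v <- c(2, 0, 1)
  com <- array(0, c(n_f, 1, 3))
  for (d in 1:3) com[, 1, d] <- v[d] * times
  msd <- compute_msd(trajectory(times, com, box_spec(1e6), wrapped = FALSE))
  expect_equal(msd$values, sum(v^2) * msd$lags^2, tolerance = 1e-9)
  # wrapped input is rejected with guidance
  trw <- trajectory(times, com, box_spec(1e6), wrapped = TRUE)
  expect_error(compute_msd(trw), "unwrap_positions")
})

test_that("linear MSD fit returns the exact slope and honors the window", {
  lags <- seq(0, 20, 0.1)
  msd <- crowd_ts(lags, 6 * 7 * lags + 3)
  fit <- fit_Dt(msd, window = c(2, 10))
  expect_equal(fit$value, 7, tolerance = 1e-12)
  expect_equal(fit$ledger[[1]]$intercept, 3, tolerance = 1e-9)
  expect_error(fit_Dt(msd, window = c(30, 40)), "window")
})

test_that("subdiffusive input produces window-dependent estimates", {
  lags <- seq(0, 60, 0.05)
  msd <- crowd_ts(lags, 50 * lags^0.7)
  d1 <- fit_Dt(msd, c(2, 10))
  d2 <- fit_Dt(msd, c(10, 50))
  # anomalous diffusion: window dependence far beyond the fit uncertainty
  expect_gt(abs(d1$value - d2$value), 3 * (d1$se + d2$se))
  expect_gt(abs(d1$value - d2$value) / d1$value, 0.2)
})

test_that("translational finite-size correction has the documented form", {
  kbt <- thermal_energy(298)
  est <- finite_size_correction_t(10, eta = 0.347, L = 100)
  want <- 2.837297 * kbt / (6 * pi * 0.347 * 100)
  expect_equal(est$value - 10, want)
  expect_equal(want, 17.85, tolerance = 1e-3)
  # 1/L scaling: halving L doubles the correction
  est2 <- finite_size_correction_t(10, eta = 0.347, L = 50)
  expect_equal(est2$value - 10, 2 * want)
  # L -> infinity: correction vanishes
  est3 <- finite_size_correction_t(10, eta = 0.347, L = 1e12)
  expect_equal(est3$value, 10, tolerance = 1e-9)
  expect_error(finite_size_correction_t(10, eta = NULL, L = 100), "eta")
})

test_that("water-model rescaling reproduces the worked value and order", {
  expect_equal(water_model_rescale(622.5)$value, 233.6, tolerance = 1e-3)
  expect_equal(water_model_rescale(10, 1, 1)$value, 10)
  # pipeline order is correct-then-rescale; the other order differs
  est_a <- water_model_rescale(finite_size_correction_t(10, 0.347, 100))
  est_b <- finite_size_correction_t(water_model_rescale(10), 0.347, 100)
  expect_false(isTRUE(all.equal(est_a$value, est_b$value)))
  # the ledger reproduces the arithmetic of the corrected estimate
  expect_equal(replay_ledger(est_a), est_a$value, tolerance = 1e-12)
})

test_that("rotational helpers follow their closed forms", {
  expect_equal(Dr_from_tau(1 / 6), 1)
  expect_equal(Dr_from_tau(5), 1 / 30)
  expect_error(Dr_from_tau(0), "positive")
  kbt <- thermal_energy(298)
  est <- finite_size_correction_r(0.05, eta = 1, L = 100)
  expect_equal(est$value - 0.05, kbt / (6 * 1 * 100^3))
  # 1/L^3 scaling: halving L multiplies the correction by 8
  est2 <- finite_size_correction_r(0.05, eta = 1, L = 50)
  expect_equal(est2$value - 0.05, 8 * (est$value - 0.05))
  # typical crowded box: correction small relative to a 12 A protein's Dr
  Dr_12A <- kbt / (8 * pi * 1 * 12^3)
  corr <- kbt / (6 * 1 * 100^3)
  expect_lt(corr / Dr_12A, 0.2)
})

test_that("hydrodynamic radii invert the Stokes-Einstein relations", {
  kbt <- thermal_energy(298)
  D20 <- kbt / (6 * pi * 1 * 20)
  expect_equal(hydrodynamic_radius(D20, eta = 1), 20, tolerance = 1e-9)
  # a sphere obeying both relations gives consistent radii
  R <- 14.3
  Dt <- kbt / (6 * pi * 0.89 * R)
  Dr <- kbt / (8 * pi * 0.89 * R^3)
  expect_equal(hydrodynamic_radius(Dt, 0.89, kind = "translational"),
               hydrodynamic_radius(Dr, 0.89, kind = "rotational"),
               tolerance = 1e-6)
  expect_error(hydrodynamic_radius(-1, 1), "positive")
})

test_that("P2 ACF matches geometric closed forms", {
  # identity rotations: C identically 1
  vec <- array(rep(c(1, 0, 0), each = 12), c(12, 1, 3))
  ot <- structure(list(times = seq_len(12) * 0.1, vectors = vec),
                  class = "orientation_trajectory")
  expect_true(all(abs(p2_acf(ot)$values - 1) < 1e-12))
  # 90-degree rotation about z of a vector along x: P2(cos 90) = -0.5
  vec <- array(0, c(2, 1, 3))
  vec[1, 1, ] <- c(1, 0, 0)
  vec[2, 1, ] <- c(0, 1, 0)
  ot <- structure(list(times = c(0.1, 0.2), vectors = vec),
                  class = "orientation_trajectory")
  ac <- p2_acf(ot, lag_grid = c(0, 0.1))
  expect_equal(ac$values[2], -0.5)
})

test_that("P2 route through Kabsch superposition matches direct vectors", {
  # rigid body rotating at fixed small angle per frame about a known axis
  set.seed(101)
  ca_ref <- matrix(rnorm(15, sd = 5), 5, 3)
  n_f <- 40
  atoms <- array(NA_real_, c(n_f, 5, 3))
  R_step <- crowdflow:::rotation_from_axis_angle(c(0, 0, 0.12))
  R <- diag(3)
  for (f in seq_len(n_f)) {
    atoms[f, , ] <- ca_ref %*% t(R)
    R <- R_step %*% R
  }
  com <- array(0, c(n_f, 1, 3))
  com[, 1, ] <- apply(atoms, c(1, 3), mean)
  tr <- trajectory(seq_len(n_f) * 0.1, com, box_spec(1e4), wrapped = FALSE,
                   atoms = atoms, molecule_index = rep(1L, 5),
                   calpha_index = list(1:5))
  ac <- p2_acf(tr, probe = 1, n_vectors = 200, seed = 2,
               lag_grid = (0:10) * 0.1)
  # isotropically averaged P2 of a rotation by angle k*0.12 about one axis:
  # <P2(cos theta)> over random vectors = P2 Legendre average
  angs <- (0:10) * 0.12
  want <- vapply(angs, function(a) {
    u <- seq(-1, 1, length.out = 20001) # cos of polar angle of v vs axis
    ct <- u^2 + (1 - u^2) * cos(a)      # v(0) . v(t) for unit v
    mean((3 * ct^2 - 1) / 2)
  }, 0)
  expect_equal(ac$values, want, tolerance = 0.02)
  # degenerate collinear reference atoms are rejected
  line <- array(rep(cbind(1:5, 0, 0), each = n_f), c(n_f, 5, 3))
  tr2 <- tr
  tr2$atoms <- line
  expect_error(p2_acf(tr2, probe = 1, n_vectors = 5), "collinear")
})

test_that("double-exponential P2 fit recovers constructed mixtures", {
  t <- seq(0, 20, 0.05)
  # single exponential: tau_overall equals tau despite degenerate split
  fit1 <- fit_p2(crowd_ts(t, exp(-t / 4)))
  expect_equal(fit1$tau_overall, 4, tolerance = 0.01)
  # a = 0.7, tau = (10, 1): tau_overall = 7.3
  y <- 0.7 * exp(-t / 10) + 0.3 * exp(-t / 1)
  fit2 <- fit_p2(crowd_ts(t, y))
  expect_equal(fit2$tau_overall, 7.3, tolerance = 0.01)
  expect_equal(fit2$a, 0.7, tolerance = 0.02)
})

test_that("full rotational pipeline recovers the generator Dr", {
  ot <- simulate_rotational_walk(Dr = 0.05, dt = 0.01, n_steps = 1e5,
                                 n_vectors = 20, seed = 5, thin = 10)
  fit <- fit_p2(p2_acf(ot), window = c(0, 20))
  expect_equal(fit$Dr_pbc, 0.05, tolerance = 0.05)
  expect_equal(fit$tau_overall, 1 / (6 * 0.05), tolerance = 0.05)
})

test_that("full translational pipeline recovers D0 across seeds", {
  vals <- vapply(1:3, function(s) {
    cfg <- crowd_config(n_molecules = 30, radius = 10, D0 = 100, dt = 1e-3,
                        n_steps = 4e4, phi = 0.1, pair_potential = "none",
                        seed = s)
    tr <- simulate_brownian_crowd(cfg)
    gt <- tr$ground_truth
    est <- fit_Dt(compute_msd(unwrap_positions(tr)), window = c(2, 10))
    finite_size_correction_t(est, eta = gt$eta_nominal,
                             L = tr$box$edge_length)$value
  }, 0)
  expect_equal(mean(vals), 100, tolerance = 0.05)
})
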