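test_that("same seed gives bit-identical generator output", {
  cfg <- crowd_config(n_molecules = 5, radius = 8, D0 = 50, dt = 1e-3,
                      n_steps = 200, phi = 0.05,
                      pair_potential = "square-well", epsilon = 1, seed = 4)
  expect_identical(simulate_brownian_crowd(cfg)$com,
                   simulate_brownian_crowd(cfg)$com)
  scfg <- stress_sim_config(0.3, 1e-3, 1e6, dt = 1e-5, n_samples = 500,
                            n_replicas = 2, seed = 8)
  expect_identical(simulate_stress_ou(scfg)[[1]]$channels,
                   simulate_stress_ou(scfg)[[1]]$channels)
  ccfg <- contact_sim_config(c(0.5, 0.3, 0.2), c(10, 1, 0.1), 0.3,
                             dt = 0.1, n_frames = 300, n_pairs = 5, seed = 2)
  expect_identical(simulate_contact_timeline(ccfg)$present,
                   simulate_contact_timeline(ccfg)$present)
})

test_that("force-free Brownian crowd matches the free-diffusion propagator", {
  cfg <- crowd_config(n_molecules = 50, radius = 10, D0 = 100, dt = 1e-3,
                      n_steps = 2000, phi = 0.05, pair_potential = "none",
                      seed = 3, pbc_mobility_reduction = FALSE)
  tr <- unwrap_positions(simulate_brownian_crowd(cfg))
  # displacement variance per axis = 2 D0 t, ~1e5 independent increments
  lag_f <- 5
  idx <- seq(1, 2000, by = lag_f)
  disp <- tr$com[idx[-1], , ] - tr$com[idx[-length(idx)], , ]
  expect_equal(mean(disp^2), 2 * 100 * lag_f * 1e-3, tolerance = 0.012)
  # MSD slope/6 recovers D0 within 3%
  msd <- compute_msd(tr)
  D <- fit_Dt(msd, window = c(0.1, 0.5))$value
  expect_equal(D, 100, tolerance = 0.03)
})

test_that("crowd generator validates its configuration", {
  expect_error(crowd_config(n_molecules = 30, radius = 10, D0 = 100,
                            dt = 1e-3, n_steps = 10, phi = 0.5), "0.45")
  expect_error(crowd_config(n_molecules = 2, radius = 1, D0 = 100,
                            dt = 1e-2, n_steps = 10, phi = 0.01), "RMS step")
})

test_that("attraction increases association at equal volume fraction", {
  mean_cluster <- function(eps, seed) {
    cfg <- crowd_config(n_molecules = 20, radius = 10, D0 = 100, dt = 5e-4,
                        n_steps = 1e4, phi = 0.1,
                        pair_potential = "square-well", epsilon = eps,
                        seed = seed, thin = 20, n_equil = 1e4)
    tl <- direct_contacts(simulate_brownian_crowd(cfg), cutoff = 2)
    mean(cluster_with_probe(tl, probe = 1)$in_cluster)
  }
  m0 <- vapply(1:5, function(s) mean_cluster(0, s), 0)
  m3 <- vapply(1:5, function(s) mean_cluster(3, s), 0)
  expect_true(all(m3 > m0))
})

test_that("rotational walk honors its closed-form P2 decay", {
  # Dr = 0: vectors constant, P2 ACF identically 1
  ot0 <- simulate_rotational_walk(Dr = 0, dt = 0.01, n_steps = 50,
                                  n_vectors = 4, seed = 1)
  expect_equal(ot0$vectors[50, , ], ot0$vectors[1, , ])
  expect_true(all(abs(p2_acf(ot0)$values - 1) < 1e-12))
  # vector norms preserved by the rigid rotations
  ot <- simulate_rotational_walk(Dr = 0.1, dt = 0.01, n_steps = 200,
                                 n_vectors = 10, seed = 2)
  norms <- sqrt(apply(ot$vectors^2, c(1, 2), sum))
  expect_equal(as.vector(norms), rep(1, length(norms)), tolerance = 1e-8)
  # two vector sets attached to the same body give the same fitted decay
  walk <- simulate_rotational_walk(0.05, 0.01, 4e4, n_vectors = 50,
                                   seed = 7, thin = 5)
  sub1 <- sub2 <- walk
  sub1$vectors <- walk$vectors[, 1:10, , drop = FALSE]
  sub2$vectors <- walk$vectors[, 11:50, , drop = FALSE]
  acf1 <- p2_acf(sub1)
  acf2 <- p2_acf(sub2)
  t1 <- fit_exp_tau(acf1$lags, acf1$values)
  t2 <- fit_exp_tau(acf2$lags, acf2$values)
  expect_equal(t1, t2, tolerance = 0.1)
  expect_error(simulate_rotational_walk(10, 0.01, 10), "Dr \\* dt")
})

test_that("OU stress generator has the advertised moments", {
  cfg <- stress_sim_config(eta_target = 0.35, tau_c = 1e-3, volume = 1e6,
                           dt = 1e-5, n_samples = 2e5, n_replicas = 2,
                           n_channels = 5, seed = 6)
  reps <- simulate_stress_ou(cfg)
  c0 <- attr(reps, "ground_truth")$c0_bar2
  # stationary variance within 2% at 1e6 samples (pooled channels)
  expect_equal(mean(reps[[1]]$channels^2), c0, tolerance = 0.02)
  # empirical ACF matches the target exponential within 3 SEM at <= 5 tau_c
  ac <- stress_acf_mean(reps, max_lag = 5e-3)
  target <- c0 * exp(-ac$tau / 1e-3)
  sem <- ac$sigma / sqrt(2) + c0 * 0.01
  expect_true(all(abs(ac$mean - target) < 3 * pmax(sem, c0 * 0.02)))
  # eta = 0 gives all-zero series
  cfg0 <- stress_sim_config(0, 1e-3, 1e6, dt = 1e-5, n_samples = 100,
                            n_replicas = 2, seed = 1)
  expect_true(all(simulate_stress_ou(cfg0)[[1]]$channels == 0))
})

test_that("contact generator hits occupancy and degenerate limits", {
  cfg <- contact_sim_config(c(0.5, 0.3, 0.2), c(10, 1, 0.1), occupancy = 0.3,
                            dt = 0.05, n_frames = 4000, n_pairs = 200, seed = 3)
  tl <- simulate_contact_timeline(cfg)
  expect_equal(mean(tl$present), 0.3, tolerance = 0.05)
  # occupancy 1: all-ones timeline, ACF identically 1
  cfg1 <- contact_sim_config(1, 5, occupancy = 1, dt = 0.1, n_frames = 100,
                             n_pairs = 3, seed = 1)
  tl1 <- simulate_contact_timeline(cfg1)
  expect_true(all(tl1$present))
  expect_true(all(abs(contact_acf(tl1)$values - 1) < 1e-12))
  expect_error(contact_sim_config(c(0.5, 0.5), c(5, 1), occupancy = 0,
                                  dt = 0.1, n_frames = 10, n_pairs = 1),
               "degenerate")
})

test_that("single-component contact kinetics match two-state theory", {
  # exponential on/off renewal is a two-state Markov process; its ACF
  # decays with 1/tau_eff = 1/tau_on + 1/tau_off toward the occupancy
  cfg <- contact_sim_config(1, 5, occupancy = 0.5, dt = 0.05,
                            n_frames = 2e4, n_pairs = 400, seed = 12)
  tl <- simulate_contact_timeline(cfg)
  ac <- contact_acf(tl)
  fit <- fit_triple_exponential(ac, n_components = 1)
  expect_equal(fit$tau[1], 2.5, tolerance = 0.1) # 1/(1/5 + 1/5)
  expect_equal(fit$c0, 0.5, tolerance = 0.05)
})
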