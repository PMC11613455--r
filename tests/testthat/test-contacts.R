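make_surrogate_traj <- function(com, L, radii) {
  trajectory(seq_len(dim(com)[1]), com, box_spec(L), wrapped = TRUE,
             radii = radii)
}

test_that("surrogate contact geometry follows the surface-distance rule", {
  com <- array(0, c(2, 2, 3))
  com[, 2, 1] <- 24 # gap = 24 - 20 = 4 A < 5
  tl <- direct_contacts(make_surrogate_traj(com, 100, c(10, 10)), cutoff = 5)
  expect_true(tl$present[1, 1])
  com[, 2, 1] <- 26 # gap = 6 A
  tl <- direct_contacts(make_surrogate_traj(com, 100, c(10, 10)), cutoff = 5)
  expect_false(tl$present[1, 1])
})

test_that("heavy-atom contacts agree with the brute-force oracle", {
  set.seed(31)
  L <- 40
  n_mol <- 12
  n_frames <- 6
  atoms_per <- 3
  n_at <- n_mol * atoms_per
  atoms <- array(runif(n_frames * n_at * 3, 0, L), c(n_frames, n_at, 3))
  mol_idx <- rep(seq_len(n_mol), each = atoms_per)
  com <- array(0, c(n_frames, n_mol, 3))
  for (m in seq_len(n_mol)) {
    com[, m, ] <- apply(atoms[, mol_idx == m, , drop = FALSE], c(1, 3), mean)
  }
  tr <- trajectory(seq_len(n_frames), com, box_spec(L), wrapped = TRUE,
                   atoms = atoms, molecule_index = mol_idx)
  tl <- direct_contacts(tr, cutoff = 5)
  for (f in seq_len(n_frames)) {
    for (k in seq_len(nrow(tl$pairs))) {
      i <- tl$pairs[k, 1]; j <- tl$pairs[k, 2]
      want <- brute_min_dist(atoms[f, mol_idx == i, , drop = TRUE],
                             atoms[f, mol_idx == j, , drop = TRUE], L) < 5
      expect_identical(tl$present[f, k], want)
    }
  }
})

test_that("hydrogens are excluded from heavy-atom contacts", {
  atoms <- array(0, c(2, 4, 3))
  atoms[, 2, 1] <- 30   # molecule 1: atoms 1 (at origin) and 2 (far)
  atoms[, 3, 1] <- 4    # molecule 2 heavy atom within 5 A of atom 1
  atoms[, 4, 1] <- 4.5  # molecule 2 hydrogen
  com <- array(0, c(2, 2, 3))
  com[, 1, 1] <- 15; com[, 2, 1] <- 4.25
  tr <- trajectory(c(0, 1), com, box_spec(100), wrapped = TRUE, atoms = atoms,
                   molecule_index = c(1, 1, 2, 2),
                   elements = c("C", "C", "N", "H"))
  expect_true(direct_contacts(tr, cutoff = 5)$present[1, 1])
  # move the heavy atom out of range: only the H remains near -> no contact
  atoms[, 3, 1] <- 20
  tr$atoms <- atoms
  expect_false(direct_contacts(tr, cutoff = 5)$present[1, 1])
})

test_that("residue contact profile counts crowder atoms near C-alphas", {
  # probe: 3 residues along x; one crowder atom 6.5 A from residue 1's CA
  atoms <- array(0, c(4, 4, 3))
  atoms[, 2, 1] <- 15; atoms[, 3, 1] <- 30  # CA2, CA3
  atoms[, 4, 1] <- 6.5                       # crowder atom
  com <- array(0, c(4, 2, 3))
  com[, 1, 1] <- 15; com[, 2, 1] <- 6.5
  tr <- trajectory(1:4 + 0, com, box_spec(200), wrapped = TRUE, atoms = atoms,
                   molecule_index = c(1, 1, 1, 2),
                   calpha_index = list(c(1L, 2L, 3L), integer()))
  prof <- residue_contact_profile(tr, probe = 1, cutoff = 7)
  expect_equal(prof$mean, c(1, 0, 0))
  # isolated probe: all-zero profile
  tr0 <- tr
  tr0$atoms[, 4, 1] <- 90
  expect_equal(residue_contact_profile(tr0, 1, 7)$mean, c(0, 0, 0))
  # randomized placements vs brute-force oracle
  set.seed(7)
  tr$atoms[, 4, ] <- matrix(runif(12, 0, 200), 4, 3)
  prof <- residue_contact_profile(tr, probe = 1, cutoff = 7)
  want <- sapply(1:3, function(r) {
    mean(sapply(1:4, function(f) {
      d <- tr$atoms[f, 4, ] - tr$atoms[f, r, ]
      d <- d - 200 * round(d / 200)
      sum(d^2) < 49
    }))
  })
  expect_equal(prof$mean, want)
})

test_that("probe cluster membership matches a union-find oracle", {
  # chain A-B-C with probe A: direct 1, in-cluster 2
  pairs <- rbind(c(1L, 2L), c(2L, 3L), c(1L, 3L))
  pres <- matrix(c(TRUE, TRUE, FALSE), 1, 3)
  tl <- contact_timeline(1, pairs, pres)
  cs <- cluster_with_probe(tl, probe = 1, n_mol = 3)
  expect_equal(cs$direct, 1L)
  expect_equal(cs$in_cluster, 2L)
  # empty graph
  tl0 <- contact_timeline(1, pairs, matrix(FALSE, 1, 3))
  cs0 <- cluster_with_probe(tl0, probe = 1, n_mol = 3)
  expect_equal(cs0$direct, 0L)
  expect_equal(cs0$in_cluster, 0L)
  # random graphs over many frames vs oracle + bounds invariant
  set.seed(41)
  n_mol <- 12
  all_pairs <- t(combn(n_mol, 2))
  pres <- matrix(runif(200 * nrow(all_pairs)) < 0.08, 200)
  tl <- contact_timeline(seq_len(200), all_pairs, pres)
  cs <- cluster_with_probe(tl, probe = 3, n_mol = n_mol)
  labs <- attr(cs, "labels")
  for (f in c(1, 17, 50, 113, 200)) {
    comp <- uf_components(n_mol, all_pairs[pres[f, ], , drop = FALSE])
    expect_equal(labs[f, ], comp)
    expect_equal(cs$in_cluster[f], sum(comp == comp[3]) - 1L)
    expect_equal(cs$direct[f], sum(all_pairs[pres[f, ], , drop = FALSE] == 3L))
  }
  expect_true(all(cs$direct <= cs$in_cluster))
  expect_true(all(cs$in_cluster <= n_mol - 1L))
})

test_that("contact ACF normalization and limits are correct", {
  # iid contacts with occupancy p: C(0) = 1, C(k > 0) ~ p
  set.seed(51)
  p <- 0.3
  pres <- matrix(runif(4000 * 50) < p, 4000, 50)
  tl <- contact_timeline(seq_len(4000) * 0.1, cbind(1L, 2:51), pres)
  ac <- contact_acf(tl)
  expect_equal(ac$values[1], 1)
  expect_equal(mean(ac$values[ac$lags > 1]), p, tolerance = 0.03)
  # invariant to pair order permutation
  perm <- sample(50)
  tl2 <- contact_timeline(tl$times, tl$pairs, pres[, perm])
  expect_equal(contact_acf(tl2)$values, ac$values, tolerance = 1e-12)
  # batching invariance: one timeline vs the same pairs split in two
  tla <- contact_timeline(tl$times, tl$pairs[1:25, ], pres[, 1:25])
  tlb <- contact_timeline(tl$times, tl$pairs[26:50, ], pres[, 26:50])
  expect_equal(contact_acf(list(tla, tlb))$values, ac$values,
               tolerance = 1e-12)
  # no contacts: undefined normalization
  expect_error(contact_acf(contact_timeline(1:10, cbind(1L, 2L),
                                            matrix(FALSE, 10, 1))),
               "undefined|no contacts")
})

test_that("telegraph-process decay time is recovered within 10%", {
  cfg <- contact_sim_config(1, 2, occupancy = 0.4, dt = 0.05,
                            n_frames = 2e4, n_pairs = 300, seed = 8)
  ac <- contact_acf(simulate_contact_timeline(cfg))
  fit <- fit_triple_exponential(ac, n_components = 1)
  # two-state telegraph: decay constant 1/(1/tau_on + 1/tau_off) with
  # tau_off = tau_on (1 - p)/p = 3 ns, plateau at the occupancy
  expect_equal(fit$tau[1], 1 / (1 / 2 + 1 / 3), tolerance = 0.1)
  expect_equal(fit$c0, 0.4, tolerance = 0.05)
})

test_that("triple-exponential fitter handles clean and degenerate input", {
  t <- log_lag_grid(0.01, 500, 24)
  # pure single exponential: one dominant weight, tau within 2%
  y <- exp(-t / 7)
  fit <- fit_triple_exponential(crowd_ts(t, y), baseline = FALSE)
  expect_equal(fit$tau[which.max(fit$w)], 7, tolerance = 0.02)
  expect_lt(sum(sort(fit$w, decreasing = TRUE)[-1]), 0.02)
  # well-separated synthetic mixture recovered accurately
  y3 <- 0.5 * exp(-t / 100) + 0.3 * exp(-t / 5) + 0.2 * exp(-t / 0.3)
  fit3 <- fit_triple_exponential(crowd_ts(t, y3), baseline = FALSE)
  expect_equal(fit3$tau, c(100, 5, 0.3), tolerance = 0.02)
  expect_equal(fit3$w, c(0.5, 0.3, 0.2), tolerance = 0.05)
  # flat input: error, never a silent finite answer
  expect_error(fit_triple_exponential(crowd_ts(t, rep(1, length(t)))),
               "no decay|Inf")
})

test_that("Z-score flags non-stationarity and passes stationary noise", {
  # constant series: Z identically 0
  zr <- convergence_zscore(rep(2, 3000), window = 400, dt = 1)
  expect_true(all(zr$Z == 0))
  # a 5-SEM step inside the long window produces Z > 1 early
  set.seed(61)
  base <- rnorm(3000)
  sem_scale <- sd(base) / sqrt(400 / 40)
  stepped <- base + c(rep(0, 1500), rep(5 * sem_scale, 1500))
  zr <- convergence_zscore(stepped, window = 400, dt = 1)
  expect_gt(max(zr$Z[zr$times < 1000]), 1)
  # stationary white noise with 3 replicates: mostly Z < 1 over 100 seeds
  frac <- vapply(1:100, function(s) {
    set.seed(s)
    x <- matrix(rnorm(1500 * 3), 1500, 3)
    mean(convergence_zscore(x, window = 400, dt = 1)$Z < 1)
  }, 0)
  expect_gte(mean(frac), 0.6)
  expect_error(convergence_zscore(rnorm(100), window = 400, dt = 1), "window")
})

test_that("burn-in trimming leaves stationary estimates unchanged", {
  cfg <- contact_sim_config(1, 3, occupancy = 0.35, dt = 0.05,
                            n_frames = 2e4, n_pairs = 150, seed = 14)
  tl <- simulate_contact_timeline(cfg)
  occ_full <- mean(tl$present)
  n_burn <- nrow(tl$present) %/% 4
  occ_trim <- mean(tl$present[-seq_len(n_burn), ])
  sem <- sd(colMeans(tl$present)) / sqrt(ncol(tl$present))
  expect_lt(abs(occ_full - occ_trim), 2 * sem)
})
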