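#' Configuration for the Brownian crowd generator
#'
#' Describes a system of spherical particles diffusing overdamped in a
#' cubic periodic box, optionally interacting through a smoothed
#' square-well pair potential (soft harmonic core plus an attractive well
#' whose outer edge is smoothed over `smoothing` A to keep the integrator
#' stable). Ground-truth stickiness is characterized by the second virial
#' coefficient of the actual smoothed potential, computed by quadrature,
#' not by the nominal well depth.
#'
#' @param n_molecules Number of particles.
#' @param radius Particle radius in A (scalar or per-particle vector).
#' @param D0 Free diffusion coefficient in A^2/ns (scalar).
#' @param dt Time step in ns.
#' @param n_steps Number of steps to record (after `n_equil`).
#' @param box_edge Box edge in A; either this or `phi` must be given.
#' @param phi Target volume fraction (box edge derived from it).
#' @param pair_potential "none" or "square-well".
#' @param epsilon Well depth in kB*T units (>= 0).
#' @param well_width Well width in A (surface-to-surface).
#' @param smoothing Width of the cosine smoothing band at the outer well
#'   edge, A.
#' @param core_k Harmonic core stiffness in kB*T / A^2.
#' @param temperature Temperature in K.
#' @param seed Integer RNG seed.
#' @param thin Record every `thin`-th step.
#' @param n_equil Equilibration steps discarded before recording.
#' @param pbc_mobility_reduction Logical; if TRUE the generator propagates
#'   particles with the reduced self-mobility a particle of this size would
#'   have in a periodic box of this edge under the implied Stokes solvent
#'   viscosity, so that the finite-size correction stage of the analysis
#'   pipeline restores exactly `D0`.
#' @return A validated `crowd_config` list.
#' @export
crowd_config <- function(n_molecules, radius, D0, dt, n_steps,
                         box_edge = NULL, phi = NULL,
                         pair_potential = c("none", "square-well"),
                         epsilon = 0, well_width = 3, smoothing = 1,
                         core_k = 10, temperature = crowd_units$temperature_default,
                         seed = 1, thin = 1L, n_equil = 0L,
                         pbc_mobility_reduction = TRUE) {
  pair_potential <- match.arg(pair_potential)
  radius <- rep_len(as.numeric(radius), n_molecules)
  vol_part <- sum(4 / 3 * pi * radius^3)
  if (is.null(box_edge)) {
    if (is.null(phi)) stop("give either `box_edge` or `phi`", call. = FALSE)
    box_edge <- (vol_part / phi)^(1 / 3)
  }
  phi_actual <- vol_part / box_edge^3
  if (phi_actual >= 0.45) {
    stop(sprintf("volume fraction %.3f exceeds the supported range (< 0.45)",
                 phi_actual), call. = FALSE)
  }
  if (sqrt(2 * D0 * dt) >= 0.1 * min(radius)) {
    stop("`dt` too large: RMS step must stay below 0.1 * min(radius)",
         call. = FALSE)
  }
  structure(list(
    n_molecules = as.integer(n_molecules), radius = radius, D0 = D0,
    dt = dt, n_steps = as.integer(n_steps), box_edge = box_edge,
    phi = phi_actual, pair_potential = pair_potential, epsilon = epsilon,
    well_width = well_width, smoothing = smoothing, core_k = core_k,
    temperature = temperature, seed = as.integer(seed),
    thin = as.integer(thin), n_equil = as.integer(n_equil),
    pbc_mobility_reduction = isTRUE(pbc_mobility_reduction)
  ), class = "crowd_config")
}

# Pair potential u(gap) in kBT and its derivative du/dgap, for
# surface-to-surface gap g = r - sigma. Harmonic core for g < 0, flat well
# of depth eps for 0 <= g <= w - s, cosine ramp to zero over [w - s, w].
pair_potential_fun <- function(config) {
  eps <- config$epsilon
  w <- config$well_width
  s <- min(config$smoothing, w)
  k <- config$core_k
  none <- config$pair_potential == "none"
  u <- function(g) {
    if (none) return(rep(0, length(g)))
    out <- numeric(length(g))
    core <- g < 0
    out[core] <- 0.5 * k * g[core]^2 - eps
    flat <- g >= 0 & g <= w - s
    out[flat] <- -eps
    ramp <- g > w - s & g < w
    out[ramp] <- -eps * 0.5 * (1 + cos(pi * (g[ramp] - (w - s)) / s))
    out
  }
  dudg <- function(g) {
    if (none) return(rep(0, length(g)))
    out <- numeric(length(g))
    core <- g < 0
    out[core] <- k * g[core]
    ramp <- g > w - s & g < w
    out[ramp] <- eps * 0.5 * pi / s * sin(pi * (g[ramp] - (w - s)) / s)
    out
  }
  list(u = u, dudg = dudg, r_cut = 2 * max(config$radius) + w)
}

#' Simulate an overdamped Brownian crowd
#'
#' Euler-Maruyama integration of x <- x + D_eff * f * dt + sqrt(2 D_eff dt) * xi
#' with minimum-image pair forces f (in kB*T/A) and periodic wrapping.
#' With `pbc_mobility_reduction` the propagated mobility is
#' D_eff = D0 - xi_cubic * kBT / (6 pi eta_nom L), where eta_nom is the
#' Stokes solvent viscosity implied by `D0` and the mean radius; the
#' analysis pipeline's finite-size correction then restores `D0` exactly in
#' expectation. Ground truth (D0, D_eff, eta_nom, B2 and Baxter tau of the
#' smoothed potential) is attached to the returned trajectory.
#'
#' @param config A [crowd_config].
#' @return A wrapped [trajectory] with `ground_truth` metadata.
#' @export
simulate_brownian_crowd <- function(config) {
  stopifnot(inherits(config, "crowd_config"))
  set.seed(config$seed)
  N <- config$n_molecules
  L <- config$box_edge
  a_mean <- mean(config$radius)
  eta_nom <- thermal_energy(config$temperature) / (6 * pi * config$D0 * a_mean)
  D_eff <- config$D0
  if (config$pbc_mobility_reduction) {
    D_eff <- config$D0 -
      2.837297 * thermal_energy(config$temperature) / (6 * pi * eta_nom * L)
    if (D_eff <= 0) stop("box too small: periodic mobility reduction exceeds D0",
                         call. = FALSE)
  }
  pot <- pair_potential_fun(config)
  sigma <- outer(config$radius, config$radius, `+`)

  # initial placement: uniform, with core overlaps relaxed for interacting runs
  x <- matrix(stats::runif(N * 3, 0, L), N, 3)
  if (config$pair_potential == "square-well") {
    for (rep in 1:200) {
      g <- pair_gaps(x, L, sigma)
      if (all(g$gap > -0.2)) break
      # push the worst overlapping pair apart along their separation vector
      i <- g$i[which.min(g$gap)]; j <- g$j[which.min(g$gap)]
      x[i, ] <- (x[i, ] + stats::runif(3, 0, L)) %% L
    }
  }

  n_total <- config$n_equil + config$n_steps
  n_out <- config$n_steps %/% config$thin
  com <- array(NA_real_, c(n_out, N, 3))
  sd_step <- sqrt(2 * D_eff * config$dt)
  out_i <- 0L

  if (config$pair_potential == "none") {
    # free diffusion: vectorized random walk
    steps <- array(stats::rnorm(n_total * N * 3, sd = sd_step), c(n_total, N, 3))
    for (d in 1:3) {
      inc <- steps[, , d]                     # n_total x N
      pos <- sweep(apply(inc, 2, cumsum), 2, x[, d], `+`)
      rec <- pos[(config$n_equil + 1):n_total, , drop = FALSE]
      rec <- rec[seq_len(n_out) * config$thin, , drop = FALSE]
      com[, , d] <- rec %% L
    }
  } else {
    s_eff <- min(config$smoothing, config$well_width)
    com <- .bd_run_cpp(x, config$radius, L, D_eff, config$dt,
                       config$epsilon, config$well_width, s_eff,
                       config$core_k, config$n_steps, config$n_equil,
                       config$thin)
    if (any(!is.finite(com))) {
      stop("instability in crowd simulation: use a smaller dt", call. = FALSE)
    }
    gap_last <- pair_gaps(com[dim(com)[1], , ], L, sigma)$gap
    if (any(gap_last < -0.5 * min(config$radius))) {
      stop("overlap explosion in crowd simulation: use a smaller dt", call. = FALSE)
    }
  }

  b2 <- b2_from_potential(pot$u, r_upper = pot$r_cut + 2,
                          sigma_ref = 2 * a_mean)
  times <- seq_len(n_out) * config$dt * config$thin
  trajectory(
    times = times, com = com, box = box_spec(L), wrapped = TRUE,
    radii = config$radius,
    ground_truth = list(
      D0 = config$D0, D_eff = D_eff, eta_nominal = eta_nom,
      epsilon = config$epsilon, phi = config$phi,
      B2 = b2, V_HS = 4 / 3 * pi * a_mean^3,
      tau_B = tryCatch(baxter_tau(b2, 4 / 3 * pi * a_mean^3),
                       error = function(e) Inf),
      seed = config$seed),
    provenance = list(generator = "simulate_brownian_crowd")
  )
}

# all-pairs minimum-image surface gaps; returns i, j, gap, and unit vectors
pair_gaps <- function(x, L, sigma) {
  N <- nrow(x)
  idx <- which(upper.tri(matrix(0, N, N)), arr.ind = TRUE)
  d <- x[idx[, 2], , drop = FALSE] - x[idx[, 1], , drop = FALSE]
  d <- minimum_image(d, L)
  r <- sqrt(rowSums(d^2))
  list(i = idx[, 1], j = idx[, 2], r = r,
       gap = r - sigma[idx], dvec = d)
}

# total force on each particle in kBT/A (F = -du/dr along the pair axis)
pair_forces <- function(x, L, sigma, pot) {
  N <- nrow(x)
  g <- pair_gaps(x, L, sigma)
  act <- which(g$gap < pot$r_cut)  # only pairs within interaction range
  f <- matrix(0, N, 3)
  if (!length(act)) return(f)
  dudg <- pot$dudg(g$gap[act])
  nz <- which(dudg != 0)
  if (!length(nz)) return(f)
  act <- act[nz]; dudg <- dudg[nz]
  unit <- g$dvec[act, , drop = FALSE] / g$r[act]
  fij <- -dudg * unit                     # force on particle j (at +dvec)
  for (k in seq_along(act)) {
    i <- g$i[act[k]]; j <- g$j[act[k]]
    f[j, ] <- f[j, ] + fij[k, ]
    f[i, ] <- f[i, ] - fij[k, ]
  }
  f
}

#' Second virial coefficient of a pair potential by quadrature
#'
#' B2 = 2 pi * integral 0..r_upper of (1 - exp(-u(r))) r^2 dr with u in
#' kB*T units. Used as the ground-truth stickiness of the synthetic crowd.
#'
#' @param u Function gap -> potential in kBT; called with `r - sigma_ref`.
#' @param r_upper Upper integration limit (A), beyond the interaction range.
#' @param sigma_ref Contact distance (A) at which the gap is zero.
#' @return B2 in A^3.
#' @export
b2_from_potential <- function(u, r_upper, sigma_ref) {
  integrand <- function(r) (1 - exp(-u(r - sigma_ref))) * r^2
  2 * pi * stats::integrate(integrand, 0, r_upper, subdivisions = 2000L,
                            rel.tol = 1e-8)$value
}
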