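#' Mean-square displacement of molecular centers of mass
#'
#' MSD(dt) averaged over all time origins (FFT algorithm) and over the
#' selected molecules, with a SEM across molecules. The trajectory must be
#' unwrapped first; wrapped input is rejected.
#'
#' @param traj An unwrapped [trajectory].
#' @param molecules Integer vector of molecule indices (default all).
#' @param max_lag Maximum lag in ns (default half the span).
#' @return A [crowd_ts] of MSD values in A^2; attribute `per_molecule`
#'   carries the `[lag, molecule]` matrix.
#' @export
compute_msd <- function(traj, molecules = NULL, max_lag = NULL) {
  stopifnot(inherits(traj, "crowd_trajectory"))
  if (traj$wrapped) {
    stop("trajectory is wrapped: call unwrap_positions() first", call. = FALSE)
  }
  if (is.null(molecules)) molecules <- seq_len(n_molecules(traj))
  dt <- traj$times[2] - traj$times[1]
  n <- length(traj$times)
  k_max <- if (is.null(max_lag)) (n - 1L) %/% 2L else min(n - 1L, round(max_lag / dt))
  per <- matrix(0, k_max + 1L, length(molecules))
  for (m in seq_along(molecules)) {
    for (d in 1:3) {
      per[, m] <- per[, m] + msd_fft_1d(traj$com[, molecules[m], d], k_max)
    }
  }
  sem <- if (length(molecules) > 1) {
    apply(per, 1, stats::sd) / sqrt(length(molecules))
  } else NULL
  out <- crowd_ts((0:k_max) * dt, rowMeans(per), sem, unit = "A^2")
  attr(out, "per_molecule") <- per
  out
}

#' Translational diffusion coefficient from an MSD curve
#'
#' Weighted linear fit MSD = 6 D t + c over the given lag window. The
#' intercept is free: it absorbs short-time anomalous behavior. The
#' standard error comes from the scatter of per-molecule slopes when the
#' curve carries them (the statistically honest route, since MSD points at
#' neighboring lags are strongly correlated), else from the linear fit.
#'
#' @param msd A [crowd_ts] from [compute_msd].
#' @param window Lag window (lo, hi) in ns, default c(2, 10).
#' @return A `transport_estimate` with value `D` (A^2/ns), `se`,
#'   `intercept`, `window`, and a correction `ledger`.
#' @export
fit_Dt <- function(msd, window = c(2, 10)) {
  stopifnot(inherits(msd, "crowd_ts"))
  sel <- msd$lags >= window[1] & msd$lags <= window[2]
  if (sum(sel) < 5) stop("fit window must contain at least 5 lag points", call. = FALSE)
  t <- msd$lags[sel]
  y <- msd$values[sel]
  w <- if (!is.null(msd$sem) && all(msd$sem[sel] > 0)) 1 / msd$sem[sel]^2 else NULL
  fit <- stats::lm(y ~ t, weights = w)
  D <- unname(stats::coef(fit)[2]) / 6
  per <- attr(msd, "per_molecule")
  se <- if (!is.null(per) && ncol(per) > 1) {
    slopes <- apply(per[sel, , drop = FALSE], 2,
                    function(col) stats::coef(stats::lm(col ~ t))[2]) / 6
    stats::sd(slopes) / sqrt(ncol(per))
  } else unname(suppressWarnings(summary(fit))$coefficients[2, 2]) / 6
  transport_estimate(D, se,
                     ledger = list(list(stage = "msd_fit", D = D, se = se,
                                        window = window,
                                        intercept = unname(stats::coef(fit)[1]))))
}

#' Transport estimate with a correction ledger
#'
#' A diffusion (or viscosity) value with uncertainty and an append-only
#' ledger of correction stages, each recording its inputs and arithmetic
#' so the final value can be reproduced from the ledger alone (see
#' [replay_ledger]).
#'
#' @param value Estimate in working units.
#' @param se Standard error.
#' @param ledger List of stage records.
#' @return An object of class `transport_estimate`.
#' @export
transport_estimate <- function(value, se = NA_real_, ledger = list()) {
  structure(list(value = value, se = se, ledger = ledger),
            class = "transport_estimate")
}

#' @export
print.transport_estimate <- function(x, ...) {
  cat(sprintf("<transport_estimate> %.5g +/- %.2g (%d ledger stages)\n",
              x$value, x$se, length(x$ledger)))
  for (st in x$ledger) cat(sprintf("  - %s\n", st$stage))
  invisible(x)
}

#' Recompute a transport estimate from its ledger
#'
#' Replays the recorded stages (base value, additive corrections,
#' multiplicative rescalings) and returns the reconstructed value; used to
#' assert that every correction is fully auditable.
#'
#' @param est A `transport_estimate`.
#' @return The value reconstructed from the ledger.
#' @export
replay_ledger <- function(est) {
  stopifnot(inherits(est, "transport_estimate"))
  v <- NA_real_
  for (st in est$ledger) {
    v <- switch(st$stage,
                msd_fit = st$D,
                p2_fit = st$D,
                base = st$value,
                pbc_correction_t = v + st$delta,
                pbc_correction_r = v + st$delta,
                water_rescale = v * st$factor,
                stop("unknown ledger stage: ", st$stage))
  }
  v
}

as_transport <- function(x) {
  if (inherits(x, "transport_estimate")) x else
    transport_estimate(x, NA_real_, list(list(stage = "base", value = x)))
}

#' Finite-size correction for translational diffusion
#'
#' Adds the leading periodic-box hydrodynamic correction
#' xi * kB * T / (6 pi eta L) with the cubic-lattice constant
#' xi = 2.837297. For crowded systems `eta` is that system's computed
#' viscosity; for effectively dilute systems the salt-water reference
#' (0.347 cP) is the conventional choice. An optional higher-order term in
#' the particle radius is available behind `higher_order` (default off).
#'
#' @param D `transport_estimate` or numeric D_PBC in A^2/ns.
#' @param eta Viscosity in cP (required).
#' @param L Box edge in A.
#' @param temperature Temperature in K.
#' @param xi Lattice constant of the correction (default 2.837297).
#' @param Rp Particle radius in A (recorded; used only by `higher_order`).
#' @param higher_order Logical; include the -(4 pi/3) Rp^2 / L^3 term.
#' @return The updated `transport_estimate` (correction appended to the
#'   ledger).
#' @export
finite_size_correction_t <- function(D, eta, L,
                                     temperature = crowd_units$temperature_default,
                                     xi = 2.837297, Rp = NULL,
                                     higher_order = FALSE) {
  if (missing(eta) || is.null(eta) || !is.finite(eta) || eta <= 0) {
    stop("`eta` is required (system viscosity, or the dilute salt-water reference 0.347 cP)",
         call. = FALSE)
  }
  if (L <= 0) stop("`L` must be positive", call. = FALSE)
  est <- as_transport(D)
  kbt <- thermal_energy(temperature)
  delta <- xi * kbt / (6 * pi * eta * L)
  if (isTRUE(higher_order)) {
    if (is.null(Rp)) stop("`Rp` required for the higher-order term", call. = FALSE)
    delta <- delta - kbt / (6 * pi * eta) * (4 * pi / 3) * Rp^2 / L^3
  }
  est$value <- est$value + delta
  est$ledger <- c(est$ledger,
                  list(list(stage = "pbc_correction_t", delta = delta,
                            eta = eta, L = L, temperature = temperature,
                            xi = xi, Rp = Rp, higher_order = higher_order)))
  est
}

#' Water-model viscosity rescaling
#'
#' Multiplies a finite-size-corrected diffusion coefficient by
#' eta_model / eta_exp to compensate for the underestimated solvent
#' viscosity of the simulation water model (defaults: TIP3P pure water
#' 0.334 cP vs experimental 0.89 cP). The pipeline order is
#' correct-then-rescale.
#'
#' @param D `transport_estimate` or numeric value.
#' @param eta_model Model-water viscosity in cP (default 0.334).
#' @param eta_exp Experimental water viscosity in cP (default 0.89).
#' @return The updated `transport_estimate`.
#' @export
water_model_rescale <- function(D, eta_model = 0.334, eta_exp = 0.89) {
  if (eta_model <= 0 || eta_exp <= 0) {
    stop("viscosities must be positive", call. = FALSE)
  }
  est <- as_transport(D)
  factor <- eta_model / eta_exp
  est$value <- est$value * factor
  if (is.finite(est$se)) est$se <- est$se * factor
  est$ledger <- c(est$ledger,
                  list(list(stage = "water_rescale", factor = factor,
                            eta_model = eta_model, eta_exp = eta_exp)))
  est
}

#' Rotational diffusion constant from the overall relaxation time
#' @param tau_overall Overall P2 relaxation time in ns (> 0).
#' @return D_r in 1/ns: 1 / (6 tau).
#' @export
Dr_from_tau <- function(tau_overall) {
  if (any(tau_overall <= 0)) stop("`tau_overall` must be positive", call. = FALSE)
  1 / (6 * tau_overall)
}

#' Finite-size correction for rotational diffusion
#'
#' Adds the leading periodic-box correction kB*T / (6 eta L^3) (prefactor
#' exposed through `c_box`), using the same viscosity conventions as the
#' translational correction.
#'
#' @param Dr `transport_estimate` or numeric D_r,PBC in 1/ns.
#' @param eta Viscosity in cP (required).
#' @param L Box edge in A.
#' @param temperature Temperature in K.
#' @param c_box Numerator constant of the correction (default 1/6).
#' @return The updated `transport_estimate`.
#' @export
finite_size_correction_r <- function(Dr, eta, L,
                                     temperature = crowd_units$temperature_default,
                                     c_box = 1 / 6) {
  if (missing(eta) || is.null(eta) || !is.finite(eta) || eta <= 0) {
    stop("`eta` is required (system viscosity, or the dilute salt-water reference 0.347 cP)",
         call. = FALSE)
  }
  if (L <= 0) stop("`L` must be positive", call. = FALSE)
  est <- as_transport(Dr)
  delta <- c_box * thermal_energy(temperature) / (eta * L^3)
  est$value <- est$value + delta
  est$ledger <- c(est$ledger,
                  list(list(stage = "pbc_correction_r", delta = delta,
                            eta = eta, L = L, temperature = temperature,
                            c_box = c_box)))
  est
}

#' Hydrodynamic radius from a diffusion coefficient
#'
#' Stokes-Einstein inversions: translational R_h = kB T / (6 pi eta D_t);
#' rotational R_h = (kB T / (8 pi eta D_r))^(1/3).
#'
#' @param D Diffusion coefficient (A^2/ns translational, 1/ns rotational)
#'   or a `transport_estimate`.
#' @param eta Viscosity in cP.
#' @param temperature Temperature in K.
#' @param kind "translational" or "rotational".
#' @return Hydrodynamic radius in A.
#' @export
hydrodynamic_radius <- function(D, eta,
                                temperature = crowd_units$temperature_default,
                                kind = c("translational", "rotational")) {
  kind <- match.arg(kind)
  if (inherits(D, "transport_estimate")) D <- D$value
  if (D <= 0 || eta <= 0) stop("`D` and `eta` must be positive", call. = FALSE)
  kbt <- thermal_energy(temperature)
  if (kind == "translational") kbt / (6 * pi * eta * D)
  else (kbt / (8 * pi * eta * D))^(1 / 3)
}
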