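#' Mean stress autocorrelation across channels and replicas
#'
#' Per replica, the raw (not mean-removed) autocorrelation of every
#' stress channel, averaged over channels; then the cross-replica mean
#' and standard deviation. Raw products are used because any nonzero mean
#' shear stress belongs in the Green-Kubo integrand; a mean much larger
#' than the fluctuation scale is reported as a data-quality warning
#' rather than silently subtracted.
#'
#' @param replicas List of [stress_series] with identical volume,
#'   temperature and sampling interval.
#' @param max_lag Maximum lag in ns.
#' @return A `stress_acf` object: lag grid `tau` (ns), per-replica matrix
#'   `per_replica` `[replica, lag]`, pooled `mean` and `sigma`, plus the
#'   shared metadata.
#' @export
stress_acf_mean <- function(replicas, max_lag) {
  stopifnot(length(replicas) >= 1,
            all(vapply(replicas, inherits, TRUE, "stress_series")))
  V <- vapply(replicas, function(r) r$volume, 0)
  T_ <- vapply(replicas, function(r) r$temperature, 0)
  dt <- vapply(replicas, function(r) r$dt, 0)
  if (length(unique(V)) > 1 || length(unique(T_)) > 1 ||
      max(abs(dt - dt[1])) > 1e-12) {
    stop("replicas must share volume, temperature and sampling interval",
         call. = FALSE)
  }
  dt <- dt[1]
  n <- nrow(replicas[[1]]$channels)
  k_max <- min(n - 1L, round(max_lag / dt))
  per <- matrix(NA_real_, length(replicas), k_max + 1L)
  norm <- n - 0:k_max
  for (r in seq_along(replicas)) {
    ch <- replicas[[r]]$channels
    mu <- mean(abs(colMeans(ch)))
    if (is.finite(mu) && mu > 0.3 * stats::sd(ch)) {
      warning("nonzero mean stress detected; check input data quality",
              call. = FALSE)
    }
    s <- acf_sums_fft_matrix(ch, k_max)
    per[r, ] <- rowMeans(s / norm)
  }
  structure(list(tau = (0:k_max) * dt, per_replica = per,
                 mean = colMeans(per),
                 sigma = apply(per, 2, stats::sd),
                 volume = V[1], temperature = T_[1], dt = dt),
            class = "stress_acf")
}

#' Green-Kubo running viscosity integral
#'
#' eta(tau) = V/(kB T) * integral_0^tau <P(0) P(t')> dt' by the trapezoid
#' rule, converted to cP. Applied to a single ACF it returns the running
#' integral as a [crowd_ts]; applied to a `stress_acf` it returns a
#' `running_integral` with per-replica curves, cross-replica mean and
#' standard deviation sigma(tau).
#'
#' @param acf A [crowd_ts] of raw stress ACF values (bar^2) with lags in
#'   ns, or a `stress_acf` from [stress_acf_mean].
#' @param volume Box volume in A^3 (taken from a `stress_acf`).
#' @param temperature Temperature in K (taken from a `stress_acf`).
#' @return A [crowd_ts] (single ACF) or `running_integral` object.
#' @export
green_kubo_integral <- function(acf, volume = NULL, temperature = NULL) {
  if (inherits(acf, "stress_acf")) {
    pref <- gk_prefactor(acf$volume, acf$temperature)
    eta <- t(apply(acf$per_replica, 1,
                   function(v) pref * pracma::cumtrapz(acf$tau, v)[, 1]))
    structure(list(tau = acf$tau, eta = eta, mean = colMeans(eta),
                   sigma = apply(eta, 2, stats::sd),
                   n_replicas = nrow(eta)),
              class = "running_integral")
  } else {
    stopifnot(inherits(acf, "crowd_ts"))
    if (is.null(volume) || is.null(temperature)) {
      stop("`volume` and `temperature` are required", call. = FALSE)
    }
    pref <- gk_prefactor(volume, temperature)
    crowd_ts(acf$lags, pref * pracma::cumtrapz(acf$lags, acf$values)[, 1],
             unit = "cP")
  }
}

#' @export
print.running_integral <- function(x, ...) {
  cat(sprintf(
    "<running_integral> %d replicas, tau up to %g ps, eta(tau_end) = %.4g cP\n",
    x$n_replicas, max(x$tau) * 1e3, x$mean[length(x$mean)]))
  invisible(x)
}

#' Power-law growth of the cross-replica uncertainty
#'
#' Fits sigma(tau) = A * tau^b by least squares on log sigma vs log tau
#' over tau in (0, tau_max], as a metric for how the uncertainty of the
#' running integral grows with integration time.
#'
#' @param ri A `running_integral`.
#' @param tau_max Upper end of the fit range in ns (default: full grid).
#' @return List with `A`, `b` (tau in ns).
#' @export
fit_sigma_power <- function(ri, tau_max = NULL) {
  stopifnot(inherits(ri, "running_integral"))
  if (is.null(tau_max)) tau_max <- max(ri$tau)
  sel <- ri$tau > 0 & ri$tau <= tau_max & ri$sigma > 0
  if (sum(sel) < 2) {
    stop("sigma(tau) is degenerate (identically zero?)", call. = FALSE)
  }
  fit <- stats::lm(log(ri$sigma[sel]) ~ log(ri$tau[sel]))
  list(A = exp(unname(stats::coef(fit)[1])), b = unname(stats::coef(fit)[2]))
}

#' Extrapolate the running viscosity integral to infinite time
#'
#' Fits eta(tau) = eta_inf * (alpha (1 - exp(-tau/tau1)) +
#' (1 - alpha)(1 - exp(-tau/tau2))) to the cross-replica mean running
#' integral up to `tau_max`, weighted by 1/sigma(tau), and reports
#' eta_inf with a bootstrap-over-replicas uncertainty.
#'
#' @param ri A `running_integral`.
#' @param tau_max Fit range upper limit in ns.
#' @param n_boot Bootstrap resamples over replicas (default 200).
#' @param max_fit_points Grid thinning bound for the fit (default 1200).
#' @return A `viscosity_estimate`: eta (cP), se, tau_max, power-law (A, b),
#'   double-exponential parameters, n_replicas.
#' @export
extrapolate_viscosity <- function(ri, tau_max, n_boot = 200,
                                  max_fit_points = 1200) {
  stopifnot(inherits(ri, "running_integral"))
  if (tau_max > max(ri$tau) + 1e-12) {
    stop("`tau_max` exceeds the integral grid", call. = FALSE)
  }
  pw <- tryCatch(fit_sigma_power(ri, tau_max),
                 error = function(e) list(A = 0, b = NA_real_))
  sel <- which(ri$tau > 0 & ri$tau <= tau_max)
  sel <- sel[unique(round(seq(1, length(sel),
                              length.out = min(length(sel), max_fit_points))))]
  tau <- ri$tau[sel]
  sig <- ri$sigma[sel]
  w <- if (max(sig) > 0) 1 / pmax(sig, max(sig) * 1e-3) else rep(1, length(sig))
  fit_once <- function(y, par0 = NULL) {
    starts <- if (is.null(par0)) {
      tail_eta <- mean(y[tau > 0.8 * tau_max])
      list(c(tail_eta, 0.5, log(tau_max / 30), log(tau_max / 3)),
           c(tail_eta, 0.8, log(tau_max / 100), log(tau_max / 5)),
           c(tail_eta, 0.3, log(tau_max / 10), log(tau_max)))
    } else list(par0)
    best <- NULL
    for (p0 in starts) {
      f <- tryCatch(minpack.lm::nls.lm(
        par = p0,
        fn = function(p) {
          pred <- p[1] * (p[2] * (1 - exp(-tau / exp(p[3]))) +
                            (1 - p[2]) * (1 - exp(-tau / exp(p[4]))))
          w * (y - pred)
        },
        lower = c(1e-12, 0, log(min(tau) / 10), log(min(tau) / 10)),
        upper = c(Inf, 1, log(tau_max * 1e3), log(tau_max * 1e3)),
        control = minpack.lm::nls.lm.control(maxiter = 300)),
        error = function(e) NULL)
      # info 1-4: converged; 5-7: iteration/tolerance limits with usable
      # parameters (e.g. on non-saturating input); 0: improper input
      if (!is.null(f) && f$info >= 1 &&
          (is.null(best) || sum(f$fvec^2) < sum(best$fvec^2))) best <- f
    }
    best
  }
  fit <- fit_once(ri$mean[sel])
  if (is.null(fit)) {
    stop(sprintf(
      "double-exponential extrapolation failed; plateau at tau_max = %.4g cP",
      ri$mean[max(sel)]), call. = FALSE)
  }
  boots <- rep(NA_real_, n_boot)
  R <- ri$n_replicas
  for (b in seq_len(n_boot)) {
    idx <- sample.int(R, R, replace = TRUE)
    yb <- colMeans(ri$eta[idx, sel, drop = FALSE])
    fb <- fit_once(yb, par0 = fit$par)
    if (!is.null(fb)) boots[b] <- fb$par[1]
  }
  structure(list(
    eta = fit$par[1],
    se = stats::sd(boots, na.rm = TRUE),
    tau_max = tau_max,
    power_law = pw,
    dexp = list(alpha = fit$par[2], tau1 = exp(fit$par[3]),
                tau2 = exp(fit$par[4])),
    n_replicas = R,
    converged = TRUE),
    class = "viscosity_estimate")
}

#' @export
print.viscosity_estimate <- function(x, ...) {
  cat(sprintf(
    "<viscosity_estimate> eta = %.4g +/- %.2g cP (tau_max = %g ps, %d replicas%s)\n",
    x$eta, x$se, x$tau_max * 1e3, x$n_replicas,
    if (isTRUE(x$converged)) "" else ", UNCONVERGED"))
  invisible(x)
}

#' Select the integration cutoff tau_max
#'
#' Evaluates the extrapolated viscosity for increasing candidate cutoffs
#' and returns the smallest candidate whose estimate agrees with the next
#' one within combined uncertainties. If no candidate stabilizes, the
#' largest is returned flagged unconverged.
#'
#' @param ri A `running_integral`.
#' @param candidates Increasing cutoffs in ns (default
#'   c(25, 50, 75, 100, 150, 200)/1000, i.e. 25-200 ps).
#' @param n_boot Bootstrap resamples per candidate (default 50).
#' @param ... Passed to [extrapolate_viscosity].
#' @return The selected `viscosity_estimate` (fields `tau_max`,
#'   `converged`, `candidates` record the protocol).
#' @export
select_tau_max <- function(ri, candidates = c(25, 50, 75, 100, 150, 200) / 1000,
                           n_boot = 50, ...) {
  candidates <- candidates[candidates <= max(ri$tau) + 1e-12]
  if (length(candidates) < 3) {
    stop("need >= 3 candidate tau_max values within the grid", call. = FALSE)
  }
  ests <- lapply(candidates, function(tm)
    tryCatch(extrapolate_viscosity(ri, tm, n_boot = n_boot, ...),
             error = function(e) NULL))
  ok <- !vapply(ests, is.null, TRUE)
  if (!any(ok)) {
    stop("extrapolation failed for every candidate tau_max", call. = FALSE)
  }
  sel <- NULL
  for (i in seq_len(length(ests) - 1L)) {
    if (!ok[i] || !ok[i + 1]) next
    # the 1e-3 relative term floors the criterion at the numerical fit
    # tolerance so noiseless input stabilizes at the first candidate
    if (abs(ests[[i]]$eta - ests[[i + 1]]$eta) <=
        ests[[i]]$se + ests[[i + 1]]$se + 1e-3 * abs(ests[[i + 1]]$eta)) {
      sel <- i
      break
    }
  }
  out <- if (is.null(sel)) {
    e <- ests[[max(which(ok))]]
    e$converged <- FALSE
    e
  } else ests[[sel]]
  out$candidates <- data.frame(
    tau_max = candidates,
    eta = vapply(ests, function(e) if (is.null(e)) NA_real_ else e$eta, 0),
    se = vapply(ests, function(e) if (is.null(e)) NA_real_ else e$se, 0))
  out
}

#' Relative viscosity
#' @param eta Viscosity in cP.
#' @param eta_ref Reference viscosity in cP (> 0).
#' @return Dimensionless ratio eta / eta_ref.
#' @export
relative_viscosity <- function(eta, eta_ref) {
  if (any(eta_ref <= 0)) stop("`eta_ref` must be positive", call. = FALSE)
  eta / eta_ref
}

#' Full Green-Kubo viscosity pipeline
#'
#' Replicate stress series -> channel-averaged ACFs -> running integrals
#' -> tau_max selection -> weighted double-exponential extrapolation.
#'
#' @param replicas List of [stress_series].
#' @param max_lag ACF length in ns (default 0.2, i.e. 200 ps).
#' @param candidates Candidate tau_max grid in ns.
#' @param ... Passed to [select_tau_max].
#' @return A `viscosity_estimate`.
#' @export
green_kubo_viscosity <- function(replicas, max_lag = 0.2,
                                 candidates = c(25, 50, 75, 100, 150, 200) / 1000,
                                 ...) {
  acf <- stress_acf_mean(replicas, max_lag)
  ri <- green_kubo_integral(acf)
  select_tau_max(ri, candidates = candidates, ...)
}
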