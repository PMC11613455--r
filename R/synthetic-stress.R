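#' Configuration for the Ornstein-Uhlenbeck stress generator
#'
#' Each replica carries `n_channels` independent stationary OU channels
#' standing in for the off-diagonal / deviatoric pressure-tensor
#' components of a short equilibrium run. The stationary covariance is
#' chosen so that <P(0)P(t)> = (eta * kB * T / (V * tau_c)) * exp(-t/tau_c)
#' in working units (bar^2), hence the Green-Kubo integral equals
#' `eta_target` exactly in expectation.
#'
#' @param eta_target Target viscosity in cP (> 0; 0 gives all-zero series).
#' @param tau_c Stress relaxation time in ns (typically ~1e-3, i.e. 1 ps).
#' @param volume Box volume in A^3.
#' @param temperature Temperature in K.
#' @param dt Sampling interval in ns (fs-scale).
#' @param n_samples Samples per replica.
#' @param n_replicas Number of replicas (>= 2).
#' @param n_channels Independent stress channels per replica.
#' @param seed Integer RNG seed.
#' @return A validated `stress_sim_config` list.
#' @export
stress_sim_config <- function(eta_target, tau_c, volume,
                              temperature = crowd_units$temperature_default,
                              dt, n_samples, n_replicas, n_channels = 5L,
                              seed = 1) {
  if (eta_target < 0 || tau_c <= 0 || volume <= 0) {
    stop("`eta_target` must be >= 0 and `tau_c`, `volume` > 0", call. = FALSE)
  }
  if (n_replicas < 2) stop("`n_replicas` must be >= 2", call. = FALSE)
  structure(list(eta_target = eta_target, tau_c = tau_c, volume = volume,
                 temperature = temperature, dt = dt,
                 n_samples = as.integer(n_samples),
                 n_replicas = as.integer(n_replicas),
                 n_channels = as.integer(n_channels),
                 seed = as.integer(seed)),
            class = "stress_sim_config")
}

#' A replica of off-diagonal pressure-tensor samples
#'
#' @param channels Numeric matrix `[sample, channel]` in bar.
#' @param dt Sampling interval in ns.
#' @param volume Box volume in A^3.
#' @param temperature Temperature in K.
#' @param replica_id Identifier.
#' @return An object of class `stress_series`.
#' @export
stress_series <- function(channels, dt, volume, temperature, replica_id = 1L) {
  channels <- as.matrix(channels)
  if (ncol(channels) < 1) stop("at least one channel required", call. = FALSE)
  if (any(!is.finite(channels))) stop("non-finite stress values", call. = FALSE)
  structure(list(channels = channels, dt = dt, volume = volume,
                 temperature = temperature, replica_id = replica_id),
            class = "stress_series")
}

#' @export
print.stress_series <- function(x, ...) {
  cat(sprintf("<stress_series> replica %s: %d samples x %d channels, dt = %g ns\n",
              x$replica_id, nrow(x$channels), ncol(x$channels), x$dt))
  invisible(x)
}

#' Simulate replicate OU stress series
#'
#' Exact OU discretization: x[n+1] = rho * x[n] + sqrt(c0 (1 - rho^2)) xi
#' with rho = exp(-dt / tau_c) and stationary variance
#' c0 = eta * kB T / (V tau_c) expressed in bar^2. Initial samples are
#' drawn from the stationary distribution, so each series is stationary
#' from the first sample.
#'
#' @param config A [stress_sim_config].
#' @return A list of `n_replicas` [stress_series] objects with the
#'   ground-truth parameters attached as an attribute.
#' @export
simulate_stress_ou <- function(config) {
  stopifnot(inherits(config, "stress_sim_config"))
  set.seed(config$seed)
  kbt_J <- crowd_units$kB_SI * config$temperature
  # invert the Green-Kubo prefactor: c0 [bar^2] s.t. c0 * tau_c * gk = eta
  c0 <- config$eta_target / (gk_prefactor(config$volume, config$temperature) *
                               config$tau_c)
  rho <- exp(-config$dt / config$tau_c)
  n <- config$n_samples
  out <- vector("list", config$n_replicas)
  for (r in seq_len(config$n_replicas)) {
    ch <- matrix(0, n, config$n_channels)
    if (config$eta_target > 0) {
      for (j in seq_len(config$n_channels)) {
        innov <- stats::rnorm(n, sd = sqrt(c0 * (1 - rho^2)))
        innov[1] <- stats::rnorm(1, sd = sqrt(c0))
        ch[, j] <- stats::filter(innov, rho, method = "recursive",
                                 init = 0)
      }
    }
    out[[r]] <- stress_series(ch, config$dt, config$volume,
                              config$temperature, replica_id = r)
  }
  attr(out, "ground_truth") <- list(eta = config$eta_target,
                                    tau_c = config$tau_c, c0_bar2 = c0,
                                    seed = config$seed)
  out
}
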