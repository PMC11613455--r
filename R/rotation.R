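#' P2 orientational autocorrelation
#'
#' C(t) = < P2(v(0) . v(t)) > with P2(x) = (3 x^2 - 1)/2, averaged over
#' body-fixed unit vectors and time origins. Two input routes:
#'
#' * an `orientation_trajectory` (vectors already rigidly attached to the
#'   body frame), used directly;
#' * a [trajectory] with atom coordinates and a C-alpha map for the probe:
#'   `n_vectors` random unit vectors are attached to the first frame, and
#'   for every frame the least-squares rigid-body rotation (Kabsch) that
#'   superposes the probe's C-alpha set onto the first frame also rotates
#'   the vectors, following the random-vector protocol.
#'
#' @param x An `orientation_trajectory` or a [trajectory].
#' @param probe Probe molecule index (trajectory route).
#' @param n_vectors Number of random vectors (trajectory route,
#'   default 1000).
#' @param seed Seed for the random vectors (trajectory route).
#' @param lag_grid Optional lag grid in ns (default: log grid, 24 points
#'   per decade up to half the span).
#' @param origin_stride Time-origin stride in frames (default: auto, at
#'   most ~5000 origins).
#' @return A [crowd_ts] with SEM across vectors.
#' @export
p2_acf <- function(x, probe = NULL, n_vectors = 1000, seed = 1,
                   lag_grid = NULL, origin_stride = NULL) {
  if (inherits(x, "orientation_trajectory")) {
    times <- x$times
    vec <- x$vectors
  } else if (inherits(x, "crowd_trajectory")) {
    if (is.null(x$atoms) || is.null(x$calpha_index) || is.null(probe)) {
      stop("trajectory route needs atoms, a C-alpha map, and a probe", call. = FALSE)
    }
    ca <- x$calpha_index[[probe]]
    ref <- x$atoms[1, ca, , drop = TRUE]
    if (qr(scale(ref, scale = FALSE))$rank < 2) {
      stop("degenerate (collinear) reference atoms", call. = FALSE)
    }
    set.seed(seed)
    v0 <- random_unit_vectors(n_vectors)
    n_f <- length(x$times)
    vec <- array(NA_real_, c(n_f, n_vectors, 3))
    for (f in seq_len(n_f)) {
      R <- kabsch_rotation(x$atoms[f, ca, , drop = TRUE], ref)
      vec[f, , ] <- v0 %*% t(R)
    }
    times <- x$times
  } else stop("unsupported input", call. = FALSE)

  dt <- times[2] - times[1]
  n_f <- dim(vec)[1]
  n_v <- dim(vec)[2]
  if (is.null(lag_grid)) {
    lag_grid <- log_lag_grid(dt, (n_f - 1) * dt / 2, points_per_decade = 24)
  }
  k_grid <- unique(round(lag_grid / dt))
  k_grid <- sort(k_grid[k_grid >= 0 & k_grid < n_f])
  if (is.null(origin_stride)) origin_stride <- max(1L, n_f %/% 5000L)

  cmat <- matrix(NA_real_, length(k_grid), n_v)
  for (ki in seq_along(k_grid)) {
    k <- k_grid[ki]
    orig <- seq(1L, n_f - k, by = origin_stride)
    for (v in seq_len(n_v)) {
      dots <- rowSums(matrix(vec[orig, v, ], ncol = 3) *
                        matrix(vec[orig + k, v, ], ncol = 3))
      cmat[ki, v] <- mean((3 * dots^2 - 1) / 2)
    }
  }
  crowd_ts(k_grid * dt, rowMeans(cmat),
           if (n_v > 1) apply(cmat, 1, stats::sd) / sqrt(n_v) else NULL)
}

#' Least-squares rigid-body rotation (Kabsch)
#'
#' Rotation matrix that best superposes the centered coordinate set `a`
#' onto the centered set `b`.
#'
#' @param a,b n x 3 coordinate matrices (same atom order).
#' @return A 3 x 3 rotation matrix R with R %*% centered-a ~ centered-b.
#' @export
kabsch_rotation <- function(a, b) {
  a <- sweep(as.matrix(a), 2, colMeans(a))
  b <- sweep(as.matrix(b), 2, colMeans(b))
  s <- svd(crossprod(b, a))          # 3x3: t(b) %*% a
  d <- sign(det(s$u %*% t(s$v)))
  s$u %*% diag(c(1, 1, d)) %*% t(s$v)
}

#' Double-exponential fit of a P2 autocorrelation
#'
#' Fits C(t) = a exp(-t/tau_a) + (1 - a) exp(-t/tau_b) with a in [0, 1]
#' over the given window (default 0-20 ns, chosen to avoid poor long-lag
#' statistics), by weighted Levenberg-Marquardt with multi-start. The
#' overall relaxation time is the amplitude-weighted mean
#' tau_overall = a tau_a + (1 - a) tau_b, which equals the time integral
#' of the fitted normalized correlation function.
#'
#' @param acf A [crowd_ts] from [p2_acf].
#' @param window Fit window in ns (default c(0, 20)).
#' @return A `rotational_fit`: amplitudes/times, `tau_overall` (ns), and
#'   `Dr_pbc` = 1/(6 tau_overall) in 1/ns.
#' @export
fit_p2 <- function(acf, window = c(0, 20)) {
  stopifnot(inherits(acf, "crowd_ts"))
  x <- ts_window(acf, window)
  t <- x$lags; y <- x$values
  if (length(t) < 6) stop("fit window contains too few points", call. = FALSE)
  w <- if (!is.null(x$sem) && all(x$sem > 0)) 1 / x$sem else rep(1, length(t))
  tpos <- t[t > 0]
  tau_guess <- tryCatch({
    below <- t[which(y < exp(-1))[1]]
    if (is.na(below) || below <= 0) max(tpos) / 3 else below
  }, error = function(e) max(tpos) / 3)
  starts <- list(c(0.5, log(tau_guess), log(tau_guess / 5)),
                 c(0.8, log(tau_guess * 2), log(tau_guess / 10)),
                 c(0.3, log(tau_guess), log(tau_guess)))
  best <- NULL
  for (p0 in starts) {
    f <- tryCatch(minpack.lm::nls.lm(
      par = p0,
      fn = function(p) {
        pred <- p[1] * exp(-t / exp(p[2])) + (1 - p[1]) * exp(-t / exp(p[3]))
        w * (y - pred)
      },
      lower = c(0, log(min(tpos) / 100), log(min(tpos) / 100)),
      upper = c(1, log(max(t) * 100), log(max(t) * 100)),
      control = minpack.lm::nls.lm.control(maxiter = 300)),
      error = function(e) NULL)
    if (!is.null(f) && f$info >= 1 && f$info <= 4 &&
        (is.null(best) || sum(f$fvec^2) < sum(best$fvec^2))) best <- f
  }
  if (is.null(best)) stop("P2 double-exponential fit failed", call. = FALSE)
  a <- best$par[1]
  taus <- exp(best$par[2:3])
  if (taus[1] < taus[2]) { taus <- rev(taus); a <- 1 - a }
  tau_overall <- a * taus[1] + (1 - a) * taus[2]
  structure(list(a = a, tau_a = taus[1], tau_b = taus[2],
                 tau_overall = tau_overall,
                 Dr_pbc = Dr_from_tau(tau_overall),
                 window = window, residual = sum(best$fvec^2)),
            class = "rotational_fit")
}

#' @export
print.rotational_fit <- function(x, ...) {
  cat(sprintf(
    "<rotational_fit> a = %.3f, tau = (%.4g, %.4g) ns, tau_overall = %.4g ns, Dr_pbc = %.4g /ns\n",
    x$a, x$tau_a, x$tau_b, x$tau_overall, x$Dr_pbc))
  invisible(x)
}
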