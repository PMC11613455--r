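#' Autocorrelation of a scalar series
#'
#' Computes C(k) = 1/(N-k) * sum_t v(t) v(t+k) for k = 0..max_lag, either
#' on the raw values (`mode = "raw"`, the convention required by the
#' Green-Kubo integrand, where the mean is part of the signal) or on
#' mean-subtracted values. Uses an FFT with zero padding; the direct
#' O(N*K) sum is the test oracle.
#'
#' @param values Numeric vector, length > `max_lag`.
#' @param max_lag Maximum lag in samples (>= 1).
#' @param mode "raw" or "mean-removed".
#' @param dt Sample interval used for the lag axis (default 1, i.e. lags
#'   in samples).
#' @return A [crowd_ts] with `max_lag + 1` points.
#' @export
autocorrelation <- function(values, max_lag, mode = c("raw", "mean-removed"),
                            dt = 1) {
  mode <- match.arg(mode)
  values <- as.numeric(values)
  n <- length(values)
  if (max_lag < 1 || max_lag >= n) {
    stop("`max_lag` must satisfy 1 <= max_lag < length(values)", call. = FALSE)
  }
  if (mode == "mean-removed") values <- values - mean(values)
  s <- acf_sums_fft(values, max_lag)
  crowd_ts((0:max_lag) * dt, s / (n - 0:max_lag))
}

# Unnormalized lagged product sums sum_t v(t) v(t+k), k = 0..max_lag,
# via zero-padded FFT (circular correlation; padding to n + max_lag + 1
# suffices to kill wrap-around at the lags kept).
acf_sums_fft <- function(values, max_lag) {
  n <- length(values)
  m <- stats::nextn(n + max_lag + 1L, 2)
  f <- stats::fft(c(values, numeric(m - n)))
  s <- Re(stats::fft(f * Conj(f), inverse = TRUE)) / m
  s[seq_len(max_lag + 1L)]
}

# Column-wise lagged product sums for a numeric matrix (series in columns).
# Returns a (max_lag+1) x ncol matrix of sum_t x(t,j) x(t+k,j). Columns
# are processed in batches to bound the complex workspace.
acf_sums_fft_matrix <- function(x, max_lag) {
  n <- nrow(x)
  m <- stats::nextn(n + max_lag + 1L, 2)
  nc <- ncol(x)
  batch <- max(1L, as.integer(2^22 %/% m))
  out <- matrix(NA_real_, max_lag + 1L, nc)
  for (j0 in seq(1L, nc, by = batch)) {
    cols <- j0:min(nc, j0 + batch - 1L)
    xp <- rbind(x[, cols, drop = FALSE],
                matrix(0, m - n, length(cols)))
    f <- stats::mvfft(xp)
    s <- Re(stats::mvfft(f * Conj(f), inverse = TRUE)) / m
    out[, cols] <- s[seq_len(max_lag + 1L), , drop = FALSE]
  }
  out
}

# FFT-based mean-square displacement for one coordinate column.
# MSD(k) = 1/(N-k) sum_t (x(t+k)-x(t))^2, k = 0..max_lag.
msd_fft_1d <- function(x, max_lag) {
  n <- length(x)
  sq <- x^2
  # SS(k) = sum_{t=1}^{n-k} (x_t^2 + x_{t+k}^2)
  css <- cumsum(sq)
  k <- 0:max_lag
  tail_sum <- css[n] - c(0, css[seq_len(max_lag)])        # sum x_{t}^2, t=k+1..n
  head_sum <- css[n - k]                                  # sum x_t^2, t=1..n-k
  ss <- head_sum + tail_sum
  ac <- acf_sums_fft(x, max_lag)
  (ss - 2 * ac) / (n - k)
}
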