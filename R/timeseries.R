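#' Lagged time-series container
#'
#' Lightweight carrier for autocorrelation functions, mean-square
#' displacements and running integrals: a grid of non-negative increasing
#' lags (or times, ns), values, and optionally a standard error per point.
#'
#' @param lags Numeric vector of lags/times in ns, non-negative increasing.
#' @param values Numeric vector, same length as `lags`.
#' @param sem Optional numeric vector of standard errors, same length.
#' @param unit Character label for the value axis (documentation only).
#' @return An object of class `crowd_ts`.
#' @export
crowd_ts <- function(lags, values, sem = NULL, unit = "") {
  lags <- as.numeric(lags)
  values <- as.numeric(values)
  if (length(lags) != length(values)) {
    stop("`lags` and `values` must have equal length", call. = FALSE)
  }
  if (any(!is.finite(lags)) || any(lags < 0) || is.unsorted(lags, strictly = FALSE)) {
    stop("`lags` must be non-negative and increasing", call. = FALSE)
  }
  if (!is.null(sem)) {
    sem <- as.numeric(sem)
    if (length(sem) != length(values)) {
      stop("`sem` must match the length of `values`", call. = FALSE)
    }
  }
  structure(list(lags = lags, values = values, sem = sem, unit = unit),
            class = "crowd_ts")
}

#' @export
print.crowd_ts <- function(x, ...) {
  cat(sprintf("<crowd_ts> %d points, lag range [%g, %g] ns%s\n",
              length(x$lags), min(x$lags), max(x$lags),
              if (nzchar(x$unit)) paste0(", values in ", x$unit) else ""))
  invisible(x)
}

#' Restrict a crowd_ts to a lag window
#' @param x A `crowd_ts`.
#' @param window Numeric length-2 vector (lo, hi) in ns, inclusive.
#' @return A `crowd_ts` restricted to the window.
#' @export
ts_window <- function(x, window) {
  stopifnot(inherits(x, "crowd_ts"), length(window) == 2)
  keep <- x$lags >= window[1] & x$lags <= window[2]
  if (!any(keep)) stop("window contains no data points", call. = FALSE)
  crowd_ts(x$lags[keep], x$values[keep],
           if (is.null(x$sem)) NULL else x$sem[keep], x$unit)
}
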