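#' Detect intermolecular contacts
#'
#' Two molecules are in contact in a frame when their minimum heavy-atom
#' distance (under minimum-image convention) is below `cutoff` (default
#' 5 A). Without atom coordinates a center-of-mass surrogate mode is used:
#' contact when the surface-to-surface distance |r_ij| - a_i - a_j is
#' below the cutoff, with per-molecule radii taken from the trajectory.
#'
#' @param traj A [trajectory]; either with `atoms` + `molecule_index`
#'   (heavy-atom mode; hydrogens excluded when `elements` are present) or
#'   with per-molecule `radii` (surrogate mode).
#' @param cutoff Contact cutoff in A.
#' @return A [contact_timeline] covering all molecule pairs.
#' @export
direct_contacts <- function(traj, cutoff = 5) {
  stopifnot(inherits(traj, "crowd_trajectory"))
  N <- n_molecules(traj)
  if (N < 2) stop("need at least two molecules", call. = FALSE)
  L <- traj$box$edge_length
  idx <- which(upper.tri(matrix(0, N, N)), arr.ind = TRUE)
  idx <- idx[order(idx[, 1], idx[, 2]), , drop = FALSE]
  pairs <- cbind(idx[, 1], idx[, 2])
  n_f <- length(traj$times)
  pres <- matrix(FALSE, n_f, nrow(pairs))

  if (!is.null(traj$atoms)) {
    heavy <- if (is.null(traj$elements)) {
      rep(TRUE, dim(traj$atoms)[2])
    } else toupper(traj$elements) != "H"
    by_mol <- split(which(heavy), traj$molecule_index[heavy])
    for (f in seq_len(n_f)) {
      at <- traj$atoms[f, , , drop = TRUE]
      for (k in seq_len(nrow(pairs))) {
        ai <- by_mol[[as.character(pairs[k, 1])]]
        aj <- by_mol[[as.character(pairs[k, 2])]]
        if (is.null(ai) || is.null(aj)) next
        pres[f, k] <- min_pair_distance(at[ai, , drop = FALSE],
                                        at[aj, , drop = FALSE], L) < cutoff
      }
    }
  } else {
    if (is.null(traj$radii)) {
      stop("no atom coordinates and no surrogate radii on the trajectory",
           call. = FALSE)
    }
    sig <- traj$radii[pairs[, 1]] + traj$radii[pairs[, 2]]
    for (f in seq_len(n_f)) {
      d <- matrix(traj$com[f, pairs[, 2], ] - traj$com[f, pairs[, 1], ],
                  ncol = 3)
      d <- minimum_image(d, L)
      pres[f, ] <- sqrt(rowSums(d^2)) - sig < cutoff
    }
  }
  contact_timeline(traj$times, pairs, pres)
}

# minimum distance between two coordinate sets under minimum image
min_pair_distance <- function(a, b, L) {
  dmin <- Inf
  for (k in seq_len(nrow(a))) {
    d <- sweep(b, 2, a[k, ])
    d <- minimum_image(d, L)
    dmin <- min(dmin, min(rowSums(d^2)))
  }
  sqrt(dmin)
}

#' Per-residue crowder contact profile
#'
#' For each residue of the probe molecule, the time-averaged number of
#' heavy atoms belonging to other molecules within `cutoff` (default 7 A)
#' of that residue's C-alpha position, with a SEM across contiguous
#' replicate blocks of frames.
#'
#' @param traj A [trajectory] with `atoms`, `molecule_index`, and
#'   `calpha_index` for the probe.
#' @param probe Probe molecule index.
#' @param cutoff Distance cutoff in A.
#' @param n_blocks Number of frame blocks for the SEM.
#' @return A data.frame with columns residue, mean, sem.
#' @export
residue_contact_profile <- function(traj, probe, cutoff = 7, n_blocks = 5) {
  stopifnot(inherits(traj, "crowd_trajectory"))
  if (is.null(traj$atoms)) stop("atom coordinates required", call. = FALSE)
  ca <- traj$calpha_index[[probe]]
  if (is.null(ca)) stop("no C-alpha index map for the probe", call. = FALSE)
  L <- traj$box$edge_length
  heavy <- if (is.null(traj$elements)) {
    rep(TRUE, dim(traj$atoms)[2])
  } else toupper(traj$elements) != "H"
  others <- which(traj$molecule_index != probe & heavy)
  n_f <- length(traj$times)
  counts <- matrix(0, n_f, length(ca))
  for (f in seq_len(n_f)) {
    at <- traj$atoms[f, , , drop = TRUE]
    for (r in seq_along(ca)) {
      d <- sweep(at[others, , drop = FALSE], 2, at[ca[r], ])
      d <- minimum_image(d, L)
      counts[f, r] <- sum(rowSums(d^2) < cutoff^2)
    }
  }
  blk <- cut(seq_len(n_f), breaks = min(n_blocks, n_f), labels = FALSE)
  bm <- apply(counts, 2, function(col) tapply(col, blk, mean))
  bm <- matrix(bm, ncol = length(ca))
  data.frame(residue = seq_along(ca),
             mean = colMeans(counts),
             sem = apply(bm, 2, stats::sd) / sqrt(nrow(bm)))
}

#' Cluster membership of a probe molecule over time
#'
#' Per frame, builds the contact graph, extracts connected components,
#' and reports the probe's number of direct contacts and the number of
#' co-members of its cluster (component size minus one). Components are
#' labeled by their lowest molecule index for determinism.
#'
#' @param timeline A [contact_timeline].
#' @param probe Probe molecule index (must appear in the pair list).
#' @param n_mol Total number of molecules (default: max index in pairs).
#' @return A `cluster_series`: data.frame with times, direct, in_cluster,
#'   plus a `labels` attribute (`[frame, molecule]` component labels).
#' @export
cluster_with_probe <- function(timeline, probe, n_mol = max(timeline$pairs)) {
  stopifnot(inherits(timeline, "contact_timeline"))
  if (!any(timeline$pairs == probe)) {
    stop("probe does not appear in the pair list", call. = FALSE)
  }
  n_f <- nrow(timeline$present)
  direct <- integer(n_f)
  in_cluster <- integer(n_f)
  labels <- matrix(seq_len(n_mol), n_f, n_mol, byrow = TRUE)
  for (f in seq_len(n_f)) {
    on <- timeline$present[f, ]
    if (any(on)) {
      g <- igraph::graph_from_edgelist(timeline$pairs[on, , drop = FALSE],
                                       directed = FALSE)
      g <- igraph::add_vertices(g, max(0L, n_mol - igraph::vcount(g)))
      memb <- igraph::components(g)$membership
      # relabel each component by its lowest molecule index
      lab <- stats::ave(seq_len(n_mol), memb, FUN = min)
      labels[f, ] <- lab
      touching <- timeline$pairs[on, , drop = FALSE]
      direct[f] <- sum(touching == probe)
      in_cluster[f] <- sum(lab == lab[probe]) - 1L
    }
  }
  stopifnot(all(direct <= in_cluster), all(in_cluster <= n_mol - 1L))
  out <- data.frame(times = timeline$times, direct = direct,
                    in_cluster = in_cluster)
  attr(out, "labels") <- labels
  class(out) <- c("cluster_series", "data.frame")
  out
}

#' Intermittent contact autocorrelation function
#'
#' C(dt_k) = [sum_pairs mean_t d(t) d(t+dt_k)] / [sum_pairs mean_t d(t)^2],
#' pooling all pairs and averaging over the time origins available at each
#' lag, so C(0) = 1. The intermittent convention is used: a contact may
#' break and reform within the lag. Accepts a single timeline or a list of
#' timelines (pooled as one ensemble of pairs).
#'
#' @param timeline A [contact_timeline] or a list of them sharing a time
#'   grid.
#' @param lag_grid Optional vector of lags in ns; defaults to a
#'   logarithmic grid with 24 points per decade from one frame up to a
#'   quarter of the span.
#' @return A [crowd_ts] on the requested lag grid (attributes `num` and
#'   `den` carry the pooled raw sums).
#' @export
contact_acf <- function(timeline, lag_grid = NULL) {
  tls <- if (inherits(timeline, "contact_timeline")) list(timeline) else timeline
  stopifnot(length(tls) >= 1, all(vapply(tls, inherits, TRUE, "contact_timeline")))
  dt <- tls[[1]]$times[2] - tls[[1]]$times[1]
  n_f <- nrow(tls[[1]]$present)
  if (is.null(lag_grid)) {
    lag_grid <- log_lag_grid(dt, (n_f - 1) * dt / 4, points_per_decade = 24)
  }
  k_grid <- unique(round(lag_grid / dt))
  k_grid <- k_grid[k_grid >= 0 & k_grid < n_f]
  max_k <- max(k_grid)
  num <- numeric(max_k + 1L)
  den <- 0
  for (tl in tls) {
    x <- tl$present * 1
    s <- acf_sums_fft_matrix(x, max_k)
    num <- num + rowSums(s) / (n_f - 0:max_k)
    den <- den + sum(s[1, ]) / n_f
  }
  if (den == 0) stop("no contacts present: autocorrelation undefined", call. = FALSE)
  crowd_ts(k_grid * dt, (num / den)[k_grid + 1L])
}

#' Logarithmic lag grid
#' @param lo,hi Grid range in ns.
#' @param points_per_decade Density of the grid.
#' @return Numeric vector of lags including 0.
#' @export
log_lag_grid <- function(lo, hi, points_per_decade = 24) {
  if (hi <= lo) return(c(0, lo))
  n <- ceiling(log10(hi / lo) * points_per_decade)
  c(0, lo * 10^(seq(0, log10(hi / lo), length.out = n + 1)))
}

#' Fit a triple-exponential survival model
#'
#' Weighted nonlinear least squares of
#' w1 exp(-t/tau1) + w2 exp(-t/tau2) + w3 exp(-t/tau3) (+ c0) against a
#' contact ACF, with multi-start over log-spaced characteristic-time
#' triplets. The optional constant `c0` absorbs the long-time plateau of
#' the intermittent ACF (the stationary contact probability). Weights are
#' 1/sem^2 when the series carries SEMs, else uniform.
#'
#' @param acf A [crowd_ts], overall decreasing, spanning several decades.
#' @param baseline Logical: fit the constant plateau term (default TRUE).
#' @param n_components Number of exponential components (default 3).
#' @return A `survival_fit`: list with `w`, `tau` (decreasing), `c0`,
#'   `residual`, `fit` (the nls object), `degenerate` flag.
#' @export
fit_triple_exponential <- function(acf, baseline = TRUE, n_components = 3L) {
  stopifnot(inherits(acf, "crowd_ts"))
  t <- acf$lags
  y <- acf$values
  keep <- is.finite(y)
  t <- t[keep]; y <- y[keep]
  if (length(t) < 4 * n_components) {
    stop("too few lag points for a stable fit", call. = FALSE)
  }
  if (diff(range(y)) < 1e-3) {
    stop("no decay in the correlation function: survival time unresolved (tau -> Inf)",
         call. = FALSE)
  }
  w_fit <- if (!is.null(acf$sem) && all(acf$sem[keep] > 0)) {
    1 / acf$sem[keep]^2
  } else rep(1, length(t))

  tpos <- t[t > 0]
  span <- range(tpos)
  starts <- make_tau_starts(span, n_components)
  best <- NULL
  for (st in starts) {
    fit <- try_multi_exp_fit(t, y, w_fit, st, baseline, n_components)
    if (!is.null(fit) &&
        (is.null(best) || fit$residual < best$residual)) best <- fit
  }
  if (is.null(best)) {
    stop("triple-exponential fit failed to converge from all starts", call. = FALSE)
  }
  ord <- order(best$tau, decreasing = TRUE)
  best$tau <- best$tau[ord]
  best$w <- best$w[ord]
  best$degenerate <- any(best$w < 0.02) ||
    any(diff(log(best$tau)) > -0.2)  # unresolved neighboring scales
  class(best) <- "survival_fit"
  best
}

make_tau_starts <- function(span, k) {
  lo <- log10(max(span[1], 1e-6)); hi <- log10(span[2])
  anchors <- 10^seq(lo, hi, length.out = max(k, 3))
  list(anchors[round(seq(1, length(anchors), length.out = k))],
       10^seq(lo + 0.25 * (hi - lo), hi, length.out = k),
       10^seq(lo, lo + 0.6 * (hi - lo), length.out = k),
       10^seq(lo + 0.1, hi - 0.1, length.out = k))
}

try_multi_exp_fit <- function(t, y, w, tau0, baseline, k) {
  par0 <- c(rep(max(y) / k, k), log(sort(tau0, decreasing = TRUE)),
            if (baseline) min(y) else NULL)
  model <- function(p) {
    wts <- p[1:k]; taus <- exp(p[(k + 1):(2 * k)])
    c0 <- if (baseline) p[2 * k + 1] else 0
    pred <- c0
    for (i in 1:k) pred <- pred + wts[i] * exp(-t / taus[i])
    pred
  }
  lower <- c(rep(0, k), rep(log(min(t[t > 0]) / 10), k), if (baseline) 0)
  upper <- c(rep(2, k), rep(log(max(t) * 100), k), if (baseline) 1)
  fit <- tryCatch(
    minpack.lm::nls.lm(par = par0,
                       fn = function(p) sqrt(w) * (y - model(p)),
                       lower = lower, upper = upper,
                       control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (is.null(fit) || fit$info < 1 || fit$info > 4) return(NULL)
  p <- fit$par
  list(w = p[1:k], tau = exp(p[(k + 1):(2 * k)]),
       c0 = if (baseline) p[2 * k + 1] else 0,
       residual = sum(fit$fvec^2), fit = fit)
}

#' @export
print.survival_fit <- function(x, ...) {
  cat("<survival_fit>\n")
  for (i in seq_along(x$tau)) {
    cat(sprintf("  component %d: w = %.3f, tau = %.4g ns\n",
                i, x$w[i], x$tau[i]))
  }
  cat(sprintf("  baseline = %.4f, residual = %.3g%s\n", x$c0, x$residual,
              if (x$degenerate) " (degenerate components flagged)" else ""))
  invisible(x)
}

#' Convergence Z-score of an observable time series
#'
#' For each evaluation time t, compares the short-window mean
#' a_w(t) = mean over [t, t + window) with the long-run mean
#' a_max(t) = mean over [t, end], via
#' Z(t) = |a_w - a_max| / (SEM(a_w) + SEM(a_max)). A Z-score around 1
#' indicates the short-window average is within one standard error of the
#' long-run average, i.e. apparent stationarity. SEMs are computed across
#' replicate series when a matrix is supplied, else by block averaging
#' with block length window/10.
#'
#' @param series Numeric vector, numeric matrix `[time, replica]`, or a
#'   [crowd_ts].
#' @param window Window length in ns (default 400).
#' @param dt Frame interval in ns (taken from the `crowd_ts` if given).
#' @param stride Evaluation stride in frames (default window/10 frames).
#' @return A `convergence_report` data.frame with times, Z, short/long
#'   means and SEMs.
#' @export
convergence_zscore <- function(series, window = 400, dt = NULL, stride = NULL) {
  if (inherits(series, "crowd_ts")) {
    dt <- series$lags[2] - series$lags[1]
    series <- series$values
  }
  x <- as.matrix(series)
  if (is.null(dt)) dt <- 1
  n <- nrow(x)
  w <- round(window / dt)
  if (w >= n) stop("`window` must be shorter than the series span", call. = FALSE)
  if (is.null(stride)) stride <- max(1L, w %/% 10L)
  starts <- seq(1L, n - w, by = stride)
  replicated <- ncol(x) > 1
  block <- max(2L, w %/% 10L)
  row_mean <- rowMeans(x)
  res <- lapply(starts, function(t0) {
    short_idx <- t0:(t0 + w - 1L)
    long_idx <- t0:n
    if (replicated) {
      sm <- colMeans(x[short_idx, , drop = FALSE])
      lm_ <- colMeans(x[long_idx, , drop = FALSE])
      sem_s <- stats::sd(sm) / sqrt(length(sm))
      sem_l <- stats::sd(lm_) / sqrt(length(lm_))
      a_s <- mean(sm); a_l <- mean(lm_)
    } else {
      a_s <- mean(row_mean[short_idx]); a_l <- mean(row_mean[long_idx])
      sem_s <- block_sem(row_mean[short_idx], block)
      sem_l <- block_sem(row_mean[long_idx], block)
    }
    c(a_s, a_l, sem_s, sem_l)
  })
  res <- do.call(rbind, res)
  dif <- abs(res[, 1] - res[, 2])
  z <- ifelse(dif == 0, 0, dif / (res[, 3] + res[, 4]))
  out <- data.frame(times = (starts - 1L) * dt, Z = z,
                    short_mean = res[, 1], long_mean = res[, 2],
                    short_sem = res[, 3], long_sem = res[, 4])
  attr(out, "window") <- window
  class(out) <- c("convergence_report", "data.frame")
  out
}

block_sem <- function(v, block) {
  nb <- length(v) %/% block
  if (nb < 2) return(stats::sd(v) / sqrt(length(v)))
  bm <- tapply(v[seq_len(nb * block)], rep(seq_len(nb), each = block), mean)
  stats::sd(bm) / sqrt(nb)
}
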