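#' Simulate isotropic rotational Brownian motion
#'
#' Evolves a rigid body frame by composing small random rotations with
#' per-axis angular variance 2 * Dr * dt (axis-angle composition, no Euler
#' angles), and carries a set of unit vectors rigidly attached to the
#' body. The P2 autocorrelation of the attached vectors decays as
#' exp(-6 * Dr * t).
#'
#' @param Dr Rotational diffusion coefficient in 1/ns (>= 0).
#' @param dt Time step in ns; requires Dr * dt < 0.05.
#' @param n_steps Number of integration steps.
#' @param n_vectors Number of attached unit vectors.
#' @param seed Integer RNG seed.
#' @param thin Record every `thin`-th step (frame interval dt * thin).
#' @return An `orientation_trajectory`: times (ns) and a
#'   `[frame, vector, 3]` array of unit vectors, with ground truth attached.
#' @export
simulate_rotational_walk <- function(Dr, dt, n_steps, n_vectors = 1000,
                                     seed = 1, thin = 1L) {
  if (Dr < 0) stop("`Dr` must be non-negative", call. = FALSE)
  if (Dr * dt >= 0.05) {
    stop("discretization too coarse: require Dr * dt < 0.05", call. = FALSE)
  }
  set.seed(seed)
  v0 <- random_unit_vectors(n_vectors)
  n_out <- as.integer(n_steps %/% thin)
  vec <- array(NA_real_, c(n_out, n_vectors, 3))
  R <- diag(3)
  sd_ang <- sqrt(2 * Dr * dt)
  out_i <- 0L
  for (step in seq_len(n_steps)) {
    if (Dr > 0) {
      R <- rotation_from_axis_angle(stats::rnorm(3, sd = sd_ang)) %*% R
    }
    if (step %% thin == 0) {
      out_i <- out_i + 1L
      vec[out_i, , ] <- v0 %*% t(R)
    }
  }
  structure(list(times = seq_len(n_out) * dt * thin, vectors = vec,
                 ground_truth = list(Dr = Dr, seed = seed)),
            class = "orientation_trajectory")
}

#' @export
print.orientation_trajectory <- function(x, ...) {
  cat(sprintf("<orientation_trajectory> %d frames x %d vectors, dt = %g ns\n",
              dim(x$vectors)[1], dim(x$vectors)[2], x$times[2] - x$times[1]))
  invisible(x)
}

#' Uniform random unit vectors
#' @param n Number of vectors.
#' @return An n x 3 matrix of unit rows.
#' @keywords internal
random_unit_vectors <- function(n) {
  v <- matrix(stats::rnorm(3 * n), n, 3)
  v / sqrt(rowSums(v^2))
}

# Rodrigues rotation matrix for rotation vector w (axis * angle)
rotation_from_axis_angle <- function(w) {
  theta <- sqrt(sum(w^2))
  if (theta < 1e-12) return(diag(3))
  k <- w / theta
  K <- matrix(c(0, k[3], -k[2], -k[3], 0, k[1], k[2], -k[1], 0), 3, 3)
  diag(3) + sin(theta) * K + (1 - cos(theta)) * (K %*% K)
}
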