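#' Center-of-mass radial distribution function
#'
#' Pair-distance histogram under minimum image, normalized by the
#' ideal-gas shell count at the finite-N pair density N_pairs / V (the
#' finite-N correction matters with only a handful of molecules per box).
#' Bins extend at most to half the box edge.
#'
#' @param traj A [trajectory] (wrapped or not; minimum-image distances are
#'   used).
#' @param pair_selection Either "all" or a list with integer vectors `i`
#'   and `j` selecting a cross set of molecules (disjoint groups).
#' @param bin_width Bin width in A.
#' @param r_max Histogram range in A (default L/2).
#' @return An `rdf_curve`: data.frame with `r` (bin centers) and `g`, with
#'   metadata attributes.
#' @export
com_rdf <- function(traj, pair_selection = "all", bin_width = 0.5,
                    r_max = NULL) {
  stopifnot(inherits(traj, "crowd_trajectory"))
  L <- traj$box$edge_length
  if (is.null(r_max)) r_max <- L / 2
  if (r_max > L / 2 + 1e-9) {
    stop("`r_max` must not exceed half the box edge", call. = FALSE)
  }
  if (identical(pair_selection, "all")) {
    N <- n_molecules(traj)
    if (N < 2) stop("need at least one pair", call. = FALSE)
    idx <- which(upper.tri(matrix(0, N, N)), arr.ind = TRUE)
    pi_ <- idx[, 1]; pj <- idx[, 2]
  } else {
    pi_ <- rep(pair_selection$i, each = length(pair_selection$j))
    pj <- rep(pair_selection$j, times = length(pair_selection$i))
    keep <- pi_ != pj
    pi_ <- pi_[keep]; pj <- pj[keep]
  }
  n_pairs <- length(pi_)
  breaks <- seq(0, r_max, by = bin_width)
  if (breaks[length(breaks)] < r_max) breaks <- c(breaks, r_max)
  counts <- numeric(length(breaks) - 1L)
  n_f <- length(traj$times)
  for (f in seq_len(n_f)) {
    d <- traj$com[f, pj, , drop = TRUE] - traj$com[f, pi_, , drop = TRUE]
    d <- minimum_image(matrix(d, ncol = 3), L)
    r <- sqrt(rowSums(d^2))
    counts <- counts + graphics::hist(r[r < r_max], breaks = breaks,
                                      plot = FALSE)$counts
  }
  shell <- 4 / 3 * pi * diff(breaks^3)
  ideal <- n_f * n_pairs * shell / L^3
  out <- data.frame(r = (breaks[-1] + breaks[-length(breaks)]) / 2,
                    g = counts / ideal)
  attr(out, "bin_width") <- bin_width
  attr(out, "n_frames") <- n_f
  attr(out, "n_pairs") <- n_pairs
  attr(out, "box_edge") <- L
  class(out) <- c("rdf_curve", "data.frame")
  out
}

#' Second virial coefficient from an RDF
#'
#' B2 = -2 pi * integral_0^r_max (g(r) - 1) r^2 dr by the trapezoid rule
#' on the bin centers. The upper limit `r_max` is a required, recorded
#' choice per pair type (typically the first minimum after the contact
#' peak).
#'
#' @param rdf An `rdf_curve` or data.frame with columns `r` and `g`.
#' @param r_max Upper integration limit in A.
#' @return B2 in A^3.
#' @export
b2_from_rdf <- function(rdf, r_max) {
  r <- rdf$r; g <- rdf$g
  if (r_max > max(r) + 1e-9) {
    stop("`r_max` exceeds the RDF range", call. = FALSE)
  }
  sel <- r <= r_max
  -2 * pi * pracma::trapz(r[sel], (g[sel] - 1) * r[sel]^2)
}

#' Hard-sphere interaction volume
#'
#' Homotypic: (4 pi / 3) a^3. Heterotypic: (4 pi / 3) ((a1 + a2)/2)^3,
#' with a1, a2 the equivalent radii of the two interacting spheres
#' (derived from molecular volumes).
#'
#' @param a1 Radius in A (> 0).
#' @param a2 Optional second radius in A.
#' @return V_HS in A^3.
#' @export
hard_sphere_volume <- function(a1, a2 = NULL) {
  if (a1 <= 0 || (!is.null(a2) && a2 <= 0)) {
    stop("radii must be positive", call. = FALSE)
  }
  a <- if (is.null(a2)) a1 else (a1 + a2) / 2
  4 / 3 * pi * a^3
}

#' Equivalent sphere radius from a molecular volume
#' @param volume Molecular volume in A^3.
#' @return Radius a = (3 V / (4 pi))^(1/3) in A.
#' @export
equivalent_radius <- function(volume) {
  if (volume <= 0) stop("`volume` must be positive", call. = FALSE)
  (3 * volume / (4 * pi))^(1 / 3)
}

#' Baxter stickiness parameter from B2
#'
#' Adhesive-hard-sphere relation B2 = 4 V_HS (1 - 1/(4 tau_B)), inverted
#' as tau_B = 1 / (4 - B2 / V_HS). Smaller tau_B means stickier; 1/tau_B
#' is a cluster-formation propensity.
#'
#' @param B2 Second virial coefficient in A^3.
#' @param V_HS Hard-sphere interaction volume in A^3.
#' @return tau_B (dimensionless).
#' @export
baxter_tau <- function(B2, V_HS) {
  if (V_HS <= 0) stop("`V_HS` must be positive", call. = FALSE)
  denom <- 4 - B2 / V_HS
  if (denom <= 0) {
    stop("B2 >= 4 V_HS: repulsive limit, no finite stickiness", call. = FALSE)
  }
  1 / denom
}

#' B2 from the Baxter parameter (inverse map)
#' @param tau_B Stickiness parameter (> 0).
#' @param V_HS Hard-sphere volume in A^3.
#' @return B2 in A^3.
#' @export
b2_from_baxter <- function(tau_B, V_HS) 4 * V_HS * (1 - 1 / (4 * tau_B))

#' Dissociation constant from the Baxter parameter
#'
#' K_D[A^-3] = tau_B / V_HS, converted to mM by multiplying by
#' 1e30 / N_A (i.e. dividing the number density by N_A per liter). For
#' probe-crowder interactions the probe's own hard-sphere volume is the
#' conventional `V_HS` so that different crowders are comparable.
#'
#' @param tau_B Stickiness parameter (> 0).
#' @param V_HS Hard-sphere volume in A^3 used in the conversion.
#' @return List with `per_A3` (A^-3) and `mM`.
#' @export
kd_from_tau <- function(tau_B, V_HS) {
  if (tau_B <= 0 || V_HS <= 0) {
    stop("`tau_B` and `V_HS` must be positive", call. = FALSE)
  }
  per_A3 <- tau_B / V_HS
  list(per_A3 = per_A3, mM = per_A3 * 1e30 / crowd_units$N_A)
}

#' Baxter parameter from the quadratic viscosity coefficient
#'
#' Adhesive-hard-sphere second-order viscosity coefficient
#' b = 5.9 + 1.9 / tau_B, inverted as tau_B = 1.9 / (b - 5.9). Requires
#' b > 5.9 (the hard-sphere limit).
#'
#' @param b Second-order coefficient of the relative-viscosity expansion.
#' @return tau_B (dimensionless).
#' @export
tau_from_viscosity_b <- function(b) {
  if (b <= 5.9) {
    stop("b <= 5.9: at or below the hard-sphere limit, no finite stickiness",
         call. = FALSE)
  }
  1.9 / (b - 5.9)
}

#' Quadratic viscosity coefficient from the Baxter parameter (inverse)
#' @param tau_B Stickiness parameter (> 0).
#' @return b = 5.9 + 1.9 / tau_B.
#' @export
viscosity_b_from_tau <- function(tau_B) 5.9 + 1.9 / tau_B

#' Colloid-theory interaction chain
#'
#' Convenience wrapper: from (a1, a2, B2) to V_HS, tau_B and K_D; for
#' heterotypic probe-crowder pairs `a_kd` (typically the probe radius)
#' selects the volume used in the K_D conversion.
#'
#' @param B2 Second virial coefficient in A^3.
#' @param a1 First radius in A.
#' @param a2 Optional second radius in A.
#' @param a_kd Radius whose sphere volume converts tau_B to K_D (default:
#'   homotypic `a1`; heterotypic pairs must supply it).
#' @return A data.frame row with V_HS, tau_B, KD_mM.
#' @export
colloid_chain <- function(B2, a1, a2 = NULL, a_kd = NULL) {
  V_HS <- hard_sphere_volume(a1, a2)
  tau <- baxter_tau(B2, V_HS)
  V_kd <- if (is.null(a_kd)) {
    if (!is.null(a2)) stop("heterotypic pairs must supply `a_kd`", call. = FALSE)
    V_HS
  } else hard_sphere_volume(a_kd)
  data.frame(V_HS = V_HS, tau_B = tau, KD_mM = kd_from_tau(tau, V_kd)$mM)
}
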