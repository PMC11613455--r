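#' Cubic periodic box specification
#'
#' Only cubic boxes are supported: every finite-size correction used in the
#' analysis is parameterized by a single edge length L.
#'
#' @param edge_length Box edge in A (> 0).
#' @param periodic Logical; whether periodic imaging applies.
#' @return An object of class `box_spec`.
#' @export
box_spec <- function(edge_length, periodic = TRUE) {
  if (!is.numeric(edge_length) || length(edge_length) != 1 ||
      !is.finite(edge_length) || edge_length <= 0) {
    stop("`edge_length` must be a single positive number (A); only cubic boxes are supported",
         call. = FALSE)
  }
  structure(list(edge_length = as.numeric(edge_length),
                 periodic = isTRUE(periodic)),
            class = "box_spec")
}

#' Molecular center-of-mass trajectory
#'
#' Holds per-frame molecular center-of-mass positions (and optionally atom
#' positions) in a cubic periodic box. Times must be uniformly spaced
#' (relative tolerance 1e-6): every lag-based estimator in the package
#' assumes a constant frame interval.
#'
#' @param times Frame times in ns, strictly increasing with constant step.
#' @param com Array `[frame, molecule, 3]` of center-of-mass positions (A).
#' @param box A [box_spec].
#' @param wrapped Logical; whether coordinates are wrapped into the box.
#' @param atoms Optional array `[frame, atom, 3]` of atom positions (A).
#' @param molecule_index Optional integer vector mapping atom -> molecule.
#' @param calpha_index Optional list per molecule of C-alpha atom indices.
#' @param elements Optional character vector of atomic elements per atom;
#'   hydrogens ("H") are excluded from heavy-atom contact counts.
#' @param radii Optional per-molecule effective radii (A) for the
#'   center-of-mass surrogate contact mode.
#' @param ground_truth Optional list of generator ground-truth parameters.
#' @param provenance Optional list recording source path / frame range.
#' @return An object of class `crowd_trajectory`.
#' @export
trajectory <- function(times, com, box, wrapped = TRUE, atoms = NULL,
                       molecule_index = NULL, calpha_index = NULL,
                       elements = NULL, radii = NULL,
                       ground_truth = NULL, provenance = NULL) {
  times <- as.numeric(times)
  if (length(times) < 2 || is.unsorted(times, strictly = TRUE)) {
    stop("`times` must be strictly increasing with at least 2 frames", call. = FALSE)
  }
  dts <- diff(times)
  if (max(abs(dts - dts[1])) > 1e-6 * abs(dts[1])) {
    stop("`times` must be uniformly spaced (relative tolerance 1e-6)", call. = FALSE)
  }
  if (length(dim(com)) != 3 || dim(com)[3] != 3) {
    stop("`com` must be an array [frame, molecule, 3]", call. = FALSE)
  }
  if (dim(com)[1] != length(times)) {
    stop("first dimension of `com` must match length(times)", call. = FALSE)
  }
  if (dim(com)[2] < 1) stop("at least one molecule is required", call. = FALSE)
  if (any(!is.finite(com))) stop("`com` contains non-finite values", call. = FALSE)
  if (!inherits(box, "box_spec")) stop("`box` must be a box_spec", call. = FALSE)
  if (!is.null(atoms)) {
    if (length(dim(atoms)) != 3 || dim(atoms)[3] != 3 ||
        dim(atoms)[1] != length(times)) {
      stop("`atoms` must be an array [frame, atom, 3] matching `times`", call. = FALSE)
    }
    if (is.null(molecule_index) || length(molecule_index) != dim(atoms)[2]) {
      stop("`molecule_index` must map every atom to a molecule", call. = FALSE)
    }
  }
  if (!is.null(radii) && length(radii) != dim(com)[2]) {
    stop("`radii` must have one entry per molecule", call. = FALSE)
  }
  structure(list(times = times, com = com, box = box, wrapped = isTRUE(wrapped),
                 atoms = atoms, molecule_index = molecule_index,
                 calpha_index = calpha_index, elements = elements,
                 radii = radii, ground_truth = ground_truth,
                 provenance = provenance),
            class = "crowd_trajectory")
}

#' @export
print.crowd_trajectory <- function(x, ...) {
  cat(sprintf(
    "<crowd_trajectory> %d frames x %d molecules, dt = %g ns, L = %g A (%s)\n",
    length(x$times), dim(x$com)[2], x$times[2] - x$times[1],
    x$box$edge_length, if (x$wrapped) "wrapped" else "unwrapped"))
  invisible(x)
}

#' Number of molecules in a trajectory
#' @param traj A `crowd_trajectory`.
#' @return Integer molecule count.
#' @export
n_molecules <- function(traj) dim(traj$com)[2]

#' Unwrap periodic coordinates
#'
#' Accumulates minimum-image inter-frame displacements of the molecular
#' centers of mass so that mean-square displacements can be computed.
#' Centers of mass are unwrapped directly (no atom-wise pre-imaging).
#' Requires that no molecule moves by half a box edge or more between
#' consecutive frames; such a jump is ambiguous under periodic imaging.
#'
#' @param traj A wrapped `crowd_trajectory`. Already-unwrapped input is
#'   returned unchanged.
#' @return The trajectory with `wrapped = FALSE` and continuous COM paths.
#' @export
unwrap_positions <- function(traj) {
  stopifnot(inherits(traj, "crowd_trajectory"))
  if (!traj$wrapped) return(traj)
  L <- traj$box$edge_length
  com <- traj$com
  d <- com[-1, , , drop = FALSE] - com[-dim(com)[1], , , drop = FALSE]
  d_mi <- d - L * round(d / L)
  bad <- abs(d_mi) >= L / 2 - 1e-9
  if (any(bad)) {
    idx <- which(bad, arr.ind = TRUE)[1, ]
    stop(sprintf(
      "ambiguous unwrap: molecule %d moved >= L/2 between frames %d and %d",
      idx[2], idx[1], idx[1] + 1), call. = FALSE)
  }
  out <- com
  for (k in seq_len(dim(com)[1] - 1)) {
    out[k + 1, , ] <- out[k, , ] + d_mi[k, , ]
  }
  traj$com <- out
  traj$wrapped <- FALSE
  traj
}

#' Wrap coordinates into the primary box
#'
#' Maps all center-of-mass coordinates into `[0, L)` by periodic imaging.
#'
#' @param traj A `crowd_trajectory`.
#' @return The trajectory with `wrapped = TRUE`.
#' @export
wrap_positions <- function(traj) {
  stopifnot(inherits(traj, "crowd_trajectory"))
  L <- traj$box$edge_length
  traj$com <- traj$com - L * floor(traj$com / L)
  if (!is.null(traj$atoms)) traj$atoms <- traj$atoms - L * floor(traj$atoms / L)
  traj$wrapped <- TRUE
  traj
}

#' Minimum-image displacement vectors
#' @param d Numeric array of raw displacement components.
#' @param L Box edge (A).
#' @return Displacements folded into (-L/2, L/2].
#' @keywords internal
minimum_image <- function(d, L) d - L * round(d / L)
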