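#' Read a center-of-mass trajectory from columnar text
#'
#' Expects columns frame, time_ns, molecule_id, x, y, z (CSV or TSV,
#' detected from the header). Provenance (path, frame range, stride) is
#' recorded on the returned object.
#'
#' @param path File path.
#' @param box_edge Box edge in A.
#' @param wrapped Whether coordinates are wrapped (default TRUE).
#' @param stride Keep every `stride`-th frame.
#' @return A [trajectory].
#' @export
read_trajectory_csv <- function(path, box_edge, wrapped = TRUE, stride = 1L) {
  sep <- if (grepl("\t", readLines(path, n = 1L))) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep)
  need <- c("frame", "time_ns", "molecule_id", "x", "y", "z")
  if (!all(need %in% names(df))) {
    stop("trajectory file must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  frames <- sort(unique(df$frame))
  frames <- frames[seq(1, length(frames), by = stride)]
  df <- df[df$frame %in% frames, ]
  mols <- sort(unique(df$molecule_id))
  times <- vapply(frames, function(f) df$time_ns[df$frame == f][1], 0)
  com <- array(NA_real_, c(length(frames), length(mols), 3))
  df <- df[order(df$frame, df$molecule_id), ]
  com[, , 1] <- t(matrix(df$x, length(mols), length(frames)))
  com[, , 2] <- t(matrix(df$y, length(mols), length(frames)))
  com[, , 3] <- t(matrix(df$z, length(mols), length(frames)))
  trajectory(times, com, box_spec(box_edge), wrapped = wrapped,
             provenance = list(path = path,
                               frame_range = range(frames), stride = stride))
}

#' Write a center-of-mass trajectory as CSV
#' @param traj A [trajectory].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_trajectory_csv <- function(traj, path) {
  n_f <- length(traj$times)
  N <- n_molecules(traj)
  df <- data.frame(
    frame = rep(seq_len(n_f), each = N),
    time_ns = rep(traj$times, each = N),
    molecule_id = rep(seq_len(N), times = n_f),
    x = as.vector(t(traj$com[, , 1])),
    y = as.vector(t(traj$com[, , 2])),
    z = as.vector(t(traj$com[, , 3])))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read replicate stress series from CSV files
#'
#' Each file holds one replica: one column per stress channel, samples in
#' rows, values in bar.
#'
#' @param paths Character vector of file paths.
#' @param dt Sampling interval in ns.
#' @param volume Box volume in A^3.
#' @param temperature Temperature in K.
#' @return A list of [stress_series].
#' @export
read_stress_csv <- function(paths, dt, volume,
                            temperature = crowd_units$temperature_default) {
  lapply(seq_along(paths), function(i) {
    stress_series(as.matrix(utils::read.csv(paths[i])), dt, volume,
                  temperature, replica_id = i)
  })
}
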