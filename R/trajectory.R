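#' Construct a single trajectory frame
#'
#' A frame holds wrapped particle positions (nm) at one time point together
#' with per-particle species labels and the box. Coordinates must lie in
#' `[0, L)` per axis.
#'
#' @param time Frame time, ns.
#' @param positions N x 3 numeric matrix of positions (nm), columns x, y, z.
#' @param species Character vector (length N) of species names.
#' @param box Length-3 box edges (nm).
#' @return An object of class `md_frame`.
#' @export
md_frame <- function(time, positions, species, box) {
  positions <- as.matrix(positions)
  if (length(positions) == 0L) positions <- matrix(numeric(0), 0L, 3L)
  stopifnot(ncol(positions) == 3L, nrow(positions) == length(species),
            length(box) == 3L)
  colnames(positions) <- c("x", "y", "z")
  structure(list(time = time, positions = positions,
                 species = as.character(species), box = as.numeric(box)),
            class = "md_frame")
}

#' Validate a frame against box and membrane invariants
#'
#' Checks that coordinates are finite and wrapped into `[0, L)` and that no
#' ion (species with non-zero valence) lies strictly inside the membrane
#' slab. Water markers are allowed inside the slab (a planted transmembrane
#' chain must be).
#'
#' @param frame An [md_frame()].
#' @param membrane A [membrane_slab()] or `NULL`.
#' @param species_table Species table, see [default_species()].
#' @return `frame`, invisibly; errors on violation.
#' @export
validate_frame <- function(frame, membrane = NULL,
                           species_table = default_species()) {
  stopifnot(inherits(frame, "md_frame"))
  p <- frame$positions
  if (nrow(p)) {
    if (any(!is.finite(p))) stop("frame contains non-finite coordinates")
    for (a in 1:3)
      if (any(p[, a] < 0 | p[, a] >= frame$box[a]))
        stop("frame coordinates not wrapped into [0, L) on axis ", a)
    if (!is.null(membrane)) {
      idx <- species_lookup(species_table, frame$species)
      ion <- species_table$valence[idx] != 0L
      z <- p[ion, 3L]
      if (any(z > membrane$z_lower & z < membrane$z_upper))
        stop("ion found strictly inside the membrane slab")
    }
  }
  invisible(frame)
}

#' Construct a trajectory
#'
#' @param frames List of [md_frame()] with strictly increasing times and a
#'   constant particle count.
#' @param species_table Species table for all frames.
#' @param config The generating [synth_config()] or arbitrary metadata.
#' @return An object of class `ion_trajectory`.
#' @export
ion_trajectory <- function(frames, species_table = default_species(),
                           config = NULL) {
  stopifnot(is.list(frames), length(frames) >= 1L,
            all(vapply(frames, inherits, TRUE, "md_frame")))
  times <- vapply(frames, `[[`, 0, "time")
  if (length(times) > 1L && any(diff(times) <= 0))
    stop("frame times must be strictly increasing")
  n <- vapply(frames, function(f) nrow(f$positions), 0L)
  if (length(unique(n)) != 1L)
    stop("particle count must be constant across frames")
  structure(list(frames = frames, species_table = species_table,
                 config = config),
            class = "ion_trajectory")
}

#' @export
print.ion_trajectory <- function(x, ...) {
  n <- nrow(x$frames[[1]]$positions)
  times <- frame_times(x)
  cat(sprintf("ion_trajectory: %d frames, %d particles, t = %.4g .. %.4g ns\n",
              length(x$frames), n, times[1], times[length(times)]))
  tab <- table(x$frames[[1]]$species)
  cat("  species:",
      paste(sprintf("%s=%d", names(tab), as.integer(tab)), collapse = ", "),
      "\n")
  invisible(x)
}

#' Frame times of a trajectory
#' @param trajectory An [ion_trajectory()].
#' @return Numeric vector of frame times (ns).
#' @export
frame_times <- function(trajectory) {
  vapply(trajectory$frames, `[[`, 0, "time")
}

#' Number of frames / particles
#' @param trajectory An [ion_trajectory()].
#' @return Integer count.
#' @export
n_frames <- function(trajectory) length(trajectory$frames)

#' @rdname n_frames
#' @export
n_particles <- function(trajectory) nrow(trajectory$frames[[1]]$positions)
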