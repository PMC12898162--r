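# Electrophoretic ion kinematics: trajectory unwrapping, drift, surface
# accumulation and the charge-concentration covariate.

#' Unwrap a periodic trajectory
#'
#' Accumulates per-step minimum-image displacements so particle paths are
#' continuous across the periodic boundaries. Requires that no particle
#' moves half a box length or more per axis between stored frames;
#' an ambiguous jump raises an error naming the particle and frame.
#' Rewrapping (`start + displacement mod L`) recovers the original wrapped
#' coordinates exactly.
#'
#' @param trajectory An [ion_trajectory()].
#' @return Object of class `unwrapped_trajectory`: `times`, `displacement`
#'   (N x 3 x n_frames cumulative displacements, zero at the first frame),
#'   `start` (first-frame positions), `species`, `box`.
#' @export
unwrap_trajectory <- function(trajectory) {
  stopifnot(inherits(trajectory, "ion_trajectory"))
  frames <- trajectory$frames
  nf <- length(frames)
  n <- nrow(frames[[1]]$positions)
  box <- frames[[1]]$box
  disp <- array(0, c(n, 3L, nf))
  if (nf > 1L) {
    cum <- matrix(0, n, 3L)
    for (k in 2:nf) {
      d <- frames[[k]]$positions - frames[[k - 1L]]$positions
      d <- d - rep(box, each = n) * round(sweep(d, 2L, box, "/"))
      bad <- abs(d) >= rep(box, each = n) / 2 - 1e-9
      if (any(bad)) {
        w <- which(bad, arr.ind = TRUE)[1L, ]
        stop(sprintf(paste0("ambiguous displacement (>= L/2) for particle ",
                            "%d on axis %d between frames %d and %d; ",
                            "reduce the frame stride"),
                     w[1L], w[2L], k - 1L, k))
      }
      cum <- cum + d
      disp[, , k] <- cum
    }
  }
  structure(list(times = frame_times(trajectory), displacement = disp,
                 start = frames[[1]]$positions,
                 species = frames[[1]]$species, box = box),
            class = "unwrapped_trajectory")
}

#' Rewrap an unwrapped trajectory
#'
#' Inverse of [unwrap_trajectory()]; mainly for round-trip validation.
#'
#' @param unwrapped An `unwrapped_trajectory`.
#' @param species_table Species table for the rebuilt frames.
#' @return An [ion_trajectory()].
#' @export
rewrap_trajectory <- function(unwrapped, species_table = default_species()) {
  stopifnot(inherits(unwrapped, "unwrapped_trajectory"))
  nf <- length(unwrapped$times)
  n <- nrow(unwrapped$start)
  frames <- lapply(seq_len(nf), function(k) {
    p <- unwrapped$start + unwrapped$displacement[, , k]
    p <- p - rep(unwrapped$box, each = n) *
      floor(sweep(p, 2L, unwrapped$box, "/"))
    md_frame(unwrapped$times[k], p, unwrapped$species, unwrapped$box)
  })
  ion_trajectory(frames, species_table)
}

#' Ensemble-mean drift displacement of a species
#'
#' Mean z-displacement versus time over all particles of one species; under
#' a positive applied field its sign follows the species valence
#' (electrophoresis).
#'
#' @param unwrapped An `unwrapped_trajectory` from [unwrap_trajectory()].
#' @param species Species name.
#' @return `data.frame` with `time` (ns), `mean_dz` (nm) and `se_dz`
#'   (standard error over particles).
#' @export
drift_displacement <- function(unwrapped, species) {
  stopifnot(inherits(unwrapped, "unwrapped_trajectory"))
  sel <- unwrapped$species == species
  if (!any(sel)) stop("no particles of species ", species)
  dz <- unwrapped$displacement[sel, 3L, , drop = FALSE]
  nf <- length(unwrapped$times)
  mean_dz <- apply(dz, 3L, mean)
  se_dz <- if (sum(sel) > 1L)
    apply(dz, 3L, stats::sd) / sqrt(sum(sel)) else rep(NA_real_, nf)
  data.frame(time = unwrapped$times, mean_dz = mean_dz, se_dz = se_dz)
}

#' Drift velocity estimate for a species
#'
#' End-point estimator: each particle's total z-displacement divided by the
#' elapsed time, averaged over particles. For a free ion this converges to
#' the Einstein-relation electrophoretic velocity `D q E_z / (kT)`.
#'
#' @inheritParams drift_displacement
#' @return List with `velocity` (nm/ns), `se` (standard error over
#'   particles) and `n` (particle count).
#' @export
drift_velocity <- function(unwrapped, species) {
  stopifnot(inherits(unwrapped, "unwrapped_trajectory"))
  sel <- unwrapped$species == species
  if (!any(sel)) stop("no particles of species ", species)
  nf <- length(unwrapped$times)
  if (nf < 2L) stop("need at least two frames to estimate a velocity")
  dt <- unwrapped$times[nf] - unwrapped$times[1L]
  v <- unwrapped$displacement[sel, 3L, nf] / dt
  list(velocity = mean(v),
       se = if (length(v) > 1L) stats::sd(v) / sqrt(length(v)) else NA_real_,
       n = length(v))
}

#' Ion counts near the membrane faces
#'
#' Counts, per frame and species, the ions within `shell` of each membrane
#' face: the upper face shell is `[z_upper, z_upper + shell]`, the lower
#' `[z_lower - shell, z_lower]`. Under a positive applied field the cation
#' counts at the lower face grow at the expense of the upper face (cations
#' drift along +z and are blocked at the lower face), and conversely for
#' anions.
#'
#' @param trajectory An [ion_trajectory()].
#' @param membrane A [membrane_slab()].
#' @param shell Shell thickness, nm (> 0).
#' @return Long `data.frame` with columns `frame`, `time`, `species`,
#'   `face` (`"upper"`/`"lower"`) and `count`.
#' @export
surface_accumulation <- function(trajectory, membrane, shell = 1.0) {
  stopifnot(inherits(trajectory, "ion_trajectory"),
            inherits(membrane, "membrane_slab"), shell > 0)
  tab <- trajectory$species_table
  sp_names <- unique(trajectory$frames[[1]]$species)
  sp_names <- sp_names[tab$valence[species_lookup(tab, sp_names)] != 0L]
  rows <- list()
  for (k in seq_along(trajectory$frames)) {
    f <- trajectory$frames[[k]]
    z <- f$positions[, 3L]
    for (sp in sp_names) {
      sel <- f$species == sp
      rows[[length(rows) + 1L]] <- data.frame(
        frame = k, time = f$time, species = sp,
        face = c("upper", "lower"),
        count = c(sum(sel & z >= membrane$z_upper &
                        z <= membrane$z_upper + shell),
                  sum(sel & z <= membrane$z_lower &
                        z >= membrane$z_lower - shell)))
    }
  }
  do.call(rbind, rows)
}

#' Charge concentration of an electrolyte
#'
#' The covariate that collapses electroporation behaviour across ion types:
#' defined here (a recorded package convention) as the cation molarity
#' times the cation valence, in mol e / L. NaCl at concentration c gives c;
#' MgCl2 gives 2c. For a [synth_config()] the per-species molarities are
#' recovered from the counts and the solvent-accessible volume.
#'
#' @param x A salt name (`"NaCl"` or `"MgCl2"`) or a [synth_config()].
#' @param concentration Molarity (mol/L) when `x` is a salt name.
#' @return Charge concentration in mol e / L.
#' @examples
#' charge_concentration("NaCl", 0.157)   # 0.157
#' charge_concentration("MgCl2", 0.15)   # 0.30
#' @export
charge_concentration <- function(x, concentration = NULL) {
  if (inherits(x, "synth_config")) {
    v_L <- solvent_volume(x) * .const$nm3_to_L
    idx <- species_lookup(x$species_table, names(x$counts))
    val <- x$species_table$valence[idx]
    cat_sel <- val > 0L
    molar <- x$counts[cat_sel] / (.const$avogadro * v_L)
    return(sum(molar * val[cat_sel]))
  }
  if (!is.character(x) || length(x) != 1L)
    stop("x must be a salt name or a synth_config")
  if (is.null(concentration) || concentration < 0)
    stop("a concentration >= 0 (mol/L) is required with a salt name")
  mult <- switch(x, NaCl = 1, MgCl2 = 2,
                 stop("unknown salt: ", x))
  mult * concentration
}
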