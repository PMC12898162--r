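# Synthetic electrolyte generator: overdamped Langevin dynamics with
# electrophoretic drift, an impermeable membrane slab and optional pairwise
# truncated-Coulomb interactions. This is a statistical stand-in for
# coarse-grained MD, not an MD engine: only stationary electrophoretic
# statistics (drift, surface accumulation, Debye screening) are emulated.

particle_properties <- function(species, species_table) {
  idx <- species_lookup(species_table, species)
  list(D = species_table$diffusion_coefficient[idx],
       q = as.numeric(species_table$valence[idx]),
       mass = species_table$mass[idx])
}

solvent_volume <- function(cfg) {
  v <- prod(cfg$box)
  if (!is.null(cfg$membrane))
    v <- v - cfg$box[1] * cfg$box[2] *
      (cfg$membrane$z_upper - cfg$membrane$z_lower)
  v
}

# uniform z in the solvent region (outside the slab)
sample_solvent_z <- function(n, Lz, membrane) {
  if (is.null(membrane)) return(runif(n, 0, Lz))
  thick <- membrane$z_upper - membrane$z_lower
  u <- runif(n, 0, Lz - thick)
  ifelse(u < membrane$z_lower, u, u + thick)
}

#' Initialize a synthetic system frame
#'
#' Places the configured ions (and free water markers, if
#' `water_density > 0`) uniformly at random in the solvent region, i.e.
#' outside the membrane slab, mirroring random solvent replacement when
#' salting a pre-built system. Deterministic given the seed.
#'
#' @param config A [synth_config()].
#' @param rng_seed Integer seed; `NULL` to use the current RNG state
#'   (as [run_simulation()] does after seeding once).
#' @return An [md_frame()] at time 0.
#' @export
initialize_system <- function(config, rng_seed = config$seed) {
  validate_synth_config(config)
  if (!is.null(rng_seed)) set.seed(as.integer(rng_seed))
  counts <- config$counts[config$counts > 0]
  species <- rep(names(counts), counts)
  n_w <- as.integer(round(config$water_density * solvent_volume(config)))
  if (n_w > 0) species <- c(species, rep("W", n_w))
  n <- length(species)
  pos <- cbind(runif(n, 0, config$box[1]),
               runif(n, 0, config$box[2]),
               sample_solvent_z(n, config$box[3], config$membrane))
  if (n == 0L) pos <- matrix(numeric(0), 0L, 3L)
  f <- md_frame(0, pos, species, config$box)
  validate_frame(f, config$membrane, config$species_table)
  f
}

langevin_args <- function(frame, config) {
  pp <- particle_properties(frame$species, config$species_table)
  m <- config$membrane
  list(pos = frame$positions, D = pp$D, q = pp$q,
       reflect = rep(TRUE, length(pp$q)),
       zlo = if (is.null(m)) 0 else m$z_lower,
       zhi = if (is.null(m)) 0 else m$z_upper,
       has_slab = !is.null(m),
       kT = .const$kB * config$temperature)
}

#' Advance a frame by overdamped Langevin steps
#'
#' One (or more) first-order Brownian-dynamics updates
#' `x' = x + (D/kT) F dt + sqrt(2 D dt) xi` with `F = q E_z zhat` plus,
#' in interacting mode, minimum-image Coulomb forces truncated at
#' `coulomb_cutoff` and scaled by `1/epsilon_r`. Particles wrap periodically
#' in all axes and reflect specularly off the membrane slab faces in z.
#' The free-ion mean drift obeys the Einstein relation
#' `v = D q E_z / (kT)`.
#'
#' @param frame An [md_frame()].
#' @param config A [synth_config()].
#' @param n_steps Number of steps to take (default 1).
#' @return The advanced [md_frame()].
#' @seealso [run_simulation()]
#' @export
step_langevin <- function(frame, config, n_steps = 1L) {
  stopifnot(inherits(frame, "md_frame"), n_steps >= 1L)
  a <- langevin_args(frame, config)
  res <- langevin_run_cpp(a$pos, a$D, a$q, a$reflect, config$box,
                          a$zlo, a$zhi, a$has_slab,
                          config$applied_field_Ez,
                          config$wall_charge_density %||% 0, a$kT,
                          config$timestep, as.integer(n_steps),
                          as.integer(n_steps), config$interacting,
                          config$coulomb_cutoff, config$epsilon_r,
                          .const$coulomb_k, frame$time)
  nf <- dim(res$frames)[3]
  md_frame(res$times[nf], res$frames[, , nf, drop = TRUE],
           frame$species, config$box)
}

#' Pairwise Coulomb forces of a frame
#'
#' Minimum-image truncated Coulomb forces (eV/nm) as used by the interacting
#' generator; mainly exposed for validation (forces on a particle pair are
#' exactly equal and opposite).
#'
#' @param frame An [md_frame()].
#' @param config A [synth_config()] supplying cutoff and `epsilon_r`.
#' @return N x 3 matrix of forces, eV/nm.
#' @export
coulomb_forces <- function(frame, config) {
  pp <- particle_properties(frame$species, config$species_table)
  coulomb_forces_cpp(frame$positions, pp$q, config$box,
                     config$coulomb_cutoff, config$epsilon_r,
                     .const$coulomb_k)
}

#' Run the synthetic Langevin simulation
#'
#' Seeds the RNG, initializes the system and integrates `n_steps` overdamped
#' Langevin steps, storing every `frame_stride`-th frame (plus the initial
#' one). Given the same configuration and seed the result is bit-identical.
#' Under a positive applied field, cations drift along +z and accumulate
#' against the lower slab face (particles in the upper solvent region wrap
#' through the periodic z boundary), anions against the upper face.
#'
#' @param config A [synth_config()].
#' @return An [ion_trajectory()] with `n_steps / frame_stride + 1` frames.
#' @examples
#' cfg <- synth_config(counts = c("NA" = 20, "CL" = 20),
#'                     n_steps = 100, frame_stride = 20, seed = 7)
#' traj <- run_simulation(cfg)
#' traj
#' @export
run_simulation <- function(config) {
  validate_synth_config(config)
  if (config$n_steps %% config$frame_stride != 0L)
    stop("n_steps must be a multiple of frame_stride")
  set.seed(config$seed)
  f0 <- initialize_system(config, rng_seed = NULL)
  if (config$n_steps == 0L)
    return(ion_trajectory(list(f0), config$species_table, config))
  a <- langevin_args(f0, config)
  res <- tryCatch(
    langevin_run_cpp(a$pos, a$D, a$q, a$reflect, config$box,
                     a$zlo, a$zhi, a$has_slab,
                     config$applied_field_Ez,
                     config$wall_charge_density %||% 0, a$kT,
                     config$timestep, config$n_steps, config$frame_stride,
                     config$interacting, config$coulomb_cutoff,
                     config$epsilon_r, .const$coulomb_k, 0),
    error = function(e) stop("simulation stage failed: ", conditionMessage(e),
                             call. = FALSE))
  nf <- dim(res$frames)[3]
  frames <- lapply(seq_len(nf), function(k)
    md_frame(res$times[k],
             matrix(res$frames[, , k], ncol = 3L),
             f0$species, config$box))
  ion_trajectory(frames, config$species_table, config)
}

#' Plant a transmembrane water chain into a frame
#'
#' Adds a straight column of water-marker beads spanning the membrane from
#' `z_lower - bead_spacing` to `z_upper + bead_spacing` at the lateral box
#' center, so the column reaches beyond both leaflet planes. The number of
#' beads is `ceiling(span / bead_spacing) + 1` with the actual spacing
#' shrunk to fit exactly (never exceeding `bead_spacing`). Repeated planting
#' offsets each new column by 1.5 nm in x so columns stay disjoint. Used as
#' a constructed positive control for the pore detector.
#'
#' @param frame An [md_frame()].
#' @param membrane A [membrane_slab()].
#' @param bead_spacing Target bead spacing, nm (> 0).
#' @return The frame with the chain appended; attribute `planted_chains`
#'   counts the planted columns and attribute `chain_ids` lists the particle
#'   indices of each.
#' @export
plant_transmembrane_chain <- function(frame, membrane, bead_spacing = 0.4) {
  stopifnot(inherits(frame, "md_frame"), inherits(membrane, "membrane_slab"),
            bead_spacing > 0)
  n_prev <- attr(frame, "planted_chains") %||% 0L
  span <- (membrane$z_upper - membrane$z_lower) + 2 * bead_spacing
  n_beads <- as.integer(ceiling(span / bead_spacing)) + 1L
  z <- seq(membrane$z_lower - bead_spacing, membrane$z_upper + bead_spacing,
           length.out = n_beads)
  x <- (frame$box[1] / 2 + n_prev * 1.5) %% frame$box[1]
  y <- frame$box[2] / 2
  z <- z %% frame$box[3]  # column may poke through the z boundary
  ids <- nrow(frame$positions) + seq_len(n_beads)
  out <- md_frame(frame$time,
                  rbind(frame$positions, cbind(x, y, z)),
                  c(frame$species, rep("W", n_beads)),
                  frame$box)
  attr(out, "planted_chains") <- n_prev + 1L
  attr(out, "chain_ids") <- c(attr(frame, "chain_ids"), list(ids))
  out
}
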