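#' Membrane slab (the impermeable bilayer region)
#'
#' The bilayer is represented as a hard slab spanning `[z_lower, z_upper]`
#' along the membrane normal: ions never enter it and its faces are the
#' leaflet planes a pore chain must span.
#'
#' @param z_lower,z_upper Slab bounds in nm, `z_lower < z_upper`.
#' @return An object of class `membrane_slab`.
#' @examples
#' membrane_slab(4.15, 8.45)
#' @export
membrane_slab <- function(z_lower, z_upper) {
  stopifnot(is.numeric(z_lower), is.numeric(z_upper),
            length(z_lower) == 1L, length(z_upper) == 1L)
  if (!is.finite(z_lower) || !is.finite(z_upper) || z_lower >= z_upper)
    stop("membrane slab requires z_lower < z_upper")
  structure(list(z_lower = z_lower, z_upper = z_upper),
            class = "membrane_slab")
}

#' @export
print.membrane_slab <- function(x, ...) {
  cat(sprintf("membrane slab: z in [%.3f, %.3f] nm (thickness %.3f nm)\n",
              x$z_lower, x$z_upper, x$z_upper - x$z_lower))
  invisible(x)
}

#' Default membrane slab
#'
#' A 4.3 nm slab centered in the default 12.6 nm box height. The thickness
#' is a package convention chosen so that the solvent layer matches the
#' reference geometry; it is not a measured bilayer property.
#'
#' @param Lz Box height in nm.
#' @param thickness Slab thickness in nm.
#' @return A [membrane_slab()].
#' @export
default_membrane <- function(Lz = 12.6, thickness = 4.3) {
  membrane_slab((Lz - thickness) / 2, (Lz + thickness) / 2)
}

#' Ion counts from a molar salt concentration
#'
#' Converts a molarity into integer particle counts in the solvent-accessible
#' volume (box volume minus the membrane slab). The cation count is rounded
#' to the nearest integer; the chloride count is then fixed by exact
#' electroneutrality (`cations * |valence|`).
#'
#' @param concentration Molar concentration (mol/L), >= 0.
#' @param salt `"NaCl"` or `"MgCl2"`.
#' @param box Numeric length-3 box edges (nm).
#' @param membrane Optional [membrane_slab()] excluded from the solvent
#'   volume; `NULL` for a membrane-free box.
#' @return Named integer vector of counts, e.g. `c("NA" = 373, "CL" = 373)`.
#' @examples
#' counts_from_concentration(0.15, "NaCl", c(18.1, 18.1, 12.6))
#' @export
counts_from_concentration <- function(concentration, salt = c("NaCl", "MgCl2"),
                                      box = c(18.1, 18.1, 12.6),
                                      membrane = NULL) {
  salt <- match.arg(salt)
  if (!is.numeric(concentration) || length(concentration) != 1L ||
      !is.finite(concentration) || concentration < 0)
    stop("concentration must be a single finite number >= 0 (mol/L)")
  stopifnot(length(box) == 3L, all(box > 0))
  v_nm3 <- prod(box)
  if (!is.null(membrane)) {
    stopifnot(inherits(membrane, "membrane_slab"))
    v_nm3 <- v_nm3 - box[1] * box[2] * (membrane$z_upper - membrane$z_lower)
  }
  if (v_nm3 <= 0) stop("solvent-accessible volume must be positive")
  v_L <- v_nm3 * .const$nm3_to_L
  cation <- if (salt == "NaCl") "NA" else "MG"
  zc <- if (salt == "NaCl") 1L else 2L
  n_cat <- as.integer(round(concentration * .const$avogadro * v_L))
  counts <- c(n_cat, n_cat * zc)
  names(counts) <- c(cation, "CL")
  counts
}

#' Configuration of the synthetic electrolyte generator
#'
#' Bundles every parameter of the overdamped Langevin electrolyte/membrane
#' generator: geometry, species counts, applied field, temperature,
#' integration settings, Coulomb interaction settings and the random seed.
#' The defaults mirror the reference system: an 18.1 x 18.1 x 12.6 nm box, a
#' centered impermeable slab, a 0.2 V/nm field along +z and 310 K.
#'
#' @param box Length-3 box edges (nm).
#' @param membrane A [membrane_slab()] or `NULL` (free electrolyte).
#' @param counts Named integer vector of particle counts per species name
#'   (species must exist in `species_table`). Must be electroneutral.
#' @param applied_field_Ez Uniform external field along +z, V/nm.
#' @param temperature Temperature in K.
#' @param timestep Integration step, ns.
#' @param n_steps Number of Langevin steps.
#' @param frame_stride Store every `frame_stride`-th step (plus step 0).
#' @param coulomb_cutoff Hard pair-interaction cutoff, nm.
#' @param seed Integer RNG seed.
#' @param interacting Logical: include pairwise minimum-image Coulomb forces?
#' @param epsilon_r Relative permittivity scaling the pair forces (implicit
#'   solvent); default 78.
#' @param wall_charge_density Surface charge density (e/nm^2) of the
#'   charged-wall test fixture: `+sigma` on the lower slab face, `-sigma`
#'   on the upper, acting on ions through the same truncated laterally
#'   integrated Coulomb kernel as the pair forces. Default 0 (off); used to
#'   validate Debye-layer formation.
#' @param water_density Number density (nm^-3) of free neutral water markers
#'   scattered in the solvent region; default 0 (none).
#' @param species_table Species property table, see [default_species()].
#' @return An object of class `synth_config`.
#' @examples
#' cfg <- synth_config(counts = c("NA" = 20, "CL" = 20), n_steps = 100)
#' cfg
#' @export
synth_config <- function(box = c(18.1, 18.1, 12.6),
                         membrane = default_membrane(box[3]),
                         counts = c("NA" = 0, "CL" = 0),
                         applied_field_Ez = 0.2,
                         temperature = 310,
                         timestep = 1e-3,
                         n_steps = 1000L,
                         frame_stride = 20L,
                         coulomb_cutoff = 1.4,
                         seed = 1L,
                         interacting = FALSE,
                         epsilon_r = 78,
                         wall_charge_density = 0,
                         water_density = 0,
                         species_table = default_species()) {
  cfg <- structure(list(
    box = as.numeric(box), membrane = membrane,
    counts = setNames(as.integer(round(counts)), names(counts)),
    applied_field_Ez = applied_field_Ez, temperature = temperature,
    timestep = timestep, n_steps = as.integer(n_steps),
    frame_stride = as.integer(frame_stride),
    coulomb_cutoff = coulomb_cutoff, seed = as.integer(seed),
    interacting = isTRUE(interacting), epsilon_r = epsilon_r,
    wall_charge_density = wall_charge_density,
    water_density = water_density, species_table = species_table
  ), class = "synth_config")
  validate_synth_config(cfg)
  cfg
}

validate_synth_config <- function(cfg) {
  stopifnot(inherits(cfg, "synth_config"))
  if (length(cfg$box) != 3L || any(!is.finite(cfg$box)) || any(cfg$box <= 0))
    stop("box must be three positive edge lengths (nm)")
  if (!is.null(cfg$membrane)) {
    m <- cfg$membrane
    if (!inherits(m, "membrane_slab")) stop("membrane must be a membrane_slab")
    if (m$z_lower <= 0 || m$z_upper >= cfg$box[3])
      stop("membrane slab must lie strictly inside the box z-extent")
  }
  if (length(cfg$counts) &&
      (is.null(names(cfg$counts)) || any(!nzchar(names(cfg$counts)))))
    stop("counts must be a named vector of species counts")
  if (any(cfg$counts < 0)) stop("species counts must be >= 0")
  idx <- species_lookup(cfg$species_table, names(cfg$counts))
  net <- sum(cfg$counts * cfg$species_table$valence[idx])
  if (net != 0)
    stop("system is not electroneutral: net charge ", net, " e")
  if (!is.finite(cfg$timestep) || cfg$timestep <= 0)
    stop("timestep must be > 0")
  if (cfg$n_steps < 0) stop("n_steps must be >= 0")
  if (cfg$frame_stride < 1) stop("frame_stride must be >= 1")
  if (cfg$interacting && any(cfg$box <= 2 * cfg$coulomb_cutoff))
    stop("box edges must exceed 2*coulomb_cutoff when interacting")
  if (cfg$epsilon_r < 1) stop("epsilon_r must be >= 1")
  if (!is.finite(cfg$wall_charge_density %||% 0))
    stop("wall_charge_density must be finite")
  if ((cfg$wall_charge_density %||% 0) != 0 && is.null(cfg$membrane))
    stop("wall_charge_density requires a membrane slab")
  if (cfg$water_density < 0) stop("water_density must be >= 0")
  invisible(cfg)
}

#' @export
print.synth_config <- function(x, ...) {
  cat("synthetic electrolyte configuration\n")
  cat(sprintf("  box: %.2f x %.2f x %.2f nm\n", x$box[1], x$box[2], x$box[3]))
  if (is.null(x$membrane)) cat("  membrane: none (free electrolyte)\n")
  else cat(sprintf("  membrane: z in [%.2f, %.2f] nm\n",
                   x$membrane$z_lower, x$membrane$z_upper))
  cts <- paste(sprintf("%s=%d", names(x$counts), x$counts), collapse = ", ")
  cat("  counts:", if (nzchar(cts)) cts else "(none)", "\n")
  cat(sprintf("  E_z = %g V/nm, T = %g K, dt = %g ns, %d steps (stride %d)\n",
              x$applied_field_Ez, x$temperature, x$timestep, x$n_steps,
              x$frame_stride))
  cat(sprintf("  interactions: %s (cutoff %g nm, eps_r %g), seed %d\n",
              if (x$interacting) "pairwise Coulomb" else "off",
              x$coulomb_cutoff, x$epsilon_r, x$seed))
  invisible(x)
}

# ---- flat key:value config files -------------------------------------------

config_keys <- function() {
  c("box_lx", "box_ly", "box_lz", "membrane_z_lower", "membrane_z_upper",
    "salt", "concentration", "counts", "applied_field_ez", "temperature",
    "timestep", "n_steps", "frame_stride", "coulomb_cutoff", "seed",
    "interacting", "epsilon_r", "wall_charge_density", "water_density",
    "grid_spacing",
    "assignment_scheme", "pore_cutoff", "pore_persistence", "slab_width",
    "slab_offset", "equilibration_fraction")
}

#' Read a pipeline configuration file
#'
#' The format is a flat `key: value` text file (a strict subset of YAML);
#' blank lines and `#` comments are ignored and unknown keys are an error.
#' Species counts may be given either directly
#' (`counts: NA=200,CL=200`) or as `salt:` + `concentration:` (mol/L), in
#' which case counts are derived with [counts_from_concentration()].
#' Analysis keys (`grid_spacing`, `pore_cutoff`, `pore_persistence`,
#' `slab_width`, `slab_offset`, `equilibration_fraction`,
#' `assignment_scheme`) parameterize the downstream pipeline stages.
#'
#' @param path Path to the config file.
#' @return A list with elements `sim` (a [synth_config()]) and `analysis`
#'   (named list of analysis settings with defaults filled in).
#' @seealso [write_run_config()], [run_pipeline()]
#' @export
read_run_config <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  kv <- regmatches(lines, regexec("^([A-Za-z_]+)\\s*:\\s*(.*)$", lines))
  bad <- vapply(kv, length, 1L) != 3L
  if (any(bad))
    stop("malformed config line(s): ", paste(lines[bad], collapse = "; "))
  keys <- vapply(kv, `[`, "", 2L)
  vals <- trimws(vapply(kv, `[`, "", 3L))
  unknown <- setdiff(keys, config_keys())
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  if (anyDuplicated(keys))
    stop("duplicate config key(s): ",
         paste(unique(keys[duplicated(keys)]), collapse = ", "))
  raw <- setNames(as.list(vals), keys)

  num <- function(key, default) {
    if (is.null(raw[[key]])) return(default)
    x <- suppressWarnings(as.numeric(raw[[key]]))
    if (is.na(x)) stop("config key '", key, "' is not numeric: ", raw[[key]])
    x
  }
  lgl <- function(key, default) {
    if (is.null(raw[[key]])) return(default)
    v <- tolower(raw[[key]])
    if (!v %in% c("true", "false", "yes", "no"))
      stop("config key '", key, "' is not a boolean: ", raw[[key]])
    v %in% c("true", "yes")
  }

  box <- c(num("box_lx", 18.1), num("box_ly", 18.1), num("box_lz", 12.6))
  membrane <- if (identical(tolower(raw[["membrane_z_lower"]] %||% ""), "none"))
    NULL
  else membrane_slab(num("membrane_z_lower", default_membrane(box[3])$z_lower),
                     num("membrane_z_upper", default_membrane(box[3])$z_upper))

  if (!is.null(raw[["counts"]])) {
    parts <- strsplit(raw[["counts"]], ",", fixed = TRUE)[[1]]
    parts <- trimws(parts)
    m <- regmatches(parts, regexec("^([A-Za-z]+)\\s*=\\s*([0-9]+)$", parts))
    if (any(vapply(m, length, 1L) != 3L))
      stop("malformed counts entry in config: ", raw[["counts"]])
    counts <- setNames(as.integer(vapply(m, `[`, "", 3L)),
                       toupper(vapply(m, `[`, "", 2L)))
  } else if (!is.null(raw[["salt"]])) {
    counts <- counts_from_concentration(num("concentration", 0),
                                        salt = raw[["salt"]],
                                        box = box, membrane = membrane)
  } else {
    counts <- c("NA" = 0L, "CL" = 0L)
  }

  sim <- synth_config(
    box = box, membrane = membrane, counts = counts,
    applied_field_Ez = num("applied_field_ez", 0.2),
    temperature = num("temperature", 310),
    timestep = num("timestep", 1e-3),
    n_steps = num("n_steps", 1000),
    frame_stride = num("frame_stride", 20),
    coulomb_cutoff = num("coulomb_cutoff", 1.4),
    seed = num("seed", 1),
    interacting = lgl("interacting", FALSE),
    epsilon_r = num("epsilon_r", 78),
    wall_charge_density = num("wall_charge_density", 0),
    water_density = num("water_density", 0)
  )
  analysis <- list(
    grid_spacing = num("grid_spacing", 0.1),
    assignment_scheme = raw[["assignment_scheme"]] %||% "CIC",
    pore_cutoff = num("pore_cutoff", 0.55),
    pore_persistence = num("pore_persistence", 2),
    slab_width = num("slab_width", 1.0),
    slab_offset = num("slab_offset", 1.0),
    equilibration_fraction = num("equilibration_fraction", 0.25),
    salt = raw[["salt"]],
    concentration = if (is.null(raw[["concentration"]])) NULL
                    else num("concentration", NA)
  )
  if (!analysis$assignment_scheme %in% c("CIC", "NGP"))
    stop("assignment_scheme must be CIC or NGP")
  list(sim = sim, analysis = analysis)
}

#' Write a pipeline configuration file
#'
#' Inverse of [read_run_config()]: serializes a `synth_config` plus analysis
#' settings to the flat `key: value` format.
#'
#' @param config A list with `sim` and (optionally) `analysis` as returned by
#'   [read_run_config()], or a bare [synth_config()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_run_config <- function(config, path) {
  if (inherits(config, "synth_config")) config <- list(sim = config)
  sim <- config$sim
  an <- config$analysis %||% list()
  lines <- c(
    sprintf("box_lx: %.10g", sim$box[1]),
    sprintf("box_ly: %.10g", sim$box[2]),
    sprintf("box_lz: %.10g", sim$box[3]),
    if (is.null(sim$membrane)) "membrane_z_lower: none" else c(
      sprintf("membrane_z_lower: %.10g", sim$membrane$z_lower),
      sprintf("membrane_z_upper: %.10g", sim$membrane$z_upper)),
    sprintf("counts: %s",
            paste(sprintf("%s=%d", names(sim$counts), sim$counts),
                  collapse = ",")),
    sprintf("applied_field_ez: %.10g", sim$applied_field_Ez),
    sprintf("temperature: %.10g", sim$temperature),
    sprintf("timestep: %.10g", sim$timestep),
    sprintf("n_steps: %d", sim$n_steps),
    sprintf("frame_stride: %d", sim$frame_stride),
    sprintf("coulomb_cutoff: %.10g", sim$coulomb_cutoff),
    sprintf("seed: %d", sim$seed),
    sprintf("interacting: %s", tolower(as.character(sim$interacting))),
    sprintf("epsilon_r: %.10g", sim$epsilon_r),
    sprintf("wall_charge_density: %.10g", sim$wall_charge_density %||% 0),
    sprintf("water_density: %.10g", sim$water_density)
  )
  defaults <- list(grid_spacing = 0.1, assignment_scheme = "CIC",
                   pore_cutoff = 0.55, pore_persistence = 2,
                   slab_width = 1.0, slab_offset = 1.0,
                   equilibration_fraction = 0.25)
  for (k in names(defaults)) {
    v <- an[[k]] %||% defaults[[k]]
    lines <- c(lines, if (is.character(v)) sprintf("%s: %s", k, v)
                      else sprintf("%s: %.10g", k, v))
  }
  writeLines(lines, path)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
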