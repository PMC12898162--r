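# Orchestration: simulate -> grid -> solve -> detect -> report.

config_hash <- function(config) {
  txt <- paste(utils::capture.output(utils::str(config)), collapse = "\n")
  b <- utf8ToInt(txt)
  h <- 0
  for (x in b) h <- (h * 31 + x) %% 2147483647
  sprintf("%08x", h)
}

stage_log <- function(stage, hash, detail) {
  message(sprintf("[innerpot] stage=%s config=%s %s", stage, hash, detail))
}

with_stage <- function(stage, hash, expr) {
  t0 <- proc.time()[["elapsed"]]
  res <- tryCatch(expr, error = function(e)
    stop(sprintf("stage '%s' failed: %s", stage, conditionMessage(e)),
         call. = FALSE))
  stage_log(stage, hash, sprintf("wall=%.2fs", proc.time()[["elapsed"]] - t0))
  res
}

# analysis-window frames: after equilibration, strictly before the pore
analysis_window <- function(times, eq_fraction, pore_frame = NA_integer_) {
  nf <- length(times)
  last <- if (is.na(pore_frame)) nf else max(1L, pore_frame - 1L)
  first <- which(times >= eq_fraction * times[nf])[1]
  if (is.na(first) || first > last) first <- 1L
  first:last
}

#' Run the full analysis pipeline
#'
#' Simulates a synthetic electrolyte/membrane trajectory, grids the ionic
#' charges frame by frame, time-averages the charge density over the
#' analysis window (after equilibration, strictly before pore formation),
#' solves Poisson's equation, extracts the inner potential, detects the
#' pore event and summarizes ion kinematics. Deterministic given the config
#' seed. With `outdir` set, also writes the trajectory (GRO + XYZ), cube
#' grids, TSV profiles/map, the echoed config and a JSON report.
#'
#' @param config A config-file path, a list with `sim`/`analysis` as from
#'   [read_run_config()], or a bare [synth_config()].
#' @param outdir Optional output directory (created if missing).
#' @param quiet Suppress per-stage log lines.
#' @return An object of class `pipeline_report`.
#' @examples
#' cfg <- synth_config(counts = c("NA" = 20, "CL" = 20),
#'                     n_steps = 100, frame_stride = 20, seed = 3)
#' rep <- run_pipeline(list(sim = cfg, analysis = list(grid_spacing = 0.6)),
#'                     quiet = TRUE)
#' rep$inner_potential
#' @export
run_pipeline <- function(config, outdir = NULL, quiet = FALSE) {
  if (is.character(config)) config <- read_run_config(config)
  if (inherits(config, "synth_config")) config <- list(sim = config)
  sim <- config$sim
  stopifnot(inherits(sim, "synth_config"))
  an <- utils::modifyList(
    list(grid_spacing = 0.1, assignment_scheme = "CIC", pore_cutoff = 0.55,
         pore_persistence = 2, slab_width = 1.0, slab_offset = 1.0,
         equilibration_fraction = 0.25, salt = NULL, concentration = NULL),
    config$analysis %||% list())
  hash <- config_hash(list(sim = sim, analysis = an))
  logq <- function(expr, stage) {
    if (quiet) suppressMessages(with_stage(stage, hash, expr))
    else with_stage(stage, hash, expr)
  }

  traj <- logq(run_simulation(sim), "simulate")
  times <- frame_times(traj)

  pore <- if (!is.null(sim$membrane))
    logq(electroporation_time(traj, sim$membrane, an$pore_cutoff,
                              an$pore_persistence), "pore")
  else structure(list(frame_index = NA_integer_, time = times[length(times)],
                      chain_particle_ids = integer(0), censored = TRUE),
                 class = "pore_event")

  spec <- default_grid_spec(sim$box, an$grid_spacing)
  window <- analysis_window(times, an$equilibration_fraction,
                            if (pore$censored) NA_integer_ else
                              pore$frame_index)
  rho <- logq({
    grids <- lapply(traj$frames[window], assign_charges, spec = spec,
                    scheme = an$assignment_scheme,
                    species_table = sim$species_table)
    time_average(grids)
  }, "density")

  phi <- logq(solve_poisson(rho, epsilon_r = 1), "potential")
  pmap <- y_average(phi)
  ip <- if (!is.null(sim$membrane))
    logq(inner_potential(phi, sim$membrane, an$slab_width, an$slab_offset),
         "inner_potential")
  else NULL

  kin <- logq({
    uw <- unwrap_trajectory(traj)
    tab <- sim$species_table
    sp <- unique(traj$frames[[1]]$species)
    sp <- sp[tab$valence[species_lookup(tab, sp)] != 0L]
    do.call(rbind, lapply(sp, function(s) {
      dv <- drift_velocity(uw, s)
      data.frame(species = s, drift_velocity = dv$velocity,
                 se = dv$se, n = dv$n)
    }))
  }, "kinematics")

  report <- structure(list(
    config = list(sim = sim, analysis = an),
    config_hash = hash,
    seed = sim$seed,
    software_version = as.character(utils::packageVersion("innerpot")),
    electroporation_time = if (pore$censored) NA_real_ else pore$time,
    censored = pore$censored,
    pore_event = pore,
    inner_potential = if (is.null(ip)) NA_real_ else ip$delta_phi,
    inner_potential_result = ip,
    charge_concentration = charge_concentration(sim),
    kinematics = kin,
    charge_density = rho,
    potential = phi,
    potential_map = pmap,
    files = character(0)
  ), class = "pipeline_report")

  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    p <- function(f) file.path(outdir, f)
    files <- c(
      config = write_run_config(list(sim = sim, analysis = an),
                                p("run_config.txt")),
      trajectory_gro = write_gro(traj, p("trajectory.gro")),
      trajectory_xyz = write_xyz(traj, p("trajectory.xyz")),
      charge_density = write_cube(rho, p("charge_density.cube")),
      potential = write_cube(phi, p("potential.cube")),
      potential_map = write_potential_map(pmap, p("potential_map.tsv")),
      charge_profile = write_axial_profile(axial_charge_profile(rho),
                                           p("charge_profile.tsv")),
      potential_profile = write_axial_profile(
        axial_potential_profile(phi), p("potential_profile.tsv")))
    report$files <- files
    write_run_report(report, p("report.json"))
    report$files <- c(files, report = p("report.json"))
    if (!quiet) stage_log("write", hash, sprintf("outdir=%s", outdir))
  }
  report
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat("innerpot pipeline report (seed", x$seed, ")\n")
  cat(sprintf("  charge concentration: %.4g mol e/L\n",
              x$charge_concentration))
  if (x$censored)
    cat(sprintf("  electroporation: censored (no pore within %.4g ns)\n",
                x$pore_event$time))
  else
    cat(sprintf("  electroporation time: %.4g ns\n", x$electroporation_time))
  cat(sprintf("  inner potential: %s\n",
              if (is.na(x$inner_potential)) "n/a (no membrane)"
              else sprintf("%+.4g V", x$inner_potential)))
  if (!is.null(x$kinematics) && nrow(x$kinematics)) {
    for (i in seq_len(nrow(x$kinematics)))
      cat(sprintf("  drift %s: %+.3g nm/ns\n", x$kinematics$species[i],
                  x$kinematics$drift_velocity[i]))
  }
  invisible(x)
}

#' Write a pipeline report as JSON
#'
#' Serializes the scalar results (times, inner potential, charge
#' concentration, drift table, conventions, file paths); grids are written
#' separately as cube files.
#'
#' @param report A `pipeline_report`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_run_report <- function(report, path) {
  stopifnot(inherits(report, "pipeline_report"))
  sim <- report$config$sim
  out <- list(
    software = "innerpot",
    version = report$software_version,
    seed = report$seed,
    config_hash = report$config_hash,
    counts = as.list(sim$counts),
    applied_field_Ez_V_per_nm = sim$applied_field_Ez,
    temperature_K = sim$temperature,
    charge_concentration_mol_e_per_L = report$charge_concentration,
    electroporation_time_ns = if (report$censored) "censored"
                              else report$electroporation_time,
    censored = report$censored,
    inner_potential_V = if (is.na(report$inner_potential)) NULL
                        else report$inner_potential,
    inner_potential_convention = if (is.null(report$inner_potential_result))
      NULL
    else list(definition = "mean potential in upper bulk slab minus lower",
              slab_width_nm = report$inner_potential_result$slab_width,
              slab_offset_nm = report$inner_potential_result$slab_offset,
              gauge = "zero-mean potential (k=0 mode removed)"),
    drift = report$kinematics,
    files = as.list(report$files)
  )
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Concentration sweep with replicate seeds
#'
#' Runs the full pipeline over a set of salt concentrations, `n_seeds`
#' replicates each (replicate seeds are derived deterministically from the
#' base config seed), and aggregates per condition. Censored runs are
#' counted separately and never averaged as finite times. Duplicate
#' concentrations are merged with combined seed counts.
#'
#' @param base_config A [synth_config()] used as the template (its counts
#'   are replaced per concentration).
#' @param concentrations Numeric vector of molarities (mol/L), non-empty.
#' @param salt `"NaCl"` or `"MgCl2"`.
#' @param n_seeds Replicates per concentration (>= 1).
#' @param analysis Named list of analysis settings passed to
#'   [run_pipeline()] (e.g. `grid_spacing`).
#' @return A `data.frame` of class `sweep_summary` with one row per
#'   condition (mean and sd of the inner potential, uncensored-mean pore
#'   time, censored count); attribute `runs` holds the per-run table.
#' @export
concentration_sweep <- function(base_config, concentrations,
                                salt = c("NaCl", "MgCl2"), n_seeds = 5L,
                                analysis = list()) {
  salt <- match.arg(salt)
  stopifnot(inherits(base_config, "synth_config"))
  if (length(concentrations) == 0L)
    stop("concentrations must be a non-empty numeric vector")
  n_seeds <- as.integer(n_seeds)
  if (n_seeds < 1L) stop("n_seeds must be >= 1")
  runs <- list()
  for (i in seq_along(concentrations)) {
    conc <- concentrations[i]
    counts <- counts_from_concentration(conc, salt, base_config$box,
                                        base_config$membrane)
    for (j in seq_len(n_seeds)) {
      cfg <- base_config
      cfg$counts <- counts
      cfg$seed <- as.integer((base_config$seed + 1009L * i + j) %% 2^31)
      validate_synth_config(cfg)
      rep <- run_pipeline(list(sim = cfg, analysis = analysis), quiet = TRUE)
      runs[[length(runs) + 1L]] <- data.frame(
        salt = salt, concentration = conc,
        charge_concentration = rep$charge_concentration,
        seed = cfg$seed,
        inner_potential = rep$inner_potential,
        pore_time = rep$electroporation_time,
        censored = rep$censored)
    }
  }
  runs <- do.call(rbind, runs)
  agg <- function(f) aggregate(
    runs[c("inner_potential", "pore_time", "censored")],
    by = runs[c("salt", "concentration")], FUN = f)
  key <- unique(runs[c("salt", "concentration")])
  key <- key[order(key$concentration), , drop = FALSE]
  summ <- do.call(rbind, lapply(seq_len(nrow(key)), function(r) {
    sel <- runs$salt == key$salt[r] & runs$concentration == key$concentration[r]
    s <- runs[sel, ]
    unc <- !s$censored
    data.frame(
      salt = key$salt[r],
      concentration = key$concentration[r],
      charge_concentration = s$charge_concentration[1],
      n_runs = nrow(s),
      inner_potential_mean = mean(s$inner_potential),
      inner_potential_sd = if (nrow(s) > 1) sd(s$inner_potential) else NA_real_,
      pore_time_mean = if (any(unc)) mean(s$pore_time[unc]) else NA_real_,
      n_censored = sum(s$censored))
  }))
  rownames(summ) <- NULL
  structure(summ, class = c("sweep_summary", "data.frame"), runs = runs)
}

#' @export
print.sweep_summary <- function(x, ...) {
  cat("concentration sweep summary (censored runs never averaged):\n")
  df <- as.data.frame(x)
  df$pore_time_mean <- ifelse(is.na(df$pore_time_mean) & df$n_censored > 0,
                              sprintf("censored (%d)", df$n_censored),
                              format(df$pore_time_mean, digits = 4))
  print.data.frame(df, row.names = FALSE)
  invisible(x)
}
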