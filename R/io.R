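# Text I/O: multi-frame GRO and XYZ trajectories, Gaussian cube scalar
# fields, TSV axial profiles and potential maps. All formats are plain text
# and round-trip within their stated precision.

#' Write a trajectory as multi-frame GRO
#'
#' One GRO model per frame (title line carrying `t= <ns>`, atom count,
#' fixed-width atom records, per-frame box line). Residue and atom names
#' are the species labels; coordinates are written in nm with 3 decimals
#' (the GRO dialect), so round-tripping is exact to 0.001 nm/0.0005 nm.
#'
#' @param trajectory An [ion_trajectory()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @seealso [read_gro()], [write_xyz()]
#' @export
write_gro <- function(trajectory, path) {
  stopifnot(inherits(trajectory, "ion_trajectory"))
  con <- file(path, "w")
  on.exit(close(con))
  for (f in trajectory$frames) {
    n <- nrow(f$positions)
    writeLines(sprintf("synthetic electrolyte trajectory, t= %.6f ns",
                       f$time), con)
    writeLines(sprintf("%5d", n), con)
    if (n) {
      id <- (seq_len(n) - 1L) %% 99999L + 1L
      writeLines(sprintf("%5d%-5s%5s%5d%8.3f%8.3f%8.3f",
                         id, f$species, f$species, id,
                         f$positions[, 1], f$positions[, 2],
                         f$positions[, 3]), con)
    }
    writeLines(sprintf("%10.5f%10.5f%10.5f", f$box[1], f$box[2], f$box[3]),
               con)
  }
  invisible(path)
}

#' Read a multi-frame GRO trajectory
#'
#' @param path Path to a GRO file written by [write_gro()] (or any GRO with
#'   `t=` time stamps in the title lines).
#' @param species_table Species table used to validate species names.
#' @return An [ion_trajectory()].
#' @export
read_gro <- function(path, species_table = default_species()) {
  lines <- readLines(path, warn = FALSE)
  frames <- list()
  i <- 1L
  while (i <= length(lines)) {
    title <- lines[i]
    n <- as.integer(trimws(lines[i + 1L]))
    if (is.na(n)) stop("malformed GRO atom-count line at line ", i + 1L)
    atoms <- lines[i + 1L + seq_len(n)]
    box <- as.numeric(strsplit(trimws(lines[i + 2L + n]), "\\s+")[[1]])[1:3]
    tm <- regmatches(title, regexec("t=\\s*([-0-9.eE+]+)", title))[[1]]
    time <- if (length(tm) == 2L) as.numeric(tm[2]) else length(frames)
    species <- trimws(substr(atoms, 6L, 10L))
    pos <- cbind(as.numeric(substr(atoms, 21L, 28L)),
                 as.numeric(substr(atoms, 29L, 36L)),
                 as.numeric(substr(atoms, 37L, 44L)))
    if (n == 0L) pos <- matrix(numeric(0), 0L, 3L)
    frames[[length(frames) + 1L]] <- md_frame(time, pos, species, box)
    i <- i + 3L + n
  }
  ion_trajectory(frames, species_table)
}

#' Write a trajectory as multi-frame XYZ
#'
#' Plain XYZ frames whose comment line carries the time stamp and box
#' (`t= <ns> box= Lx Ly Lz`), coordinates in nm with 6 decimals.
#'
#' @inheritParams write_gro
#' @return `path`, invisibly.
#' @export
write_xyz <- function(trajectory, path) {
  stopifnot(inherits(trajectory, "ion_trajectory"))
  con <- file(path, "w")
  on.exit(close(con))
  for (f in trajectory$frames) {
    n <- nrow(f$positions)
    writeLines(as.character(n), con)
    writeLines(sprintf("t= %.9g box= %.9g %.9g %.9g",
                       f$time, f$box[1], f$box[2], f$box[3]), con)
    if (n)
      writeLines(sprintf("%-5s %12.6f %12.6f %12.6f", f$species,
                         f$positions[, 1], f$positions[, 2],
                         f$positions[, 3]), con)
  }
  invisible(path)
}

#' Read a multi-frame XYZ trajectory
#'
#' @inheritParams read_gro
#' @return An [ion_trajectory()].
#' @export
read_xyz <- function(path, species_table = default_species()) {
  lines <- readLines(path, warn = FALSE)
  frames <- list()
  i <- 1L
  while (i <= length(lines)) {
    n <- as.integer(trimws(lines[i]))
    if (is.na(n)) stop("malformed XYZ count line at line ", i)
    comment <- lines[i + 1L]
    tm <- regmatches(comment, regexec(
      "t=\\s*([-0-9.eE+]+)\\s+box=\\s*([-0-9.eE+]+)\\s+([-0-9.eE+]+)\\s+([-0-9.eE+]+)",
      comment))[[1]]
    if (length(tm) != 5L)
      stop("XYZ comment line lacks 't= ... box= ...' at line ", i + 1L)
    time <- as.numeric(tm[2])
    box <- as.numeric(tm[3:5])
    rows <- strsplit(trimws(lines[i + 1L + seq_len(n)]), "\\s+")
    species <- vapply(rows, `[`, "", 1L)
    pos <- t(vapply(rows, function(r) as.numeric(r[2:4]), numeric(3L)))
    if (n == 0L) { pos <- matrix(numeric(0), 0L, 3L); species <- character(0) }
    frames[[length(frames) + 1L]] <- md_frame(time, pos, species, box)
    i <- i + 2L + n
  }
  ion_trajectory(frames, species_table)
}

# ---- Gaussian cube ----------------------------------------------------------

#' Write a scalar grid as a Gaussian cube file
#'
#' Standard cube layout (lengths in Bohr, one dummy atom, z-fastest value
#' order). Charge densities are converted to the cube-native e/bohr^3;
#' potential (V) and mass density (kg/m^3) are stored unconverted, with the
#' dialect recorded in the header comment so [read_cube()] can invert it.
#'
#' @param grid A [scalar_grid()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cube <- function(grid, path) {
  stopifnot(inherits(grid, "scalar_grid"))
  b <- .const$bohr_per_nm
  dims <- grid$spec$dims
  vals <- grid$values
  conv <- if (grid$quantity == "charge_density") 1 / b^3 else 1
  unit_note <- switch(grid$quantity,
                      charge_density = "values in e/bohr^3",
                      potential = "values in V (dialect: not atomic units)",
                      mass_density = "values in kg/m^3 (dialect)")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("innerpot scalar field: %s", grid$quantity),
               unit_note), con)
  writeLines(sprintf("%5d%12.6f%12.6f%12.6f", 1L, 0, 0, 0), con)
  for (a in 1:3) {
    v <- c(0, 0, 0)
    v[a] <- grid$spec$spacing[a] * b
    writeLines(sprintf("%5d%12.6f%12.6f%12.6f", dims[a], v[1], v[2], v[3]),
               con)
  }
  writeLines(sprintf("%5d%12.6f%12.6f%12.6f%12.6f", 1L, 0, 0, 0, 0), con)
  # cube order: x slowest, z fastest
  flat <- as.vector(aperm(vals, c(3, 2, 1))) * conv
  pad <- (-length(flat)) %% 6L
  if (pad) flat <- c(flat, rep(NA_real_, pad))
  m <- matrix(flat, nrow = 6L)
  lines <- apply(m, 2L, function(r)
    paste(sprintf("%13.5E", r[!is.na(r)]), collapse = ""))
  writeLines(lines, con)
  invisible(path)
}

#' Read a Gaussian cube file written by [write_cube()]
#'
#' @param path Path to the cube file.
#' @return A [scalar_grid()].
#' @export
read_cube <- function(path) {
  lines <- readLines(path, warn = FALSE)
  quantity <- sub("^innerpot scalar field:\\s*", "", lines[1])
  if (!quantity %in% c("charge_density", "potential", "mass_density"))
    stop("unrecognized cube header: ", lines[1])
  hdr <- function(k) as.numeric(strsplit(trimws(lines[k]), "\\s+")[[1]])
  natoms <- as.integer(hdr(3)[1])
  b <- .const$bohr_per_nm
  dims <- integer(3L)
  spacing <- numeric(3L)
  for (a in 1:3) {
    v <- hdr(3L + a)
    dims[a] <- as.integer(v[1])
    spacing[a] <- v[1L + a] / b
  }
  first_val <- 4L + 3L + natoms
  vals <- as.numeric(unlist(strsplit(trimws(lines[first_val:length(lines)]),
                                     "\\s+")))
  if (length(vals) != prod(dims))
    stop("cube value count does not match grid dims")
  conv <- if (quantity == "charge_density") b^3 else 1
  arr <- aperm(array(vals, dim = rev(dims)), c(3, 2, 1)) * conv
  scalar_grid(grid_spec(dims, spacing), arr, quantity)
}

# ---- TSV profiles and maps --------------------------------------------------

#' Write an axial profile as 2-column TSV
#'
#' Header comments name the quantity and units; columns are `z_nm` and
#' `value`.
#'
#' @param profile An [axial_profile()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_axial_profile <- function(profile, path) {
  stopifnot(inherits(profile, "axial_profile"))
  writeLines(c(sprintf("# axial profile: %s", profile$quantity),
               sprintf("# units: %s", profile$units),
               "z_nm\tvalue",
               sprintf("%.10g\t%.10g", profile$z_centers, profile$values)),
             path)
  invisible(path)
}

#' Read an axial profile TSV
#' @param path Path written by [write_axial_profile()].
#' @return An [axial_profile()].
#' @export
read_axial_profile <- function(path) {
  lines <- readLines(path, warn = FALSE)
  quantity <- sub("^# axial profile:\\s*", "", lines[1])
  units <- sub("^# units:\\s*", "", lines[2])
  df <- read.table(text = lines[-(1:3)], sep = "\t",
                   col.names = c("z", "value"))
  axial_profile(df$z, df$value, quantity, units)
}

#' Write a 2D potential map as TSV
#'
#' A matrix with x node coordinates down the first column and z node
#' coordinates across the header row; values in volts.
#'
#' @param map A [potential_map2d()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_potential_map <- function(map, path) {
  stopifnot(inherits(map, "potential_map2d"))
  header <- paste(c("x_nm", sprintf("%.10g", map$z_centers)),
                  collapse = "\t")
  rows <- vapply(seq_along(map$x_centers), function(i)
    paste(c(sprintf("%.10g", map$x_centers[i]),
            sprintf("%.10g", map$values[i, ])), collapse = "\t"), "")
  writeLines(c("# potential map (V); rows = x (nm), columns = z (nm)",
               header, rows), path)
  invisible(path)
}

#' Read a 2D potential map TSV
#' @param path Path written by [write_potential_map()].
#' @return A [potential_map2d()].
#' @export
read_potential_map <- function(path) {
  lines <- readLines(path, warn = FALSE)
  z <- as.numeric(strsplit(lines[2], "\t")[[1]][-1])
  body <- do.call(rbind, lapply(strsplit(lines[-(1:2)], "\t"), as.numeric))
  potential_map2d(body[, 1], z, body[, -1, drop = FALSE])
}
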