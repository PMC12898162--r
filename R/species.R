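#' Define an ion (or water-marker) species
#'
#' A species record carries the properties the Langevin generator and the
#' gridding/kinematics stages need: valence (in elementary charges),
#' diffusion coefficient (nm^2/ns) and mass (amu). Water markers are
#' represented as a zero-valence species; they are excluded from all charge
#' assignment (only solution ions contribute to the charge density) but are
#' the particles the pore detector looks at.
#'
#' @param name Short label, e.g. `"NA"`, `"CL"`, `"MG"`, `"W"`.
#' @param valence Signed integer charge in e; must be in -2..2.
#' @param diffusion_coefficient Positive diffusion coefficient, nm^2/ns.
#' @param mass Positive particle mass, amu.
#' @return A one-row `data.frame` with the four fields.
#' @seealso [default_species()]
#' @export
ion_species <- function(name, valence, diffusion_coefficient, mass) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  if (!valence %in% c(-2L, -1L, 0L, 1L, 2L))
    stop("valence must be an integer in {-2,-1,0,+1,+2}, got ", valence)
  if (!is.finite(diffusion_coefficient) || diffusion_coefficient <= 0)
    stop("diffusion_coefficient must be > 0")
  if (!is.finite(mass) || mass <= 0)
    stop("mass must be > 0")
  data.frame(name = name, valence = as.integer(valence),
             diffusion_coefficient = diffusion_coefficient, mass = mass,
             stringsAsFactors = FALSE)
}

#' Built-in species table
#'
#' Na+, Cl-, Mg2+ and the neutral water marker `W`. Diffusion coefficients
#' are standard infinite-dilution values (nm^2/ns); the source study states
#' none, so these are package conventions. The water marker mass of 72 amu
#' reflects a 4-to-1 coarse-grained water bead, which makes a uniform marker
#' number density of about 8.74 nm^-3 correspond to 1045 kg/m^3.
#'
#' @return A `data.frame` with one row per species
#'   (`NA`, `CL`, `MG`, `W`).
#' @examples
#' default_species()
#' @export
default_species <- function() {
  rbind(
    ion_species("NA", +1L, 1.33, 22.990),
    ion_species("CL", -1L, 2.03, 35.453),
    ion_species("MG", +2L, 0.706, 24.305),
    ion_species("W", 0L, 2.30, 72.0)
  )
}

species_lookup <- function(species_table, names) {
  idx <- match(names, species_table$name)
  if (anyNA(idx))
    stop("unknown species: ", paste(unique(names[is.na(idx)]), collapse = ", "))
  idx
}
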