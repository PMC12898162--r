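# Unit system: length nm, time ns, charge e, energy eV, potential V.
# In these units eV/e = V, so Poisson output is directly in volts.

#' Physical constants in the package unit system
#'
#' Named constants used throughout: lengths in nm, time in ns, charge in
#' elementary charges (e), energy in eV, potential in V.
#'
#' * `kB` — Boltzmann constant, 8.617333e-5 eV/K.
#' * `coulomb_k` — Coulomb constant 1/(4 pi eps0), 1.43996 eV nm / e^2.
#' * `eps0` — vacuum permittivity, e / (V nm), derived from `coulomb_k`.
#' * `avogadro` — Avogadro constant, 1/mol.
#' * `nm3_to_L` — litres per cubic nanometre (1e-24).
#' * `amu_per_nm3_to_kg_m3` — converts amu/nm^3 to kg/m^3 (1.66053907).
#' * `bohr_per_nm` — Bohr radii per nm (used by cube-file I/O).
#'
#' @return A named list of constants.
#' @examples
#' ip_constants()$kB * 310  # thermal energy at 310 K, in eV
#' @export
ip_constants <- function() {
  list(
    kB = 8.617333e-5,
    coulomb_k = 1.43996,
    eps0 = 1 / (4 * pi * 1.43996),
    avogadro = 6.02214076e23,
    nm3_to_L = 1e-24,
    amu_per_nm3_to_kg_m3 = 1.66053907,
    bohr_per_nm = 18.89726125
  )
}

.const <- ip_constants()
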