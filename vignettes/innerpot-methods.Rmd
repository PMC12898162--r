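---
title: "Methods: synthetic electrolytes, the inner potential, and pore detection"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: synthetic electrolytes, the inner potential, and pore detection}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(innerpot)
```

## The problem and the model

Electroporation — field-induced pore formation in a lipid bilayer — is
modulated by the ionic environment. Under an applied field ions migrate
electrophoretically, accumulate against the impermeable membrane, and the
resulting charge double layers create an *inner potential* that
redistributes the electric field across the system. This package
implements the analysis chain that quantifies this mechanism:

1. a **synthetic trajectory generator** (Brownian electrolyte with a hard
   membrane slab) standing in for coarse-grained MD;
2. **charge gridding** of the solution ions (water and any membrane
   markers carry no charge here);
3. a **spectral Poisson solve** of the time-averaged ionic charge density;
4. the **inner potential** scalar and 2D maps;
5. **pore detection** via transmembrane water chains, with censoring;
6. **ion kinematics** (unwrapping, drift, surface accumulation, charge
   concentration).

Units are nm, ns, elementary charge e, eV and V throughout, with
`k_B = 8.617333e-5` eV/K and `1/(4 pi eps0) = 1.43996` eV nm/e^2, so the
Poisson solve returns volts directly.

## The generator: overdamped Langevin electrolyte

Each particle follows the first-order update

```
x' = x + (D / k_B T) F dt + sqrt(2 D dt) xi,
```

with `F = q E_z zhat` plus, in interacting mode, minimum-image Coulomb
forces `k_e q_i q_j / (eps_r r^2)` hard-truncated at `coulomb_cutoff`.
Dynamics are inertialess by design: only the stationary electrophoretic
statistics matter to the analysis, not force-field kinetics. Boundaries
are periodic in all axes; the membrane slab reflects specularly in z,
which preserves the uniform equilibrium density in the field-free case.
The solvent is implicit (a uniform `eps_r`, default 78, scales pair
forces); explicit neutral water markers exist only for pore detection and
density calibration. The membrane interior is excluded volume, not a
dielectric discontinuity — consistent with solving Poisson's equation with
vacuum permittivity and ion charges only.

Key defaults and why:

| parameter | default | rationale |
|---|---|---|
| box | 18.1 x 18.1 x 12.6 nm | reference system geometry |
| membrane slab | 4.3 nm thick, centred | matches the solvent layer convention; a package convention, not a measured bilayer thickness |
| `applied_field_Ez` | 0.2 V/nm | the field used in the source setting |
| temperature | 310 K | physiological |
| `timestep` | 1e-3 ns | drift and diffusion per step stay far below grid and box scales |
| diffusion coefficients | Na+ 1.33, Cl- 2.03, Mg2+ 0.706, W 2.30 nm^2/ns | standard infinite-dilution values; the source states none, so these are labelled conventions |
| `coulomb_cutoff` | 1.4 nm | echoes the electrostatics cutoff convention of the reference setting |
| water marker | 72 amu, 8.74 nm^-3 | a 4:1 coarse-grained bead; at that density the solvent plateau is 1045 kg/m^3 |

Ion counts come from molarity via `round(c N_A V_solvent)` on the cation,
with the chloride count fixed by exact electroneutrality. Free-ion drift
obeys the Einstein relation: `D q E_z / k_B T = 7.49` nm/ns for a
`D = 1` monovalent ion at 0.2 V/nm and 310 K, which the tests verify to
within stochastic error.

### What the generator does and does not emulate

It reproduces: directional electrophoresis of cations/anions, ion
accumulation at the membrane faces (cations against the lower face under
a +z field — upper-region ions wrap through the periodic boundary),
field-free double-layer symmetry, Debye-type screening (see below),
electroneutrality, and planted transmembrane water chains as positive
controls. It does **not** contain lipids, membrane deformation or a
self-consistent pore-formation mechanism: synthetic pore events exist
only where chains are planted, so pipeline runs on plain electrolyte are
(correctly) censored. Consequently a green trend test establishes that
the *analysis chain* recovers the physics present in the generator
(monotone inner potential with concentration, divalent > monovalent), not
that MD-scale pore kinetics are reproduced. Absolute inner-potential
magnitudes are inflated relative to a real electrolyte: in the default
non-interacting mode nothing limits the compression of the surface layer
(thickness ~ `k_B T / (q E_z)` = 0.13 nm), so reported values are useful
for trends, not as physical voltages.

## Charge gridding

Grids are corner-anchored with dims = box edge / 0.1 nm rounded to the
nearest even integer and the spacing recomputed so `dims * spacing` is
exactly the box (within 1% of the 1 Angstrom target; even sizes keep the
FFT fast). Two assignment schemes are provided because the source does
not name one: nearest grid point (NGP) for exact toy tests, and
cloud-in-cell (CIC, default) — trilinear spreading over the 8 surrounding
nodes with periodic wrap — for a smoother density to feed the spectral
solve. Both conserve total charge to rounding, agree bit-for-bit for
node-placed charges, and are translation covariant under whole-voxel
shifts. Time averaging is a plain voxel mean over the analysis window:
frames after an equilibration fraction (default 25%) and strictly before
the detected pore frame, mirroring the "before pore formation"
convention.

## The spectral Poisson solve

`solve_poisson()` inverts the continuum symbol:

```
phihat(k) = rhohat(k) / (eps0 eps_r |k|^2),  phihat(0) = 0.
```

Numerical choices:

* **Gauge.** Under full periodic boundary conditions "zero at infinity"
  does not exist; the k = 0 mode is removed, giving a zero-mean potential.
  Only potential differences are reported, so the gauge cancels.
* **Continuum vs discrete symbol.** The continuum `-|k|^2` is exactly
  invertible and matches an FFT-method description most directly; the
  residual identity (`spectral_laplacian(phi)` returning the mean-removed
  `-rho/eps0 eps_r` to ~1e-10 relative) uses the same operator, and a
  dense direct solve of the identical finite-spectrum system (assembled
  as a Kronecker sum of per-axis circulants, solved by LU) agrees to
  1e-8 V on small grids.
* **Neutrality.** A net charge makes the periodic problem unsolvable at
  k = 0; densities must be neutral to 1e-6 e or the solver errors.
* **Permittivity.** `eps_r = 1` by default: the inner potential is
  defined on bare ionic charges in vacuum permittivity; it is exposed for
  sensitivity studies.

The parallel-sheet capacitor (sheets of +/-0.1 e/nm^2, 4 nm apart in a
12.6 nm box) reproduces the 1D closed form
`delta_phi = sigma d (1 - d/Lz) / eps0 = 4.94 V` to better than 1% at
0.1 nm spacing, and the cosine eigenmode is exact to machine precision.

### The inner-potential scalar

How a single per-condition value is extracted from the 2D potential map
is not specified at the source; the package records its convention in
every report: `delta_phi` = mean potential in a bulk slab 1 nm above the
upper membrane face minus the mean in a slab 1 nm below the lower face
(slab width 1 nm; both configurable). The applied uniform field is
excluded by construction, because only the ionic charge density enters
the solve.

## Pore detection

A pore is a connected component of the water contact graph containing
waters at or beyond both leaflet planes, with contacts at minimum-image
distance <= 0.55 nm. Conventions, all configurable:

* **Cutoff 0.55 nm** suits coarse-grained water-bead first-shell
  distances; no value is stated at the source.
* **z is non-periodic** in the contact graph used for spanning: bulk
  water touching itself through the z boundary is the *other* aqueous
  pathway around the box, not a membrane-traversing chain. x/y remain
  periodic, and a chain crossing the x/y boundary is found identically to
  its translate. The graph is restricted to the slab window
  `[z_lower - cutoff, z_upper + cutoff]`, an exact reduction (any
  crossing path can be trimmed to the window).
* **Persistence 2 frames** rejects single-frame flickers while keeping
  the "first distinct chain" bookkeeping: the event time is the first
  frame of the first persistent run. A trajectory without such a run
  yields a *censored* event at the end time — a lower bound that sweep
  summaries count separately and never average as a finite time.

## Kinematics conventions

Unwrapping accumulates per-step minimum-image displacements (no
end-point heuristics) and errors on any step of at least half a box
length, naming the particle and frame. "Charge concentration" — the
covariate that collapses electroporation behaviour across salts — is
recorded as cation molarity times cation valence (NaCl at c gives c,
MgCl2 gives 2c); whether the source includes anions is unstated, and the
cationic definition is written into every report.

## Validating screening: the charged-wall fixture

The generator's realism target is the Debye length
`lambda_D = sqrt(eps eps0 k_B T / sum_i n_i q_i^2)`. A hard-truncated
Coulomb kernel, however, cannot support exponential screening at
arbitrary parameters: linearizing the steady state for decay modes
`exp(-kappa z)` gives the dispersion relation
`lambda_D^2 kappa^2 = cosh(kappa r_c) - 1`, so genuine Debye-like decay
requires the cutoff `r_c` to span several screening lengths, and a
mean-field solve of the truncated-kernel integral equation shows the
recovered decay length converging to `lambda_D` only as
`lambda_D / r_c` becomes small. The validation fixture therefore uses
0.4 mol/L NaCl (`lambda_D = 0.489` nm) with `r_c = 4.4` nm in a reduced
9.2 x 9.2 x 12.6 nm box, and implements the charged wall with the *same*
truncated, laterally integrated kernel as the pair forces (+sigma on the
lower slab face, -sigma on the upper, 0.08 e/nm^2 — weak enough for the
linear regime). With no applied field the wall then drives no unscreened
far tail. The decay length is estimated from the time-averaged axial
charge profile by a truncation-corrected first-moment estimator on
`[0, 3 lambda_D]`, averaging the two faces; it recovers `lambda_D`
within ~6%, against a 15% acceptance band. At the 1.4 nm production
cutoff screening is qualitatively present but quantitatively too long —
a documented fidelity/simplicity trade-off of cutoff electrostatics.

## Sweeps and determinism

Concentration sweeps re-derive counts per molarity, run `n_seeds`
replicates with seeds derived deterministically from the base seed, and
aggregate means/sds per condition; censored runs are tallied, never
averaged. Sweep trend tests (inner-potential magnitude non-decreasing in
concentration; divalent >= monovalent at equal molarity) use one-sided
sign tests over per-seed pairs at alpha = 0.05. Sweeps default to the
non-interacting generator: electrophoretic accumulation — the mechanism
behind both trends — is driven by the external field, pair interactions
mainly broaden the surface layer, and the O(N^2) force loop would
dominate the runtime at the higher concentrations; this is a scaling
decision recorded here. Grid spacing 0.2 nm is used in the trend tests
for the same reason (the inner potential depends on the integrated layer
charge, not on resolving the layer profile).

All randomness flows from explicit integer seeds (never wall clock);
identical config + seed reproduces every report number and written
artifact byte-for-byte, which the tests assert.

## Degenerate inputs and tie-breaks

Zero ions give a valid empty frame and a zero density; `n_steps = 0`
yields the initialization frame; a non-neutral density, an empty grid
list, mismatched grid specs, reference slabs touching the membrane or
box boundary, unknown config keys and unknown species are errors. The
spanning-chain path tie-break is deterministic: lowest particle id on
each side, breadth-first shortest path between them.

## Known limitations

* No lipid degrees of freedom, membrane deformation, pore expansion or
  closure kinetics; no dielectric-discontinuity or Poisson-Boltzmann
  solver; no Ewald electrostatics in the generator.
* Inner-potential magnitudes from the non-interacting generator are
  trend-faithful but not physical voltages (see above).
* GRO output carries 3-decimal coordinates; round-trips are exact only
  to that precision (XYZ is written at 6 decimals).
* The cube writer stores potential in volts and mass density in kg/m^3
  as documented dialect notes; charge density is converted to the
  cube-native e/bohr^3.
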