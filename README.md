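# innerpot

Analysis toolkit for how electrolyte ions modulate membrane electroporation
under an applied electric field.

When an external field `E_z` is applied across a membrane immersed in
electrolyte, ions migrate electrophoretically (drift velocity
`v = D q E_z / (k_B T)`), cannot cross the intact bilayer, and pile up
against its surfaces. The resulting double layers generate an
*inner potential*: the ion-induced electrostatic contribution obtained by
solving Poisson's equation on the time-averaged ionic charge density,

```
laplacian(phi)(r) = -rho(r) / eps0 ,
```

solved spectrally (FFT) under full periodic boundary conditions and reduced
to a transmembrane scalar `delta_phi` (mean potential in a bulk slab above
the membrane minus one below). Electroporation itself is detected
geometrically: a pore exists when water particles form a connected chain
whose contacts (distance <= 0.55 nm) span the bilayer slab, and the
electroporation time is the first frame starting a persistent run of such
chains (censored if none occurs).

Because the MD trajectories behind such analyses are expensive, the package
ships a synthetic generator: an overdamped Langevin (Brownian dynamics)
electrolyte with an impermeable membrane slab, periodic boundaries,
optional truncated-Coulomb pair interactions, and planted water chains.
Its stationary statistics — Einstein-relation drift, field-free symmetry,
Debye screening length `lambda_D = sqrt(eps eps0 k_B T / sum_i n_i q_i^2)`
at a charged wall — are validated against closed forms, which makes every
downstream stage (gridding, Poisson solve, pore detection, kinematics)
testable without an MD engine.

## Worked example

0.157 mol/L NaCl in the 18.1 x 18.1 x 12.6 nm reference box, 0.2 V/nm
field along +z, 2 ns of Brownian dynamics, charge density on a 0.2 nm
grid averaged over the second half of the run:

```r
library(innerpot)
cfg <- synth_config(
  counts = counts_from_concentration(0.157, "NaCl",
                                     box = c(18.1, 18.1, 12.6),
                                     membrane = default_membrane()),
  n_steps = 2000, frame_stride = 50, seed = 1)
rep <- run_pipeline(list(sim = cfg,
                         analysis = list(grid_spacing = 0.2,
                                         equilibration_fraction = 0.5)),
                    quiet = TRUE)
rep
#> innerpot pipeline report (seed 1 )
#>   charge concentration: 0.1569 mol e/L
#>   electroporation: censored (no pore within 2 ns)
#>   inner potential: -27.26 V
#>   drift NA: +1.91 nm/ns
#>   drift CL: -2.08 nm/ns
```

Reading the numbers: the charge concentration (cation molarity times
valence) echoes the 0.157 mol/L input after integer particle rounding.
The pore event is censored — this run contains no water markers, so no
transmembrane chain can form, and the end time (2 ns) is a lower bound,
not an observation. The inner potential is negative: cations drifting
along +z are blocked at the lower slab face (ions in the upper solvent
region wrap through the periodic boundary), so the potential below the
membrane exceeds that above it; its magnitude grows with concentration
and valence. The mean drift velocities are far below the free-ion
Einstein value (about 10 nm/ns for Na+) precisely because the membrane
blocks sustained migration. With `outdir=` the same call also writes the
trajectory (GRO/XYZ), cube grids, TSV profiles/maps and a JSON report.

`plot(rep$potential_map)` images the y-averaged potential; an axial view
is `plot(axial_potential_profile(rep$potential))`.

## Acceptance script

`scripts/acceptance.R` re-runs the main computation from scratch against
the installed package — generating the synthetic trajectory, gridding the
ionic charges, solving Poisson's equation and extracting the report — and
writes the acceptance-target JSON:

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```
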