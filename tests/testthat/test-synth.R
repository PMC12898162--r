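test_that("counts_from_concentration: zero, arithmetic oracle, neutrality", {
  z <- counts_from_concentration(0, "NaCl")
  expect_identical(unname(z), c(0L, 0L))
  z <- counts_from_concentration(0, "MgCl2")
  expect_identical(unname(z), c(0L, 0L))

  # N = round(c * N_A * V): 0.15 * 6.02214076e23 * 4.1279e-21 L = 373
  cts <- counts_from_concentration(0.15, "NaCl", box = c(18.1, 18.1, 12.6),
                                   membrane = NULL)
  expect_identical(cts[["NA"]], 373L)
  expect_identical(cts[["CL"]], 373L)

  # neutrality forces 2:1 for MgCl2; pick c such that N_Mg = 10
  K <- ip_constants()
  v_L <- prod(c(18.1, 18.1, 12.6)) * 1e-24
  c10 <- 10 / (K$avogadro * v_L)
  cts <- counts_from_concentration(c10, "MgCl2", membrane = NULL)
  expect_identical(cts[["MG"]], 10L)
  expect_identical(cts[["CL"]], 20L)

  # slab excluded from the solvent volume
  full <- counts_from_concentration(0.3, "NaCl", membrane = NULL)
  slab <- counts_from_concentration(0.3, "NaCl", membrane = default_membrane())
  expect_lt(slab[["NA"]], full[["NA"]])

  expect_error(counts_from_concentration(-0.1, "NaCl"), "concentration")
})

test_that("generated systems are electroneutral for all salts and sizes", {
  tab <- default_species()
  for (salt in c("NaCl", "MgCl2"))
    for (conc in c(0.05, 0.157, 0.411, 0.854)) {
      cts <- counts_from_concentration(conc, salt, membrane = default_membrane())
      val <- tab$valence[match(names(cts), tab$name)]
      expect_identical(sum(cts * val), 0L)
      cfg <- synth_config(counts = cts)  # validates neutrality internally
      expect_s3_class(cfg, "synth_config")
    }
  expect_error(synth_config(counts = c("NA" = 3, "CL" = 2)), "neutral")
})

test_that("initialize_system: empty, deterministic, slab-excluding", {
  cfg0 <- tiny_config(counts = c("NA" = 0, "CL" = 0))
  f0 <- initialize_system(cfg0)
  expect_identical(nrow(f0$positions), 0L)

  cfg <- tiny_config(counts = c("NA" = 500, "CL" = 500), seed = 42)
  f1 <- initialize_system(cfg, rng_seed = 42)
  f2 <- initialize_system(cfg, rng_seed = 42)
  expect_identical(f1, f2)

  z <- f1$positions[, 3]
  m <- cfg$membrane
  expect_false(any(z > m$z_lower & z < m$z_upper))
  expect_true(all(f1$positions >= 0))
  expect_true(all(sweep(f1$positions, 2, cfg$box, "<")))
})

test_that("field-free stepping is diffusive: first and second moments", {
  n <- 2000L
  cfg <- synth_config(box = c(20, 20, 20), membrane = NULL,
                      counts = c("X" = n, "Y" = n),
                      applied_field_Ez = 0, timestep = 1e-3,
                      species_table = unit_species(), seed = 8)
  f0 <- initialize_system(cfg)
  f1 <- step_langevin(f0, cfg)
  d <- f1$positions - f0$positions
  d <- d - 20 * round(d / 20)
  # D = 1 nm^2/ns, dt = 1e-3 -> var = 2e-3 per axis, mean 0
  se_mean <- sqrt(2e-3 / (2 * n))
  for (a in 1:3) {
    expect_lt(abs(mean(d[, a])), 4 * se_mean)
    expect_equal(mean(d[, a]^2), 2e-3, tolerance = 0.08)
  }
})

test_that("free-ion drift follows the Einstein relation D q E / kT", {
  # D = 1 nm^2/ns, z = +1, E = 0.2 V/nm, T = 310 K -> 7.487 nm/ns
  kT <- ip_constants()$kB * 310
  v_expect <- 1.0 * 1 * 0.2 / kT
  expect_equal(v_expect, 7.487, tolerance = 1e-3)
  cfg <- synth_config(box = c(12, 12, 12), membrane = NULL,
                      counts = c("X" = 60, "Y" = 60),
                      applied_field_Ez = 0.2, timestep = 5e-4,
                      n_steps = 4000, frame_stride = 200,
                      species_table = unit_species(), seed = 31)
  traj <- run_simulation(cfg)
  uw <- unwrap_trajectory(traj)
  vx <- drift_velocity(uw, "X")
  expect_lt(abs(vx$velocity - v_expect), 3 * vx$se)
  # anion: equal magnitude, opposite sign
  vy <- drift_velocity(uw, "Y")
  expect_lt(abs(vy$velocity + v_expect), 3 * vy$se)
})

test_that("pair Coulomb forces are equal and opposite with correct magnitude", {
  cfg <- synth_config(box = c(10, 10, 10), membrane = NULL,
                      counts = c("NA" = 1, "CL" = 1), interacting = TRUE,
                      coulomb_cutoff = 4, epsilon_r = 1)
  f <- make_frame(c(2, 5, 5, 4, 5, 5), c("NA", "CL"), box = c(10, 10, 10))
  F <- coulomb_forces(f, cfg)
  expect_equal(F[1, ], -F[2, ])
  # attractive pair 2 nm apart: |F| = k |q1 q2| / r^2 = 1.43996 / 4
  expect_equal(F[1, 1], 1.43996 / 4, tolerance = 1e-12)
  expect_equal(F[1, 2:3], c(0, 0))
  # beyond the cutoff: no force
  cfg2 <- synth_config(box = c(12, 12, 12), membrane = NULL,
                       counts = c("NA" = 1, "CL" = 1), interacting = TRUE,
                       coulomb_cutoff = 1.4, epsilon_r = 1)
  f2 <- make_frame(c(2, 6, 6, 8, 6, 6), c("NA", "CL"), box = c(12, 12, 12))
  expect_true(all(coulomb_forces(f2, cfg2) == 0))
})

test_that("membrane slab is impermeable in every frame", {
  cfg <- tiny_config(counts = c("NA" = 150, "CL" = 150),
                     n_steps = 2000, frame_stride = 100, seed = 5,
                     water_density = 0.05)
  traj <- run_simulation(cfg)
  m <- cfg$membrane
  for (f in traj$frames) {
    expect_silent(validate_frame(f, m, cfg$species_table))
    expect_identical(nrow(f$positions), n_particles(traj))
  }
  expect_true(all(diff(frame_times(traj)) > 0))
})

test_that("run_simulation: zero steps, bit-identical reruns", {
  cfg <- tiny_config(n_steps = 0L)
  traj <- run_simulation(cfg)
  expect_identical(n_frames(traj), 1L)
  expect_identical(traj$frames[[1]], initialize_system(cfg))

  cfg2 <- tiny_config(n_steps = 200L, frame_stride = 50L, seed = 77)
  expect_identical(run_simulation(cfg2), run_simulation(cfg2))
})

test_that("cations accumulate below the slab under a +z field", {
  # drift along +z is blocked at the LOWER slab face (upper-region ions wrap
  # through the periodic boundary); checked over 5 seeds
  wins <- vapply(1:5, function(s) {
    cfg <- synth_config(box = c(9, 9, 12.6), counts = c("NA" = 200, "CL" = 200),
                        n_steps = 10000, frame_stride = 2000, seed = s,
                        timestep = 1e-3)
    traj <- run_simulation(cfg)
    f <- traj$frames[[n_frames(traj)]]
    m <- cfg$membrane
    z <- f$positions[f$species == "NA", 3]
    below <- sum(z >= m$z_lower - 1 & z <= m$z_lower)
    above <- sum(z >= m$z_upper & z <= m$z_upper + 1)
    below > above
  }, TRUE)
  expect_true(all(wins))
})

test_that("with no field the ion density is symmetric about the slab midplane", {
  cfg <- synth_config(counts = c("NA" = 300, "CL" = 300),
                      applied_field_Ez = 0, n_steps = 4000,
                      frame_stride = 200, seed = 12)
  traj <- run_simulation(cfg)
  m <- cfg$membrane
  lower <- upper <- 0
  for (f in traj$frames[-(1:5)]) {
    z <- f$positions[, 3]
    lower <- lower + sum(z <= m$z_lower)
    upper <- upper + sum(z >= m$z_upper)
  }
  # lower solvent region: 4.15 nm of 8.3 nm total -> expect a 50/50 split
  frac <- lower / (lower + upper)
  expect_gt(frac, 0.45)
  expect_lt(frac, 0.55)
})

test_that("plant_transmembrane_chain builds spanning columns as specified", {
  f <- make_frame(numeric(0), character(0))
  m <- membrane_slab(4, 8.3)
  g <- plant_transmembrane_chain(f, m, bead_spacing = 0.4)
  # ceiling((8.3 - 4 + 0.8) / 0.4) + 1 = 14 beads
  expect_identical(nrow(g$positions), 14L)
  z <- g$positions[, 3]
  expect_equal(min(z), 4 - 0.4)
  expect_equal(max(z), 8.3 + 0.4)
  expect_lte(max(diff(sort(z))), 0.4 + 1e-12)
  expect_identical(attr(g, "planted_chains"), 1L)

  g2 <- plant_transmembrane_chain(g, m, bead_spacing = 0.4)
  expect_identical(attr(g2, "planted_chains"), 2L)
  xs <- unique(g2$positions[, 1])
  expect_identical(length(xs), 2L)  # disjoint columns, offset in x
  expect_equal(abs(diff(xs)), 1.5)
})

test_that("config validation catches bad geometry and parameters", {
  expect_error(membrane_slab(5, 5), "z_lower < z_upper")
  expect_error(synth_config(box = c(18.1, 18.1, 8),
                            membrane = membrane_slab(4.15, 8.45)),
               "inside the box")
  expect_error(synth_config(interacting = TRUE, coulomb_cutoff = 10),
               "2\\*coulomb_cutoff")
  expect_error(synth_config(timestep = 0), "timestep")
  expect_error(synth_config(counts = c("ZZ" = 2)), "unknown species")
  expect_error(ion_species("Q", 3L, 1, 1), "valence")
})
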