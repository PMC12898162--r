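test_that("default grid honors the 0.1 nm target with even FFT-friendly dims", {
  spec <- default_grid_spec(c(18.1, 18.1, 12.6))
  expect_true(all(spec$dims %% 2 == 0))
  expect_equal(spec$dims * spec$spacing, c(18.1, 18.1, 12.6))
  expect_true(all(abs(spec$spacing - 0.1) / 0.1 < 0.01))
})

test_that("NGP and CIC place single charges as specified", {
  spec <- grid_spec(c(8, 8, 8), 0.5)
  box <- c(4, 4, 4)
  # +1 e exactly on a node: NGP puts everything in that voxel
  f <- make_frame(c(1.0, 1.5, 2.0), "NA", box = box)
  g <- assign_charges(f, spec, "NGP")
  vol <- prod(spec$spacing)
  expect_equal(g$values[3, 4, 5], 1 / vol)
  expect_equal(sum(g$values != 0), 1L)
  # CIC on the same node agrees bit-for-bit
  gc <- assign_charges(f, spec, "CIC")
  expect_identical(g$values, gc$values)
  # +1 e at a voxel center: CIC spreads e/8 to each surrounding node
  f2 <- make_frame(c(1.25, 1.25, 1.25), "NA", box = box)
  g2 <- assign_charges(f2, spec, "CIC")
  nz <- which(g2$values != 0)
  expect_identical(length(nz), 8L)
  expect_true(all(abs(g2$values[nz] - 1 / 8 / vol) < 1e-14))
})

test_that("charge is conserved for both schemes on random configurations", {
  spec <- grid_spec(c(10, 8, 6), c(0.5, 0.625, 0.7))
  box <- spec$box
  vol <- prod(spec$spacing)
  set.seed(99)
  for (rep in 1:50) {
    n <- sample(1:40, 1)
    f <- make_frame(cbind(runif(3 * n, 0, box[1]), runif(3 * n, 0, box[2]),
                          runif(3 * n, 0, box[3])),
                    sample(c("NA", "CL", "MG"), 3 * n, replace = TRUE),
                    box = box)
    tab <- default_species()
    qtot <- sum(tab$valence[match(f$species, tab$name)])
    for (scheme in c("NGP", "CIC")) {
      g <- assign_charges(f, spec, scheme)
      expect_lt(abs(sum(g$values) * vol - qtot), 1e-12)
    }
  }
})

test_that("water and other zero-valence markers never contribute charge", {
  spec <- grid_spec(c(6, 6, 6), 0.5)
  f <- make_frame(c(1, 1, 1, 2, 2, 2), c("W", "W"), box = c(3, 3, 3))
  g <- assign_charges(f, spec, "CIC")
  expect_true(all(g$values == 0))
})

test_that("gridding is translation covariant under whole-voxel shifts", {
  spec <- grid_spec(c(6, 6, 6), 0.5)
  box <- spec$box
  set.seed(4)
  pos <- cbind(runif(20, 0, box[1]), runif(20, 0, box[2]),
               runif(20, 0, box[3]))
  sp <- sample(c("NA", "CL"), 20, replace = TRUE)
  f1 <- make_frame(pos, sp, box = box)
  pos2 <- pos
  pos2[, 1] <- (pos2[, 1] + spec$spacing[1]) %% box[1]
  f2 <- make_frame(pos2, sp, box = box)
  for (scheme in c("NGP", "CIC")) {
    g1 <- assign_charges(f1, spec, scheme)$values
    g2 <- assign_charges(f2, spec, scheme)$values
    shifted <- g1[c(6, 1:5), , ]  # cyclic permutation along x
    expect_equal(g2, shifted, tolerance = 1e-12)
  }
})

test_that("time_average is the voxelwise mean with strict spec checks", {
  spec <- grid_spec(c(4, 4, 4), 1)
  g <- random_neutral_grid(spec, seed = 2)
  expect_identical(time_average(list(g)), g)
  neg <- scalar_grid(spec, -g$values, "charge_density")
  expect_true(all(time_average(list(g, neg))$values == 0))
  expect_equal(time_average(list(g, g, g)), g)
  expect_error(time_average(list()), "non-empty")
  other <- random_neutral_grid(grid_spec(c(6, 4, 4), 1), seed = 3)
  expect_error(time_average(list(g, other)), "share spec")
})

test_that("axial charge profile: constants, sheets, mirror antisymmetry, integral", {
  spec <- grid_spec(c(6, 6, 10), 0.5)
  const <- scalar_grid(spec, array(0.3, spec$dims), "charge_density")
  expect_true(all(abs(axial_charge_profile(const)$values - 0.3) < 1e-14))

  sheet <- array(0, spec$dims); sheet[, , 4] <- 2
  p <- axial_charge_profile(scalar_grid(spec, sheet, "charge_density"))
  expect_identical(which(p$values != 0), 4L)

  # mirrored charges about the box midplane -> antisymmetric profile
  box <- spec$box
  set.seed(11)
  pos <- cbind(runif(15, 0, box[1]), runif(15, 0, box[2]),
               runif(15, 0, box[3] / 2))
  mir <- pos; mir[, 3] <- box[3] - pos[, 3]
  f <- make_frame(rbind(pos, mir), rep(c("NA", "CL"), each = 15), box = box)
  prof <- axial_charge_profile(assign_charges(f, spec, "CIC"))
  v <- prof$values
  # node 1 sits on the mirror-fixed plane z=0; nodes k and n+2-k pair up
  n <- length(v)
  expect_lt(max(abs(v[2:n] + rev(v[2:n]))), 1e-12)

  # integral recovers total charge
  g <- assign_charges(f, spec, "CIC")
  tot <- sum(axial_charge_profile(g)$values) * box[1] * box[2] *
    spec$spacing[3]
  expect_lt(abs(tot - 0), 1e-12)
})

test_that("axial profile from the grid matches a direct z-histogram (NGP)", {
  spec <- grid_spec(c(4, 4, 12), c(1, 1, 0.5))
  box <- spec$box
  set.seed(21)
  n <- 60
  f <- make_frame(cbind(runif(n, 0, box[1]), runif(n, 0, box[2]),
                        runif(n, 0, box[3])),
                  sample(c("NA", "CL"), n, replace = TRUE), box = box)
  prof <- axial_charge_profile(assign_charges(f, spec, "NGP"))
  # direct histogram with node-centered bins
  tab <- default_species()
  q <- tab$valence[match(f$species, tab$name)]
  hz <- spec$spacing[3]
  bin <- (round(f$positions[, 3] / hz)) %% spec$dims[3] + 1
  hist_q <- vapply(seq_len(spec$dims[3]),
                   function(b) sum(q[bin == b]), 0)
  expect_equal(prof$values * box[1] * box[2] * hz, hist_q,
               tolerance = 1e-12)
})

test_that("mass density profile: single-particle arithmetic and water plateau", {
  box <- c(18.1, 18.1, 12.6)
  f <- make_frame(c(3, 3, 1.0), "W", box = box)
  traj <- ion_trajectory(list(f, md_frame(1, f$positions, f$species, box)))
  prof <- axial_mass_density_profile(traj, "W", bin_width = 0.2)
  nb <- round(12.6 / 0.2)
  dz <- 12.6 / nb
  expected <- 72 / (18.1 * 18.1 * dz) * ip_constants()$amu_per_nm3_to_kg_m3
  bin <- floor(1.0 / dz) + 1
  expect_equal(prof$values[bin], expected, tolerance = 1e-12)
  expect_true(all(prof$values[-bin] == 0))

  # uniform 8.74 nm^-3 water markers give the 1045 kg/m^3 solvent plateau
  cfg <- synth_config(counts = c("NA" = 0, "CL" = 0), water_density = 8.74,
                      n_steps = 0, seed = 6)
  traj <- run_simulation(cfg)
  prof <- axial_mass_density_profile(traj, "W", bin_width = 0.2)
  m <- cfg$membrane
  plateau <- prof$values[prof$z_centers < m$z_lower - 0.3 |
                         prof$z_centers > m$z_upper + 0.3]
  expect_equal(mean(plateau), 1045, tolerance = 0.02)
  # membrane interior holds no water markers
  inside <- prof$values[prof$z_centers > m$z_lower + 0.3 &
                        prof$z_centers < m$z_upper - 0.3]
  expect_true(all(inside == 0))

  expect_error(axial_mass_density_profile(traj, character(0)), "empty")
  expect_error(axial_mass_density_profile(traj, "NA"), "no particles")
})
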