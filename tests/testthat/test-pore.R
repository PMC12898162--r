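test_that("contact graph edges respect the cutoff and x/y periodicity", {
  box <- c(18.1, 18.1, 12.6)
  f <- water_column(c(5.0, 5.0 + 0.54), box = box)
  g <- water_contact_graph(f, cutoff = 0.55)
  expect_identical(as.integer(igraph::ecount(g)), 1L)
  f2 <- water_column(c(5.0, 5.0 + 0.56), box = box)
  expect_identical(as.integer(igraph::ecount(water_contact_graph(f2, cutoff = 0.55))), 0L)

  # colinear beads 0.4 nm apart -> path graph (n-1 edges, no extras)
  f3 <- water_column(seq(3, 6, by = 0.4), box = box)
  g3 <- water_contact_graph(f3, cutoff = 0.55)
  expect_identical(as.integer(igraph::ecount(g3)),
                   as.integer(igraph::vcount(g3)) - 1L)
  expect_true(igraph::is_connected(g3))

  # x-periodic contact: beads at x = 0.1 and x = 18.0 are 0.2 nm apart
  f4 <- make_frame(c(0.1, 9, 5, 18.0, 9, 5), c("W", "W"), box = box)
  expect_identical(as.integer(igraph::ecount(water_contact_graph(f4, cutoff = 0.55))), 1L)
  # but z is non-periodic for spanning purposes
  f5 <- make_frame(c(9, 9, 0.1, 9, 9, 12.5), c("W", "W"), box = box)
  expect_identical(as.integer(igraph::ecount(water_contact_graph(f5, cutoff = 0.55))), 0L)
})

test_that("cell-list and brute-force edge search agree", {
  box <- c(18.1, 18.1, 12.6)
  set.seed(14)
  n <- 600  # above the cell-list threshold
  f <- make_frame(cbind(runif(n, 0, box[1]), runif(n, 0, box[2]),
                        runif(n, 0, box[3])), rep("W", n), box = box)
  g_cell <- water_contact_graph(f, cutoff = 0.55)
  # brute force reference in R with the same pbc convention
  d2 <- function(i, j) {
    dd <- f$positions[i, ] - f$positions[j, ]
    dd[1] <- dd[1] - box[1] * round(dd[1] / box[1])
    dd[2] <- dd[2] - box[2] * round(dd[2] / box[2])
    sum(dd^2)
  }
  ref <- 0L
  for (i in 1:(n - 1)) for (j in (i + 1):n)
    if (d2(i, j) <= 0.55^2) ref <- ref + 1L
  expect_identical(as.integer(igraph::ecount(g_cell)), as.integer(ref))
})

test_that("spanning chain: planted positive, gapped negative, one-sided none", {
  m <- membrane_slab(4, 8.3)
  base <- make_frame(numeric(0), character(0))
  planted <- plant_transmembrane_chain(base, m, bead_spacing = 0.4)
  ch <- spanning_chain(planted, m, cutoff = 0.55)
  expect_false(is.null(ch))
  z <- planted$positions[ch, 3]
  expect_lte(min(z), m$z_lower)
  expect_gte(max(z), m$z_upper)

  # delete one interior bead -> gap 0.78 > cutoff -> no chain
  idx <- order(planted$positions[, 3])
  drop <- idx[7]
  gapped <- md_frame(0, planted$positions[-drop, , drop = FALSE],
                     planted$species[-drop], planted$box)
  expect_null(spanning_chain(gapped, m, cutoff = 0.55))

  # spacing above the cutoff must not span
  sparse <- plant_transmembrane_chain(base, m, bead_spacing = 0.7)
  expect_null(spanning_chain(sparse, m, cutoff = 0.55))

  # waters only above the membrane
  above <- water_column(seq(8.3, 11, by = 0.3))
  expect_null(spanning_chain(above, m, cutoff = 0.55))

  # bulk water touching itself through the z boundary is not a pore
  around <- water_column(c(seq(0.1, 3.9, by = 0.3), seq(8.5, 12.5, by = 0.3)))
  expect_null(spanning_chain(around, m, cutoff = 0.55))
})

test_that("a chain crossing the x boundary is detected like its translate", {
  m <- membrane_slab(4, 8.3)
  z <- seq(3.6, 8.7, by = 0.3)
  # drift the column in x so consecutive beads stay within the cutoff but
  # the column wraps through x = 0
  x <- (17.9 + 0.25 * seq_along(z)) %% 18.1
  f_wrap <- make_frame(cbind(x, 9, z), rep("W", length(z)))
  f_flat <- make_frame(cbind((5 + 0.25 * seq_along(z)), 9, z),
                       rep("W", length(z)))
  ch1 <- spanning_chain(f_wrap, m, cutoff = 0.55)
  ch2 <- spanning_chain(f_flat, m, cutoff = 0.55)
  expect_false(is.null(ch1))
  expect_identical(ch1, ch2)
})

test_that("adding waters never destroys a detected chain (supergraph)", {
  m <- membrane_slab(4, 8.3)
  base <- plant_transmembrane_chain(make_frame(numeric(0), character(0)),
                                    m, bead_spacing = 0.4)
  set.seed(33)
  for (rep in 1:10) {
    extra <- 50
    pos <- cbind(runif(extra, 0, 18.1), runif(extra, 0, 18.1),
                 runif(extra, 0, 12.6))
    f <- md_frame(0, rbind(base$positions, pos),
                  c(base$species, rep("W", extra)), base$box)
    expect_false(is.null(spanning_chain(f, m, cutoff = 0.55)))
  }
  # cutoff monotonicity: a chain at c exists at any larger cutoff
  for (cc in c(0.55, 0.7, 0.9))
    expect_false(is.null(spanning_chain(base, m, cutoff = cc)))
})

test_that("electroporation time: persistence bookkeeping and censoring", {
  m <- membrane_slab(4, 8.3)
  box <- c(18.1, 18.1, 12.6)
  chain_frame <- function(t) {
    f <- plant_transmembrane_chain(md_frame(t, matrix(numeric(0), 0, 3),
                                            character(0), box), m, 0.4)
    f
  }
  # same particle count as a chain frame (14 beads), but all waters sit
  # below the membrane, so nothing spans
  empty_frame <- function(t)
    water_column(seq(0.2, 2.8, by = 0.2), time = t)

  # chain present from frame 1 (time 0), persistence 2 -> event at time 0
  traj <- ion_trajectory(lapply(0:4 * 0.2, chain_frame))
  ev <- electroporation_time(traj, m, persistence = 2)
  expect_false(ev$censored)
  expect_identical(ev$frame_index, 1L)
  expect_identical(ev$time, 0)
  expect_gt(length(ev$chain_particle_ids), 0L)

  # single-frame flicker with persistence 2 -> censored at the end time
  frames <- list(empty_frame(0), chain_frame(0.2), empty_frame(0.4),
                 empty_frame(0.6))
  ev2 <- electroporation_time(ion_trajectory(frames), m, persistence = 2)
  expect_true(ev2$censored)
  expect_identical(ev2$time, 0.6)
  expect_identical(ev2$chain_particle_ids, integer(0))
  # ... but persistence 1 accepts the flicker
  ev3 <- electroporation_time(ion_trajectory(frames), m, persistence = 1)
  expect_identical(ev3$time, 0.2)

  expect_error(electroporation_time(ion_trajectory(frames), m,
                                    persistence = 0), "persistence")
})
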