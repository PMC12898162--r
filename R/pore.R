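# Transmembrane water-chain pore detection. A pore is recorded when water
# particles on both sides of the membrane connect into a chain that
# traverses the bilayer slab.

water_ids <- function(frame, species_table) {
  idx <- species_lookup(species_table, frame$species)
  which(species_table$valence[idx] == 0L)
}

#' Water contact graph of a frame
#'
#' Builds the undirected graph whose vertices are water particles and whose
#' edges join waters closer than `cutoff`. The minimum-image convention is
#' applied on the periodic axes given by `pbc` — by default x and y only:
#' for membrane-spanning detection z is treated as non-periodic, otherwise
#' bulk water touching itself through the z boundary would masquerade as a
#' transmembrane path.
#'
#' @param frame An [md_frame()].
#' @param selection Integer particle ids of the waters to include; default
#'   all zero-valence particles.
#' @param cutoff Contact distance, nm (> 0).
#' @param pbc Logical length-3: periodic per axis.
#' @param species_table Species table.
#' @return An [igraph::graph] whose vertex attribute `id` holds the particle
#'   indices within the frame.
#' @export
water_contact_graph <- function(frame, selection = NULL, cutoff = 0.55,
                                pbc = c(TRUE, TRUE, FALSE),
                                species_table = default_species()) {
  stopifnot(inherits(frame, "md_frame"), cutoff > 0, length(pbc) == 3L)
  if (is.null(selection)) selection <- water_ids(frame, species_table)
  pos <- frame$positions[selection, , drop = FALSE]
  edges <- contact_edges_cpp(pos, frame$box, cutoff, as.logical(pbc))
  g <- igraph::make_empty_graph(n = length(selection), directed = FALSE)
  if (nrow(edges)) g <- igraph::add_edges(g, t(edges))
  igraph::V(g)$id <- selection
  g
}

#' Find a membrane-spanning water chain
#'
#' Searches for a connected component of the water contact graph containing
#' at least one water at or below the lower leaflet plane (`z <= z_lower`)
#' and one at or above the upper plane (`z >= z_upper`), and returns a path
#' between them. Ties are broken deterministically: the endpoints are the
#' lowest particle ids on each side and the path is a breadth-first
#' shortest path. Only waters within `cutoff` of the slab interval matter
#' for spanning, so the graph is restricted to
#' `z in [z_lower - cutoff, z_upper + cutoff]` (an exact reduction, since
#' any crossing path can be trimmed to that window).
#'
#' @param frame An [md_frame()].
#' @param membrane A [membrane_slab()].
#' @param cutoff Contact distance, nm.
#' @param species_table Species table.
#' @return Integer vector of particle ids along the chain (ordered from the
#'   lower to the upper side), or `NULL` if no spanning chain exists.
#' @export
spanning_chain <- function(frame, membrane, cutoff = 0.55,
                           species_table = default_species()) {
  stopifnot(inherits(membrane, "membrane_slab"))
  waters <- water_ids(frame, species_table)
  if (length(waters) < 2L) return(NULL)
  z <- frame$positions[waters, 3L]
  win <- z >= membrane$z_lower - cutoff & z <= membrane$z_upper + cutoff
  waters <- waters[win]
  z <- z[win]
  if (length(waters) < 2L) return(NULL)
  below <- z <= membrane$z_lower
  above <- z >= membrane$z_upper
  if (!any(below) || !any(above)) return(NULL)
  g <- water_contact_graph(frame, selection = waters, cutoff = cutoff,
                           species_table = species_table)
  comp <- igraph::components(g)
  cb <- unique(comp$membership[below])
  ca <- unique(comp$membership[above])
  shared <- intersect(cb, ca)
  if (!length(shared)) return(NULL)
  cid <- min(shared)
  from <- min(which(below & comp$membership == cid))
  to <- min(which(above & comp$membership == cid))
  path <- igraph::shortest_paths(g, from = from, to = to,
                                 output = "vpath")$vpath[[1]]
  waters[as.integer(path)]
}

#' Pore (electroporation) event of a trajectory
#'
#' Scans frames for a membrane-spanning water chain and records the time of
#' the first frame that begins a run of at least `persistence` consecutive
#' spanning frames (persistence rejects single-frame flickers). If no such
#' run exists the event is censored: its time is the trajectory end time
#' and is a lower bound, not an observation.
#'
#' @param trajectory An [ion_trajectory()].
#' @param membrane A [membrane_slab()].
#' @param cutoff Water contact distance, nm (default 0.55, a coarse-grained
#'   water-bead first-shell distance).
#' @param persistence Minimum run length in frames (>= 1, default 2).
#' @return Object of class `pore_event` with fields `frame_index` (1-based),
#'   `time` (ns), `chain_particle_ids` and `censored`.
#' @export
electroporation_time <- function(trajectory, membrane, cutoff = 0.55,
                                 persistence = 2L) {
  stopifnot(inherits(trajectory, "ion_trajectory"),
            inherits(membrane, "membrane_slab"))
  persistence <- as.integer(persistence)
  if (persistence < 1L) stop("persistence must be >= 1")
  nf <- length(trajectory$frames)
  if (nf == 0L) stop("empty trajectory")
  chains <- vector("list", nf)
  spans <- logical(nf)
  run <- 0L
  for (k in seq_len(nf)) {
    ch <- spanning_chain(trajectory$frames[[k]], membrane, cutoff,
                         trajectory$species_table)
    chains[[k]] <- ch
    spans[k] <- !is.null(ch)
    run <- if (spans[k]) run + 1L else 0L
    if (run >= persistence) {
      first <- k - persistence + 1L
      return(structure(list(frame_index = first,
                            time = trajectory$frames[[first]]$time,
                            chain_particle_ids = chains[[first]],
                            censored = FALSE),
                       class = "pore_event"))
    }
  }
  structure(list(frame_index = NA_integer_,
                 time = trajectory$frames[[nf]]$time,
                 chain_particle_ids = integer(0),
                 censored = TRUE),
            class = "pore_event")
}

#' @export
print.pore_event <- function(x, ...) {
  if (x$censored)
    cat(sprintf("pore event: censored (no pore within %.4g ns)\n", x$time))
  else
    cat(sprintf("pore event: frame %d, t = %.4g ns, chain of %d waters\n",
                x$frame_index, x$time, length(x$chain_particle_ids)))
  invisible(x)
}
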