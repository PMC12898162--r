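# Shared fixture builders. Everything is generated in code; no data files.

# species with unit diffusion/mass for closed-form kinematics checks
unit_species <- function() {
  rbind(
    ion_species("X", +1L, 1.0, 1.0),
    ion_species("Y", -1L, 1.0, 1.0),
    ion_species("W", 0L, 1.0, 72.0)
  )
}

tiny_config <- function(..., counts = c("NA" = 20, "CL" = 20),
                        n_steps = 100L, frame_stride = 20L, seed = 1L) {
  synth_config(counts = counts, n_steps = n_steps,
               frame_stride = frame_stride, seed = seed, ...)
}

# frame with explicit positions (row-wise vector or n x 3 matrix)
make_frame <- function(pos, species, box = c(18.1, 18.1, 12.6), time = 0) {
  if (!is.matrix(pos)) pos <- matrix(pos, ncol = 3L, byrow = TRUE)
  md_frame(time, pos, species, box)
}

# a straight water column along z at (x, y), possibly with gaps
water_column <- function(z, x = 9, y = 9, box = c(18.1, 18.1, 12.6),
                         time = 0) {
  md_frame(time, cbind(rep(x, length(z)), rep(y, length(z)), z),
           rep("W", length(z)), box)
}

# random neutral ion frame: n cations and n anions uniform in the box
random_neutral_frame <- function(n, box = c(4, 4, 4), seed = 1) {
  set.seed(seed)
  make_frame(cbind(runif(2 * n, 0, box[1]), runif(2 * n, 0, box[2]),
                   runif(2 * n, 0, box[3])),
             rep(c("NA", "CL"), each = n), box = box) -> f
  f$positions <- cbind(runif(2 * n, 0, box[1]), runif(2 * n, 0, box[2]),
                       runif(2 * n, 0, box[3]))
  colnames(f$positions) <- c("x", "y", "z")
  f
}

# random neutral charge-density grid on the given spec
random_neutral_grid <- function(spec, seed = 1) {
  set.seed(seed)
  v <- array(rnorm(prod(spec$dims)), spec$dims)
  v <- v - mean(v)
  scalar_grid(spec, v, "charge_density")
}
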