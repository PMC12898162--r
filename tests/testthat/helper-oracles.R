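# Independent oracles, kept free of the package's FFT solve path.

# 1D spectral Laplacian as an explicit dense circulant matrix, built by
# direct DFT summation (no fft()).
dense_axis_laplacian <- function(n, L) {
  j <- seq_len(n) - 1L
  jj <- ifelse(j <= n %/% 2, j, j - n)
  k <- 2 * pi * jj / L
  W <- exp(-2i * pi * outer(j, j) / n)          # DFT matrix
  Winv <- Conj(t(W)) / n
  Re(Winv %*% (-k^2 * W))
}

# Dense direct solve of the periodic finite-spectrum Poisson system:
# assembles the 3D spectral Laplacian as a Kronecker sum of per-axis dense
# circulants and solves with LU (base solve()), pinning the mean to zero.
# Ordering matches R arrays: x fastest.
dense_poisson_oracle <- function(rho, epsilon_r = 1) {
  spec <- rho$spec
  n <- spec$dims
  Ax <- dense_axis_laplacian(n[1], spec$box[1])
  Ay <- dense_axis_laplacian(n[2], spec$box[2])
  Az <- dense_axis_laplacian(n[3], spec$box[3])
  Ix <- diag(n[1]); Iy <- diag(n[2]); Iz <- diag(n[3])
  A <- kronecker(Iz, kronecker(Iy, Ax)) +
       kronecker(Iz, kronecker(Ay, Ix)) +
       kronecker(Az, kronecker(Iy, Ix))
  N <- prod(n)
  eps0 <- ip_constants()$eps0
  b <- -as.vector(rho$values) / (eps0 * epsilon_r)
  b <- b - mean(b)
  phi <- solve(A + matrix(1 / N, N, N), b)
  array(phi, n)
}

# capacitor oracle: potential difference across two oppositely charged
# sheets (surface density sigma e/nm^2) at separation d in a periodic box
# of height Lz (1D integration of the periodic field, closed form)
capacitor_delta_phi <- function(sigma, d, Lz, epsilon_r = 1) {
  eps0 <- ip_constants()$eps0
  sigma * d * (1 - d / Lz) / (eps0 * epsilon_r)
}

# Debye length closed form, nm; concentration mol/L of a z:z or 2:1 salt
debye_length <- function(concentration, temperature = 310, epsilon_r = 78,
                         salt = "NaCl") {
  K <- ip_constants()
  n0 <- concentration * K$avogadro * 1e-24   # nm^-3 of the cation
  sum_nq2 <- switch(salt,
                    NaCl = n0 * 1 + n0 * 1,
                    MgCl2 = n0 * 4 + 2 * n0 * 1,
                    stop("unknown salt"))
  sqrt(epsilon_r * K$eps0 * K$kB * temperature / sum_nq2)
}

# truncated-exponential first-moment estimator of a decay length from a
# layer profile rho(s >= 0) observed on a window [0, S]
decay_length_moment <- function(s, rho, S) {
  sel <- s > 0 & s <= S
  m_obs <- sum(s[sel] * rho[sel]) / sum(rho[sel])
  f <- function(l) l * (1 - (1 + S / l) * exp(-S / l)) /
    (1 - exp(-S / l)) - m_obs
  stats::uniroot(f, c(0.01, 50))$root
}
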