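#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Pairwise truncated-Coulomb forces (eV/nm), minimum image in all three axes.
// Hard cutoff, no shifting: the generator is validated against Debye-length
// recovery, not against energy conservation.
// [[Rcpp::export]]
NumericMatrix coulomb_forces_cpp(NumericMatrix pos, NumericVector q,
                                 NumericVector box, double cutoff,
                                 double eps_r, double k_e) {
  const int n = pos.nrow();
  NumericMatrix F(n, 3);
  const double c2 = cutoff * cutoff;
  for (int i = 0; i < n - 1; ++i) {
    if (q[i] == 0.0) continue;
    for (int j = i + 1; j < n; ++j) {
      if (q[j] == 0.0) continue;
      double d[3], r2 = 0.0;
      for (int a = 0; a < 3; ++a) {
        double dd = pos(i, a) - pos(j, a);
        dd -= box[a] * std::round(dd / box[a]);
        d[a] = dd;
        r2 += dd * dd;
      }
      if (r2 > c2 || r2 < 1e-12) continue;
      const double r = std::sqrt(r2);
      const double fmag = k_e * q[i] * q[j] / (eps_r * r2); // repulsive > 0
      for (int a = 0; a < 3; ++a) {
        const double f = fmag * d[a] / r;
        F(i, a) += f;
        F(j, a) -= f;
      }
    }
  }
  return F;
}

// Overdamped Langevin propagation with periodic wrap, optional pairwise
// Coulomb forces and specular reflection off the membrane slab faces.
// Positions in nm, time in ns, charge in e, energies in eV; kT in eV.
// Uses R's RNG (norm_rand) so trajectories are reproducible via set.seed().
// Returns frames at steps 0, stride, 2*stride, ... as a (n x 3 x n_frames)
// array plus the frame times.
// [[Rcpp::export]]
List langevin_run_cpp(NumericMatrix pos0, NumericVector D, NumericVector q,
                      LogicalVector reflect, NumericVector box,
                      double zlo, double zhi, bool has_slab,
                      double Ez, double wall_sigma, double kT, double dt,
                      int n_steps, int stride,
                      bool interacting, double cutoff, double eps_r,
                      double k_e, double t0) {
  const int n = pos0.nrow();
  const int n_frames = n_steps / stride + 1;
  NumericVector frames(Dimension(n, 3, n_frames));
  NumericVector times(n_frames);

  std::vector<double> x(n), y(n), z(n), sig(n), mob(n);
  for (int i = 0; i < n; ++i) {
    x[i] = pos0(i, 0);
    y[i] = pos0(i, 1);
    z[i] = pos0(i, 2);
    sig[i] = std::sqrt(2.0 * D[i] * dt);
    mob[i] = D[i] * dt / kT;
  }

  const double c2 = cutoff * cutoff;
  std::vector<double> fx(n), fy(n), fz(n);
  std::vector<double> qv(n);
  std::vector<int> charged;
  for (int i = 0; i < n; ++i) {
    qv[i] = q[i];
    if (qv[i] != 0.0) charged.push_back(i);
  }
  const int ncg = (int)charged.size();
  const double bx = box[0], by = box[1], bz = box[2];
  const double ibz = 1.0 / bz;
  const double kee = k_e / eps_r;

  int iframe = 0;
  for (int i = 0; i < n; ++i) {
    frames[i] = x[i];
    frames[n + i] = y[i];
    frames[2 * n + i] = z[i];
  }
  times[0] = t0;
  iframe = 1;

  for (int step = 1; step <= n_steps; ++step) {
    if (interacting) {
      std::fill(fx.begin(), fx.end(), 0.0);
      std::fill(fy.begin(), fy.end(), 0.0);
      std::fill(fz.begin(), fz.end(), 0.0);
      for (int a = 0; a < ncg - 1; ++a) {
        const int i = charged[a];
        const double xi = x[i], yi = y[i], zi = z[i], qi = qv[i];
        for (int b = a + 1; b < ncg; ++b) {
          const int j = charged[b];
          // wrapped coordinates => |raw difference| < L, so a single
          // branch applies the minimum image (faster than std::round)
          double dx = xi - x[j];
          if (dx > 0.5 * bx) dx -= bx; else if (dx < -0.5 * bx) dx += bx;
          if (std::fabs(dx) > cutoff) continue;
          double dy = yi - y[j];
          if (dy > 0.5 * by) dy -= by; else if (dy < -0.5 * by) dy += by;
          if (std::fabs(dy) > cutoff) continue;
          double dz = zi - z[j];
          if (dz > 0.5 * bz) dz -= bz; else if (dz < -0.5 * bz) dz += bz;
          const double r2 = dx * dx + dy * dy + dz * dz;
          if (r2 > c2 || r2 < 1e-12) continue;
          const double fmag = kee * qi * qv[j] / (r2 * std::sqrt(r2));
          fx[i] += fmag * dx; fx[j] -= fmag * dx;
          fy[i] += fmag * dy; fy[j] -= fmag * dy;
          fz[i] += fmag * dz; fz[j] -= fmag * dz;
        }
      }
    }

    for (int i = 0; i < n; ++i) {
      double Fx = 0.0, Fy = 0.0, Fz = qv[i] * Ez;
      if (has_slab && wall_sigma != 0.0 && qv[i] != 0.0) {
        // charged-wall fixture: +sigma sheet on the lower face, -sigma on
        // the upper face, with the same laterally integrated truncated
        // Coulomb kernel as the pair forces (field decays linearly to zero
        // at the cutoff): E(d) = sigma/(2 eps0 eps_r) (1 - |d|/rc)
        const double epref = wall_sigma * 2.0 * M_PI * k_e / eps_r;
        double d = z[i] - zlo;
        d -= bz * std::round(d * ibz);
        if (std::fabs(d) < cutoff)
          Fz += qv[i] * epref * (d > 0 ? 1.0 : -1.0) *
                (1.0 - std::fabs(d) / cutoff);
        d = z[i] - zhi;
        d -= bz * std::round(d * ibz);
        if (std::fabs(d) < cutoff)
          Fz -= qv[i] * epref * (d > 0 ? 1.0 : -1.0) *
                (1.0 - std::fabs(d) / cutoff);
      }
      if (interacting) { Fx += fx[i]; Fy += fy[i]; Fz += fz[i]; }

      double xn = x[i] + mob[i] * Fx + sig[i] * norm_rand();
      double yn = y[i] + mob[i] * Fy + sig[i] * norm_rand();
      double zn = z[i] + mob[i] * Fz + sig[i] * norm_rand();

      if (!R_finite(xn) || !R_finite(yn) || !R_finite(zn))
        stop("non-finite coordinate for particle %d at step %d", i + 1, step);

      if (has_slab && reflect[i]) {
        const bool below = z[i] <= zlo;  // which side the particle came from
        int guard = 0;
        while (zn > zlo && zn < zhi) {
          zn = below ? 2.0 * zlo - zn : 2.0 * zhi - zn;
          if (++guard > 16)
            stop("reflection failed to converge for particle %d at step %d",
                 i + 1, step);
        }
      }

      xn -= box[0] * std::floor(xn / box[0]);
      yn -= box[1] * std::floor(yn / box[1]);
      zn -= box[2] * std::floor(zn / box[2]);
      x[i] = xn; y[i] = yn; z[i] = zn;
    }

    if (step % stride == 0) {
      const R_xlen_t off = (R_xlen_t)iframe * 3 * n;
      for (int i = 0; i < n; ++i) {
        frames[off + i] = x[i];
        frames[off + n + i] = y[i];
        frames[off + 2 * n + i] = z[i];
      }
      times[iframe] = t0 + step * dt;
      ++iframe;
    }
  }

  return List::create(_["frames"] = frames, _["times"] = times);
}

// Contact edges (1-based, i < j) between the given positions under a distance
// cutoff. Minimum-image convention is applied only on axes with pbc TRUE;
// for transmembrane-chain detection z is non-periodic so that bulk water
// connecting through the z boundary is not mistaken for a membrane-spanning
// path. Uses a cell list when the box supports >= 3 cells per periodic axis,
// otherwise falls back to the O(n^2) scan.
// [[Rcpp::export]]
IntegerMatrix contact_edges_cpp(NumericMatrix pos, NumericVector box,
                                double cutoff, LogicalVector pbc) {
  const int n = pos.nrow();
  const double c2 = cutoff * cutoff;
  std::vector<int> ei, ej;

  int nc[3];
  bool cells_ok = n > 200;
  for (int a = 0; a < 3; ++a) {
    nc[a] = std::max(1, (int)std::floor(box[a] / cutoff));
    if (pbc[a] && nc[a] < 3) cells_ok = false;
  }

  auto dist2 = [&](int i, int j) {
    double r2 = 0.0;
    for (int a = 0; a < 3; ++a) {
      double dd = pos(i, a) - pos(j, a);
      if (pbc[a]) dd -= box[a] * std::round(dd / box[a]);
      r2 += dd * dd;
    }
    return r2;
  };

  if (!cells_ok) {
    for (int i = 0; i < n - 1; ++i)
      for (int j = i + 1; j < n; ++j)
        if (dist2(i, j) <= c2) { ei.push_back(i + 1); ej.push_back(j + 1); }
  } else {
    const int nctot = nc[0] * nc[1] * nc[2];
    std::vector<std::vector<int> > cells(nctot);
    std::vector<int> ci(n), cj(n), ck(n);
    for (int i = 0; i < n; ++i) {
      int c[3];
      for (int a = 0; a < 3; ++a) {
        int idx = (int)std::floor(pos(i, a) / box[a] * nc[a]);
        if (idx < 0) idx = 0;
        if (idx >= nc[a]) idx = nc[a] - 1;
        c[a] = idx;
      }
      ci[i] = c[0]; cj[i] = c[1]; ck[i] = c[2];
      cells[(c[0] * nc[1] + c[1]) * nc[2] + c[2]].push_back(i);
    }
    for (int i = 0; i < n; ++i) {
      for (int da = -1; da <= 1; ++da) {
        int a0 = ci[i] + da;
        if (pbc[0]) a0 = (a0 + nc[0]) % nc[0];
        else if (a0 < 0 || a0 >= nc[0]) continue;
        for (int db = -1; db <= 1; ++db) {
          int b0 = cj[i] + db;
          if (pbc[1]) b0 = (b0 + nc[1]) % nc[1];
          else if (b0 < 0 || b0 >= nc[1]) continue;
          for (int dc = -1; dc <= 1; ++dc) {
            int c0 = ck[i] + dc;
            if (pbc[2]) c0 = (c0 + nc[2]) % nc[2];
            else if (c0 < 0 || c0 >= nc[2]) continue;
            const std::vector<int>& cell = cells[(a0 * nc[1] + b0) * nc[2] + c0];
            for (size_t m = 0; m < cell.size(); ++m) {
              const int j = cell[m];
              if (j <= i) continue;
              if (dist2(i, j) <= c2) { ei.push_back(i + 1); ej.push_back(j + 1); }
            }
          }
        }
      }
    }
  }

  IntegerMatrix out(ei.size(), 2);
  for (size_t m = 0; m < ei.size(); ++m) {
    out(m, 0) = ei[m];
    out(m, 1) = ej[m];
  }
  return out;
}
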