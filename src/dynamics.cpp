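// Compiled kernels for the bead-chain chromosome model: pairwise forces
// (WCA excluded volume + shifted-truncated LJ attraction with per-pair
// depths), BAOAB Langevin integration, self-avoiding chain growth inside a
// spherical cage, contact detection, pair-distance histograms, and the
// breakage-first lesion-contact kinetics loop.
//
// All randomness is drawn from R's RNG (RNGScope), so set.seed() on the R
// side makes every run bit-reproducible on one platform.

#include <Rcpp.h>
#include <cmath>
#include <vector>

using namespace Rcpp;

static const double SIGMA_MIN_POW6 = 2.0; // (2^(1/6))^6

// Pair forces. u0_attr may be a 0x0 matrix meaning "no attraction".
// Bonded pairs (|i-j| == 1) interact only through the harmonic bond.
static void compute_forces(const std::vector<double>& x,
                           const std::vector<double>& y,
                           const std::vector<double>& z,
                           const NumericMatrix& u0_attr,
                           double u0_ev, double d, double rcut,
                           double kbond,
                           double cage_radius, double cage_k,
                           std::vector<double>& fx,
                           std::vector<double>& fy,
                           std::vector<double>& fz) {
  const int N = (int)x.size();
  const bool has_attr = u0_attr.nrow() == N;
  const double d2 = d * d;
  const double rmin2 = d2 * std::pow(2.0, 1.0 / 3.0); // (2^(1/6) d)^2
  const double rcut2 = rcut * rcut;
  std::fill(fx.begin(), fx.end(), 0.0);
  std::fill(fy.begin(), fy.end(), 0.0);
  std::fill(fz.begin(), fz.end(), 0.0);

  for (int i = 0; i < N; ++i) {
    for (int j = i + 1; j < N; ++j) {
      double dx = x[i] - x[j], dy = y[i] - y[j], dz = z[i] - z[j];
      double r2 = dx * dx + dy * dy + dz * dz;
      if (j == i + 1) {
        // harmonic bond, rest length d
        double r = std::sqrt(r2);
        double fmag = -kbond * (r - d); // dU/dr = kbond (r - d)
        if (r > 1e-12) {
          double s = fmag / r;
          fx[i] += s * dx; fy[i] += s * dy; fz[i] += s * dz;
          fx[j] -= s * dx; fy[j] -= s * dy; fz[j] -= s * dz;
        }
        continue;
      }
      if (r2 >= rcut2) continue;
      double inv2 = d2 / r2;
      double inv6 = inv2 * inv2 * inv2;
      double coef = 0.0; // force magnitude coefficient: F = coef * rvec
      if (r2 <= rmin2) {
        // WCA branch: U = 4 u0_ev (s^12 - s^6 + 1/4)
        // -dU/dr * (1/r) = 24 u0_ev (2 s^12 - s^6) / r^2
        coef = 24.0 * u0_ev * (2.0 * inv6 * inv6 - inv6) / r2;
      } else if (has_attr) {
        double u0a = u0_attr(i, j);
        if (u0a > 0.0)
          coef = 24.0 * u0a * (2.0 * inv6 * inv6 - inv6) / r2;
      }
      if (coef != 0.0) {
        fx[i] += coef * dx; fy[i] += coef * dy; fz[i] += coef * dz;
        fx[j] -= coef * dx; fy[j] -= coef * dy; fz[j] -= coef * dz;
      }
    }
    if (cage_radius > 0.0) {
      double r2c = x[i] * x[i] + y[i] * y[i] + z[i] * z[i];
      double rc = std::sqrt(r2c);
      if (rc > cage_radius) {
        double fmag = -cage_k * (rc - cage_radius) / rc;
        fx[i] += fmag * x[i]; fy[i] += fmag * y[i]; fz[i] += fmag * z[i];
      }
    }
  }
}

// [[Rcpp::export]]
double cpp_total_energy(NumericMatrix pos, NumericMatrix u0_attr,
                        double u0_ev, double d, double rcut, double kbond) {
  const int N = pos.nrow();
  const bool has_attr = u0_attr.nrow() == N;
  const double rmin = d * std::pow(2.0, 1.0 / 6.0);
  double e = 0.0;
  double shift = std::pow(d / rcut, 12.0) - std::pow(d / rcut, 6.0);
  for (int i = 0; i < N; ++i)
    for (int j = i + 1; j < N; ++j) {
      double dx = pos(i, 0) - pos(j, 0), dy = pos(i, 1) - pos(j, 1),
             dz = pos(i, 2) - pos(j, 2);
      double r = std::sqrt(dx * dx + dy * dy + dz * dz);
      if (j == i + 1) {
        e += 0.5 * kbond * (r - d) * (r - d);
        continue;
      }
      double s6 = std::pow(d / r, 6.0);
      if (r <= rmin) {
        e += 4.0 * u0_ev * (s6 * s6 - s6 + 0.25);
      } else if (has_attr && r <= rcut) {
        e += 4.0 * u0_attr(i, j) * (s6 * s6 - s6 - shift);
      }
    }
  return e;
}

static double rg_of(const std::vector<double>& x,
                    const std::vector<double>& y,
                    const std::vector<double>& z) {
  const int N = (int)x.size();
  double cx = 0, cy = 0, cz = 0;
  for (int i = 0; i < N; ++i) { cx += x[i]; cy += y[i]; cz += z[i]; }
  cx /= N; cy /= N; cz /= N;
  double s = 0;
  for (int i = 0; i < N; ++i) {
    double dx = x[i] - cx, dy = y[i] - cy, dz = z[i] - cz;
    s += dx * dx + dy * dy + dz * dz;
  }
  return std::sqrt(s / N);
}

// BAOAB Langevin run. Samples frames every sample_stride steps (0 = none)
// and Rg every rg_stride steps (0 = none). Returns final positions, frames,
// and the Rg trace. kT = 0 gives deterministic damped dynamics.
// [[Rcpp::export]]
List cpp_langevin_run(NumericMatrix pos0, NumericMatrix u0_attr,
                      double u0_ev, double d, double rcut, double kbond,
                      double mass, double gamma, double kT, double dt,
                      int n_steps, int sample_stride, int rg_stride,
                      double cage_radius, double cage_k) {
  RNGScope scope;
  const int N = pos0.nrow();
  std::vector<double> x(N), y(N), z(N), vx(N), vy(N), vz(N),
      fx(N), fy(N), fz(N);
  for (int i = 0; i < N; ++i) {
    x[i] = pos0(i, 0); y[i] = pos0(i, 1); z[i] = pos0(i, 2);
  }
  const double vscale = kT > 0 ? std::sqrt(kT / mass) : 0.0;
  for (int i = 0; i < N; ++i) {
    vx[i] = vscale * norm_rand();
    vy[i] = vscale * norm_rand();
    vz[i] = vscale * norm_rand();
  }
  const double c1 = std::exp(-gamma * dt);
  const double c2 = kT > 0 ? std::sqrt((1.0 - c1 * c1) * kT / mass) : 0.0;
  const double hdtm = 0.5 * dt / mass;
  const double hdt = 0.5 * dt;

  int n_frames = sample_stride > 0 ? n_steps / sample_stride : 0;
  NumericVector frames(n_frames > 0 ? (R_xlen_t)n_frames * N * 3 : 0);
  int n_rg = rg_stride > 0 ? n_steps / rg_stride : 0;
  NumericVector rg_trace(n_rg);
  int fidx = 0, ridx = 0;

  compute_forces(x, y, z, u0_attr, u0_ev, d, rcut, kbond,
                 cage_radius, cage_k, fx, fy, fz);
  for (int step = 1; step <= n_steps; ++step) {
    for (int i = 0; i < N; ++i) {           // B
      vx[i] += hdtm * fx[i]; vy[i] += hdtm * fy[i]; vz[i] += hdtm * fz[i];
      x[i] += hdt * vx[i]; y[i] += hdt * vy[i]; z[i] += hdt * vz[i]; // A
    }
    for (int i = 0; i < N; ++i) {           // O
      vx[i] = c1 * vx[i] + c2 * norm_rand();
      vy[i] = c1 * vy[i] + c2 * norm_rand();
      vz[i] = c1 * vz[i] + c2 * norm_rand();
      x[i] += hdt * vx[i]; y[i] += hdt * vy[i]; z[i] += hdt * vz[i]; // A
    }
    compute_forces(x, y, z, u0_attr, u0_ev, d, rcut, kbond,
                   cage_radius, cage_k, fx, fy, fz);
    for (int i = 0; i < N; ++i) {           // B
      vx[i] += hdtm * fx[i]; vy[i] += hdtm * fy[i]; vz[i] += hdtm * fz[i];
    }
    if (!std::isfinite(x[0]) || std::fabs(x[0]) > 1e8)
      stop("numerical blow-up at step %d", step);
    if (sample_stride > 0 && step % sample_stride == 0 && fidx < n_frames) {
      for (int i = 0; i < N; ++i) {
        frames[(R_xlen_t)fidx * N * 3 + i] = x[i];
        frames[(R_xlen_t)fidx * N * 3 + N + i] = y[i];
        frames[(R_xlen_t)fidx * N * 3 + 2 * N + i] = z[i];
      }
      ++fidx;
    }
    if (rg_stride > 0 && step % rg_stride == 0 && ridx < n_rg)
      rg_trace[ridx++] = rg_of(x, y, z);
  }
  NumericMatrix fin(N, 3);
  for (int i = 0; i < N; ++i) { fin(i, 0) = x[i]; fin(i, 1) = y[i]; fin(i, 2) = z[i]; }
  if (n_frames > 0)
    frames.attr("dim") = IntegerVector::create(N, 3, n_frames);
  return List::create(_["final"] = fin, _["frames"] = frames,
                      _["rg"] = rg_trace);
}

// Self-avoiding chain growth inside a spherical cage: each new bead is
// placed at distance d from the previous one in a uniformly random
// direction; a placement is accepted when no non-bonded bead lies closer
// than d and the bead is inside the cage. Retries per bead are capped;
// exhaustion restarts the whole chain.
// [[Rcpp::export]]
NumericMatrix cpp_grow_saw(int N, double d, double cage_radius,
                           int max_tries, int max_restarts) {
  RNGScope scope;
  NumericMatrix pos(N, 3);
  const double d2 = d * d * 0.999999; // tolerate exact-d placements
  for (int attempt = 0; attempt <= max_restarts; ++attempt) {
    bool ok = true;
    // first bead uniform in the cage interior (or origin if no cage)
    if (cage_radius > 0) {
      double rr = cage_radius * std::cbrt(unif_rand());
      double ct = 2.0 * unif_rand() - 1.0, ph = 2.0 * M_PI * unif_rand();
      double st = std::sqrt(1.0 - ct * ct);
      pos(0, 0) = rr * st * std::cos(ph);
      pos(0, 1) = rr * st * std::sin(ph);
      pos(0, 2) = rr * ct;
    } else {
      pos(0, 0) = pos(0, 1) = pos(0, 2) = 0.0;
    }
    for (int b = 1; b < N && ok; ++b) {
      bool placed = false;
      for (int t = 0; t < max_tries; ++t) {
        double ct = 2.0 * unif_rand() - 1.0, ph = 2.0 * M_PI * unif_rand();
        double st = std::sqrt(1.0 - ct * ct);
        double nx = pos(b - 1, 0) + d * st * std::cos(ph);
        double ny = pos(b - 1, 1) + d * st * std::sin(ph);
        double nz = pos(b - 1, 2) + d * ct;
        if (cage_radius > 0 &&
            nx * nx + ny * ny + nz * nz > cage_radius * cage_radius)
          continue;
        bool clash = false;
        for (int k = 0; k < b - 1; ++k) {
          double dx = nx - pos(k, 0), dy = ny - pos(k, 1), dz = nz - pos(k, 2);
          if (dx * dx + dy * dy + dz * dz < d2) { clash = true; break; }
        }
        if (!clash) {
          pos(b, 0) = nx; pos(b, 1) = ny; pos(b, 2) = nz;
          placed = true;
          break;
        }
      }
      if (!placed) ok = false;
    }
    if (ok) return pos;
  }
  stop("self-avoiding chain growth did not converge (N = %d)", N);
  return pos; // unreached
}

// [[Rcpp::export]]
IntegerMatrix cpp_contact_matrix(NumericMatrix pos, double Rcont) {
  const int N = pos.nrow();
  const double R2 = Rcont * Rcont;
  IntegerMatrix m(N, N);
  for (int i = 0; i < N; ++i)
    for (int j = i + 1; j < N; ++j) {
      double dx = pos(i, 0) - pos(j, 0), dy = pos(i, 1) - pos(j, 1),
             dz = pos(i, 2) - pos(j, 2);
      if (dx * dx + dy * dy + dz * dz <= R2) { m(i, j) = 1; m(j, i) = 1; }
    }
  return m;
}

// Sum of binary contact maps over a list of N x 3 conformations.
// [[Rcpp::export]]
NumericMatrix cpp_ensemble_contact_counts(List confs, double Rcont) {
  const int K = confs.size();
  NumericMatrix first = confs[0];
  const int N = first.nrow();
  const double R2 = Rcont * Rcont;
  NumericMatrix m(N, N);
  for (int k = 0; k < K; ++k) {
    NumericMatrix p = confs[k];
    for (int i = 0; i < N; ++i)
      for (int j = i + 1; j < N; ++j) {
        double dx = p(i, 0) - p(j, 0), dy = p(i, 1) - p(j, 1),
               dz = p(i, 2) - p(j, 2);
        if (dx * dx + dy * dy + dz * dz <= R2) { m(i, j) += 1; m(j, i) += 1; }
      }
  }
  return m;
}

// Histogram of anchor-to-j distances over an ensemble: nbins x N counts,
// bin b covers [b*dr, (b+1)*dr). Distances beyond the grid are dropped.
// anchor is 0-based.
// [[Rcpp::export]]
NumericMatrix cpp_pair_distance_counts(List confs, int anchor, double dr,
                                       int nbins) {
  const int K = confs.size();
  NumericMatrix first = confs[0];
  const int N = first.nrow();
  NumericMatrix counts(nbins, N);
  for (int k = 0; k < K; ++k) {
    NumericMatrix p = confs[k];
    for (int j = 0; j < N; ++j) {
      if (j == anchor) continue;
      double dx = p(anchor, 0) - p(j, 0), dy = p(anchor, 1) - p(j, 1),
             dz = p(anchor, 2) - p(j, 2);
      double r = std::sqrt(dx * dx + dy * dy + dz * dz);
      int b = (int)std::floor(r / dr);
      if (b >= 0 && b < nbins) counts(b, j) += 1;
    }
  }
  return counts;
}

// Breakage-first kinetics for one chromosome copy. Damaged bead indices are
// 0-based. Contacts among damaged pairs are checked every steps_per_check
// integration steps (steps_per_check = 0 freezes the conformation); while a
// pair is in contact it converts with probability p_step per check. A pair
// whose first contact episode ends without conversion is retired (re-formed
// contacts neglected). Check index 0 is the initial (t = 0) configuration.
// Returns one row per damaged pair: i, j (0-based), r0, first_contact
// (check index, -1 if never), convert (check index, -1 if never).
// [[Rcpp::export]]
List cpp_breakage_first(NumericMatrix pos0, IntegerVector damaged,
                        NumericMatrix u0_attr, double u0_ev, double d,
                        double rcut, double kbond, double mass,
                        double gamma, double kT, double dt,
                        int steps_per_check, int n_checks, double Rcont,
                        double p_step) {
  RNGScope scope;
  const int N = pos0.nrow();
  const int nd = damaged.size();
  const int npairs = nd * (nd - 1) / 2;
  const double R2 = Rcont * Rcont;

  std::vector<double> x(N), y(N), z(N), vx(N), vy(N), vz(N),
      fx(N), fy(N), fz(N);
  for (int i = 0; i < N; ++i) {
    x[i] = pos0(i, 0); y[i] = pos0(i, 1); z[i] = pos0(i, 2);
  }
  const double vscale = kT > 0 ? std::sqrt(kT / mass) : 0.0;
  for (int i = 0; i < N; ++i) {
    vx[i] = vscale * norm_rand();
    vy[i] = vscale * norm_rand();
    vz[i] = vscale * norm_rand();
  }
  const double c1 = std::exp(-gamma * dt);
  const double c2 = kT > 0 ? std::sqrt((1.0 - c1 * c1) * kT / mass) : 0.0;
  const double hdtm = 0.5 * dt / mass;
  const double hdt = 0.5 * dt;

  IntegerVector pi(npairs), pj(npairs), first_contact(npairs, -1),
      convert(npairs, -1);
  NumericVector r0(npairs);
  // state: 0 never contacted, 1 in contact, 2 retired, 3 converted
  std::vector<int> state(npairs, 0);
  int idx = 0;
  for (int a = 0; a < nd; ++a)
    for (int b = a + 1; b < nd; ++b) {
      pi[idx] = damaged[a]; pj[idx] = damaged[b];
      double dx = x[damaged[a]] - x[damaged[b]],
             dy = y[damaged[a]] - y[damaged[b]],
             dz = z[damaged[a]] - z[damaged[b]];
      r0[idx] = std::sqrt(dx * dx + dy * dy + dz * dz);
      ++idx;
    }

  if (steps_per_check > 0)
    compute_forces(x, y, z, u0_attr, u0_ev, d, rcut, kbond, 0.0, 0.0,
                   fx, fy, fz);

  for (int chk = 0; chk < n_checks; ++chk) {
    if (chk > 0 && steps_per_check > 0) {
      for (int s = 0; s < steps_per_check; ++s) {
        for (int i = 0; i < N; ++i) {
          vx[i] += hdtm * fx[i]; vy[i] += hdtm * fy[i]; vz[i] += hdtm * fz[i];
          x[i] += hdt * vx[i]; y[i] += hdt * vy[i]; z[i] += hdt * vz[i];
        }
        for (int i = 0; i < N; ++i) {
          vx[i] = c1 * vx[i] + c2 * norm_rand();
          vy[i] = c1 * vy[i] + c2 * norm_rand();
          vz[i] = c1 * vz[i] + c2 * norm_rand();
          x[i] += hdt * vx[i]; y[i] += hdt * vy[i]; z[i] += hdt * vz[i];
        }
        compute_forces(x, y, z, u0_attr, u0_ev, d, rcut, kbond, 0.0, 0.0,
                       fx, fy, fz);
        for (int i = 0; i < N; ++i) {
          vx[i] += hdtm * fx[i]; vy[i] += hdtm * fy[i]; vz[i] += hdtm * fz[i];
        }
      }
      if (!std::isfinite(x[0]) || std::fabs(x[0]) > 1e8)
        stop("numerical blow-up at check %d", chk);
    }
    for (int p = 0; p < npairs; ++p) {
      if (state[p] >= 2) continue;
      int i = pi[p], j = pj[p];
      double dx = x[i] - x[j], dy = y[i] - y[j], dz = z[i] - z[j];
      bool in_contact = dx * dx + dy * dy + dz * dz <= R2;
      if (in_contact) {
        if (state[p] == 0) {
          state[p] = 1;
          first_contact[p] = chk;
        }
        if (unif_rand() < p_step) {
          state[p] = 3;
          convert[p] = chk;
        }
      } else if (state[p] == 1) {
        state[p] = 2; // episode ended without conversion: retired
      }
    }
  }
  return List::create(_["i"] = pi, _["j"] = pj, _["r0"] = r0,
                      _["first_contact"] = first_contact,
                      _["convert"] = convert);
}
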