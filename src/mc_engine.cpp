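// Metropolis Monte Carlo engine for the spherical cell model.
//
// Geometry and energetics: a hard-sphere macroion (radius r_macro, valence
// z_macro) is fixed at the origin of a closed spherical cell of radius
// r_cell.  Mobile hard-sphere ions interact with each other and with the
// macroion through the bare Coulomb potential u_ij = z_i z_j l_B / r_ij
// (in kBT units, lengths in Å), infinite on hard-sphere overlap.  There are
// no periodic images: the cell is a closed container and ion centres are
// confined to r_macro + R_i <= |r| <= r_cell - R_i.
//
// The RNG is a self-contained xoshiro256++ seeded through splitmix64, so a
// trajectory is bit-reproducible from the seed alone, independent of R's
// RNG state.

#include <Rcpp.h>
#include <cmath>
#include <cstdint>
#include <vector>

using namespace Rcpp;

namespace {

struct Xoshiro256 {
  uint64_t s[4];

  explicit Xoshiro256(uint64_t seed) {
    // splitmix64 scrambles even tiny/adjacent seeds into good states
    uint64_t x = seed;
    for (int i = 0; i < 4; ++i) {
      x += 0x9e3779b97f4a7c15ULL;
      uint64_t z = x;
      z = (z ^ (z >> 30)) * 0xbf58476d1ce4e5b9ULL;
      z = (z ^ (z >> 27)) * 0x94d049bb133111ebULL;
      s[i] = z ^ (z >> 31);
    }
  }

  static inline uint64_t rotl(uint64_t v, int k) {
    return (v << k) | (v >> (64 - k));
  }

  inline uint64_t next() {
    const uint64_t result = rotl(s[0] + s[3], 23) + s[0];
    const uint64_t t = s[1] << 17;
    s[2] ^= s[0];
    s[3] ^= s[1];
    s[1] ^= s[2];
    s[0] ^= s[3];
    s[2] ^= t;
    s[3] = rotl(s[3], 45);
    return result;
  }

  // uniform double in [0, 1)
  inline double unif() { return (next() >> 11) * 0x1.0p-53; }

  // uniform integer in [0, n)
  inline int below(int n) { return static_cast<int>(unif() * n); }
};

inline double dist3(const std::vector<double>& x, const std::vector<double>& y,
                    const std::vector<double>& z, int i, int j) {
  const double dx = x[i] - x[j], dy = y[i] - y[j], dz = z[i] - z[j];
  return std::sqrt(dx * dx + dy * dy + dz * dz);
}

// Coulomb energy (kBT) of ion i with the macroion and all other ions.
// Positions assumed overlap-free.
double ion_energy(int i, const std::vector<double>& x,
                  const std::vector<double>& y, const std::vector<double>& z,
                  const std::vector<double>& q, double z_macro,
                  double l_bjerrum, int n) {
  const double ri = std::sqrt(x[i] * x[i] + y[i] * y[i] + z[i] * z[i]);
  double u = q[i] * z_macro / ri;
  for (int j = 0; j < n; ++j) {
    if (j == i) continue;
    u += q[i] * q[j] / dist3(x, y, z, i, j);
  }
  return l_bjerrum * u;
}

// same but for an explicit trial position of ion i
double ion_energy_at(int i, double xi, double yi, double zi,
                     const std::vector<double>& x, const std::vector<double>& y,
                     const std::vector<double>& z, const std::vector<double>& q,
                     double z_macro, double l_bjerrum, int n) {
  const double ri = std::sqrt(xi * xi + yi * yi + zi * zi);
  double u = q[i] * z_macro / ri;
  for (int j = 0; j < n; ++j) {
    if (j == i) continue;
    const double dx = xi - x[j], dy = yi - y[j], dz = zi - z[j];
    u += q[i] * q[j] / std::sqrt(dx * dx + dy * dy + dz * dz);
  }
  return l_bjerrum * u;
}

double full_energy(const std::vector<double>& x, const std::vector<double>& y,
                   const std::vector<double>& z, const std::vector<double>& q,
                   double z_macro, double l_bjerrum, int n) {
  double u = 0.0;
  for (int i = 0; i < n; ++i) {
    const double ri = std::sqrt(x[i] * x[i] + y[i] * y[i] + z[i] * z[i]);
    u += q[i] * z_macro / ri;
    for (int j = i + 1; j < n; ++j) u += q[i] * q[j] / dist3(x, y, z, i, j);
  }
  return l_bjerrum * u;
}

}  // namespace

//' @name cpp_place_ions
//' @title Random non-overlapping placement of ions in the cell (internal)
//' @keywords internal
// [[Rcpp::export]]
NumericMatrix cpp_place_ions(NumericVector radius, double r_macro,
                             double r_cell, double seed,
                             int max_attempts_per_ion) {
  const int n = radius.size();
  NumericMatrix pos(n, 3);
  if (n == 0) return pos;
  Xoshiro256 rng(static_cast<uint64_t>(seed));
  std::vector<double> x(n), y(n), z(n);
  for (int i = 0; i < n; ++i) {
    const double rmin = r_macro + radius[i];
    const double rmax = r_cell - radius[i];
    bool placed = false;
    for (int attempt = 0; attempt < max_attempts_per_ion; ++attempt) {
      // uniform in the enclosing cube, then shell + overlap rejection:
      // accepted points are uniform over the accessible volume
      const double xi = (2.0 * rng.unif() - 1.0) * rmax;
      const double yi = (2.0 * rng.unif() - 1.0) * rmax;
      const double zi = (2.0 * rng.unif() - 1.0) * rmax;
      const double r = std::sqrt(xi * xi + yi * yi + zi * zi);
      if (r < rmin || r > rmax) continue;
      bool overlap = false;
      for (int j = 0; j < i; ++j) {
        const double dx = xi - x[j], dy = yi - y[j], dz = zi - z[j];
        if (std::sqrt(dx * dx + dy * dy + dz * dz) < radius[i] + radius[j]) {
          overlap = true;
          break;
        }
      }
      if (overlap) continue;
      x[i] = xi;
      y[i] = yi;
      z[i] = zi;
      placed = true;
      break;
    }
    if (!placed)
      stop("initial placement failed for ion %d: packing looks infeasible", i + 1);
  }
  for (int i = 0; i < n; ++i) {
    pos(i, 0) = x[i];
    pos(i, 1) = y[i];
    pos(i, 2) = z[i];
  }
  return pos;
}

//' @name cpp_total_energy
//' @title Engine-side total Coulomb energy in kBT (internal)
//' @keywords internal
// [[Rcpp::export]]
double cpp_total_energy(NumericMatrix pos, NumericVector valence,
                        double z_macro, double l_bjerrum) {
  const int n = pos.nrow();
  std::vector<double> x(n), y(n), z(n), q(n);
  for (int i = 0; i < n; ++i) {
    x[i] = pos(i, 0);
    y[i] = pos(i, 1);
    z[i] = pos(i, 2);
    q[i] = valence[i];
  }
  return full_energy(x, y, z, q, z_macro, l_bjerrum, n);
}

//' @name cpp_run_mc
//' @title Metropolis MC driver (internal)
//' @description Runs equilibration (with optional step-size adaptation,
//'   frozen before production) followed by production sampling.  Maintains
//'   a running total energy updated from single-ion terms and audits it
//'   against a full recomputation every \code{audit_every} moves.
//' @keywords internal
// [[Rcpp::export]]
List cpp_run_mc(NumericMatrix pos0, NumericVector valence, NumericVector radius,
                double z_macro, double r_macro, double r_cell,
                double l_bjerrum, double n_equil_moves, double n_prod_moves,
                double sample_every, double max_disp, bool adapt, double seed,
                double audit_every, double audit_tol, bool record_moves) {
  const int n = pos0.nrow();
  std::vector<double> x(n), y(n), z(n), q(n), hs(n);
  for (int i = 0; i < n; ++i) {
    x[i] = pos0(i, 0);
    y[i] = pos0(i, 1);
    z[i] = pos0(i, 2);
    q[i] = valence[i];
    hs[i] = radius[i];
  }

  Xoshiro256 rng(static_cast<uint64_t>(seed));
  const long long n_equil = static_cast<long long>(n_equil_moves);
  const long long n_prod = static_cast<long long>(n_prod_moves);
  const long long samp = sample_every > 0 ? static_cast<long long>(sample_every)
                                          : (n_prod > 0 ? n_prod : 1);
  const long long audit = audit_every > 0 ? static_cast<long long>(audit_every)
                                          : 100000;

  double disp = max_disp;
  const double disp_max = 0.5 * (r_cell - r_macro);
  double u_run = full_energy(x, y, z, q, z_macro, l_bjerrum, n);
  double max_audit_dev = 0.0;

  const long long n_samples = (n > 0 && n_prod > 0) ? n_prod / samp : 0;
  NumericVector sample_pos(n_samples * n * 3);
  NumericVector sample_energy(n_samples);
  long long stored = 0;

  const long long n_rec = record_moves ? (n_equil + n_prod) : 0;
  NumericVector rec_du(n_rec);
  LogicalVector rec_acc(n_rec);
  LogicalVector rec_overlap(n_rec);
  IntegerVector rec_ion(n_rec);
  NumericVector rec_pos(record_moves ? n_rec * n * 3 : 0);

  long long prod_attempted = 0, prod_accepted = 0;
  long long win_attempted = 0, win_accepted = 0;
  const long long adapt_window = std::max<long long>(2000, 100LL * n);
  long long since_audit = 0;

  const long long total_moves = n_equil + n_prod;
  for (long long m = 0; m < total_moves && n > 0; ++m) {
    const bool production = m >= n_equil;
    const int i = rng.below(n);
    const double xi = x[i] + (2.0 * rng.unif() - 1.0) * disp;
    const double yi = y[i] + (2.0 * rng.unif() - 1.0) * disp;
    const double zi = z[i] + (2.0 * rng.unif() - 1.0) * disp;

    bool reject_hard = false;
    const double r = std::sqrt(xi * xi + yi * yi + zi * zi);
    if (r < r_macro + hs[i] || r > r_cell - hs[i]) {
      reject_hard = true;
    } else {
      for (int j = 0; j < n; ++j) {
        if (j == i) continue;
        const double dx = xi - x[j], dy = yi - y[j], dz = zi - z[j];
        if (std::sqrt(dx * dx + dy * dy + dz * dz) < hs[i] + hs[j]) {
          reject_hard = true;
          break;
        }
      }
    }

    bool accepted = false;
    double du = NA_REAL;
    if (!reject_hard) {
      const double u_old = ion_energy(i, x, y, z, q, z_macro, l_bjerrum, n);
      const double u_new =
          ion_energy_at(i, xi, yi, zi, x, y, z, q, z_macro, l_bjerrum, n);
      du = u_new - u_old;
      if (du <= 0.0 || rng.unif() < std::exp(-du)) {
        x[i] = xi;
        y[i] = yi;
        z[i] = zi;
        u_run += du;
        accepted = true;
      }
    }

    if (production) {
      ++prod_attempted;
      if (accepted) ++prod_accepted;
    } else if (adapt) {
      ++win_attempted;
      if (accepted) ++win_accepted;
      if (win_attempted >= adapt_window) {
        const double rate = static_cast<double>(win_accepted) / win_attempted;
        if (rate > 0.6)
          disp *= 1.15;
        else if (rate < 0.4)
          disp /= 1.15;
        if (disp > disp_max) disp = disp_max;
        if (disp < 0.05) disp = 0.05;
        win_attempted = win_accepted = 0;
      }
    }

    if (record_moves) {
      rec_du[m] = du;
      rec_acc[m] = accepted;
      rec_overlap[m] = reject_hard;
      rec_ion[m] = i + 1;
      for (int k = 0; k < n; ++k) {
        rec_pos[m * n * 3 + k] = x[k];
        rec_pos[m * n * 3 + n + k] = y[k];
        rec_pos[m * n * 3 + 2 * n + k] = z[k];
      }
    }

    // periodic audit of the incremental bookkeeping
    if (++since_audit >= audit) {
      const double u_full = full_energy(x, y, z, q, z_macro, l_bjerrum, n);
      const double dev = std::fabs(u_run - u_full);
      if (dev > max_audit_dev) max_audit_dev = dev;
      if (dev > audit_tol)
        stop("energy audit failed: running total deviates by %g kBT after %lld moves",
             dev, m + 1);
      u_run = u_full;
      since_audit = 0;
    }

    if (production && stored < n_samples) {
      const long long m_prod = m - n_equil + 1;
      if (m_prod % samp == 0) {
        for (int k = 0; k < n; ++k) {
          sample_pos[stored * n * 3 + k] = x[k];
          sample_pos[stored * n * 3 + n + k] = y[k];
          sample_pos[stored * n * 3 + 2 * n + k] = z[k];
        }
        sample_energy[stored] = u_run;
        ++stored;
      }
    }
  }

  NumericMatrix final_pos(n, 3);
  for (int i = 0; i < n; ++i) {
    final_pos(i, 0) = x[i];
    final_pos(i, 1) = y[i];
    final_pos(i, 2) = z[i];
  }

  List out = List::create(
      _["samples"] = sample_pos, _["n_samples"] = static_cast<double>(stored),
      _["energies"] = sample_energy,
      _["acceptance_rate"] = prod_attempted > 0
          ? static_cast<double>(prod_accepted) / prod_attempted
          : NA_REAL,
      _["final_positions"] = final_pos, _["tuned_displacement"] = disp,
      _["max_audit_deviation"] = max_audit_dev,
      _["final_energy"] = n > 0 ? full_energy(x, y, z, q, z_macro, l_bjerrum, n)
                                : 0.0);
  if (record_moves) {
    out["trace"] = List::create(_["delta_u"] = rec_du, _["accepted"] = rec_acc,
                                _["hard_reject"] = rec_overlap,
                                _["ion"] = rec_ion, _["positions"] = rec_pos);
  }
  return out;
}
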