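// One-bead-per-residue Langevin dynamics (BAOAB splitting).
// Units: nm, ps, g/mol, kJ/mol. Open boundaries; bonded (i,i+1) pairs are
// excluded from the nonbonded sums.
#include <Rcpp.h>
#include <cmath>
#include <cstdint>
#include <vector>
using namespace Rcpp;

namespace {

const double KB = 0.0083144621; // kJ mol^-1 K^-1

// xoshiro256++ seeded via splitmix64: deterministic per seed, independent
// of R's RNG state.
struct Rng {
  uint64_t s[4];
  explicit Rng(uint64_t seed) {
    uint64_t z = seed;
    for (int i = 0; i < 4; ++i) {
      z += 0x9e3779b97f4a7c15ULL;
      uint64_t t = z;
      t = (t ^ (t >> 30)) * 0xbf58476d1ce4e5b9ULL;
      t = (t ^ (t >> 27)) * 0x94d049bb133111ebULL;
      s[i] = t ^ (t >> 31);
    }
  }
  static uint64_t rotl(uint64_t x, int k) { return (x << k) | (x >> (64 - k)); }
  uint64_t next() {
    uint64_t r = rotl(s[0] + s[3], 23) + s[0];
    uint64_t t = s[1] << 17;
    s[2] ^= s[0]; s[3] ^= s[1]; s[1] ^= s[2]; s[0] ^= s[3]; s[2] ^= t;
    s[3] = rotl(s[3], 45);
    return r;
  }
  double unif() { // in (0,1)
    return (next() >> 11) * (1.0 / 9007199254740992.0) + 5.0e-17;
  }
  bool have_spare = false;
  double spare = 0.0;
  double norm() { // Box-Muller with caching
    if (have_spare) { have_spare = false; return spare; }
    double u = unif(), v = unif();
    double r = std::sqrt(-2.0 * std::log(u)), a = 6.283185307179586 * v;
    spare = r * std::sin(a);
    have_spare = true;
    return r * std::cos(a);
  }
};

struct PairTable {
  std::vector<int> i, j;
  std::vector<double> sig2, rmin2, lam, qq, ljshift, dhshift;
};

inline void add_forces(const std::vector<double>& x, const std::vector<double>& y,
                       const std::vector<double>& z, int n,
                       const PairTable& pt, double eps, double rc2,
                       double kappa, double lb, double kbond,
                       bool ah_on, bool dh_on,
                       std::vector<double>& fx, std::vector<double>& fy,
                       std::vector<double>& fz) {
  std::fill(fx.begin(), fx.end(), 0.0);
  std::fill(fy.begin(), fy.end(), 0.0);
  std::fill(fz.begin(), fz.end(), 0.0);
  // harmonic bonds
  for (int i = 0; i + 1 < n; ++i) {
    double dx = x[i + 1] - x[i], dy = y[i + 1] - y[i], dz = z[i + 1] - z[i];
    double r = std::sqrt(dx * dx + dy * dy + dz * dz);
    double f = kbond * (r - lb) / r; // pulls i toward i+1 when stretched
    fx[i] += f * dx; fy[i] += f * dy; fz[i] += f * dz;
    fx[i + 1] -= f * dx; fy[i + 1] -= f * dy; fz[i + 1] -= f * dz;
  }
  const size_t np = pt.i.size();
  for (size_t p = 0; p < np; ++p) {
    const int a = pt.i[p], b = pt.j[p];
    double dx = x[a] - x[b], dy = y[a] - y[b], dz = z[a] - z[b];
    double r2 = dx * dx + dy * dy + dz * dz;
    if (r2 >= rc2) continue;
    double fs = 0.0;
    if (ah_on) {
      double s2 = pt.sig2[p] / r2;
      double s6 = s2 * s2 * s2, s12 = s6 * s6;
      double flj = 24.0 * eps * (2.0 * s12 - s6) / r2;
      fs += (r2 <= pt.rmin2[p]) ? flj : pt.lam[p] * flj;
    }
    if (dh_on && pt.qq[p] != 0.0) {
      double r = std::sqrt(r2);
      fs += pt.qq[p] * std::exp(-kappa * r) * (kappa * r + 1.0) / (r2 * r);
    }
    fx[a] += fs * dx; fy[a] += fs * dy; fz[a] += fs * dz;
    fx[b] -= fs * dx; fy[b] -= fs * dy; fz[b] -= fs * dz;
  }
}

inline double potential_energy(const std::vector<double>& x,
                               const std::vector<double>& y,
                               const std::vector<double>& z, int n,
                               const PairTable& pt, double eps, double rc2,
                               double kappa, double lb, double kbond,
                               bool ah_on, bool dh_on) {
  double u = 0.0;
  for (int i = 0; i + 1 < n; ++i) {
    double dx = x[i + 1] - x[i], dy = y[i + 1] - y[i], dz = z[i + 1] - z[i];
    double r = std::sqrt(dx * dx + dy * dy + dz * dz);
    u += 0.5 * kbond * (r - lb) * (r - lb);
  }
  const size_t np = pt.i.size();
  for (size_t p = 0; p < np; ++p) {
    double dx = x[pt.i[p]] - x[pt.j[p]], dy = y[pt.i[p]] - y[pt.j[p]],
           dz = z[pt.i[p]] - z[pt.j[p]];
    double r2 = dx * dx + dy * dy + dz * dz;
    if (r2 >= rc2) continue;
    if (ah_on) {
      double s2 = pt.sig2[p] / r2;
      double s6 = s2 * s2 * s2;
      double lj = 4.0 * eps * (s6 * s6 - s6);
      double ah = (r2 <= pt.rmin2[p]) ? lj + (1.0 - pt.lam[p]) * eps
                                      : pt.lam[p] * lj;
      u += ah - pt.ljshift[p];
    }
    if (dh_on && pt.qq[p] != 0.0) {
      double r = std::sqrt(r2);
      u += pt.qq[p] * std::exp(-kappa * r) / r - pt.dhshift[p];
    }
  }
  return u;
}

} // namespace

// [[Rcpp::export]]
List langevin_run_cpp(NumericMatrix x0, NumericVector sigma,
                      NumericVector lambda, NumericVector charge,
                      NumericVector mass, double temperature, double kappa,
                      double coulomb_pref, double eps, double cutoff,
                      double lb, double kbond, double dt, double gamma,
                      double nsteps_d, int stride_steps, int log_every,
                      double seed_d, bool include_ah, bool include_dh) {
  const int n = x0.nrow();
  const long long nsteps = (long long)nsteps_d;
  const double rc2 = cutoff * cutoff;
  Rng rng((uint64_t)seed_d);

  // pair table: all (i, j>i+1); charged product folded into Debye-Hueckel
  // prefactor qq = q_i q_j * lB kB T (coulomb_pref)
  PairTable pt;
  for (int i = 0; i < n; ++i)
    for (int j = i + 2; j < n; ++j) {
      pt.i.push_back(i); pt.j.push_back(j);
      double sij = 0.5 * (sigma[i] + sigma[j]);
      double lij = 0.5 * (lambda[i] + lambda[j]);
      double s2 = sij * sij;
      pt.sig2.push_back(s2);
      pt.rmin2.push_back(std::cbrt(2.0) * s2);
      pt.lam.push_back(lij);
      double qq = charge[i] * charge[j] * coulomb_pref;
      pt.qq.push_back(qq);
      double s6c = (s2 / rc2) * (s2 / rc2) * (s2 / rc2);
      pt.ljshift.push_back(lij * 4.0 * eps * (s6c * s6c - s6c));
      pt.dhshift.push_back(qq != 0.0 ? qq * std::exp(-kappa * cutoff) / cutoff
                                     : 0.0);
    }

  std::vector<double> x(n), y(n), z(n), vx(n), vy(n), vz(n),
      fx(n), fy(n), fz(n);
  for (int i = 0; i < n; ++i) {
    x[i] = x0(i, 0); y[i] = x0(i, 1); z[i] = x0(i, 2);
  }
  // Maxwell-Boltzmann start velocities
  for (int i = 0; i < n; ++i) {
    double s = std::sqrt(KB * temperature / mass[i]);
    vx[i] = s * rng.norm(); vy[i] = s * rng.norm(); vz[i] = s * rng.norm();
  }
  // O-step constants
  const double c1 = std::exp(-gamma * dt);
  std::vector<double> c2(n);
  for (int i = 0; i < n; ++i)
    c2[i] = std::sqrt(KB * temperature * (1.0 - c1 * c1) / mass[i]);

  add_forces(x, y, z, n, pt, eps, rc2, kappa, lb, kbond,
             include_ah, include_dh, fx, fy, fz);

  const long long nframes = nsteps / stride_steps;
  NumericVector frames((R_xlen_t)nframes * n * 3);
  NumericVector temp_series(nframes);
  std::vector<double> log_step, log_pot, log_temp;
  long long frame = 0;
  bool aborted = false;
  long long abort_step = -1;
  double abort_maxf = 0.0;
  const double half = 0.5 * dt;

  for (long long step = 1; step <= nsteps; ++step) {
    for (int i = 0; i < n; ++i) { // B (half kick) + A (half drift)
      vx[i] += half * fx[i] / mass[i];
      vy[i] += half * fy[i] / mass[i];
      vz[i] += half * fz[i] / mass[i];
      x[i] += half * vx[i]; y[i] += half * vy[i]; z[i] += half * vz[i];
    }
    for (int i = 0; i < n; ++i) { // O
      vx[i] = c1 * vx[i] + c2[i] * rng.norm();
      vy[i] = c1 * vy[i] + c2[i] * rng.norm();
      vz[i] = c1 * vz[i] + c2[i] * rng.norm();
      x[i] += half * vx[i]; y[i] += half * vy[i]; z[i] += half * vz[i]; // A
    }
    add_forces(x, y, z, n, pt, eps, rc2, kappa, lb, kbond,
               include_ah, include_dh, fx, fy, fz);
    double ke = 0.0;
    for (int i = 0; i < n; ++i) { // B
      vx[i] += half * fx[i] / mass[i];
      vy[i] += half * fy[i] / mass[i];
      vz[i] += half * fz[i] / mass[i];
    }
    if (step % stride_steps == 0) {
      for (int i = 0; i < n; ++i)
        ke += 0.5 * mass[i] *
              (vx[i] * vx[i] + vy[i] * vy[i] + vz[i] * vz[i]);
      double tinst = 2.0 * ke / (3.0 * n * KB);
      bool ok = std::isfinite(tinst);
      for (int i = 0; i < n && ok; ++i)
        ok = std::isfinite(x[i]) && std::isfinite(y[i]) && std::isfinite(z[i]);
      if (!ok) {
        aborted = true; abort_step = step;
        for (int i = 0; i < n; ++i) {
          double f = std::sqrt(fx[i] * fx[i] + fy[i] * fy[i] + fz[i] * fz[i]);
          if (std::isfinite(f) && f > abort_maxf) abort_maxf = f;
        }
        break;
      }
      for (int i = 0; i < n; ++i) {
        frames[frame + nframes * (R_xlen_t)(0 * n + i)] = x[i];
        frames[frame + nframes * (R_xlen_t)(1 * n + i)] = y[i];
        frames[frame + nframes * (R_xlen_t)(2 * n + i)] = z[i];
      }
      temp_series[frame] = tinst;
      ++frame;
    }
    if (log_every > 0 && step % log_every == 0) {
      double u = potential_energy(x, y, z, n, pt, eps, rc2, kappa, lb, kbond,
                                  include_ah, include_dh);
      double ke2 = 0.0;
      for (int i = 0; i < n; ++i)
        ke2 += 0.5 * mass[i] *
               (vx[i] * vx[i] + vy[i] * vy[i] + vz[i] * vz[i]);
      log_step.push_back((double)step);
      log_pot.push_back(u);
      log_temp.push_back(2.0 * ke2 / (3.0 * n * KB));
    }
  }

  frames.attr("dim") = IntegerVector::create((int)nframes, n, 3);
  return List::create(
      _["frames"] = frames, _["n_frames"] = (double)frame,
      _["temperature_series"] = temp_series,
      _["log"] = DataFrame::create(_["step"] = wrap(log_step),
                                   _["potential"] = wrap(log_pot),
                                   _["temperature"] = wrap(log_temp)),
      _["aborted"] = aborted, _["abort_step"] = (double)abort_step,
      _["abort_max_force"] = abort_maxf);
}

// Energy of a single configuration, decomposed by term (bond, ah, dh).
// [[Rcpp::export]]
NumericVector config_energy_cpp(NumericMatrix xyz, NumericVector sigma,
                                NumericVector lambda, NumericVector charge,
                                double kappa, double coulomb_pref, double eps,
                                double cutoff, double lb, double kbond) {
  const int n = xyz.nrow();
  const double rc2 = cutoff * cutoff;
  double ub = 0.0, uah = 0.0, udh = 0.0;
  for (int i = 0; i + 1 < n; ++i) {
    double dx = xyz(i + 1, 0) - xyz(i, 0), dy = xyz(i + 1, 1) - xyz(i, 1),
           dz = xyz(i + 1, 2) - xyz(i, 2);
    double r = std::sqrt(dx * dx + dy * dy + dz * dz);
    ub += 0.5 * kbond * (r - lb) * (r - lb);
  }
  for (int i = 0; i < n; ++i)
    for (int j = i + 2; j < n; ++j) {
      double dx = xyz(i, 0) - xyz(j, 0), dy = xyz(i, 1) - xyz(j, 1),
             dz = xyz(i, 2) - xyz(j, 2);
      double r2 = dx * dx + dy * dy + dz * dz;
      if (r2 >= rc2) continue;
      double sij = 0.5 * (sigma[i] + sigma[j]),
             lij = 0.5 * (lambda[i] + lambda[j]);
      double s2 = sij * sij / r2, s6 = s2 * s2 * s2;
      double lj = 4.0 * eps * (s6 * s6 - s6);
      double s6c = std::pow(sij * sij / rc2, 3.0);
      double shift = lij * 4.0 * eps * (s6c * s6c - s6c);
      uah += ((r2 <= std::cbrt(2.0) * sij * sij)
                  ? lj + (1.0 - lij) * eps
                  : lij * lj) - shift;
      double qq = charge[i] * charge[j] * coulomb_pref;
      if (qq != 0.0) {
        double r = std::sqrt(r2);
        udh += qq * (std::exp(-kappa * r) / r -
                     std::exp(-kappa * cutoff) / cutoff);
      }
    }
  return NumericVector::create(_["bond"] = ub, _["ah"] = uah, _["dh"] = udh,
                               _["total"] = ub + uah + udh);
}
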