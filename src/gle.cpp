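// Compiled core: GLE integrator with exact Markovian embedding of
// exponential memory-kernel components, online first-passage accumulation,
// an Ornstein-Uhlenbeck noise-stream generator, and an independent
// Markovian Langevin (BAOAB) reference integrator.

#include <Rcpp.h>
#include <cstdint>
#include <cmath>
#include <vector>

using namespace Rcpp;

// ---------------------------------------------------------------------------
// RNG: xoshiro256++ seeded via splitmix64, Box-Muller normals.
// Platform-independent determinism for a given 32-bit seed; R's RNG is kept
// for R-level draws only so compiled chunks never perturb the user's stream.
// ---------------------------------------------------------------------------

// Ziggurat tables for the standard normal (Marsaglia & Tsang layout,
// 128 layers), built once at load time; exact rejection sampling.
struct ZigTables {
  uint32_t kn[128];
  double wn[128], fn[128];
  ZigTables() {
    const double m1 = 2147483648.0;  // 2^31
    const double vn = 9.91256303526217e-3;
    double dn = 3.442619855899, tn = dn;
    double q = vn / std::exp(-0.5 * dn * dn);
    kn[0] = static_cast<uint32_t>((dn / q) * m1);
    kn[1] = 0;
    wn[0] = q / m1;
    wn[127] = dn / m1;
    fn[0] = 1.0;
    fn[127] = std::exp(-0.5 * dn * dn);
    for (int i = 126; i >= 1; --i) {
      dn = std::sqrt(-2.0 * std::log(vn / dn + std::exp(-0.5 * dn * dn)));
      kn[i + 1] = static_cast<uint32_t>((dn / tn) * m1);
      tn = dn;
      fn[i] = std::exp(-0.5 * dn * dn);
      wn[i] = dn / m1;
    }
  }
};
static const ZigTables zigt;

struct Xoshiro {
  uint64_t s[4];
  bool has_spare;
  double spare;

  explicit Xoshiro(uint64_t seed) : has_spare(false), spare(0.0) {
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

  // uniform on (0, 1), never exactly 0 so log() below is safe
  inline double unif() {
    return ((next() >> 11) + 0.5) * (1.0 / 9007199254740992.0);
  }

  // ziggurat normal: one 32-bit draw + table compare on the fast path
  inline double normal() {
    for (;;) {
      const int32_t hz = static_cast<int32_t>(next() >> 32);
      const uint32_t iz = static_cast<uint32_t>(hz) & 127u;
      const uint32_t ahz = hz < 0 ? static_cast<uint32_t>(-(int64_t)hz)
                                  : static_cast<uint32_t>(hz);
      if (ahz < zigt.kn[iz]) return hz * zigt.wn[iz];
      const double r = 3.442619855899;
      if (iz == 0) {  // tail
        double x, y;
        do {
          x = -std::log(unif()) / r;
          y = -std::log(unif());
        } while (y + y < x * x);
        return hz > 0 ? r + x : -(r + x);
      }
      const double x = hz * zigt.wn[iz];
      if (zigt.fn[iz] + unif() * (zigt.fn[iz - 1] - zigt.fn[iz]) <
          std::exp(-0.5 * x * x))
        return x;
    }
  }
};

// ---------------------------------------------------------------------------
// Potentials.  pot_type: 0 = free, 1 = harmonic (par: K),
// 2 = asymmetric piecewise-quartic double well (par: U_L, U_R, L_L, L_R).
// ---------------------------------------------------------------------------

static inline double pot_force(int pot_type, const double *p, double x) {
  if (pot_type == 0) return 0.0;
  if (pot_type == 1) return -p[0] * x;
  // double well: -4 (U_s / L_s^2) x [(x/L_s)^2 - 1], side chosen by sign of x
  double U, L;
  if (x <= 0.0) {
    U = p[0];
    L = p[2];
  } else {
    U = p[1];
    L = p[3];
  }
  const double q = (x / L) * (x / L) - 1.0;
  return -4.0 * (U / (L * L)) * x * q;
}

static inline double pot_energy(int pot_type, const double *p, double x) {
  if (pot_type == 0) return 0.0;
  if (pot_type == 1) return 0.5 * p[0] * x * x;
  double U, L, off;
  if (x <= 0.0) {
    U = p[0];
    L = p[2];
    off = 0.0;
  } else {
    U = p[1];
    L = p[3];
    off = p[0] - p[1];
  }
  const double q = (x / L) * (x / L) - 1.0;
  return U * q * q + off;
}

// ---------------------------------------------------------------------------
// Online all-to-first-passage accumulator for one (start, target) level pair.
// Every crossing of the start level opens a pending passage; the next
// crossing of the target level closes all pending passages at once (they
// share that arrival, which is why durations are grouped per arrival for
// block-bootstrap error estimation).  Only group sufficient statistics
// (count, duration sum, arrival time) are kept so memory stays O(#arrivals).
// ---------------------------------------------------------------------------

struct PairAcc {
  double start_level;
  double target_level;
  long long pending_n;
  double pending_tsum;
  std::vector<double> grp_n;
  std::vector<double> grp_sum;
  std::vector<double> grp_time;

  PairAcc(double s, double t)
    : start_level(s), target_level(t), pending_n(0), pending_tsum(0.0) {}

  inline void on_start(double tc) {
    pending_n += 1;
    pending_tsum += tc;
  }

  inline void on_target(double tc) {
    if (pending_n > 0) {
      grp_n.push_back(static_cast<double>(pending_n));
      grp_sum.push_back(static_cast<double>(pending_n) * tc - pending_tsum);
      grp_time.push_back(tc);
      pending_n = 0;
      pending_tsum = 0.0;
    }
  }

  // Process one integration step x_a -> x_b over [ta, ta + dt].
  inline void step(double x_a, double x_b, double ta, double dt) {
    double ts = -1.0, tt = -1.0;
    if ((x_a - start_level) * (x_b - start_level) < 0.0)
      ts = ta + dt * (start_level - x_a) / (x_b - x_a);
    if ((x_a - target_level) * (x_b - target_level) < 0.0)
      tt = ta + dt * (target_level - x_a) / (x_b - x_a);
    if (ts >= 0.0 && tt >= 0.0) {
      if (ts <= tt) {
        on_start(ts);
        on_target(tt);
      } else {
        on_target(tt);
        on_start(ts);
      }
    } else if (ts >= 0.0) {
      on_start(ts);
    } else if (tt >= 0.0) {
      on_target(tt);
    }
  }
};

static List pairs_to_list(const std::vector<PairAcc> &accs) {
  List out(accs.size());
  for (size_t i = 0; i < accs.size(); ++i) {
    out[i] = List::create(
      _["start"] = accs[i].start_level,
      _["target"] = accs[i].target_level,
      _["n"] = NumericVector(accs[i].grp_n.begin(), accs[i].grp_n.end()),
      _["sum"] = NumericVector(accs[i].grp_sum.begin(), accs[i].grp_sum.end()),
      _["arrival_time"] =
        NumericVector(accs[i].grp_time.begin(), accs[i].grp_time.end()),
      // open passages at the end of the run: carried across chunked calls
      // so waits longer than one chunk are never clipped
      _["pending_n"] = static_cast<double>(accs[i].pending_n),
      _["pending_tsum"] = accs[i].pending_tsum);
  }
  return out;
}

// ---------------------------------------------------------------------------
// GLE integrator.
//
// Equilibrium (neq = false): each exponential kernel component i carries an
// auxiliary force variable z_i with
//   z_i(t) = -int_0^t (gamma_i/tau_i) e^{-(t-s)/tau_i} v(s) ds + OU noise,
// updated exactly over dt (exponential decay + exactly integrated Gaussian
// increment) while the velocity is held at its mid-step value, embedded in a
// velocity-Verlet splitting.  The stationary OU part reproduces the
// fluctuation-dissipation relation <F_R(t)F_R(t')> = Gamma(t - t')/beta per
// component.
//
// Non-equilibrium (neq = true): the friction is carried by a deterministic
// auxiliary variable with decay tau_V and the random force by an independent
// stationary OU process eta with autocorrelation (gamma/(beta tau_R))
// e^{-|dt|/tau_R}; tau_V = tau_R recovers the equilibrium scheme in
// distribution.
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
List gle_simulate_cpp(int pot_type, NumericVector pot_par, double mass,
                      double beta, double dt, double n_steps_d,
                      double burn_in_d, double stride_d, double x0, double v0,
                      NumericVector z0, double eta0, NumericVector gammas,
                      NumericVector taus, bool neq, double tau_V, double tau_R,
                      NumericMatrix pairs, bool record_velocity, bool noise_on,
                      double seed_d, double t_offset,
                      NumericVector pending_n0, NumericVector pending_tsum0) {
  const long long n_steps = static_cast<long long>(n_steps_d);
  const long long burn_in = static_cast<long long>(burn_in_d);
  const long long stride = static_cast<long long>(stride_d);
  const int n_comp = gammas.size();

  std::vector<double> par(pot_par.begin(), pot_par.end());
  par.resize(4, 0.0);
  const double *pp = par.data();

  Xoshiro rng(static_cast<uint64_t>(seed_d));

  // precomputed per-component update coefficients
  std::vector<double> th(n_comp), fr(n_comp), sg(n_comp), z(n_comp);
  double gamma_tot = 0.0;
  for (int i = 0; i < n_comp; ++i) gamma_tot += gammas[i];
  if (!neq) {
    for (int i = 0; i < n_comp; ++i) {
      th[i] = std::exp(-dt / taus[i]);
      fr[i] = (1.0 - th[i]) * gammas[i];
      sg[i] = noise_on
                ? std::sqrt((1.0 - th[i] * th[i]) * gammas[i] / (beta * taus[i]))
                : 0.0;
      z[i] = z0[i];
    }
  } else {
    th[0] = std::exp(-dt / tau_V);
    fr[0] = (1.0 - th[0]) * gamma_tot;
    sg[0] = 0.0;  // friction channel is deterministic
    z[0] = z0[0];
  }
  const double th_R = neq ? std::exp(-dt / tau_R) : 0.0;
  const double sg_R =
    (neq && noise_on)
      ? std::sqrt((1.0 - th_R * th_R) * gamma_tot / (beta * tau_R))
      : 0.0;
  double eta = neq ? eta0 : 0.0;

  std::vector<PairAcc> accs;
  for (int i = 0; i < pairs.nrow(); ++i) {
    PairAcc acc(pairs(i, 0), pairs(i, 1));
    if (pending_n0.size() == pairs.nrow()) {
      acc.pending_n = static_cast<long long>(pending_n0[i]);
      acc.pending_tsum = pending_tsum0[i];
    }
    accs.push_back(acc);
  }
  const bool track = !accs.empty();

  long long n_rec = 0;
  if (stride > 0 && n_steps > burn_in) n_rec = (n_steps - burn_in) / stride;
  NumericVector xs(static_cast<R_xlen_t>(n_rec));
  NumericVector vs(record_velocity ? static_cast<R_xlen_t>(n_rec) : 0);

  double x = x0, v = v0;
  double S = eta;
  for (int i = 0; i < (neq ? 1 : n_comp); ++i) S += z[i];
  double F = pot_force(pot_type, pp, x);
  const double hdt_m = 0.5 * dt / mass;

  long long irec = 0;
  for (long long s = 0; s < n_steps; ++s) {
    const double vh = v + hdt_m * (F + S);
    const double x_new = x + dt * vh;

    if (neq) {
      z[0] = th[0] * z[0] - fr[0] * vh;
      eta = th_R * eta + sg_R * rng.normal();
      S = z[0] + eta;
    } else {
      S = 0.0;
      for (int i = 0; i < n_comp; ++i) {
        z[i] = th[i] * z[i] - fr[i] * vh + sg[i] * rng.normal();
        S += z[i];
      }
    }
    F = pot_force(pot_type, pp, x_new);
    v = vh + hdt_m * (F + S);

    if (track && s >= burn_in)
      for (size_t k = 0; k < accs.size(); ++k)
        accs[k].step(x, x_new, t_offset + s * dt, dt);
    x = x_new;

    if (s >= burn_in && ((s - burn_in + 1) % stride == 0) && irec < n_rec) {
      xs[irec] = x;
      if (record_velocity) vs[irec] = v;
      ++irec;
    }

    if ((s & 0xFFFFFLL) == 0 && !std::isfinite(x + v)) break;
  }

  if (!std::isfinite(x) || !std::isfinite(v)) {
    stop("GLE integration diverged (non-finite state): the timestep violates "
         "the stability contract dt <= 0.1 * min(tau_m, min tau_i, "
         "sqrt(m / K_max)); reduce dt or check parameter scales.");
  }

  NumericVector zfin(neq ? 1 : n_comp);
  for (int i = 0; i < (neq ? 1 : n_comp); ++i) zfin[i] = z[i];

  return List::create(
    _["positions"] = xs, _["velocities"] = vs,
    _["x"] = x, _["v"] = v, _["z"] = zfin, _["eta"] = eta,
    _["t_end"] = t_offset + static_cast<double>(n_steps) * dt,
    _["pairs"] = pairs_to_list(accs));
}

// ---------------------------------------------------------------------------
// Stationary coloured-noise stream: sum of independent OU components with
// autocorrelation sum_i (gamma_i/(beta tau_i)) e^{-|dt|/tau_i}, i.e. the
// random force consistent with the fluctuation-dissipation relation for the
// (multi-)exponential kernel.  Used to test realized noise statistics.
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
NumericVector noise_stream_cpp(NumericVector gammas, NumericVector taus,
                               double beta, double dt, double n_d,
                               double seed_d) {
  const long long n = static_cast<long long>(n_d);
  const int n_comp = gammas.size();
  Xoshiro rng(static_cast<uint64_t>(seed_d));

  std::vector<double> th(n_comp), sg(n_comp), sd0(n_comp), z(n_comp);
  for (int i = 0; i < n_comp; ++i) {
    th[i] = std::exp(-dt / taus[i]);
    sd0[i] = std::sqrt(gammas[i] / (beta * taus[i]));
    sg[i] = std::sqrt((1.0 - th[i] * th[i])) * sd0[i];
    z[i] = sd0[i] * rng.normal();
  }

  NumericVector out(static_cast<R_xlen_t>(n));
  for (long long s = 0; s < n; ++s) {
    double tot = 0.0;
    for (int i = 0; i < n_comp; ++i) {
      z[i] = th[i] * z[i] + sg[i] * rng.normal();
      tot += z[i];
    }
    out[s] = tot;
  }
  return out;
}

// ---------------------------------------------------------------------------
// Independent Markovian reference: underdamped Langevin BAOAB integrator
// with memoryless friction gamma.  Serves as the tau -> 0 oracle for the
// GLE engine; shares only the potential/RNG utilities, not the propagation
// scheme.
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
List langevin_simulate_cpp(int pot_type, NumericVector pot_par, double mass,
                           double beta, double gamma, double dt,
                           double n_steps_d, double burn_in_d, double stride_d,
                           double x0, double v0, NumericMatrix pairs,
                           bool record_velocity, double seed_d) {
  const long long n_steps = static_cast<long long>(n_steps_d);
  const long long burn_in = static_cast<long long>(burn_in_d);
  const long long stride = static_cast<long long>(stride_d);

  std::vector<double> par(pot_par.begin(), pot_par.end());
  par.resize(4, 0.0);
  const double *pp = par.data();

  Xoshiro rng(static_cast<uint64_t>(seed_d));
  const double c1 = std::exp(-gamma * dt / mass);
  const double c2 = std::sqrt((1.0 - c1 * c1) / (beta * mass));

  std::vector<PairAcc> accs;
  for (int i = 0; i < pairs.nrow(); ++i)
    accs.push_back(PairAcc(pairs(i, 0), pairs(i, 1)));
  const bool track = !accs.empty();

  long long n_rec = 0;
  if (stride > 0 && n_steps > burn_in) n_rec = (n_steps - burn_in) / stride;
  NumericVector xs(static_cast<R_xlen_t>(n_rec));
  NumericVector vs(record_velocity ? static_cast<R_xlen_t>(n_rec) : 0);

  double x = x0, v = v0;
  double F = pot_force(pot_type, pp, x);
  const double hdt_m = 0.5 * dt / mass;
  long long irec = 0;

  for (long long s = 0; s < n_steps; ++s) {
    const double x_old = x;
    v += hdt_m * F;
    x += 0.5 * dt * v;
    v = c1 * v + c2 * rng.normal();
    x += 0.5 * dt * v;
    F = pot_force(pot_type, pp, x);
    v += hdt_m * F;

    if (track && s >= burn_in)
      for (size_t k = 0; k < accs.size(); ++k)
        accs[k].step(x_old, x, s * dt, dt);

    if (s >= burn_in && ((s - burn_in + 1) % stride == 0) && irec < n_rec) {
      xs[irec] = x;
      if (record_velocity) vs[irec] = v;
      ++irec;
    }
  }

  if (!std::isfinite(x) || !std::isfinite(v))
    stop("Langevin integration diverged (non-finite state); reduce dt.");

  return List::create(
    _["positions"] = xs, _["velocities"] = vs, _["x"] = x, _["v"] = v,
    _["pairs"] = pairs_to_list(accs));
}

// [[Rcpp::export]]
NumericVector potential_energy_cpp(int pot_type, NumericVector pot_par,
                                   NumericVector x) {
  std::vector<double> par(pot_par.begin(), pot_par.end());
  par.resize(4, 0.0);
  NumericVector out(x.size());
  for (R_xlen_t i = 0; i < x.size(); ++i)
    out[i] = pot_energy(pot_type, par.data(), x[i]);
  return out;
}
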