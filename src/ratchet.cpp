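// Compiled core of the flashing-ratchet simulator.
//
// All stochastic dynamics are overdamped Langevin (Euler-Maruyama):
//   x' = x + (F/gamma) dt + sqrt(2 kBT dt / gamma) * N(0,1)
// The jump process is a per-step Bernoulli flip with probability rate*dt
// (the rates depend continuously on the diffusing position, which is why a
// Gillespie scheme is not used); accuracy requires rate*dt <= 0.01,
// enforced on the R side.
//
// RNG: xoshiro256++ seeded via splitmix64 from a single integer, so every
// run is reproducible from its seed independently of R's global RNG state.

#include <Rcpp.h>
#include <cmath>
#include <cstdint>
#include <vector>

using namespace Rcpp;

namespace {

struct Xoshiro {
  uint64_t s[4];
  bool has_spare;
  double spare;

  explicit Xoshiro(uint64_t seed_val) { seed(seed_val); }

  void seed(uint64_t x) {
    // splitmix64 expansion of the seed
    for (int i = 0; i < 4; ++i) {
      x += 0x9E3779B97f4A7C15ULL;
      uint64_t z = x;
      z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
      z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
      s[i] = z ^ (z >> 31);
    }
    has_spare = false;
    spare = 0.0;
  }

  static inline uint64_t rotl(uint64_t x, int k) {
    return (x << k) | (x >> (64 - k));
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

  inline double unif() {  // in [0, 1)
    return (next() >> 11) * 0x1.0p-53;
  }

  inline double norm() {  // Marsaglia polar method with spare caching
    if (has_spare) {
      has_spare = false;
      return spare;
    }
    double u, v, s2;
    do {
      u = 2.0 * unif() - 1.0;
      v = 2.0 * unif() - 1.0;
      s2 = u * u + v * v;
    } while (s2 >= 1.0 || s2 == 0.0);
    const double f = std::sqrt(-2.0 * std::log(s2) / s2);
    spare = v * f;
    has_spare = true;
    return u * f;
  }
};

// Piecewise-linear potential over one period [0, L], breakpoints inclusive
// of both endpoints (energy identical at 0 and L).
struct PiecePot {
  std::vector<double> bx, be, slope;
  double L;
  int nseg;

  PiecePot(const NumericVector& x, const NumericVector& e, double period)
      : bx(x.begin(), x.end()), be(e.begin(), e.end()), L(period) {
    nseg = static_cast<int>(bx.size()) - 1;
    slope.resize(nseg);
    for (int i = 0; i < nseg; ++i) {
      slope[i] = (be[i + 1] - be[i]) / (bx[i + 1] - bx[i]);
    }
  }

  inline double reduce(double x) const {
    double r = x - L * std::floor(x / L);
    if (r >= L) r -= L;
    return r;
  }

  inline int seg(double r) const {
    // forward-side segment at breakpoints (tie-break): segment i covers
    // [bx[i], bx[i+1])
    int lo = 0;
    for (int j = 1; j <= nseg; ++j) {
      if (r < bx[j]) { lo = j - 1; break; }
      lo = nseg - 1;
    }
    return lo;
  }

  inline double force(double x) const { return -slope[seg(reduce(x))]; }

  inline double energy(double x) const {
    const double r = reduce(x);
    const int i = seg(r);
    return be[i] + slope[i] * (r - bx[i]);
  }
};

inline double elastic_f(double s, double kp, double km) {
  return (s > 0 ? kp : km) * s;
}

inline double elastic_e(double s, double kp, double km) {
  return 0.5 * (s > 0 ? kp : km) * s * s;
}

}  // namespace

// First-passage times of a particle in a (non-periodic) piecewise-linear
// potential defined by breakpoints over [a, b]: start at x0, absorb at b
// and, unless reflect_a, also at a. Crossing detection uses the Brownian
// bridge between consecutive Euler points (crossing probability
// exp(-2 (b-x)(b-x') / sigma^2)), which removes the leading
// O(sqrt(dt)) bias of naive post-step threshold checks. Returns the vector
// of passage times.
// [[Rcpp::export]]
NumericVector cpp_first_passage(NumericVector bx, NumericVector be,
                                double a, double b, double x0,
                                bool reflect_a,
                                int n_escapes, double gamma_head, double kBT,
                                double dt, double max_steps, int seed,
                                bool bridge = true) {
  const int nseg = static_cast<int>(bx.size()) - 1;
  if (nseg < 1 || nseg > 30) stop("cpp_first_passage: 1..30 segments supported");
  double BX[32], DRIFT[32];
  const double mob = dt / gamma_head;
  for (int i = 0; i <= nseg; ++i) BX[i] = bx[i];
  for (int i = 0; i < nseg; ++i) {
    DRIFT[i] = -(be[i + 1] - be[i]) / (bx[i + 1] - bx[i]) * mob;
  }
  const double sig2 = 2.0 * kBT * dt / gamma_head;
  const double sig = std::sqrt(sig2);
  const double near = 5.0 * sig;  // bridge correction only near a boundary
  const long long max_n = static_cast<long long>(max_steps);
  Xoshiro rng(static_cast<uint64_t>(seed) * 0x9E3779B97f4A7C15ULL + 1ULL);

  NumericVector out(n_escapes);
  for (int e = 0; e < n_escapes; ++e) {
    double x = x0;
    long long steps = 0;
    for (;;) {
      int i = nseg - 1;
      for (int j = 1; j < nseg; ++j) {
        if (x < BX[j]) { i = j - 1; break; }
      }
      double xn = x + DRIFT[i] + sig * rng.norm();
      ++steps;
      if (xn >= b) break;
      if (xn <= a && !reflect_a) break;
      if (bridge) {
        if (b - xn < near && b - x < near &&
            rng.unif() < std::exp(-2.0 * (b - x) * (b - xn) / sig2)) {
          break;
        }
        if (!reflect_a && xn - a < near && x - a < near &&
            rng.unif() < std::exp(-2.0 * (x - a) * (xn - a) / sig2)) {
          break;
        }
      }
      if (reflect_a && xn < a) xn = 2.0 * a - xn;
      x = xn;
      if (steps >= max_n) {
        stop("cpp_first_passage: escape %d exceeded max_steps", e + 1);
      }
    }
    out[e] = steps * dt;
  }
  return out;
}

// Half-sarcomere ensemble (also used with N = 1 as the single-motor
// engine). Backbone coordinate Zb increases in the shortening direction;
// strain of head i is s_i = x_i - Zb - c_i and the reported tension is
// sum(elastic force). mode 0: Zb prescribed (constant, or a linear ramp of
// amplitude ramp_dZ starting at ramp_t0 lasting ramp_dur). mode 1: force
// clamp, Gb * dZb/dt = tension - F_load (backbone thermal noise omitted:
// its variance is suppressed by the huge backbone drag).
// jump_model: 0 none, 1 Huxley search-and-catch rates, 2 equilibrium
// (detailed-balance Metropolis rates with attempt frequency f1).
// [[Rcpp::export]]
List cpp_simulate_ensemble(NumericVector bx, NumericVector be, double L,
                           double allowed_end, double d_spacing, int n_bind,
                           double kp, double km,
                           double f1, double g1, double g2, double rate_scale,
                           double attach_window,
                           double gamma_head, double kBT, double Gb,
                           double dt, double n_steps_d, int stride,
                           int mode, double F_load,
                           double ramp_t0, double ramp_dur, double ramp_dZ,
                           int jump_model, bool freeze_heads,
                           double Fext_head,
                           double Z0, NumericVector x_init,
                           IntegerVector psi_init, NumericVector c_off,
                           IntegerVector atp_init,
                           int seed, bool record_x) {
  PiecePot pot(bx, be, L);
  const int N = x_init.size();
  const long long n_steps = static_cast<long long>(n_steps_d);
  const double sig = std::sqrt(2.0 * kBT * dt / gamma_head);
  const double mob = dt / gamma_head;
  const double f1s = f1 * rate_scale, g1s = g1 * rate_scale,
               g2s = g2 * rate_scale;
  Xoshiro rng(static_cast<uint64_t>(seed) * 0x9E3779B97f4A7C15ULL + 2ULL);

  std::vector<double> x(x_init.begin(), x_init.end());
  std::vector<int> psi(psi_init.begin(), psi_init.end());
  std::vector<double> c(c_off.begin(), c_off.end());
  std::vector<long long> atp(N);
  for (int i = 0; i < N; ++i) atp[i] = atp_init[i];
  double Zb = Z0;

  const long long n_rec = n_steps / stride + 1;
  NumericVector rec_t(n_rec), rec_Z(n_rec), rec_T(n_rec);
  IntegerVector rec_na(n_rec), rec_ns(n_rec), rec_atp(n_rec);
  IntegerMatrix rec_occ(n_rec, n_bind);
  NumericMatrix rec_x;
  IntegerMatrix rec_psi;
  if (record_x) {
    rec_x = NumericMatrix(n_rec, N);
    rec_psi = IntegerMatrix(n_rec, N);
  }

  std::vector<double> ev_t, ev_x, ev_Eb, ev_Ea;
  std::vector<int> ev_motor, ev_kind;  // kind: 1 attach, 2 detach

  const double half_d = 0.5 * d_spacing;
  long long rec_i = 0;

  auto record = [&](double t) {
    double tension = 0.0;
    int na = 0, ns = 0;
    std::vector<int> occ(n_bind, 0);
    for (int i = 0; i < N; ++i) {
      const double s = x[i] - Zb - c[i];
      tension += elastic_f(s, kp, km);
      if (psi[i]) {
        ++na;
        if (s > 0) ++ns;
        // nearest permitted minimum in the actin frame
        const double r = pot.reduce(x[i]);
        int k;
        if (r < allowed_end - half_d) {
          k = static_cast<int>(std::floor(r / d_spacing + 0.5));
        } else if (r > L - half_d) {
          k = 0;
        } else {
          k = n_bind - 1;
        }
        if (k < 0) k = 0;
        if (k >= n_bind) k = n_bind - 1;
        ++occ[k];
      }
    }
    long long atp_tot = 0;
    for (int i = 0; i < N; ++i) atp_tot += atp[i];
    rec_t[rec_i] = t;
    rec_Z[rec_i] = Zb;
    rec_T[rec_i] = tension;
    rec_na[rec_i] = na;
    rec_ns[rec_i] = ns;
    rec_atp[rec_i] = static_cast<int>(atp_tot);
    for (int k = 0; k < n_bind; ++k) rec_occ(rec_i, k) = occ[k];
    if (record_x) {
      for (int i = 0; i < N; ++i) {
        rec_x(rec_i, i) = x[i];
        rec_psi(rec_i, i) = psi[i];
      }
    }
    ++rec_i;
  };

  record(0.0);

  for (long long step = 0; step < n_steps; ++step) {
    const double t = step * dt;
    double tension = 0.0;

    for (int i = 0; i < N; ++i) {
      const double s = x[i] - Zb - c[i];

      // jump process (rates evaluated at the pre-move state)
      if (jump_model != 0) {
        double rate = 0.0;
        if (jump_model == 1) {
          if (psi[i]) {
            rate = (s <= 0) ? g2s
                            : g1s * std::min(s / attach_window, 1.0);
          } else {
            if (s > 0 && s <= attach_window &&
                pot.reduce(x[i]) < allowed_end) {
              rate = f1s;
            }
          }
        } else {  // equilibrium / detailed balance
          const double u = pot.energy(x[i]) / kBT;
          rate = psi[i] ? f1s * std::min(1.0, std::exp(u))
                        : f1s * std::min(1.0, std::exp(-u));
        }
        if (rate > 0.0 && rng.unif() < rate * dt) {
          const double Eel = elastic_e(s, kp, km);
          const double U = pot.energy(x[i]);
          if (psi[i]) {  // detach, one ATP consumed
            psi[i] = 0;
            ++atp[i];
            ev_t.push_back(t);
            ev_motor.push_back(i + 1);
            ev_kind.push_back(2);
            ev_x.push_back(x[i]);
            ev_Eb.push_back(Eel + U);
            ev_Ea.push_back(Eel);
          } else {  // attach
            psi[i] = 1;
            ev_t.push_back(t);
            ev_motor.push_back(i + 1);
            ev_kind.push_back(1);
            ev_x.push_back(x[i]);
            ev_Eb.push_back(Eel);
            ev_Ea.push_back(Eel + U);
          }
        }
      }

      const double Fel = -elastic_f(s, kp, km);  // on the head
      double F = Fel + Fext_head;
      if (psi[i]) F += pot.force(x[i]);
      if (!freeze_heads) x[i] += F * mob + sig * rng.norm();

      tension += elastic_f(x[i] - Zb - c[i], kp, km);
    }

    // backbone update
    if (mode == 1) {
      Zb += (tension - F_load) * dt / Gb;
    } else if (ramp_dur > 0.0 && t >= ramp_t0) {
      const double frac = std::min((t + dt - ramp_t0) / ramp_dur, 1.0);
      Zb = Z0 + ramp_dZ * frac;
    }

    if ((step + 1) % stride == 0) record((step + 1) * dt);
  }

  IntegerVector atp_out(N);
  for (int i = 0; i < N; ++i) atp_out[i] = static_cast<int>(atp[i]);

  List trace = List::create(
      _["t_s"] = rec_t, _["Zb_nm"] = rec_Z, _["tension_pN"] = rec_T,
      _["n_attached"] = rec_na, _["n_stretched"] = rec_ns,
      _["atp_cum"] = rec_atp, _["occ"] = rec_occ);
  if (record_x) {
    trace["x"] = rec_x;
    trace["psi"] = rec_psi;
  }

  DataFrame events = DataFrame::create(
      _["t_s"] = NumericVector(ev_t.begin(), ev_t.end()),
      _["motor"] = IntegerVector(ev_motor.begin(), ev_motor.end()),
      _["kind"] = IntegerVector(ev_kind.begin(), ev_kind.end()),
      _["x_nm"] = NumericVector(ev_x.begin(), ev_x.end()),
      _["E_before"] = NumericVector(ev_Eb.begin(), ev_Eb.end()),
      _["E_after"] = NumericVector(ev_Ea.begin(), ev_Ea.end()));

  return List::create(_["trace"] = trace, _["events"] = events,
                      _["Z_final"] = Zb,
                      _["x_final"] = NumericVector(x.begin(), x.end()),
                      _["psi_final"] = IntegerVector(psi.begin(), psi.end()),
                      _["atp_final"] = atp_out);
}

// Single-molecule experiment: an always-attached head diffusing in the
// periodic potential, linked by a symmetric spring to a high-drag needle
// held by a trap; a constant external force can load the needle. The run
// terminates when the head is first assigned (within the hysteresis band)
// to a lowest minimum of a period, or at max_steps.
// [[Rcpp::export]]
List cpp_simulate_sme(NumericVector bx, NumericVector be, double L,
                      double d_spacing, int n_bind,
                      double gamma_head, double Gamma_needle, double kBT,
                      double kappa_link, double kappa_trap, double X0,
                      double F_ext,
                      double dt, double max_steps_d, int stride,
                      double hysteresis, double x_start,
                      int seed) {
  PiecePot pot(bx, be, L);
  const long long max_steps = static_cast<long long>(max_steps_d);
  const double sig_h = std::sqrt(2.0 * kBT * dt / gamma_head);
  const double sig_n = std::sqrt(2.0 * kBT * dt / Gamma_needle);
  const double mob_h = dt / gamma_head;
  const double mob_n = dt / Gamma_needle;
  Xoshiro rng(static_cast<uint64_t>(seed) * 0x9E3779B97f4A7C15ULL + 3ULL);

  double x = x_start, X = X0;

  // nearest-minimum assignment over the infinite lattice of permitted
  // minima (global index m = period * n_bind + local)
  auto nearest_min = [&](double xx, long long& m_out, double& pos_out) {
    const double p = std::floor(xx / L);
    const double r = xx - p * L;
    const double run_end = (n_bind - 1) * d_spacing;
    long long base = static_cast<long long>(p) * n_bind;
    int l;
    double pos;
    if (r <= run_end) {
      l = static_cast<int>(std::floor(r / d_spacing + 0.5));
      if (l > n_bind - 1) l = n_bind - 1;
      pos = p * L + l * d_spacing;
      m_out = base + l;
    } else {
      // between the last minimum of this period and minimum 0 of the next
      if (r - run_end <= L - r) {
        m_out = base + (n_bind - 1);
        pos = p * L + run_end;
      } else {
        m_out = base + n_bind;
        pos = (p + 1) * L;
      }
    }
    pos_out = pos;
  };

  long long cur_m;
  double cur_pos;
  nearest_min(x, cur_m, cur_pos);

  std::vector<double> rt, rx, rX;
  std::vector<double> jump_t;
  std::vector<int> jump_dir;
  rt.reserve(1024); rx.reserve(1024); rX.reserve(1024);

  bool completed = false;
  long long step = 0;
  rt.push_back(0.0); rx.push_back(x); rX.push_back(X);

  for (step = 0; step < max_steps; ++step) {
    const double spring = kappa_link * (x - X);
    const double Fh = pot.force(x) - spring;
    const double Fn = spring - kappa_trap * (X - X0) - F_ext;
    x += Fh * mob_h + sig_h * rng.norm();
    X += Fn * mob_n + sig_n * rng.norm();

    long long m;
    double pos;
    nearest_min(x, m, pos);
    if (m != cur_m && std::fabs(x - pos) <= hysteresis) {
      jump_t.push_back((step + 1) * dt);
      jump_dir.push_back(m > cur_m ? 1 : -1);
      cur_m = m;
      cur_pos = pos;
      // lowest minimum of a period reached -> stop
      long long l = ((cur_m % n_bind) + n_bind) % n_bind;
      if (l == n_bind - 1) {
        completed = true;
      }
    }
    if ((step + 1) % stride == 0 || completed || step + 1 == max_steps) {
      rt.push_back((step + 1) * dt);
      rx.push_back(x);
      rX.push_back(X);
    }
    if (completed) break;
  }

  int nf = 0, nb = 0;
  for (size_t j = 0; j < jump_dir.size(); ++j) {
    if (jump_dir[j] > 0) ++nf; else ++nb;
  }

  return List::create(
      _["t_s"] = NumericVector(rt.begin(), rt.end()),
      _["x_nm"] = NumericVector(rx.begin(), rx.end()),
      _["X_nm"] = NumericVector(rX.begin(), rX.end()),
      _["jump_t"] = NumericVector(jump_t.begin(), jump_t.end()),
      _["jump_dir"] = IntegerVector(jump_dir.begin(), jump_dir.end()),
      _["n_forward"] = nf, _["n_backward"] = nb,
      _["completed"] = completed,
      _["t_end"] = (completed ? (step + 1) * dt
                              : static_cast<double>(max_steps) * dt),
      _["x_final"] = x, _["X_final"] = X);
}
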