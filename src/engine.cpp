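// Compiled inner loop of the agent-based chemotaxis simulator.
//
// Each cell owns an independent PCG32 random stream derived from the master
// seed, consumed in a fixed order (3 initialisation draws in R, then per
// step: decision draw, and for tumbles sign and angle draws), so every
// trajectory is replayable and the pure-R reference engine can reproduce the
// compiled one draw for draw.

#include <Rcpp.h>
#include <cstdint>
#include <cmath>
using namespace Rcpp;

namespace {

inline uint64_t splitmix64(uint64_t x) {
  x += 0x9E3779B97F4A7C15ULL;
  x = (x ^ (x >> 30)) * 0xBF58476D1CE4E5B9ULL;
  x = (x ^ (x >> 27)) * 0x94D049BB133111EBULL;
  return x ^ (x >> 31);
}

// PCG32 (O'Neill): 64-bit state, stream selected by the increment
struct pcg32 {
  uint64_t state, inc;
  pcg32(uint64_t seed, uint64_t stream) {
    inc = (stream << 1u) | 1u;
    state = 0u;
    next();
    state += splitmix64(seed);
    next();
  }
  uint32_t next() {
    uint64_t old = state;
    state = old * 6364136223846793005ULL + inc;
    uint32_t xorshifted = static_cast<uint32_t>(((old >> 18u) ^ old) >> 27u);
    uint32_t rot = static_cast<uint32_t>(old >> 59u);
    return (xorshifted >> rot) | (xorshifted << ((32u - rot) & 31u));
  }
  double uniform() { return next() * (1.0 / 4294967296.0); }  // [0, 1)
};

struct cascade_p {
  double AT, BT, RT, YT, ZT;                    // beta-scaled totals (uM)
  double kA, ky, kb, kz, gY, gB, kR, kB_;       // rate constants
  double n, m_off, m_slope, m_min, m_max;       // receptor
};

inline void deriv(const double y[4], const cascade_p& p, double lig,
                  double dy[4]) {
  const double m = y[0], Ap = y[1], Bp = y[2], Yp = y[3];
  const double F = p.n * (p.m_off - p.m_slope * m + lig);
  const double phi = 1.0 / (1.0 + std::exp(F));
  double dm = p.kR * p.RT * (1.0 - phi) - p.kB_ * Bp * phi;
  if ((m <= p.m_min && dm < 0) || (m >= p.m_max && dm > 0)) dm = 0;
  dy[0] = dm;
  dy[1] = p.kA * phi * (p.AT - Ap) - p.ky * Ap * (p.YT - Yp)
        - p.kb * Ap * (p.BT - Bp);
  dy[2] = p.kb * Ap * (p.BT - Bp) - p.gB * Bp;
  dy[3] = p.ky * Ap * (p.YT - Yp) - p.kz * p.ZT * Yp - p.gY * Yp;
}

inline void clamp_state(double y[4], const cascade_p& p) {
  if (y[0] < p.m_min) y[0] = p.m_min;
  if (y[0] > p.m_max) y[0] = p.m_max;
  if (y[1] < 0) y[1] = 0;
  if (y[1] > p.AT) y[1] = p.AT;
  if (y[2] < 0) y[2] = 0;
  if (y[2] > p.BT) y[2] = p.BT;
  if (y[3] < 0) y[3] = 0;
  if (y[3] > p.YT) y[3] = p.YT;
}

// classic RK4 with n_sub fixed substeps, ligand terms frozen
inline void rk4(double y[4], const cascade_p& p, double lig, double dt,
                int n_sub) {
  const double h = dt / n_sub;
  double k1[4], k2[4], k3[4], k4[4], yt[4];
  for (int s = 0; s < n_sub; ++s) {
    deriv(y, p, lig, k1);
    for (int i = 0; i < 4; ++i) yt[i] = y[i] + 0.5 * h * k1[i];
    deriv(yt, p, lig, k2);
    for (int i = 0; i < 4; ++i) yt[i] = y[i] + 0.5 * h * k2[i];
    deriv(yt, p, lig, k3);
    for (int i = 0; i < 4; ++i) yt[i] = y[i] + h * k3[i];
    deriv(yt, p, lig, k4);
    for (int i = 0; i < 4; ++i)
      y[i] += h / 6.0 * (k1[i] + 2.0 * k2[i] + 2.0 * k3[i] + k4[i]);
    clamp_state(y, p);
  }
}

// per-species field: type 0 absent, 1 exponential (l0, d, cx, cy, scaling),
// 2 constant (level)
inline double field_value(const double* f, double x, double y) {
  const int type = static_cast<int>(f[0]);
  if (type == 0) return 0.0;
  if (type == 2) return f[1];
  const double dx = x - f[3], dy = y - f[4];
  return f[5] * (f[1] + std::exp(-(dx * dx + dy * dy) / f[2]));
}

inline double lig_terms(double ca, double cs, const double* rc) {
  // rc: tar_f, tsr_f, KoffA, KonA, KoffS, KonS
  double out = 0.0;
  if (ca > 0)
    out += rc[0] * std::log((1.0 + ca / rc[2]) / (1.0 + ca / rc[3]));
  if (cs > 0)
    out += rc[1] * std::log((1.0 + cs / rc[4]) / (1.0 + cs / rc[5]));
  return out;
}

// floor-based modulo, matching R's `%%` semantics (result in [0, y))
inline double pmod(double x, double y) {
  double w = x - std::floor(x / y) * y;
  if (w >= y) w -= y;   // guard against rounding at the boundary
  if (w < 0) w += y;
  return w;
}

inline double wrap_angle(double t) { return pmod(t, 2.0 * M_PI); }

}  // namespace

//' Deterministic per-stream uniform draws
//'
//' Draws from the counter-based random stream a simulated cell would use:
//' stream `stream` under master seed `seed`. Exposed so that the pure-R
//' reference engine (and tests) can consume exactly the same random numbers
//' as the compiled engine.
//'
//' @param seed Master seed (non-negative integer-valued scalar).
//' @param stream Stream identifier (0-based cell index).
//' @param n Number of draws.
//' @return Numeric vector of `n` uniforms in `[0, 1)`.
//' @export
// [[Rcpp::export]]
NumericVector rng_uniforms(double seed, double stream, int n) {
  pcg32 rng(static_cast<uint64_t>(seed), static_cast<uint64_t>(stream));
  NumericVector out(n);
  for (int i = 0; i < n; ++i) out[i] = rng.uniform();
  return out;
}

// [[Rcpp::export]]
List rt_simulate_cpp(int n_cells, int n_steps, double dt,
                     IntegerVector rec_steps,
                     NumericVector x0, NumericVector y0, NumericVector theta0,
                     NumericMatrix state0, NumericVector beta,
                     NumericVector ypstar, IntegerVector n_sub,
                     NumericVector totals0, NumericVector rates,
                     NumericVector receptor, NumericMatrix field,
                     double prefactor, double hill,
                     NumericVector speed, double turn_min_rad,
                     double turn_max_rad, int boundary, NumericVector domain,
                     double seed) {
  const int n_rec = rec_steps.size();
  NumericMatrix rec(static_cast<R_xlen_t>(n_rec) * n_cells, 9);
  NumericMatrix fin(n_cells, 7);

  const double fa[6] = {field(0, 0), field(0, 1), field(0, 2),
                        field(0, 3), field(0, 4), field(0, 5)};
  const double fs[6] = {field(1, 0), field(1, 1), field(1, 2),
                        field(1, 3), field(1, 4), field(1, 5)};
  const double rc[6] = {receptor[1], receptor[2], receptor[3],
                        receptor[4], receptor[5], receptor[6]};
  const double xmin = domain[0], xmax = domain[1];
  const double ymin = domain[2], ymax = domain[3];
  const double wx = xmax - xmin, wy = ymax - ymin;

  std::vector<cascade_p> par(n_cells);
  std::vector<pcg32> rng;
  rng.reserve(n_cells);
  for (int c = 0; c < n_cells; ++c) {
    cascade_p p;
    p.AT = beta[c] * totals0[0];
    p.BT = beta[c] * totals0[1];
    p.RT = beta[c] * totals0[2];
    p.YT = beta[c] * totals0[3];
    p.ZT = beta[c] * totals0[4];
    p.kA = rates[0]; p.ky = rates[1]; p.kb = rates[2]; p.kz = rates[3];
    p.gY = rates[4]; p.gB = rates[5]; p.kR = rates[6]; p.kB_ = rates[7];
    p.n = receptor[0]; p.m_off = receptor[7]; p.m_slope = receptor[8];
    p.m_min = receptor[9]; p.m_max = receptor[10];
    par[c] = p;
    rng.emplace_back(static_cast<uint64_t>(seed), static_cast<uint64_t>(c));
    for (int k = 0; k < 3; ++k) rng[c].uniform();  // initialisation draws
  }

  std::vector<double> x(x0.begin(), x0.end());
  std::vector<double> y(y0.begin(), y0.end());
  std::vector<double> th(theta0.begin(), theta0.end());
  std::vector<std::array<double, 4>> st(n_cells);
  for (int c = 0; c < n_cells; ++c)
    for (int i = 0; i < 4; ++i) st[c][i] = state0(c, i);

  int rec_i = 0;        // index into rec_steps
  R_xlen_t rec_row = 0;
  auto record = [&](int step, int c, double bias, double tumble) {
    rec(rec_row, 0) = step;
    rec(rec_row, 1) = c + 1;
    rec(rec_row, 2) = x[c];
    rec(rec_row, 3) = y[c];
    rec(rec_row, 4) = th[c];
    rec(rec_row, 5) = st[c][3];
    rec(rec_row, 6) = st[c][0];
    rec(rec_row, 7) = bias;
    rec(rec_row, 8) = tumble;
    ++rec_row;
  };

  if (n_rec > 0 && rec_steps[0] == 0) {
    for (int c = 0; c < n_cells; ++c) {
      const double Yp = st[c][3];
      const double bias = (Yp > 0)
        ? 1.0 / (1.0 + prefactor * std::pow(ypstar[c] / Yp, hill)) : 0.0;
      record(0, c, bias, NA_REAL);
    }
    ++rec_i;
  }

  for (int step = 1; step <= n_steps; ++step) {
    const bool do_rec = (rec_i < n_rec && rec_steps[rec_i] == step);
    for (int c = 0; c < n_cells; ++c) {
      // 1. ligand concentrations at the current location
      const double ca = field_value(fa, x[c], y[c]);
      const double cs = field_value(fs, x[c], y[c]);
      const double lig = lig_terms(ca, cs, rc);
      // 2. update the intracellular pathway over dt
      rk4(st[c].data(), par[c], lig, dt, n_sub[c]);
      // 3. flagellar rotational bias from the post-update CheY-P
      const double Yp = st[c][3];
      const double bias = (Yp > 0)
        ? 1.0 / (1.0 + prefactor * std::pow(ypstar[c] / Yp, hill)) : 0.0;
      // 4. run/tumble decision and movement
      const double u = rng[c].uniform();
      const bool tumble = bias > u;
      if (tumble) {
        const double us = rng[c].uniform();
        const double ua = rng[c].uniform();
        const double s = (us < 0.5) ? 1.0 : -1.0;
        const double turn = turn_min_rad + ua * (turn_max_rad - turn_min_rad);
        th[c] = wrap_angle(th[c] + s * turn);
      }
      x[c] += speed[c] * std::sin(th[c]) * dt;
      y[c] += speed[c] * std::cos(th[c]) * dt;
      // 5. boundary correction
      if (boundary == 0) {
        if (x[c] < xmin) x[c] = xmin;
        if (x[c] > xmax) x[c] = xmax;
        if (y[c] < ymin) y[c] = ymin;
        if (y[c] > ymax) y[c] = ymax;
      } else {
        x[c] = xmin + pmod(x[c] - xmin, wx);
        y[c] = ymin + pmod(y[c] - ymin, wy);
      }
      if (do_rec) record(step, c, bias, tumble ? 1.0 : 0.0);
    }
    if (do_rec) ++rec_i;
    if (step % 2048 == 0) Rcpp::checkUserInterrupt();
  }

  for (int c = 0; c < n_cells; ++c) {
    fin(c, 0) = x[c];
    fin(c, 1) = y[c];
    fin(c, 2) = th[c];
    fin(c, 3) = st[c][0];
    fin(c, 4) = st[c][1];
    fin(c, 5) = st[c][2];
    fin(c, 6) = st[c][3];
  }
  return List::create(_["records"] = rec, _["final"] = fin);
}
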