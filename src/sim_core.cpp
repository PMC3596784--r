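#include <Rcpp.h>
#include <cstdint>
#include <cmath>
#include <vector>

// Self-contained counter-seeded RNG (xoshiro256++ / splitmix64) so that each
// neuron owns an independent, platform-stable noise stream: a network with
// all-zero weights then reproduces, spike for spike, the union of independent
// single-neuron runs driven by the same streams.

namespace {

// Marsaglia-Tsang ziggurat tables for the standard normal (128 layers)
struct ZigTables {
  double wn[128], fn[128];
  uint32_t kn[128];
  ZigTables() {
    const double m1 = 2147483648.0;
    double dn = 3.442619855899, tn = dn;
    const double vn = 9.91256303526217e-3;
    double q = vn / std::exp(-0.5 * dn * dn);
    kn[0] = (uint32_t)((dn / q) * m1);
    kn[1] = 0;
    wn[0] = q / m1;
    wn[127] = dn / m1;
    fn[0] = 1.0;
    fn[127] = std::exp(-0.5 * dn * dn);
    for (int i = 126; i >= 1; i--) {
      dn = std::sqrt(-2.0 * std::log(vn / dn + std::exp(-0.5 * dn * dn)));
      kn[i + 1] = (uint32_t)((dn / tn) * m1);
      tn = dn;
      fn[i] = std::exp(-0.5 * dn * dn);
      wn[i] = dn / m1;
    }
  }
};

static const ZigTables zig;

struct Xoshiro {
  uint64_t s[4];

  static uint64_t splitmix64(uint64_t &x) {
    x += 0x9E3779B97f4A7C15ULL;
    uint64_t z = x;
    z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
    z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
    return z ^ (z >> 31);
  }

  void seed(uint64_t global_seed, uint64_t stream_id) {
    uint64_t x = global_seed * 0x9E3779B97f4A7C15ULL + stream_id + 1ULL;
    for (int i = 0; i < 4; ++i) s[i] = splitmix64(x);
  }

  static uint64_t rotl(uint64_t x, int k) { return (x << k) | (x >> (64 - k)); }

  uint64_t next() {
    uint64_t result = rotl(s[0] + s[3], 23) + s[0];
    uint64_t t = s[1] << 17;
    s[2] ^= s[0]; s[3] ^= s[1]; s[1] ^= s[2]; s[0] ^= s[3];
    s[2] ^= t;
    s[3] = rotl(s[3], 45);
    return result;
  }

  // uniform in [0, 1)
  double unif() { return (next() >> 11) * 0x1.0p-53; }

  // standard normal, Marsaglia-Tsang ziggurat
  double norm() {
    const double r = 3.442619855899;
    for (;;) {
      int32_t hz = (int32_t)(uint32_t)(next() >> 32);
      int iz = hz & 127;
      if ((uint32_t)std::abs(hz) < zig.kn[iz]) return hz * zig.wn[iz];
      if (iz == 0) {                       // base strip tail
        double x, y;
        do {
          x = -std::log(unif()) / r;
          y = -std::log(unif());
        } while (y + y < x * x);
        return hz > 0 ? r + x : -(r + x);
      }
      double x = hz * zig.wn[iz];
      if (zig.fn[iz] + unif() * (zig.fn[iz - 1] - zig.fn[iz]) <
          std::exp(-0.5 * x * x))
        return x;
    }
  }
};

} // namespace

using namespace Rcpp;

// One Euler pass over the pulse-coupled Izhikevich network.
//
// v' = 0.04 v^2 + 5 v + 140 - u + I_syn + I_noise
// u' = a (b v - u);  v >= v_peak  =>  v <- c, u <- u + d
// I_noise follows the Euler-Maruyama Ornstein-Uhlenbeck recursion.
// Pulses emitted by spikes at step k are added to postsynaptic v before the
// Euler update of step k+1 (no conduction delays).
//
// [[Rcpp::export]]
List sim_network_cpp(NumericVector a, NumericVector b, NumericVector c_,
                     NumericVector d, NumericMatrix S, double dt, int n_steps,
                     double t0, double v_peak, double tau_I, double m_I,
                     double s_I, double seed, IntegerVector stream_ids,
                     Nullable<NumericVector> v_init, Nullable<NumericVector> u_init,
                     Nullable<NumericVector> I_init, double guard,
                     bool record = true) {
  const int n = a.size();
  if (S.nrow() != n || S.ncol() != n)
    stop("weight matrix dimensions do not match the neuron count");
  if (tau_I <= 0) stop("tau_I must be positive");
  if (dt <= 0) stop("dt must be positive");

  std::vector<Xoshiro> rng(n);
  const uint64_t gseed = (uint64_t)((int64_t)seed);
  for (int i = 0; i < n; ++i) rng[i].seed(gseed, (uint64_t)stream_ids[i]);

  std::vector<double> v(n), u(n), I(n), syn(n, 0.0);
  if (v_init.isNotNull()) {
    NumericVector v0(v_init), u0(u_init), I0(I_init);
    for (int i = 0; i < n; ++i) { v[i] = v0[i]; u[i] = u0[i]; I[i] = I0[i]; }
  } else {
    // v ~ U on the interval between c and -60 mV, u = b v, I at the OU mean
    for (int i = 0; i < n; ++i) {
      double lo = std::min(c_[i], -60.0), hi = std::max(c_[i], -60.0);
      v[i] = lo + rng[i].unif() * (hi - lo);
      u[i] = b[i] * v[i];
      I[i] = m_I;
    }
  }

  const double drift = dt / tau_I;
  const double diff = s_I * std::sqrt(2.0 * dt / tau_I);
  const double *Sp = S.begin();

  std::vector<int> sp_neuron;
  std::vector<double> sp_time;
  std::vector<int> fired;
  fired.reserve(n);
  std::vector<int> last_fired;

  for (int k = 1; k <= n_steps; ++k) {
    const double t = t0 + k * dt;
    fired.clear();
    for (int i = 0; i < n; ++i) {
      // pulses emitted on the previous step arrive first
      double vi = v[i] + syn[i];
      I[i] += -I[i] * drift + m_I * drift + diff * rng[i].norm();
      if (vi >= v_peak) {
        // after-spike reset; the reset state holds for the rest of the step
        fired.push_back(i);
        v[i] = c_[i];
        u[i] += d[i];
        continue;
      }
      double vnew = vi + dt * (0.04 * vi * vi + 5.0 * vi + 140.0 - u[i] + I[i]);
      u[i] += dt * a[i] * (b[i] * vi - u[i]);
      v[i] = vnew;
      if (!std::isfinite(v[i]) || std::fabs(v[i]) > guard)
        stop("numerical divergence: neuron %d at t = %.4f ms", i + 1, t);
    }
    std::fill(syn.begin(), syn.end(), 0.0);
    for (size_t f = 0; f < fired.size(); ++f) {
      const int j = fired[f];
      const double *col = Sp + (size_t)j * n;
      for (int i = 0; i < n; ++i) syn[i] += col[i];
      if (record) { sp_neuron.push_back(j + 1); sp_time.push_back(t); }
    }
    if (k == n_steps) last_fired.assign(fired.begin(), fired.end());
    if (k % 200000 == 0) Rcpp::checkUserInterrupt();
  }

  IntegerVector lf(last_fired.size());
  for (size_t i = 0; i < last_fired.size(); ++i) lf[i] = last_fired[i] + 1;

  return List::create(
      _["neuron"] = IntegerVector(sp_neuron.begin(), sp_neuron.end()),
      _["time"] = NumericVector(sp_time.begin(), sp_time.end()),
      _["v"] = NumericVector(v.begin(), v.end()),
      _["u"] = NumericVector(u.begin(), u.end()),
      _["I_noise"] = NumericVector(I.begin(), I.end()),
      _["t"] = t0 + (double)n_steps * dt,
      _["fired"] = lf);
}

// Ornstein-Uhlenbeck iterates of the Euler-Maruyama recursion, for
// stationarity checks. Returns the full path (excluding the initial value).
// [[Rcpp::export]]
NumericVector ou_path_cpp(double I0, int n_steps, double dt, double tau_I,
                          double m_I, double s_I, double seed,
                          int stream_id = 0) {
  if (tau_I <= 0) stop("tau_I must be positive");
  Xoshiro r;
  r.seed((uint64_t)((int64_t)seed), (uint64_t)stream_id);
  NumericVector out(n_steps);
  double I = I0;
  const double drift = dt / tau_I;
  const double diff = s_I * std::sqrt(2.0 * dt / tau_I);
  for (int k = 0; k < n_steps; ++k) {
    I += -I * drift + m_I * drift + diff * r.norm();
    out[k] = I;
  }
  return out;
}
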