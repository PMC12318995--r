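#include <Rcpp.h>
#include <cstdint>
#include <cmath>

// Self-contained xoshiro256+ stream with splitmix64 seeding so that large
// simulation runs do not go through R's RNG (too slow for the fitting loop).
// Reproducibility contract: identical (seed, n, parameters, dt) => identical
// output, independent of R's RNG state.

namespace {

// Marsaglia-Tsang ziggurat tables for the standard normal (128 layers)
struct ZigTables {
  uint32_t kn[128];
  double wn[128], fn[128];
  ZigTables() {
    const double m1 = 2147483648.0;
    double dn = 3.442619855899, tn = dn;
    const double vn = 9.91256303526217e-3;
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
static const ZigTables zig;

struct Xoshiro {
  uint64_t s[4];

  explicit Xoshiro(uint64_t seed) {
    // splitmix64 expansion of the scalar seed
    uint64_t z = seed;
    for (int i = 0; i < 4; ++i) {
      z += 0x9e3779b97f4a7c15ULL;
      uint64_t t = z;
      t = (t ^ (t >> 30)) * 0xbf58476d1ce4e5b9ULL;
      t = (t ^ (t >> 27)) * 0x94d049bb133111ebULL;
      s[i] = t ^ (t >> 31);
    }
  }

  static inline uint64_t rotl(uint64_t x, int k) {
    return (x << k) | (x >> (64 - k));
  }

  inline uint64_t next() {
    const uint64_t result = s[0] + s[3];
    const uint64_t t = s[1] << 17;
    s[2] ^= s[0];
    s[3] ^= s[1];
    s[1] ^= s[2];
    s[0] ^= s[3];
    s[2] ^= t;
    s[3] = rotl(s[3], 45);
    return result;
  }

  // uniform on (0, 1); never returns 0 (needed for log below)
  inline double unif() {
    return ((next() >> 11) + 0.5) * (1.0 / 9007199254740992.0);
  }

  inline int32_t next32() {
    return static_cast<int32_t>(next() >> 32);
  }

  // standard normal via the Marsaglia-Tsang ziggurat
  double norm_tail(int32_t hz, int iz) {
    const double r = 3.442619855899;
    double x, y;
    for (;;) {
      x = hz * zig.wn[iz];
      if (iz == 0) {  // base strip: exponential tail
        do {
          x = -std::log(unif()) / r;
          y = -std::log(unif());
        } while (y + y < x * x);
        return (hz > 0) ? r + x : -(r + x);
      }
      if (zig.fn[iz] + unif() * (zig.fn[iz - 1] - zig.fn[iz]) <
          std::exp(-0.5 * x * x))
        return x;
      hz = next32();
      iz = hz & 127;
      if (static_cast<uint32_t>(hz < 0 ? -static_cast<int64_t>(hz) : hz) < zig.kn[iz])
        return hz * zig.wn[iz];
    }
  }

  inline double norm() {
    int32_t hz = next32();
    int iz = hz & 127;
    if (static_cast<uint32_t>(hz < 0 ? -static_cast<int64_t>(hz) : hz) < zig.kn[iz])
      return hz * zig.wn[iz];
    return norm_tail(hz, iz);
  }
};

// Broadie-Glasserman-Kou continuity correction constant zeta(1/2)/sqrt(2*pi):
// a discretely monitored barrier is shifted inward by beta*sigma*sqrt(dt) to
// emulate continuous monitoring of the underlying diffusion.
const double kBarrierBeta = 0.5826;

} // namespace

//' @name dstp_simulate_cpp
//' @title Low-level DSTP trial simulator (compiled)
//' @description Internal Euler-Maruyama engine; use [simulate_dstp()].
//' @keywords internal
// [[Rcpp::export(name = ".dstp_simulate_cpp")]]
Rcpp::List dstp_simulate_cpp(int n, double mu_tc, double mu_cw, double mu_ss,
                             double mu_rs2, double crit_a, double crit_c,
                             double ter, bool congruent, double dt,
                             double sigma, double max_t, double seed) {
  Xoshiro rng(static_cast<uint64_t>(seed));

  const double v1 = congruent ? (mu_tc + mu_cw) : (mu_tc - mu_cw);
  const double sd_step = sigma * std::sqrt(dt);
  const double shift = kBarrierBeta * sd_step;
  const double a_eff = std::max(crit_a - shift, 1e-12);
  const double c_eff = std::max(crit_c - shift, 1e-12);
  const int max_steps = static_cast<int>(std::ceil(max_t / dt));
  const double v1dt = v1 * dt;
  const double vssdt = mu_ss * dt;

  Rcpp::NumericVector rt(n);
  Rcpp::LogicalVector correct(n);
  Rcpp::IntegerVector phase_winner(n); // 1 = RS1, 2 = SS
  Rcpp::IntegerVector selected(n);     // 0 = none, 1 = target, 2 = word
  Rcpp::LogicalVector censored(n);

  for (int i = 0; i < n; ++i) {
    double x = 0.0, y = 0.0;
    int phase = 1;
    int sel = 0;
    double vdt = v1dt;
    int step = 0;
    bool done = false;
    bool corr = false;

    while (step < max_steps) {
      ++step;
      x += vdt + sd_step * rng.norm();
      if (phase == 1) {
        y += vssdt + sd_step * rng.norm();
      }
      // response selection terminates the trial; on a same-step tie the
      // response wins (checked first)
      if (x >= a_eff) { done = true; corr = true; break; }
      if (x <= -a_eff) { done = true; corr = false; break; }
      if (phase == 1) {
        if (y >= c_eff) {
          phase = 2;
          sel = 1; // target selected: second phase drifts toward correct
          vdt = mu_rs2 * dt;
        } else if (y <= -c_eff) {
          phase = 2;
          sel = 2; // word selected: direction set by congruency
          vdt = (congruent ? mu_rs2 : -mu_rs2) * dt;
        }
      }
    }

    if (done) {
      rt[i] = step * dt + ter;
      correct[i] = corr;
      censored[i] = false;
    } else {
      // censored at the response deadline: respond by accumulator sign
      rt[i] = max_steps * dt + ter;
      correct[i] = (x > 0.0);
      censored[i] = true;
    }
    phase_winner[i] = (phase == 1) ? 1 : 2;
    selected[i] = sel;
  }

  return Rcpp::List::create(Rcpp::Named("rt_s") = rt,
                            Rcpp::Named("correct") = correct,
                            Rcpp::Named("phase_winner") = phase_winner,
                            Rcpp::Named("selected") = selected,
                            Rcpp::Named("censored") = censored);
}

//' @name dstp_bin_counts_cpp
//' @title Simulate DSTP trials and tally RT-bin counts (compiled)
//' @description Internal fast path for the G2 objective; simulates trials and
//'   classifies each into correct/error RT bins without materialising the
//'   trial table. Bins are right-closed: rt in bin b iff edge[b-1] < rt <= edge[b].
//' @keywords internal
// [[Rcpp::export(name = ".dstp_bin_counts_cpp")]]
Rcpp::List dstp_bin_counts_cpp(int n, double mu_tc, double mu_cw, double mu_ss,
                               double mu_rs2, double crit_a, double crit_c,
                               double ter, bool congruent, double dt,
                               double sigma, double max_t, double seed,
                               Rcpp::NumericVector correct_edges,
                               Rcpp::NumericVector error_edges) {
  Xoshiro rng(static_cast<uint64_t>(seed));

  const double v1 = congruent ? (mu_tc + mu_cw) : (mu_tc - mu_cw);
  const double sd_step = sigma * std::sqrt(dt);
  const double shift = kBarrierBeta * sd_step;
  const double a_eff = std::max(crit_a - shift, 1e-12);
  const double c_eff = std::max(crit_c - shift, 1e-12);
  const int max_steps = static_cast<int>(std::ceil(max_t / dt));
  const double v1dt = v1 * dt;
  const double vssdt = mu_ss * dt;
  const double v2t_dt = mu_rs2 * dt;                          // target selected
  const double v2w_dt = (congruent ? mu_rs2 : -mu_rs2) * dt;  // word selected

  const int ncb = correct_edges.size() + 1;
  const int neb = error_edges.size() + 1;
  Rcpp::IntegerVector ccounts(ncb), ecounts(neb);

  for (int i = 0; i < n; ++i) {
    double x = 0.0, y = 0.0;
    int phase = 1;
    double vdt = v1dt;
    int step = 0;
    bool done = false;
    bool corr = false;

    while (step < max_steps) {
      ++step;
      x += vdt + sd_step * rng.norm();
      if (phase == 1) {
        y += vssdt + sd_step * rng.norm();
        if (x >= a_eff) { done = true; corr = true; break; }
        if (x <= -a_eff) { done = true; corr = false; break; }
        if (y >= c_eff) { phase = 2; vdt = v2t_dt; }
        else if (y <= -c_eff) { phase = 2; vdt = v2w_dt; }
      } else {
        if (x >= a_eff) { done = true; corr = true; break; }
        if (x <= -a_eff) { done = true; corr = false; break; }
      }
    }
    double rt;
    if (done) {
      rt = step * dt + ter;
    } else {
      rt = max_steps * dt + ter;
      corr = (x > 0.0);
    }
    if (corr) {
      int b = 0;
      while (b < ncb - 1 && rt > correct_edges[b]) ++b;
      ++ccounts[b];
    } else {
      int b = 0;
      while (b < neb - 1 && rt > error_edges[b]) ++b;
      ++ecounts[b];
    }
  }

  return Rcpp::List::create(Rcpp::Named("correct_counts") = ccounts,
                            Rcpp::Named("error_counts") = ecounts);
}
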