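// Euler-Maruyama core for the two-state active particle on a disk with an
// absorbing rim.  Heading update: the displacement of a step uses the
// pre-step heading, then the heading receives its Gaussian increment
// (variance 2*Dtheta*dt).  Absorption is detected at the first step
// end-point with r >= R; no interpolation of the crossing time.
//
// Each trajectory runs on its own RNG stream derived deterministically from
// (root seed, trajectory index), so ensembles are reproducible and
// independent of batching or execution order.  The stream is an
// mt19937_64 seeded through splitmix64, with Box-Muller normals; all of it
// is fully specified by the C++ standard, hence bit-stable across platforms.

#include <Rcpp.h>
#include <cmath>
#include <cstdint>
#include <random>
#include <vector>

namespace {

inline std::uint64_t splitmix64(std::uint64_t x) {
  x += 0x9E3779B97F4A7C15ULL;
  x = (x ^ (x >> 30)) * 0xBF58476D1CE4E5B9ULL;
  x = (x ^ (x >> 27)) * 0x94D049BB133111EBULL;
  return x ^ (x >> 31);
}

inline std::uint64_t stream_seed(std::uint64_t seed, std::uint64_t index) {
  return splitmix64(splitmix64(seed) ^ (0x9E3779B97F4A7C15ULL * (index + 1)));
}

class Stream {
 public:
  explicit Stream(std::uint64_t s) : eng_(s), has_spare_(false), spare_(0.0) {}
  // uniform on [0, 1) with 53 random bits
  double unif() { return (eng_() >> 11) * (1.0 / 9007199254740992.0); }
  double gauss() {
    if (has_spare_) {
      has_spare_ = false;
      return spare_;
    }
    double u1;
    do {
      u1 = unif();
    } while (u1 <= 0.0);
    const double u2 = unif();
    const double m = std::sqrt(-2.0 * std::log(u1));
    spare_ = m * std::sin(2.0 * M_PI * u2);
    has_spare_ = true;
    return m * std::cos(2.0 * M_PI * u2);
  }
  double expo(double rate) {
    double u;
    do {
      u = unif();
    } while (u <= 0.0);
    return -std::log(u) / rate;
  }

 private:
  std::mt19937_64 eng_;
  bool has_spare_;
  double spare_;
};

// switch modes (must match the R-side encoding)
enum Mode { CONSTANT = 0, RATE = 1, POSITIONAL = 2 };

struct TrajResult {
  double escape_time = NA_REAL;  // first-passage or censoring time
  bool absorbed = false;
  bool switched = false;
  double switch_time = NA_REAL;
  double switch_radius = NA_REAL;
  double exit_x = NA_REAL, exit_y = NA_REAL;
};

struct Recorder {
  int stride = 0;  // 0 = no recording
  std::vector<double> t, x, y, theta;
  std::vector<int> state;
  void push(double tt, double xx, double yy, double th, int st) {
    t.push_back(tt);
    x.push_back(xx);
    y.push_back(yy);
    theta.push_back(th);
    state.push_back(st);
  }
};

TrajResult run_trajectory(Stream& rng, int mode, double v1, double d1,
                          double v2, double d2, double k, double r_switch,
                          bool bernoulli, double R, double dt, long max_steps,
                          double* dwell, int n_bins, Recorder* rec) {
  TrajResult out;
  double x = 0.0, y = 0.0;
  double theta = 2.0 * M_PI * rng.unif();
  double v = v1, dth = d1;
  int state = 1;
  double t = 0.0;
  double t_rate_switch = -1.0;
  if (mode == RATE && !bernoulli) t_rate_switch = rng.expo(k);

  const double R2 = R * R;
  const double bin_w = (n_bins > 0) ? R / n_bins : 1.0;

  for (long step = 0; step < max_steps; ++step) {
    const double r2 = x * x + y * y;

    if (state == 1) {
      bool do_switch = false;
      if (mode == RATE) {
        if (bernoulli) {
          if (rng.unif() < k * dt) do_switch = true;
        } else if (t >= t_rate_switch) {
          do_switch = true;
        }
      } else if (mode == POSITIONAL) {
        if (r2 >= r_switch * r_switch) do_switch = true;
      }
      if (do_switch) {
        state = 2;
        v = v2;
        dth = d2;
        out.switched = true;
        out.switch_time = t;
        out.switch_radius = std::sqrt(r2);
      }
    }

    if (rec && rec->stride > 0 && step % rec->stride == 0)
      rec->push(t, x, y, theta, state);

    if (dwell) {
      int b = static_cast<int>(std::sqrt(r2) / bin_w);
      if (b >= n_bins) b = n_bins - 1;
      dwell[b] += dt;
    }

    // displacement with the pre-step heading, then the heading update
    x += v * dt * std::cos(theta);
    y += v * dt * std::sin(theta);
    theta += std::sqrt(2.0 * dth * dt) * rng.gauss();
    t = (step + 1) * dt;

    if (x * x + y * y >= R2) {
      out.absorbed = true;
      out.escape_time = t;
      break;
    }
  }
  if (!out.absorbed) out.escape_time = max_steps * dt;  // censored
  out.exit_x = x;
  out.exit_y = y;
  if (rec && rec->stride > 0) {
    // terminal point (the only recorded point allowed to satisfy r >= R)
    if (rec->t.empty() || rec->t.back() < t) rec->push(t, x, y, theta, state);
  }
  return out;
}

long steps_from_horizon(double t_max, double dt) {
  double s = std::ceil(t_max / dt - 1e-9);
  if (s < 1) s = 1;
  return static_cast<long>(s);
}

}  // namespace

// [[Rcpp::export]]
Rcpp::List cpp_run_ensemble(int n, double seed, int mode, double v1, double d1,
                            double v2, double d2, double k, double r_switch,
                            bool bernoulli, double R, double dt, double t_max,
                            int n_bins) {
  const long max_steps = steps_from_horizon(t_max, dt);
  Rcpp::NumericVector escape(n), sw_time(n), sw_radius(n), azimuth(n);
  Rcpp::LogicalVector absorbed(n), switched(n);
  Rcpp::NumericMatrix dwell(n, n_bins);
  std::vector<double> row(n_bins);
  const std::uint64_t root = static_cast<std::uint64_t>(seed);

  for (int i = 0; i < n; ++i) {
    std::fill(row.begin(), row.end(), 0.0);
    Stream rng(stream_seed(root, static_cast<std::uint64_t>(i + 1)));
    TrajResult r = run_trajectory(rng, mode, v1, d1, v2, d2, k, r_switch,
                                  bernoulli, R, dt, max_steps, row.data(),
                                  n_bins, nullptr);
    escape[i] = r.escape_time;
    absorbed[i] = r.absorbed;
    switched[i] = r.switched;
    sw_time[i] = r.switch_time;
    sw_radius[i] = r.switch_radius;
    azimuth[i] = std::atan2(r.exit_y, r.exit_x);
    for (int b = 0; b < n_bins; ++b) dwell(i, b) = row[b];
    if (i % 256 == 0) Rcpp::checkUserInterrupt();
  }
  return Rcpp::List::create(
      Rcpp::Named("escape_time") = escape, Rcpp::Named("absorbed") = absorbed,
      Rcpp::Named("switched") = switched, Rcpp::Named("switch_time") = sw_time,
      Rcpp::Named("switch_radius") = sw_radius,
      Rcpp::Named("exit_azimuth") = azimuth, Rcpp::Named("dwell") = dwell);
}

// [[Rcpp::export]]
Rcpp::List cpp_run_path(double seed, int index, int mode, double v1, double d1,
                        double v2, double d2, double k, double r_switch,
                        bool bernoulli, double R, double dt, double t_max,
                        int stride) {
  const long max_steps = steps_from_horizon(t_max, dt);
  Stream rng(stream_seed(static_cast<std::uint64_t>(seed),
                         static_cast<std::uint64_t>(index)));
  Recorder rec;
  rec.stride = stride;
  const long expect = max_steps / stride + 2;
  rec.t.reserve(expect);
  rec.x.reserve(expect);
  rec.y.reserve(expect);
  rec.theta.reserve(expect);
  rec.state.reserve(expect);
  TrajResult r = run_trajectory(rng, mode, v1, d1, v2, d2, k, r_switch,
                                bernoulli, R, dt, max_steps, nullptr, 0, &rec);
  return Rcpp::List::create(
      Rcpp::Named("t") = Rcpp::wrap(rec.t), Rcpp::Named("x") = Rcpp::wrap(rec.x),
      Rcpp::Named("y") = Rcpp::wrap(rec.y),
      Rcpp::Named("theta") = Rcpp::wrap(rec.theta),
      Rcpp::Named("state") = Rcpp::wrap(rec.state),
      Rcpp::Named("escape_time") = r.escape_time,
      Rcpp::Named("absorbed") = r.absorbed,
      Rcpp::Named("switched") = r.switched,
      Rcpp::Named("switch_time") = r.switch_time,
      Rcpp::Named("switch_radius") = r.switch_radius);
}

// Thomas algorithm for tridiagonal systems; used by the implicit
// finite-volume steps of the radial diffusion solver.
// [[Rcpp::export]]
Rcpp::NumericVector cpp_tridiag_solve(Rcpp::NumericVector lower,
                                      Rcpp::NumericVector diag,
                                      Rcpp::NumericVector upper,
                                      Rcpp::NumericVector rhs) {
  const int n = diag.size();
  Rcpp::NumericVector cp(n), dp(n), x(n);
  cp[0] = upper[0] / diag[0];
  dp[0] = rhs[0] / diag[0];
  for (int i = 1; i < n; ++i) {
    const double m = diag[i] - lower[i] * cp[i - 1];
    cp[i] = (i < n - 1) ? upper[i] / m : 0.0;
    dp[i] = (rhs[i] - lower[i] * dp[i - 1]) / m;
  }
  x[n - 1] = dp[n - 1];
  for (int i = n - 2; i >= 0; --i) x[i] = dp[i] - cp[i] * x[i + 1];
  return x;
}
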