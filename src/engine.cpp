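// Overdamped Langevin propagation and 1-D metadynamics inner loops.
// All randomness comes from R's RNG so runs are reproducible with
// set.seed(); Rcpp attributes insert the RNGScope.

#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Analytic 1-D potentials.
// family 0: flat            params: (ignored)
// family 1: harmonic        params: k, x0
// family 2: double well     params: h (barrier, kcal/mol), xm (minima at +-xm)
//           V(x) = h ((x/xm)^2 - 1)^2  -> minima at +-xm (V=0), top at 0 (V=h)
static inline double pot_force(int family, const double* p, double x,
                               double& energy) {
  switch (family) {
  case 0:
    energy = 0.0;
    return 0.0;
  case 1: {
    double d = x - p[1];
    energy = 0.5 * p[0] * d * d;
    return -p[0] * d;
  }
  case 2: {
    double u = x / p[1];
    double q = u * u - 1.0;
    energy = p[0] * q * q;
    return -4.0 * p[0] * q * u / p[1];
  }
  default:
    stop("unknown potential family");
  }
  return 0.0; // not reached
}

static inline double bias_force_1d(const std::vector<double>& centers,
                                   const std::vector<double>& heights,
                                   double sigma, double x, double& energy) {
  energy = 0.0;
  double f = 0.0;
  const double cut = 8.0 * sigma;
  const double inv_s2 = 1.0 / (sigma * sigma);
  for (size_t j = 0; j < centers.size(); ++j) {
    double d = x - centers[j];
    if (std::fabs(d) > cut) continue;
    double g = heights[j] * std::exp(-0.5 * d * d * inv_s2);
    energy += g;
    f += g * d * inv_s2;
  }
  return f;
}

// Euler-Maruyama overdamped update. fric = gamma * mass (kcal ps A^-2 ...
// effectively the friction coefficient); kT in kcal/mol.
// [[Rcpp::export]]
NumericVector cpp_langevin_1d(double x0, int family, NumericVector params,
                              double dt, double fric, double kT,
                              int n_steps, int sample_every) {
  std::vector<double> out;
  out.reserve(n_steps / sample_every + 1);
  double x = x0, e;
  const double noise = std::sqrt(2.0 * kT * dt / fric);
  const double mob = dt / fric;
  for (int i = 1; i <= n_steps; ++i) {
    double f = pot_force(family, params.begin(), x, e);
    x += f * mob + noise * norm_rand();
    if (!std::isfinite(x)) stop("numerical failure: non-finite position");
    if (i % sample_every == 0) out.push_back(x);
  }
  return wrap(out);
}

// First-passage time (in steps) from x0 to x >= boundary; -1 if the cap
// is reached first.
// [[Rcpp::export]]
double cpp_fpt_1d(double x0, int family, NumericVector params,
                  double dt, double fric, double kT,
                  double boundary, double max_steps) {
  double x = x0, e;
  const double noise = std::sqrt(2.0 * kT * dt / fric);
  const double mob = dt / fric;
  for (double i = 1; i <= max_steps; ++i) {
    double f = pot_force(family, params.begin(), x, e);
    x += f * mob + noise * norm_rand();
    if (!std::isfinite(x)) stop("numerical failure: non-finite position");
    if (x >= boundary) return i;
  }
  return -1.0;
}

// Metadynamics over a 1-D analytic system whose single CV is the
// coordinate itself. Every stride: record V(s,t) just before deposition,
// test the unbound predicate (x >= unbound_at), deposit a hill (height
// rescaled when well-tempered). Wall energies are applied to the
// dynamics but excluded from the recorded V(s,t).
// [[Rcpp::export]]
List cpp_metad_1d(double x0, int family, NumericVector params,
                  double dt, double fric, double kT,
                  int steps_per_stride, int max_deposits,
                  double omega0, double kb_deltaT, bool wt,
                  double sigma,
                  double floor_loc, double floor_k,
                  double wall_loc, double wall_k,
                  double unbound_at, bool stop_on_unbound) {
  std::vector<double> centers, heights;
  std::vector<double> rec_cv, rec_v, rec_h;
  std::vector<int> rec_unb;
  centers.reserve(max_deposits);
  heights.reserve(max_deposits);
  double x = x0, e, eb;
  const double noise = std::sqrt(2.0 * kT * dt / fric);
  const double mob = dt / fric;
  const bool has_floor = R_finite(floor_loc);
  const bool has_wall = R_finite(wall_loc);
  const bool has_unbound = R_finite(unbound_at);
  std::string status = "max_time_reached";

  for (int k = 0; k < max_deposits; ++k) {
    for (int i = 0; i < steps_per_stride; ++i) {
      double f = pot_force(family, params.begin(), x, e);
      f += bias_force_1d(centers, heights, sigma, x, eb);
      if (has_floor && x < floor_loc) f += -2.0 * floor_k * (x - floor_loc);
      if (has_wall && x > wall_loc) f += -2.0 * wall_k * (x - wall_loc);
      x += f * mob + noise * norm_rand();
      if (!std::isfinite(x)) stop("numerical failure: non-finite position");
    }
    double v_here;
    bias_force_1d(centers, heights, sigma, x, v_here);
    bool unb = has_unbound && x >= unbound_at;
    rec_cv.push_back(x);
    rec_v.push_back(v_here);
    rec_unb.push_back(unb ? 1 : 0);
    if (unb && stop_on_unbound) {
      rec_h.push_back(0.0);           // no deposit on the terminal record
      status = "unbound";
      break;
    }
    double h = wt ? omega0 * std::exp(-v_here / kb_deltaT) : omega0;
    rec_h.push_back(h);
    centers.push_back(x);
    heights.push_back(h);
  }
  return List::create(_["cv"] = wrap(rec_cv), _["bias"] = wrap(rec_v),
                      _["height"] = wrap(rec_h), _["unbound"] = wrap(rec_unb),
                      _["status"] = status, _["x_final"] = x);
}
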