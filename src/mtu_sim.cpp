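// Hill-type MTU contraction integrator.
//
// State: fascicle length l_CE. At each instant the fascicle velocity is the
// unique root of the series force balance
//   F_SE(lambda) = (a F_max f_l(l) f_v(v) + F_PE(l)) cos(theta(l)),
// obtained by closed-form inversion of the force-velocity curve on each
// branch. Time stepping is backward Euler with bisection on the length
// update, which is unconditionally stable for stiff (near-rigid) tendons;
// sub-steps refine the mechanics grid.

#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

namespace {

struct Par {
  double F_max, l_opt, l_sl, K_sh, lambda_ref, theta0, w,
         v_max, K_hill, N_ecc;
  double sin0, se_denom;         // precomputed constants
  double sin_theta0() const { return sin0; }
};

const double THETA_CLAMP_SIN = std::sin(89.9 * M_PI / 180.0);
const double LOG005 = std::log(0.05);

inline double pennation(const Par& p, double l, bool& clamped_geom) {
  if (p.theta0 == 0.0) return 0.0;
  double s = p.l_opt * p.sin0 / l;
  if (s > THETA_CLAMP_SIN) { clamped_geom = true; s = THETA_CLAMP_SIN; }
  return std::asin(s);
}

inline double f_l(const Par& p, double l) {
  double z = std::fabs((l - p.l_opt) / (p.l_opt * p.w));
  return std::exp(LOG005 * z * z * z);
}

inline double f_pe(const Par& p, double l) {
  double e = (l - p.l_opt) / (p.l_opt * p.w);
  if (e <= 0.0) return 0.0;
  return p.F_max * e * e;
}

inline double f_se(const Par& p, double lambda) {
  if (lambda <= 0.0) return 0.0;
  return p.F_max * (std::exp(p.K_sh * lambda / p.lambda_ref) - 1.0) /
         p.se_denom;
}

inline double fv_of_v(const Par& p, double v) {
  if (v < 0.0) {
    double s = std::min(-v, p.v_max);
    return (p.v_max - s) / (p.v_max + p.K_hill * s);
  }
  return p.N_ecc - (p.N_ecc - 1.0) * (p.v_max + v) /
         (7.56 * p.K_hill * v + p.v_max);
}

// closed-form inverse of fv_of_v, clamped outside range
inline double v_of_fv(const Par& p, double fv, bool& clamped) {
  double fv_sat = p.N_ecc - (p.N_ecc - 1.0) / (7.56 * p.K_hill);
  if (fv <= 0.0) { clamped = true; return -p.v_max; }
  if (fv < 1.0)
    return -p.v_max * (1.0 - fv) / (1.0 + p.K_hill * fv);
  if (fv < fv_sat)
    return p.v_max * (fv - 1.0) /
           (7.56 * p.K_hill * (p.N_ecc - fv) - (p.N_ecc - 1.0));
  clamped = true; return p.v_max;
}

// fascicle velocity from the force balance at (a, l, l_MTC)
inline double velocity(const Par& p, double a, double l, double l_MTC,
                       bool& clamped) {
  bool cg = false;
  double th = pennation(p, l, cg);
  double ct = std::cos(th);
  double l_SE = l_MTC - l * ct;
  double lambda = (l_SE - p.l_sl) / p.l_sl;
  double F_fiber = f_se(p, lambda) / ct;
  double F_PE = f_pe(p, l);
  double denom = a * p.F_max * f_l(p, l);
  if (denom <= 0.0) {
    if (std::fabs(F_fiber - F_PE) < 1e-12 * p.F_max) return 0.0;
    clamped = true;
    return (F_fiber > F_PE) ? p.v_max : -p.v_max;
  }
  double fv = (F_fiber - F_PE) / denom;
  return v_of_fv(p, fv, clamped);
}

// quasi-static equilibrium fascicle length at fixed (a, l_MTC)
double static_equilibrium(const Par& p, double a, double l_MTC) {
  double l_min = std::max(1e-4, p.l_opt * p.sin_theta0() / THETA_CLAMP_SIN);
  l_min = std::max(l_min, 0.05 * p.l_opt);
  double l_max = std::max(p.l_opt * (1.0 + 2.0 * p.w), l_MTC);
  // residual g(l) = F_SE - (a F_max f_l + F_PE) cos(theta); g decreasing in l
  auto g = [&](double l) {
    bool cg = false;
    double th = pennation(p, l, cg), ct = std::cos(th);
    double lambda = (l_MTC - l * ct - p.l_sl) / p.l_sl;
    return f_se(p, lambda) - (a * p.F_max * f_l(p, l) + f_pe(p, l)) * ct;
  };
  double glo = g(l_min), ghi = g(l_max);
  if (glo <= 0.0) {
    // no equilibrium with a taut tendon: the tendon is slack over the
    // admissible range, so the fiber rests at its optimal (PE rest)
    // length, or at the taut-tendon boundary if that lies beyond it
    bool cg = false;
    double lr = (l_MTC - p.l_sl) / std::cos(pennation(p, p.l_opt, cg));
    return (lr > p.l_opt) ? std::min(lr, l_max) : p.l_opt;
  }
  if (ghi >= 0.0) return l_max;
  double lo = l_min, hi = l_max;
  for (int i = 0; i < 80; ++i) {
    double mid = 0.5 * (lo + hi);
    if (g(mid) > 0.0) lo = mid; else hi = mid;
  }
  return 0.5 * (lo + hi);
}

} // namespace

// [[Rcpp::export(name = ".mtu_simulate_cpp")]]
List mtu_simulate_cpp(NumericVector time, NumericVector l_MTC,
                      NumericVector act, List params,
                      int n_sub = 4, double l_CE0 = NA_REAL) {
  int n = time.size();
  if (l_MTC.size() != n || act.size() != n)
    stop("time, l_MTC and activation must share one grid");
  if (n < 2) stop("need at least two samples");
  Par p;
  p.F_max = params["F_max"]; p.l_opt = params["l_opt"];
  p.l_sl = params["l_sl"]; p.K_sh = params["K_sh"];
  p.lambda_ref = params["lambda_ref"]; p.theta0 = params["theta0"];
  p.w = params["w"]; p.v_max = params["v_max"];
  p.K_hill = params["K_hill"]; p.N_ecc = params["N_ecc"];
  p.sin0 = std::sin(p.theta0);
  p.se_denom = std::exp(p.K_sh) - 1.0;

  NumericVector lce(n), vce(n), theta(n), lambda(n),
                F_SE(n), F_PE(n), F_CE(n);
  LogicalVector clamped(n);

  double l = ISNA(l_CE0) ? static_equilibrium(p, act[0], l_MTC[0]) : l_CE0;
  double l_floor = std::max(1e-4,
      0.5 * p.l_opt * (p.theta0 > 0 ? p.sin_theta0() : 0.1));

  int n_clamped_steps = 0;
  for (int i = 0; i < n; ++i) {
    if (i > 0) {
      double dt = (time[i] - time[i - 1]) / n_sub;
      if (dt <= 0) stop("time must be strictly increasing");
      for (int k = 1; k <= n_sub; ++k) {
        double frac = double(k) / n_sub;
        double a_k = act[i - 1] + frac * (act[i] - act[i - 1]);
        double lm_k = l_MTC[i - 1] + frac * (l_MTC[i] - l_MTC[i - 1]);
        // backward Euler: solve phi(x) = x - l - dt v(x) = 0 with
        // safeguarded Newton inside the reachable bracket (|v| <= v_max)
        double lo = std::max(l - dt * p.v_max * 1.0000001, l_floor);
        double hi = l + dt * p.v_max * 1.0000001;
        bool c2 = false;
        double x = l + dt * velocity(p, a_k, l, lm_k, c2); // predictor
        if (x < lo) x = lo; else if (x > hi) x = hi;
        for (int it = 0; it < 60; ++it) {
          double phi = x - l - dt * velocity(p, a_k, x, lm_k, c2);
          if (std::fabs(phi) < 1e-12 || hi - lo < 1e-13) break;
          if (phi < 0.0) lo = x; else hi = x;
          double h = 1e-9 * std::max(1.0, std::fabs(x));
          double phi2 = (x + h) - l - dt * velocity(p, a_k, x + h, lm_k, c2);
          double dphi = (phi2 - phi) / h;
          double xn = (dphi > 1e-8) ? x - phi / dphi : 0.5 * (lo + hi);
          if (xn <= lo || xn >= hi) xn = 0.5 * (lo + hi);
          x = xn;
        }
        l = std::max(x, l_floor);
      }
    }
    bool cl = false;
    double v = velocity(p, act[i], l, l_MTC[i], cl);
    bool cg = false;
    double th = pennation(p, l, cg);
    double ct = std::cos(th);
    double lam = (l_MTC[i] - l * ct - p.l_sl) / p.l_sl;
    lce[i] = l; vce[i] = v; theta[i] = th; lambda[i] = lam;
    F_SE[i] = f_se(p, lam);
    F_PE[i] = f_pe(p, l);
    F_CE[i] = act[i] * p.F_max * f_l(p, l) * fv_of_v(p, v);
    clamped[i] = cl || cg;
    if (clamped[i]) ++n_clamped_steps;
  }

  return List::create(_["time"] = time, _["l_CE"] = lce, _["v_CE"] = vce,
                      _["theta"] = theta, _["lambda"] = lambda,
                      _["F_SE"] = F_SE, _["F_PE"] = F_PE, _["F_CE"] = F_CE,
                      _["clamped"] = clamped,
                      _["n_clamped"] = n_clamped_steps);
}
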