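// Inner per-trial recursions of the learning models. These are the hot
// loops of the fitting objective; the R-level wrappers in R/models.R
// document the semantics.

#include <Rcpp.h>
using namespace Rcpp;

// state recursion x(n+1) = A*x(n) + input(n), x(1) = 0; returns the state
// at each trial (before that trial's update)
// [[Rcpp::export]]
NumericVector cpp_core_lin(double A, NumericVector input) {
  int n = input.size();
  NumericVector x(n);
  for (int i = 1; i < n; ++i) {
    x[i] = A * x[i - 1] + input[i - 1];
  }
  return x;
}

// adaptation-modulation recursion: gains on retention/update on hit trials
// [[Rcpp::export]]
NumericVector cpp_core_am(double A, double U, double gamma_A,
                          double gamma_u, NumericVector err,
                          NumericVector hit) {
  int n = err.size();
  NumericVector x(n);
  for (int i = 0; i < n - 1; ++i) {
    double a = (hit[i] == 1) ? gamma_A * A : A;
    double u = 0.0;
    if (err[i] == 1) u = (hit[i] == 1) ? gamma_u * U : U;
    x[i + 1] = a * x[i] + u;
  }
  return x;
}

// population-vector reinforcement combined with an adaptation state x.
// The 36,000-unit weight vector is carried through its x/y components:
// the uniform decay and the single-unit increment act linearly on the
// components, so the incremental update equals the dense computation.
// The reinforced direction is y rounded to the nearest 0.01-degree unit,
// ties away from zero.
// [[Rcpp::export]]
List cpp_core_reinforce(NumericVector x, NumericVector rew, double A_prime,
                        double s) {
  int n = x.size();
  NumericVector y(n), V_l(n), V_d(n, NA_REAL);
  double Vx = 0.0, Vy = 0.0;
  const double deg2rad = M_PI / 180.0;
  for (int i = 0; i < n; ++i) {
    double len = std::sqrt(Vx * Vx + Vy * Vy);
    if (len > 0.0) {
      double vl = len < 1.0 ? len : 1.0;
      double vd = std::atan2(Vy, Vx) / deg2rad;
      // wrap into [-180, 180) without fmod (symbol-version portability)
      vd -= 360.0 * std::floor((vd + 180.0) / 360.0);
      V_l[i] = vl;
      V_d[i] = vd;
      y[i] = (1.0 - vl) * x[i] + vl * vd;
    } else {
      y[i] = x[i];  // zero-length vector: reinforcement carries no weight
    }
    Vx *= A_prime;
    Vy *= A_prime;
    if (rew[i] == 1) {
      double theta = std::floor(std::fabs(y[i]) * 100.0 + 0.5) / 100.0;
      if (y[i] < 0.0) theta = -theta;
      theta *= deg2rad;
      Vx += s * std::cos(theta);
      Vy += s * std::sin(theta);
    }
  }
  return List::create(_["y"] = y, _["V_l"] = V_l, _["V_d"] = V_d);
}
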