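#include <Rcpp.h>
using namespace Rcpp;

// Objective and gradient kernels for the patient-specific decay model
//   m(p) = A * exp(-B * (p + delta)) + C,   delta = ga_days + Tc
// evaluated against observations y at postnatal ages p.
//
// loss = 0: plain least squares, cost = sum r^2
// loss = 1: soft-L1 (smooth absolute-error) with scale s:
//           cost = sum 2 s^2 (sqrt(1 + (r/s)^2) - 1)
// Both reduce the influence of large residuals smoothly under loss 1 while
// staying exactly quadratic near zero, so the plain SSR used for candidate
// selection remains well defined at any solution.

// [[Rcpp::export]]
double decay_cost(NumericVector th, NumericVector p, NumericVector y,
                  int loss, double scale) {
  const double A = th[0], B = th[1], C = th[2], delta = th[3];
  const int n = p.size();
  double cost = 0.0;
  for (int i = 0; i < n; ++i) {
    const double m = A * std::exp(-B * (p[i] + delta)) + C;
    const double r = y[i] - m;
    if (loss == 0) {
      cost += r * r;
    } else {
      const double z = r / scale;
      cost += 2.0 * scale * scale * (std::sqrt(1.0 + z * z) - 1.0);
    }
  }
  return cost;
}

// [[Rcpp::export]]
NumericVector decay_grad(NumericVector th, NumericVector p, NumericVector y,
                         int loss, double scale) {
  const double A = th[0], B = th[1], C = th[2], delta = th[3];
  const int n = p.size();
  double gA = 0.0, gB = 0.0, gC = 0.0, gD = 0.0;
  for (int i = 0; i < n; ++i) {
    const double t = p[i] + delta;
    const double E = std::exp(-B * t);
    const double m = A * E + C;
    const double r = y[i] - m;
    // d cost / d r
    double w;
    if (loss == 0) {
      w = 2.0 * r;
    } else {
      const double z = r / scale;
      w = 2.0 * r / std::sqrt(1.0 + z * z);
    }
    // dr/dtheta = -dm/dtheta
    gA += w * (-E);
    gB += w * (A * t * E);
    gC += w * (-1.0);
    gD += w * (A * B * E);
  }
  return NumericVector::create(gA, gB, gC, gD);
}

// Plain sum of squared residuals at a parameter point (selection criterion).
// [[Rcpp::export]]
double decay_ssr(NumericVector th, NumericVector p, NumericVector y) {
  return decay_cost(th, p, y, 0, 1.0);
}
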