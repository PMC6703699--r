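#include <Rcpp.h>
using namespace Rcpp;

// Forward simulation of the delta-rule state equation
//   x(n+1) = A*x(n) + K*(s(n) - x(n)) + m + D*(s(n-1) - x(n-1))
// with 1-based trial index, x(1) = G, and the start-up convention
// s(0) = 0, x(0) = x(1) (the first update then matches the single-error
// model; the influence of the convention decays within a few trials).
//
// Divergence (|x| exceeding `bound`) is flagged, not raised, so that an
// optimizer can penalize unstable parameter proposals; the remaining
// entries are filled with the last finite value to keep residuals finite.
// [[Rcpp::export(name = ".sim_state_cpp")]]
NumericVector sim_state_cpp(double K, double A, double m, double D, double G,
                            NumericVector s, double bound) {
  int n = s.size();
  NumericVector x(n);
  bool unstable = false;
  if (n == 0) {
    x.attr("unstable") = unstable;
    return x;
  }
  x[0] = G;
  double s_prev2 = 0.0;  // s(n-1) with s(0) = 0
  double x_prev2 = G;    // x(n-1) with x(0) = x(1)
  for (int i = 1; i < n; ++i) {
    // i is 0-based position of trial i+1; update uses trial i quantities
    double xn = x[i - 1];
    double sn = s[i - 1];
    double xnext = A * xn + K * (sn - xn) + m + D * (s_prev2 - x_prev2);
    if (!R_finite(xnext) || std::abs(xnext) > bound) {
      unstable = true;
      for (int j = i; j < n; ++j) x[j] = xn;
      break;
    }
    x[i] = xnext;
    s_prev2 = sn;
    x_prev2 = xn;
  }
  x.attr("unstable") = unstable;
  return x;
}
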