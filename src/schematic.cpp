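#include <Rcpp.h>
using namespace Rcpp;

// Sum of squared residuals between an observed time profile (sampled at
// projection coordinates 0..n-1) and the schematic step-wedge model: seven
// flat levels s1..s7 joined by six linear ramps with transition coordinates
// p1..p12 (sorted, strictly increasing). Hot loop of the profile fit; the
// exported R function evaluate_schematic() is the reference implementation.
// [[Rcpp::export(name = ".sse_schematic_cpp")]]
double sse_schematic_cpp(NumericVector p, NumericVector s, NumericVector v) {
  const int n = v.size();
  if (p.size() != 12 || s.size() != 7) return R_PosInf;
  for (int j = 1; j < 12; ++j)
    if (!(p[j] > p[j - 1])) return R_PosInf;
  double sse = 0.0;
  int seg = 0; // number of p's <= t so far
  for (int i = 0; i < n; ++i) {
    const double t = (double)i;
    while (seg < 12 && t >= p[seg]) ++seg;
    double m;
    if (seg % 2 == 0) {
      m = s[seg / 2];
    } else {
      const int k = (seg + 1) / 2;            // ramp number 1..6
      const double a = p[2 * k - 2], b = p[2 * k - 1];
      const double al = (t - a) / (b - a);
      m = s[k - 1] + (s[k] - s[k - 1]) * al;
    }
    const double d = v[i] - m;
    sse += d * d;
  }
  return sse;
}

// Model values on the full projection grid 0..n-1 (used by the level refit).
// [[Rcpp::export(name = ".eval_schematic_cpp")]]
NumericVector eval_schematic_cpp(NumericVector p, NumericVector s, int n) {
  NumericVector out(n);
  int seg = 0;
  for (int i = 0; i < n; ++i) {
    const double t = (double)i;
    while (seg < 12 && t >= p[seg]) ++seg;
    if (seg % 2 == 0) {
      out[i] = s[seg / 2];
    } else {
      const int k = (seg + 1) / 2;
      const double a = p[2 * k - 2], b = p[2 * k - 1];
      const double al = (t - a) / (b - a);
      out[i] = s[k - 1] + (s[k] - s[k - 1]) * al;
    }
  }
  return out;
}
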