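// Fixed-step Euler-Maruyama integration of the radial diffusion SDE
//   dr = (D / r) dt + sqrt(2 D) dW
// (the radial coordinate of 2-D isotropic diffusion), with reflecting or
// absorbing boundaries.  Serves as the independent numerical oracle for
// the spectral first-passage samplers.

#include <Rcpp.h>
using namespace Rcpp;

// boundary codes: 0 = reflecting, 1 = absorbing

// [[Rcpp::export(name = ".sde_fpt_cpp")]]
DataFrame sde_fpt_cpp(int n, double r0, double a, double b,
                      int bc_a, int bc_b, double D, double dt,
                      double max_time) {
  if (!(a < b) || r0 < a || r0 > b)
    stop("require a < b and r0 in [a, b]");
  const double sig = std::sqrt(2.0 * D * dt);
  NumericVector time(n);
  IntegerVector side(n); // 1 = absorbed at a, 2 = absorbed at b, 0 = censored
  RNGScope rngScope;
  for (int i = 0; i < n; ++i) {
    double r = r0, t = 0.0;
    int s = 0;
    while (t < max_time) {
      r += (D / r) * dt + sig * norm_rand();
      t += dt;
      if (r <= a) {
        if (bc_a == 1) { s = 1; break; }
        r = 2.0 * a - r;
        if (r > b) r = b; // pathological double-crossing guard
      } else if (r >= b) {
        if (bc_b == 1) { s = 2; break; }
        r = 2.0 * b - r;
        if (r < a) r = a;
      }
    }
    time[i] = t;
    side[i] = s;
  }
  return DataFrame::create(_["time"] = time, _["side"] = side);
}
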