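#include <Rcpp.h>
using namespace Rcpp;

// First-order linear recursion y[i] = u[i] + phi * y[i-1], y[0] = 0.
// This is the discrete forward step shared by every compartment model and
// runs thousands of times per fit, hence the compiled kernel.
// [[Rcpp::export]]
NumericVector euler_recursion(NumericVector u, double phi) {
  R_xlen_t n = u.size();
  NumericVector out(n);
  double c = 0.0;
  for (R_xlen_t i = 0; i < n; ++i) {
    c = u[i] + phi * c;
    out[i] = c;
  }
  return out;
}
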