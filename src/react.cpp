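#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Exact closed-form update of the two-species mass-action pair
// Ca + B <-> CaB over dt (constant-coefficient Riccati ODE for free Ca with
// the pair invariant S = Ca + CaB). Conserves S to machine precision and
// preserves positivity for any dt.
// [[Rcpp::export]]
List react_pair_cpp(NumericVector ca, NumericVector bound, double total,
                    double k_on, double k_off, double dt) {
  int n = ca.size();
  NumericVector ca1(n), b1(n);
  double KD = k_off / k_on;
  for (int i = 0; i < n; ++i) {
    double S = ca[i] + bound[i];
    double p = total - S + KD;
    double q = KD * S;
    double disc = std::sqrt(p * p + 4.0 * q);
    double rp = 0.5 * (-p + disc);
    double rn = 0.5 * (-p - disc);
    double denom = ca[i] - rn;
    double u = denom > 0 ? (ca[i] - rp) / denom * std::exp(-k_on * disc * dt)
                         : 0.0;
    double c1 = (rp - rn * u) / (1.0 - u);
    ca1[i] = c1;
    b1[i] = S - c1;
  }
  return List::create(_["ca"] = ca1, _["bound"] = b1);
}
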