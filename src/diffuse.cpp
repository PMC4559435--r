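#include <Rcpp.h>
using namespace Rcpp;

// One explicit finite-volume diffusion step on the voxel domain.
// f: field values on the N domain voxels. nbr: N x 6 matrix of 1-based
// neighbour indices into f (0 where the face is closed: outer boundary or a
// mitochondrion). coef[k] = D * dt / h_k^2 for the axis of face k
// (faces ordered -x,+x,-y,+y,-z,+z). Zero-flux faces contribute nothing,
// which makes the scheme conservative by construction.
// [[Rcpp::export]]
NumericVector diffuse_step_cpp(NumericVector f, IntegerMatrix nbr,
                               NumericVector coef) {
  int n = f.size();
  NumericVector out(n);
  const int* nb = INTEGER(nbr);
  for (int i = 0; i < n; ++i) {
    double fi = f[i];
    double acc = fi;
    for (int k = 0; k < 6; ++k) {
      int j = nb[(R_xlen_t)k * n + i];
      if (j > 0) acc += coef[k] * (f[j - 1] - fi);
    }
    out[i] = acc;
  }
  return out;
}
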