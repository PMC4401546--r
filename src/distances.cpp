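#include <Rcpp.h>
using namespace Rcpp;

// Minimum Euclidean distance from each target point to the nearest point of
// each neighbour group. Brute force O(n_target * n_pool): the exhaustive
// computation is the defining contract; at census scales (1e2-1e3 targets,
// 1e4-1e5 pool) it stays well inside interactive budgets.
//
// group is 1-based (R factor codes). Groups with no points get R_PosInf.
// [[Rcpp::export]]
NumericMatrix cpp_min_dist_by_group(NumericVector tx, NumericVector ty,
                                    NumericVector px, NumericVector py,
                                    IntegerVector group, int ngroups) {
  const int nt = tx.size(), np = px.size();
  NumericMatrix out(nt, ngroups);
  std::fill(out.begin(), out.end(), R_PosInf);
  for (int i = 0; i < nt; ++i) {
    const double xi = tx[i], yi = ty[i];
    for (int j = 0; j < np; ++j) {
      const double dx = px[j] - xi, dy = py[j] - yi;
      const double d2 = dx * dx + dy * dy;
      const int g = group[j] - 1;
      if (d2 < out(i, g)) out(i, g) = d2;
    }
  }
  for (int i = 0; i < nt; ++i)
    for (int g = 0; g < ngroups; ++g)
      if (out(i, g) < R_PosInf) out(i, g) = std::sqrt(out(i, g));
  return out;
}

// Epanechnikov kernel sum over points, evaluated at a grid of cell centres.
// k_R(d) = max(0, 1 - (d/R)^2); normalisation is applied in R afterwards.
// [[Rcpp::export]]
NumericVector cpp_kernel_sum(NumericVector cx, NumericVector cy,
                             NumericVector px, NumericVector py,
                             double bandwidth) {
  const int nc = cx.size(), np = px.size();
  const double R2 = bandwidth * bandwidth;
  NumericVector out(nc);
  for (int i = 0; i < nc; ++i) {
    double s = 0.0;
    for (int j = 0; j < np; ++j) {
      const double dx = px[j] - cx[i], dy = py[j] - cy[i];
      const double d2 = dx * dx + dy * dy;
      if (d2 < R2) s += 1.0 - d2 / R2;
    }
    out[i] = s;
  }
  return out;
}
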