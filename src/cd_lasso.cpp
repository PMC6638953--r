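#include <Rcpp.h>
using namespace Rcpp;

// Pathwise coordinate descent for the lasso in Gram ("covariance") form.
//
// Minimizes (1/(2n)) ||y - X b||^2 + lambda * sum_i pf_i |b_i| given
// G = X'X and xy = X'y, over a decreasing lambda path with warm starts and
// active-set cycling. Cost per coordinate update is O(p), independent of
// n, which is what makes the resampling modules (bootstrap accuracy,
// case-dropping stability) affordable. A non-finite penalty factor
// excludes the predictor.
//
// [[Rcpp::export]]
NumericMatrix cd_lasso_path(NumericMatrix G, NumericVector xy, double n,
                            NumericVector lambda, NumericVector pf,
                            double tol = 1e-6, int max_sweeps = 10000) {
  const int p = xy.size();
  const int nl = lambda.size();
  NumericMatrix beta(p, nl);
  std::vector<double> b(p, 0.0);
  std::vector<double> gb(p, 0.0); // gb[i] = (G b)[i]
  std::vector<bool> eligible(p), in_active(p, false);
  std::vector<int> active;
  active.reserve(p);
  for (int i = 0; i < p; ++i) eligible[i] = R_finite(pf[i]);

  auto update_coord = [&](int i, double lam) -> double {
    const double gii = G(i, i);
    if (gii <= 0) return 0.0;
    const double z = (xy[i] - gb[i] + gii * b[i]) / n;
    const double thr = lam * pf[i];
    double bn = 0.0;
    if (z > thr) bn = (z - thr) / (gii / n);
    else if (z < -thr) bn = (z + thr) / (gii / n);
    const double del = bn - b[i];
    if (del != 0.0) {
      for (int j = 0; j < p; ++j) gb[j] += G(j, i) * del;
      b[i] = bn;
      if (!in_active[i]) {
        in_active[i] = true;
        active.push_back(i);
      }
    }
    return std::fabs(del);
  };

  for (int l = 0; l < nl; ++l) {
    const double lam = lambda[l];
    int sweeps = 0;
    for (;;) {
      // full sweep over eligible coordinates
      double maxdel = 0.0;
      for (int i = 0; i < p; ++i) {
        if (!eligible[i]) continue;
        maxdel = std::max(maxdel, update_coord(i, lam));
      }
      if (maxdel < tol || ++sweeps >= max_sweeps) break;
      // iterate the active set to convergence
      for (;;) {
        double ad = 0.0;
        for (size_t a = 0; a < active.size(); ++a) {
          ad = std::max(ad, update_coord(active[a], lam));
        }
        if (ad < tol || ++sweeps >= max_sweeps) break;
      }
      if (sweeps >= max_sweeps) break;
    }
    for (int i = 0; i < p; ++i) beta(i, l) = b[i];
  }
  return beta;
}
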