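#include <Rcpp.h>
using namespace Rcpp;

// Dual coordinate descent for the L1-loss (hinge) linear SVM,
//   min_w 0.5 ||w||^2 + sum_i C_i max(0, 1 - y_i w.x_i),
// solved in the dual with per-instance costs C_i (class weighting).
// Rows are given in CSR form; the bias is handled by the caller as an
// appended constant-one column. Internal xorshift RNG keeps the row
// permutation deterministic for a given seed, independent of R's RNG.

static inline uint32_t xorshift32(uint32_t &s) {
  s ^= s << 13; s ^= s >> 17; s ^= s << 5;
  return s;
}

// [[Rcpp::export(name = ".dcd_svm")]]
List dcd_svm(IntegerVector row_ptr, IntegerVector col_idx, NumericVector xval,
             int n, int d, NumericVector y, NumericVector cost,
             int max_epochs, double tol, int seed) {
  std::vector<double> w(d, 0.0), alpha(n, 0.0), qii(n, 0.0);
  std::vector<int> order(n);
  for (int i = 0; i < n; ++i) {
    order[i] = i;
    double q = 0.0;
    for (int k = row_ptr[i]; k < row_ptr[i + 1]; ++k) q += xval[k] * xval[k];
    qii[i] = q;
  }
  uint32_t rng = (uint32_t)seed; if (rng == 0) rng = 88172645u;
  int epoch = 0;
  for (epoch = 0; epoch < max_epochs; ++epoch) {
    // Fisher-Yates shuffle of the visiting order
    for (int i = n - 1; i > 0; --i) {
      int j = (int)(xorshift32(rng) % (uint32_t)(i + 1));
      std::swap(order[i], order[j]);
    }
    double pg_max = -1e300, pg_min = 1e300;
    for (int t = 0; t < n; ++t) {
      int i = order[t];
      if (qii[i] <= 0.0) continue;
      double g = 0.0;
      for (int k = row_ptr[i]; k < row_ptr[i + 1]; ++k)
        g += w[col_idx[k]] * xval[k];
      g = g * y[i] - 1.0;                       // gradient of dual
      double pg = g;                            // projected gradient
      if (alpha[i] <= 0.0) pg = std::min(g, 0.0);
      else if (alpha[i] >= cost[i]) pg = std::max(g, 0.0);
      if (pg > pg_max) pg_max = pg;
      if (pg < pg_min) pg_min = pg;
      if (std::fabs(pg) > 1e-12) {
        double a_old = alpha[i];
        double a_new = std::min(std::max(a_old - g / qii[i], 0.0), (double)cost[i]);
        alpha[i] = a_new;
        double delta = (a_new - a_old) * y[i];
        if (delta != 0.0)
          for (int k = row_ptr[i]; k < row_ptr[i + 1]; ++k)
            w[col_idx[k]] += delta * xval[k];
      }
    }
    if (pg_max - pg_min < tol) { ++epoch; break; }
  }
  return List::create(_["w"] = NumericVector(w.begin(), w.end()),
                      _["alpha"] = NumericVector(alpha.begin(), alpha.end()),
                      _["epochs"] = epoch);
}
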