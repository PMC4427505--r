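#include <Rcpp.h>
using namespace Rcpp;

// Dual coordinate descent for the L2-regularized L1-loss (hinge) linear SVM,
// the standard large-scale solver for this model (Hsieh et al., ICML 2008).
// The bias is handled by augmenting each example with a constant feature, so
// it is regularized like the weights. Examples are visited in a randomly
// permuted order per epoch using R's RNG (reproducible under set.seed).
//
// Solves: min_w 1/2 ||w||^2 + C * sum_i max(0, 1 - y_i w'x~_i)
// via its dual with box constraints 0 <= alpha_i <= C.
// [[Rcpp::export(name = ".svm_dcd")]]
List svm_dcd(NumericMatrix x, NumericVector y, double C, double bias_scale,
             double tol, int max_epochs) {
  const int n = x.nrow();
  const int d = x.ncol();
  const int da = d + 1; // augmented with bias feature

  std::vector<double> w(da, 0.0);
  std::vector<double> alpha(n, 0.0);
  std::vector<double> qd(n); // diagonal of the Gram matrix
  for (int i = 0; i < n; ++i) {
    double s = bias_scale * bias_scale;
    for (int j = 0; j < d; ++j) s += x(i, j) * x(i, j);
    qd[i] = s;
  }

  IntegerVector idx = seq_len(n) - 1;
  int epochs = 0;
  bool converged = false;
  for (epochs = 0; epochs < max_epochs; ++epochs) {
    idx = sample(idx, n, false);
    double max_pg = 0.0;
    for (int k = 0; k < n; ++k) {
      int i = idx[k];
      double dot = w[d] * bias_scale;
      for (int j = 0; j < d; ++j) dot += w[j] * x(i, j);
      double g = y[i] * dot - 1.0;
      double pg = g;
      if (alpha[i] <= 0.0 && g > 0.0) pg = 0.0;
      if (alpha[i] >= C && g < 0.0) pg = 0.0;
      if (std::fabs(pg) > max_pg) max_pg = std::fabs(pg);
      if (pg != 0.0 && qd[i] > 0.0) {
        double a_old = alpha[i];
        double a_new = std::min(std::max(a_old - g / qd[i], 0.0), C);
        alpha[i] = a_new;
        double delta = (a_new - a_old) * y[i];
        if (delta != 0.0) {
          for (int j = 0; j < d; ++j) w[j] += delta * x(i, j);
          w[d] += delta * bias_scale;
        }
      }
    }
    if (max_pg < tol) {
      converged = true;
      break;
    }
  }

  NumericVector weights(d);
  for (int j = 0; j < d; ++j) weights[j] = w[j];
  return List::create(
    _["weights"] = weights,
    _["bias"] = w[d] * bias_scale,
    _["converged"] = converged,
    _["epochs"] = epochs + 1
  );
}
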