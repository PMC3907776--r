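#include <Rcpp.h>
#include <algorithm>
#include <cmath>
using namespace Rcpp;

// For each query interval [lo[q], hi[q]] over a mass-sorted peak list, return
// the 1-based index of the peak with the largest `value`; 0 when the interval
// holds no peak. Ties keep the lowest-mass peak (first index).
// [[Rcpp::export]]
IntegerVector cpp_interval_max_idx(NumericVector mass, NumericVector value,
                                   NumericVector lo, NumericVector hi) {
  const int n = mass.size(), q = lo.size();
  IntegerVector out(q);
  for (int i = 0; i < q; ++i) {
    int first = std::lower_bound(mass.begin(), mass.end(), lo[i]) - mass.begin();
    int best = -1;
    double bestv = -1.0;
    for (int j = first; j < n && mass[j] <= hi[i]; ++j) {
      if (value[j] > bestv) { bestv = value[j]; best = j; }
    }
    out[i] = best + 1;
  }
  return out;
}

static inline double sigmoid(double z) { return 1.0 / (1.0 + std::exp(-z)); }

// One epoch of per-instance stochastic gradient descent with momentum for a
// 3-layer network (input -> sigmoid hidden -> 3 sigmoid outputs) under the
// summed per-node binary cross-entropy objective. `order` gives the 1-based
// instance visiting order. Returns updated parameters, momentum buffers and
// the mean pre-update cross-entropy over the epoch.
// [[Rcpp::export]]
List cpp_backprop_epoch(NumericMatrix W1_, NumericVector b1_,
                        NumericMatrix W2_, NumericVector b2_,
                        NumericMatrix vW1_, NumericVector vb1_,
                        NumericMatrix vW2_, NumericVector vb2_,
                        NumericMatrix X, NumericMatrix T,
                        IntegerVector order, double lr, double momentum) {
  NumericMatrix W1 = clone(W1_), W2 = clone(W2_), vW1 = clone(vW1_), vW2 = clone(vW2_);
  NumericVector b1 = clone(b1_), b2 = clone(b2_), vb1 = clone(vb1_), vb2 = clone(vb2_);
  const int d = W1.ncol(), h = W1.nrow(), o = W2.nrow(), n = order.size();
  if (X.ncol() != d || T.ncol() != o || W2.ncol() != h)
    stop("dimension mismatch in backprop epoch");
  std::vector<double> hid(h), out(o), d2(o), d1(h);
  const double eps = 1e-12;
  double total_err = 0.0;
  for (int s = 0; s < n; ++s) {
    const int i = order[s] - 1;
    // forward
    for (int j = 0; j < h; ++j) {
      double z = b1[j];
      for (int k = 0; k < d; ++k) z += W1(j, k) * X(i, k);
      hid[j] = sigmoid(z);
    }
    for (int m = 0; m < o; ++m) {
      double z = b2[m];
      for (int j = 0; j < h; ++j) z += W2(m, j) * hid[j];
      out[m] = sigmoid(z);
    }
    for (int m = 0; m < o; ++m) {
      double om = std::min(1.0 - eps, std::max(eps, out[m]));
      total_err -= T(i, m) * std::log(om) + (1.0 - T(i, m)) * std::log(1.0 - om);
      d2[m] = out[m] - T(i, m);  // dE/dz2 for sigmoid + cross-entropy
    }
    for (int j = 0; j < h; ++j) {
      double acc = 0.0;
      for (int m = 0; m < o; ++m) acc += W2(m, j) * d2[m];
      d1[j] = acc * hid[j] * (1.0 - hid[j]);
    }
    // momentum update
    for (int m = 0; m < o; ++m) {
      for (int j = 0; j < h; ++j) {
        vW2(m, j) = momentum * vW2(m, j) - lr * d2[m] * hid[j];
        W2(m, j) += vW2(m, j);
      }
      vb2[m] = momentum * vb2[m] - lr * d2[m];
      b2[m] += vb2[m];
    }
    for (int j = 0; j < h; ++j) {
      for (int k = 0; k < d; ++k) {
        vW1(j, k) = momentum * vW1(j, k) - lr * d1[j] * X(i, k);
        W1(j, k) += vW1(j, k);
      }
      vb1[j] = momentum * vb1[j] - lr * d1[j];
      b1[j] += vb1[j];
    }
    if (!std::isfinite(total_err))
      stop("non-finite training error at instance %d", i + 1);
  }
  return List::create(_["W1"] = W1, _["b1"] = b1, _["W2"] = W2, _["b2"] = b2,
                      _["vW1"] = vW1, _["vb1"] = vb1, _["vW2"] = vW2, _["vb2"] = vb2,
                      _["mean_error"] = n ? total_err / n : 0.0);
}
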