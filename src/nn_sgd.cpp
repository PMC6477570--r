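#include <Rcpp.h>
using namespace Rcpp;

// Direct-form II transposed linear filter with explicit initial state.
// [[Rcpp::export]]
NumericVector df2t_filter(NumericVector b, NumericVector a, NumericVector x,
                          NumericVector zi) {
  int n = x.size();
  int nf = b.size();          // b and a padded to equal length in R
  std::vector<double> z(zi.begin(), zi.end());
  z.resize(nf - 1, 0.0);
  NumericVector y(n);
  for (int i = 0; i < n; ++i) {
    double xi = x[i];
    double yi = b[0] * xi + (nf > 1 ? z[0] : 0.0);
    for (int j = 0; j < nf - 2; ++j)
      z[j] = b[j + 1] * xi + z[j + 1] - a[j + 1] * yi;
    if (nf > 1)
      z[nf - 2] = b[nf - 1] * xi - a[nf - 1] * yi;
    y[i] = yi;
  }
  return y;
}

// Windowed local maxima: sample i is a peak iff it beats every other sample
// in the centered window of half-width h (truncated at the edges); ties are
// broken toward the earlier sample (an equal later sample does not
// disqualify, an equal-or-greater earlier one does).
// [[Rcpp::export]]
LogicalVector local_maxima(NumericVector x, int h) {
  int n = x.size();
  LogicalVector out(n);
  for (int i = 0; i < n; ++i) {
    bool peak = true;
    int lo = std::max(0, i - h), hi = std::min(n - 1, i + h);
    for (int j = lo; j <= hi && peak; ++j) {
      if (j == i) continue;
      if (j < i ? x[j] >= x[i] : x[j] > x[i]) peak = false;
    }
    out[i] = peak;
  }
  return out;
}

static inline double sigmoid(double v) { return 1.0 / (1.0 + std::exp(-v)); }

// Per-sample SGD training of a single-hidden-layer sigmoid network with one
// sigmoid output and binary cross-entropy loss. X is n x d (z-scored in R),
// y in {0,1}. 'order' is an n x epochs matrix of 1-based visit orders
// produced in R from the seed, so the kernel itself is deterministic.
// Weights are updated in place and returned.
// [[Rcpp::export]]
List nn_sgd_train(NumericMatrix X, IntegerVector y, NumericMatrix W1,
                  NumericVector b1, NumericVector W2, double b2,
                  IntegerMatrix order, double lr) {
  int n = X.nrow(), d = X.ncol(), h = W1.ncol();
  int epochs = order.ncol();
  const double *Xp = X.begin();      // n x d, column-major
  double *W1p = W1.begin();          // d x h, column-major
  double *b1p = b1.begin(), *W2p = W2.begin();
  const int *ordp = order.begin();
  std::vector<double> hid(h), xrow(d);
  for (int e = 0; e < epochs; ++e) {
    const int *oe = ordp + (size_t)e * n;
    for (int s = 0; s < n; ++s) {
      int i = oe[s] - 1;
      for (int j = 0; j < d; ++j) xrow[j] = Xp[i + (size_t)n * j];
      // forward: each W1 column is contiguous
      for (int k = 0; k < h; ++k) {
        const double *w = W1p + (size_t)d * k;
        double acc = b1p[k];
        for (int j = 0; j < d; ++j) acc += xrow[j] * w[j];
        hid[k] = sigmoid(acc);
      }
      double out = b2;
      for (int k = 0; k < h; ++k) out += hid[k] * W2p[k];
      out = sigmoid(out);
      // backward: d(BCE)/d(pre-activation of output) = out - y
      double delta = out - (double)y[i];
      double lrd = lr * delta;
      for (int k = 0; k < h; ++k) {
        double dh = delta * W2p[k] * hid[k] * (1.0 - hid[k]);
        double lrdh = lr * dh;
        W2p[k] -= lrd * hid[k];
        double *w = W1p + (size_t)d * k;
        for (int j = 0; j < d; ++j) w[j] -= lrdh * xrow[j];
        b1p[k] -= lrdh;
      }
      b2 -= lrd;
    }
  }
  return List::create(_["W1"] = W1, _["b1"] = b1, _["W2"] = W2, _["b2"] = b2);
}

// Forward pass: returns P(class 1) for each row of X.
// [[Rcpp::export]]
NumericVector nn_forward(NumericMatrix X, NumericMatrix W1, NumericVector b1,
                         NumericVector W2, double b2) {
  int n = X.nrow(), d = X.ncol(), h = W1.ncol();
  NumericVector p(n);
  for (int i = 0; i < n; ++i) {
    double out = b2;
    for (int k = 0; k < h; ++k) {
      double acc = b1[k];
      for (int j = 0; j < d; ++j) acc += X(i, j) * W1(j, k);
      out += sigmoid(acc) * W2[k];
    }
    p[i] = sigmoid(out);
  }
  return p;
}
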