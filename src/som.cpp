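#include <Rcpp.h>
using namespace Rcpp;

// Online self-organising map with bubble neighbourhood.
//
// x:      data matrix (samples x dims)
// codes:  initial codebook (units x dims), modified copy returned
// order:  0-based presentation order, one row per epoch (epochs x samples)
// gx, gy: unit coordinates on the map grid
// alpha0: initial learning rate, linear decay to 0 over all steps
// radius0: initial neighbourhood radius (grid Euclidean distance),
//          linear decay to 0; the bubble update moves every unit whose
//          grid distance to the BMU is <= current radius by the full
//          learning rate.
// [[Rcpp::export(name = ".som_train_cpp")]]
NumericMatrix som_train_cpp(NumericMatrix x, NumericMatrix codes,
                            IntegerMatrix order, NumericVector gx,
                            NumericVector gy, double alpha0,
                            double radius0) {
  int n = x.nrow(), d = x.ncol(), k = codes.nrow();
  int epochs = order.nrow();
  NumericMatrix w = clone(codes);
  double total = (double) epochs * n;
  double step = 0.0;
  for (int e = 0; e < epochs; ++e) {
    for (int s = 0; s < n; ++s, ++step) {
      int i = order(e, s);
      double frac = 1.0 - step / total;
      double alpha = alpha0 * frac;
      double radius = radius0 * frac;
      // best-matching unit (ties -> lowest index)
      int bmu = 0;
      double best = R_PosInf;
      for (int u = 0; u < k; ++u) {
        double dist = 0.0;
        for (int j = 0; j < d; ++j) {
          double diff = x(i, j) - w(u, j);
          dist += diff * diff;
        }
        if (dist < best) { best = dist; bmu = u; }
      }
      for (int u = 0; u < k; ++u) {
        double dgx = gx[u] - gx[bmu], dgy = gy[u] - gy[bmu];
        if (std::sqrt(dgx * dgx + dgy * dgy) <= radius) {
          for (int j = 0; j < d; ++j)
            w(u, j) += alpha * (x(i, j) - w(u, j));
        }
      }
    }
  }
  return w;
}

// Nearest codebook unit per sample, 1-based, ties -> lowest index.
// [[Rcpp::export(name = ".som_map_cpp")]]
IntegerVector som_map_cpp(NumericMatrix x, NumericMatrix codes) {
  int n = x.nrow(), d = x.ncol(), k = codes.nrow();
  IntegerVector out(n);
  for (int i = 0; i < n; ++i) {
    int bmu = 0;
    double best = R_PosInf;
    for (int u = 0; u < k; ++u) {
      double dist = 0.0;
      for (int j = 0; j < d; ++j) {
        double diff = x(i, j) - codes(u, j);
        dist += diff * diff;
      }
      if (dist < best) { best = dist; bmu = u; }
    }
    out[i] = bmu + 1;
  }
  return out;
}
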