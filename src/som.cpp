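// Sequential multilayer self-organizing map core.
//
// Data and codebooks are passed transposed (features x observations /
// features x units, column-major) so the inner loops walk contiguous
// memory.  The BMU criterion is the layer-weighted squared Euclidean
// distance sum_l w_l * ||x_l - m_l||^2; the update is the classic online
// rule m += alpha * h * (x - m) applied to every layer of every unit whose
// Gaussian neighborhood factor h = exp(-d_grid^2 / (2 sigma^2)) exceeds
// 1e-12 (h below that is skipped; at sigma = 0 only the BMU moves).

#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

static inline int find_bmu(const double* x, const double* M, int p, int u,
                           const int* lstart, const int* llen, int nl,
                           const double* w, double* bestd) {
  int bmu = 0;
  double best = R_PosInf;
  for (int k = 0; k < u; ++k) {
    const double* m = M + (size_t)k * p;
    double d = 0.0;
    for (int l = 0; l < nl; ++l) {
      double dl = 0.0;
      const int s = lstart[l], e = lstart[l] + llen[l];
      for (int j = s; j < e; ++j) {
        const double diff = x[j] - m[j];
        dl += diff * diff;
      }
      d += w[l] * dl;
    }
    if (d < best) { best = d; bmu = k; }
  }
  *bestd = best;
  return bmu;
}

// [[Rcpp::export(name = ".som_train_cpp")]]
NumericMatrix som_train_cpp(NumericMatrix Xt, NumericMatrix Mt,
                            IntegerVector layer_start, IntegerVector layer_len,
                            NumericVector layer_w, NumericMatrix grid_d2,
                            IntegerMatrix orders, double lr_start,
                            double lr_end, double sigma_start) {
  const int p = Xt.nrow(), n = Xt.ncol(), u = Mt.ncol();
  const int nl = layer_start.size();
  const int epochs = orders.nrow();
  NumericMatrix M = clone(Mt);
  const double* X = Xt.begin();
  double* Mp = M.begin();
  const int* ls = layer_start.begin();
  const int* ll = layer_len.begin();
  const double* w = layer_w.begin();
  const double* G = grid_d2.begin();
  const double total = (double)epochs * n;
  const double denom = total > 1 ? total - 1 : 1;
  const double log_eps = std::log(1e-12);

  long step = 0;
  double bestd;
  for (int e = 0; e < epochs; ++e) {
    for (int s = 0; s < n; ++s, ++step) {
      const int i = orders(e, s);          // 0-based observation index
      const double* x = X + (size_t)i * p;
      const double frac = step / denom;
      const double alpha = lr_start + (lr_end - lr_start) * frac;
      const double sigma = sigma_start * (1.0 - frac);
      const int bmu = find_bmu(x, Mp, p, u, ls, ll, nl, w, &bestd);
      if (sigma <= 0.0) {
        double* m = Mp + (size_t)bmu * p;
        for (int j = 0; j < p; ++j) m[j] += alpha * (x[j] - m[j]);
        continue;
      }
      const double inv2s2 = 1.0 / (2.0 * sigma * sigma);
      const double thr = -log_eps / inv2s2;  // skip units with h < 1e-12
      const double* grow = G + (size_t)bmu * u;
      for (int k = 0; k < u; ++k) {
        const double d2 = grow[k];
        if (d2 > thr) continue;
        const double h = std::exp(-d2 * inv2s2);
        const double ah = alpha * h;
        double* m = Mp + (size_t)k * p;
        for (int j = 0; j < p; ++j) m[j] += ah * (x[j] - m[j]);
      }
    }
  }
  return M;
}

// [[Rcpp::export(name = ".som_map_cpp")]]
List som_map_cpp(NumericMatrix Xt, NumericMatrix Mt,
                 IntegerVector layer_start, IntegerVector layer_len,
                 NumericVector layer_w) {
  const int p = Xt.nrow(), n = Xt.ncol(), u = Mt.ncol();
  const int nl = layer_start.size();
  IntegerVector bmu(n);
  NumericVector dist(n);
  const double* X = Xt.begin();
  const double* M = Mt.begin();
  double bestd;
  for (int i = 0; i < n; ++i) {
    const int b = find_bmu(X + (size_t)i * p, M, p, u, layer_start.begin(),
                           layer_len.begin(), nl, layer_w.begin(), &bestd);
    bmu[i] = b + 1;                         // 1-based for R
    dist[i] = std::sqrt(bestd);
  }
  return List::create(_["unit"] = bmu, _["dist"] = dist);
  (void)u;
}
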