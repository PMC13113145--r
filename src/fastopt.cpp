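// Hot optimizer kernels: fused Adam update on the flat parameter vector
// and scatter back into the per-tensor matrices. Called once per training
// step; everything else stays in R.

#include <Rcpp.h>
using namespace Rcpp;

// In-place fused Adam step with optional global-norm clipping and EMA
// accumulation. `flat`, `m`, `v` and `ema` are modified in place; the
// caller owns them exclusively.
// [[Rcpp::export]]
void adam_update_(NumericVector flat, NumericVector grad,
                  NumericVector m, NumericVector v, NumericVector ema,
                  double lr, int t, double beta1, double beta2,
                  double eps, double clip_norm, double ema_decay) {
  R_xlen_t n = flat.size();
  double scale = 1.0;
  if (clip_norm > 0) {
    double ss = 0.0;
    for (R_xlen_t i = 0; i < n; ++i) ss += grad[i] * grad[i];
    double gn = std::sqrt(ss);
    if (gn > clip_norm) scale = clip_norm / gn;
  }
  const double c1 = 1.0 - std::pow(beta1, t);
  const double c2 = 1.0 - std::pow(beta2, t);
  const bool do_ema = ema_decay > 0 && ema.size() == n;
  for (R_xlen_t i = 0; i < n; ++i) {
    const double g = grad[i] * scale;
    m[i] = beta1 * m[i] + (1.0 - beta1) * g;
    v[i] = beta2 * v[i] + (1.0 - beta2) * g * g;
    flat[i] -= lr * (m[i] / c1) / (std::sqrt(v[i] / c2) + eps);
    if (do_ema) ema[i] = ema_decay * ema[i] + (1.0 - ema_decay) * flat[i];
  }
}

// Scatter the flat vector back into a list of matrices, in place. The
// matrices must be exclusively owned by the training loop.
// [[Rcpp::export]]
void scatter_params_(NumericVector flat, List params) {
  R_xlen_t off = 0;
  for (R_xlen_t k = 0; k < params.size(); ++k) {
    NumericMatrix mkk = params[k];
    R_xlen_t len = mkk.size();
    std::copy(flat.begin() + off, flat.begin() + off + len, mkk.begin());
    off += len;
  }
}

// Gather per-tensor gradients (NULL entries become zeros) into `out`;
// `lens` gives each tensor's length.
// [[Rcpp::export]]
void gather_grads_(List grads, IntegerVector lens, NumericVector out) {
  R_xlen_t off = 0;
  for (R_xlen_t k = 0; k < grads.size(); ++k) {
    RObject g = grads[k];
    if (g.isNULL()) {
      std::fill(out.begin() + off, out.begin() + off + lens[k], 0.0);
    } else {
      NumericMatrix gm(g);
      std::copy(gm.begin(), gm.end(), out.begin() + off);
    }
    off += lens[k];
  }
}
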