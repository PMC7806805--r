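// Single-threaded reference trainer: skip-gram with negative sampling over a
// walk corpus, plus a lambda-weighted chemical-structure-prediction (CSP)
// head that backpropagates mean binary cross-entropy over 881 fingerprint
// bits into both the head weights and the center embedding.  Deterministic
// given the seed: one mt19937_64 stream drives initialization and sampling.
#include <Rcpp.h>
#include <R_ext/BLAS.h>
#include <random>
#include <vector>
#include <cmath>
#include <algorithm>
using namespace Rcpp;

static const double CLIP = 30.0; // logit clip before exp/log

static inline double unif01(std::mt19937_64 &rng) {
  return (rng() >> 11) * (1.0 / 9007199254740992.0);
}

static inline double clipd(double x) {
  return x > CLIP ? CLIP : (x < -CLIP ? -CLIP : x);
}

static inline double sigmoid(double x) {
  return 1.0 / (1.0 + std::exp(-clipd(x)));
}

// draw a token index from the cumulative distribution, excluding `excl`
static int draw_negative(std::mt19937_64 &rng, const std::vector<double> &cum,
                         int excl) {
  int V = (int)cum.size();
  for (int tries = 0; tries < 100; ++tries) {
    double u = unif01(rng);
    int idx = (int)(std::upper_bound(cum.begin(), cum.end(), u) - cum.begin());
    if (idx >= V) idx = V - 1;
    if (idx != excl) return idx;
  }
  return (excl + 1) % V; // degenerate distribution fallback
}

// One CSP step on center vector x (length d).  W is column-major d x D
// (one column per fingerprint bit); BLAS does the three dense sweeps:
//   z = W^T x + b;  gx = W g;  W <- W - lr * x g^T.
// Returns lambda * mean BCE.
static double csp_step(double *x, std::vector<double> &W,
                       std::vector<double> &b, const int *y, int D, int d,
                       double lr, double lambda, std::vector<double> &z,
                       std::vector<double> &g, std::vector<double> &gx) {
  const double one = 1.0, zero = 0.0, neg_lr = -lr;
  const int inc = 1;
  std::copy(b.begin(), b.end(), z.begin());
  F77_CALL(dgemv)("T", &d, &D, &one, W.data(), &d, x, &inc, &one,
                  z.data(), &inc FCONE);
  double loss = 0.0;
  for (int dd = 0; dd < D; ++dd) {
    double p = sigmoid(z[dd]);
    loss += y[dd] ? -std::log(p) : -std::log(1.0 - p);
    g[dd] = lambda * (p - (double)y[dd]) / D;
  }
  F77_CALL(dgemv)("N", &d, &D, &one, W.data(), &d, g.data(), &inc, &zero,
                  gx.data(), &inc FCONE);
  F77_CALL(dger)(&d, &D, &neg_lr, x, &inc, g.data(), &inc, W.data(), &d);
  for (int dd = 0; dd < D; ++dd) b[dd] -= lr * g[dd];
  for (int j = 0; j < d; ++j) x[j] -= lr * gx[j];
  return lambda * loss / D;
}

// [[Rcpp::export]]
List train_cpp(IntegerVector tokens, IntegerVector offsets, int V, int d,
               int window, int M, double lambda, int epochs, double lr0,
               double lr_min, NumericVector neg_cum, IntegerVector fp_row,
               IntegerMatrix Y, bool use_csp, bool csp_per_epoch, int seed) {
  std::mt19937_64 rng((uint64_t)(uint32_t)seed);
  int D = Y.ncol();

  // initialization order is fixed (center, then CSP weights) so that runs
  // with and without the CSP head consume identical RNG prefixes
  std::vector<double> center((size_t)V * d), context((size_t)V * d, 0.0);
  for (size_t i = 0; i < center.size(); ++i)
    center[i] = (unif01(rng) - 0.5) / d;
  std::vector<double> W((size_t)D * d), b(D, 0.0);
  double xavier = std::sqrt(6.0 / (d + D));
  for (int dd = 0; dd < D; ++dd) // column dd of the d x D weight matrix
    for (int j = 0; j < d; ++j)
      W[(size_t)dd * d + j] = (2.0 * unif01(rng) - 1.0) * xavier;

  std::vector<double> cum(neg_cum.begin(), neg_cum.end());
  std::vector<int> fpr(fp_row.begin(), fp_row.end());
  std::vector<std::vector<int> > ybuf(Y.nrow());
  for (int r = 0; r < Y.nrow(); ++r) {
    ybuf[r].resize(D);
    for (int dd = 0; dd < D; ++dd) ybuf[r][dd] = Y(r, dd);
  }

  long n_tokens = tokens.size();
  long total_positions = (long)epochs * n_tokens;
  bool csp_active = use_csp && lambda > 0.0 && Y.nrow() > 0;

  std::vector<double> acc(d), zbuf(std::max(D, 1)), gbuf(std::max(D, 1)),
      gx(d);
  NumericVector epoch_losses(epochs);
  long n_pair_updates = 0;
  long t = 0;
  int n_walks = offsets.size() - 1;

  for (int e = 0; e < epochs; ++e) {
    double loss_sum = 0.0;
    long loss_n = 0;
    double lr = lr0;
    for (int wk = 0; wk < n_walks; ++wk) {
      int lo = offsets[wk], hi = offsets[wk + 1];
      for (int i = lo; i < hi; ++i) {
        lr = lr0 * (1.0 - (double)t / total_positions);
        if (lr < lr_min) lr = lr_min;
        ++t;
        int u = tokens[i];
        double *xu = &center[(size_t)u * d];

        if (csp_active && !csp_per_epoch && fpr[u] >= 0) {
          loss_sum += csp_step(xu, W, b, ybuf[fpr[u]].data(), D, d, lr,
                               lambda, zbuf, gbuf, gx);
          ++loss_n;
        }

        int jlo = std::max(lo, i - window), jhi = std::min(hi - 1, i + window);
        for (int j = jlo; j <= jhi; ++j) {
          if (j == i) continue;
          int c = tokens[j];
          double *xc = &context[(size_t)c * d];
          std::fill(acc.begin(), acc.end(), 0.0);

          // positive pair: sigma(context_c . center_u)
          double dot = 0.0;
          for (int k = 0; k < d; ++k) dot += xc[k] * xu[k];
          double s = sigmoid(dot);
          loss_sum += -std::log(s);
          double g = s - 1.0;
          for (int k = 0; k < d; ++k) {
            double xu_old = xu[k];
            acc[k] += g * xu_old;
            xu[k] = xu_old - lr * g * xc[k];
          }

          // M negatives: sigma(-center_neg . context_c)
          for (int m = 0; m < M; ++m) {
            int n = draw_negative(rng, cum, c);
            double *xn = &center[(size_t)n * d];
            double dn = 0.0;
            for (int k = 0; k < d; ++k) dn += xn[k] * xc[k];
            double s2 = sigmoid(dn);
            loss_sum += -std::log(sigmoid(-dn));
            for (int k = 0; k < d; ++k) {
              double xn_old = xn[k];
              acc[k] += s2 * xn_old;
              xn[k] = xn_old - lr * s2 * xc[k];
            }
          }
          for (int k = 0; k < d; ++k) xc[k] -= lr * acc[k];
          ++n_pair_updates;
          ++loss_n;
        }
      }
    }
    if (csp_active && csp_per_epoch) {
      for (int u = 0; u < V; ++u) {
        if (fpr[u] >= 0) {
          loss_sum += csp_step(&center[(size_t)u * d], W, b,
                               ybuf[fpr[u]].data(), D, d, lr, lambda,
                               zbuf, gbuf, gx);
          ++loss_n;
        }
      }
    }
    epoch_losses[e] = loss_n ? loss_sum / loss_n : 0.0;
  }

  NumericMatrix center_out(V, d), context_out(V, d), W_out(d, D);
  for (int v = 0; v < V; ++v)
    for (int k = 0; k < d; ++k) {
      center_out(v, k) = center[(size_t)v * d + k];
      context_out(v, k) = context[(size_t)v * d + k];
    }
  std::copy(W.begin(), W.end(), W_out.begin()); // both column-major d x D
  return List::create(
    _["center"] = center_out, _["context"] = context_out,
    _["csp_weights"] = W_out, _["csp_bias"] = NumericVector(b.begin(), b.end()),
    _["n_pair_updates"] = (double)n_pair_updates,
    _["epoch_losses"] = epoch_losses);
}
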