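// Training core for the two-hidden-layer MLP bioactivity classifier.
// Minibatch Adam on binary cross-entropy; ReLU hidden units, inverted
// dropout between the hidden layers, sigmoid output. All randomness
// (weight init, shuffling, dropout masks) is drawn from R's RNG so a
// single set.seed() on the R side makes training bit-reproducible.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static arma::mat r_randn(int nr, int nc, double sd) {
  arma::mat m(nr, nc);
  for (arma::uword j = 0; j < m.n_cols; ++j)
    for (arma::uword i = 0; i < m.n_rows; ++i)
      m(i, j) = norm_rand() * sd;
  return m;
}

struct AdamState {
  arma::mat mW, vW;
  arma::rowvec mb, vb;
  AdamState(int nin, int nout)
      : mW(nin, nout, arma::fill::zeros), vW(nin, nout, arma::fill::zeros),
        mb(nout, arma::fill::zeros), vb(nout, arma::fill::zeros) {}
};

// One fused pass per parameter array keeps the update memory-bound at the
// minimum number of reads/writes; this is the training hot spot.
static void adam_apply(double* w, double* m, double* v, const double* g,
                       arma::uword len, double lr_t, double eps_t,
                       double beta1, double beta2) {
  const double c1 = 1.0 - beta1, c2 = 1.0 - beta2;
  for (arma::uword i = 0; i < len; ++i) {
    const double gi = g[i];
    const double mi = (m[i] = beta1 * m[i] + c1 * gi);
    const double vi = (v[i] = beta2 * v[i] + c2 * gi * gi);
    w[i] -= lr_t * mi / (std::sqrt(vi) + eps_t);
  }
}

static void adam_step(arma::mat& W, arma::rowvec& b, AdamState& st,
                      const arma::mat& gW, const arma::rowvec& gb,
                      double lr, long t, double beta1, double beta2,
                      double eps) {
  const double c1 = 1.0 - std::pow(beta1, (double)t);
  const double c2 = 1.0 - std::pow(beta2, (double)t);
  const double lr_t = lr * std::sqrt(c2) / c1;
  const double eps_t = eps * std::sqrt(c2);
  adam_apply(W.memptr(), st.mW.memptr(), st.vW.memptr(), gW.memptr(),
             W.n_elem, lr_t, eps_t, beta1, beta2);
  adam_apply(b.memptr(), st.mb.memptr(), st.vb.memptr(), gb.memptr(),
             b.n_elem, lr_t, eps_t, beta1, beta2);
}

// [[Rcpp::export(name = ".mlp_train_core")]]
List mlp_train_core(const arma::mat& X, const arma::vec& y, int h1, int h2,
                    double dropout, double lr, int epochs, int batch_size) {
  const int n = X.n_rows, d = X.n_cols;
  RNGScope scope;  // sync with R's RNG

  arma::mat W1 = r_randn(d, h1, std::sqrt(2.0 / d));
  arma::mat W2 = r_randn(h1, h2, std::sqrt(2.0 / h1));
  arma::mat W3 = r_randn(h2, 1, std::sqrt(2.0 / h2));
  arma::rowvec b1(h1, arma::fill::zeros), b2(h2, arma::fill::zeros),
      b3(1, arma::fill::zeros);
  AdamState s1(d, h1), s2(h1, h2), s3(h2, 1);

  arma::vec loss_trace(epochs, arma::fill::zeros);
  std::vector<int> perm(n);
  long t_step = 0;
  const double beta1 = 0.9, beta2 = 0.999, eps = 1e-8, tiny = 1e-12;

  for (int epoch = 0; epoch < epochs; ++epoch) {
    for (int i = 0; i < n; ++i) perm[i] = i;
    // Fisher-Yates with R's RNG (matches sample.int semantics closely
    // enough for our purposes: deterministic given the seed)
    for (int i = n - 1; i > 0; --i) {
      int j = (int)(unif_rand() * (i + 1));
      if (j > i) j = i;
      std::swap(perm[i], perm[j]);
    }
    double epoch_loss = 0.0;
    for (int start = 0; start < n; start += batch_size) {
      const int end = std::min(start + batch_size, n) - 1;
      const int m = end - start + 1;
      arma::uvec idx(m);
      for (int i = 0; i < m; ++i) idx[i] = perm[start + i];
      arma::mat xb = X.rows(idx);
      arma::vec yb = y.elem(idx);

      arma::mat z1 = xb * W1;
      z1.each_row() += b1;
      arma::mat a1 = arma::clamp(z1, 0.0, arma::datum::inf);
      arma::mat a1d = a1;
      arma::mat mask;
      if (dropout > 0) {
        mask.set_size(a1.n_rows, a1.n_cols);
        const double keep = 1.0 - dropout;
        for (arma::uword j = 0; j < mask.n_cols; ++j)
          for (arma::uword i = 0; i < mask.n_rows; ++i)
            mask(i, j) = (unif_rand() >= dropout) ? 1.0 / keep : 0.0;
        a1d %= mask;
      }
      arma::mat z2 = a1d * W2;
      z2.each_row() += b2;
      arma::mat a2 = arma::clamp(z2, 0.0, arma::datum::inf);
      arma::mat z3 = a2 * W3;
      z3.each_row() += b3;
      arma::vec p = 1.0 / (1.0 + arma::exp(-z3.col(0)));

      epoch_loss -= arma::accu(yb % arma::log(p + tiny) +
                               (1.0 - yb) % arma::log(1.0 - p + tiny));

      arma::mat d3 = (p - yb) / (double)m;  // BCE + sigmoid
      arma::mat gW3 = a2.t() * d3;
      arma::rowvec gb3 = arma::sum(d3, 0);
      arma::mat d2 = (d3 * W3.t()) %
          arma::conv_to<arma::mat>::from(z2 > 0);
      arma::mat gW2 = a1d.t() * d2;
      arma::rowvec gb2 = arma::sum(d2, 0);
      arma::mat d1 = d2 * W2.t();
      if (dropout > 0) d1 %= mask;
      d1 %= arma::conv_to<arma::mat>::from(z1 > 0);
      arma::mat gW1 = xb.t() * d1;
      arma::rowvec gb1 = arma::sum(d1, 0);

      ++t_step;
      adam_step(W1, b1, s1, gW1, gb1, lr, t_step, beta1, beta2, eps);
      adam_step(W2, b2, s2, gW2, gb2, lr, t_step, beta1, beta2, eps);
      adam_step(W3, b3, s3, gW3, gb3, lr, t_step, beta1, beta2, eps);
    }
    loss_trace[epoch] = epoch_loss / n;
  }

  return List::create(
      _["W1"] = W1, _["b1"] = arma::vec(b1.t()),
      _["W2"] = W2, _["b2"] = arma::vec(b2.t()),
      _["W3"] = W3, _["b3"] = arma::vec(b3.t()),
      _["loss_trace"] = loss_trace);
}
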