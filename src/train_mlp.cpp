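// Mini-batch SGD with momentum for the fully connected classifier.
// Shuffling and dropout masks draw from R's RNG so training is
// reproducible from set.seed() on the R side.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// [[Rcpp::export]]
List cpp_train_mlp(List W_in, List b_in, const arma::mat& X,
                   const arma::ivec& y, int epochs, int batch_size,
                   double lr0, double lr_decay, int lr_step,
                   double momentum, double dropout_rate,
                   const arma::ivec& dropout_layers) {
  const int nlayers = W_in.size();
  std::vector<arma::mat> W(nlayers), vW(nlayers);
  std::vector<arma::rowvec> b(nlayers), vb(nlayers);
  for (int k = 0; k < nlayers; ++k) {
    W[k] = as<arma::mat>(W_in[k]);
    b[k] = as<arma::rowvec>(b_in[k]);
    vW[k].zeros(W[k].n_rows, W[k].n_cols);
    vb[k].zeros(b[k].n_elem);
  }
  std::vector<bool> drop(nlayers, false);
  for (arma::uword i = 0; i < dropout_layers.n_elem; ++i) {
    int l = dropout_layers[i];
    if (l >= 1 && l <= nlayers) drop[l - 1] = true;
  }
  const int n = X.n_rows;
  arma::mat Y(n, 2, arma::fill::zeros);
  for (int i = 0; i < n; ++i) Y(i, y[i]) = 1.0;

  NumericVector loss_hist(epochs), lr_hist(epochs);
  const double keep = 1.0 - dropout_rate;

  for (int epoch = 0; epoch < epochs; ++epoch) {
    const double lr = lr0 * std::pow(lr_decay, epoch / lr_step);
    // Fisher-Yates shuffle driven by R's RNG
    arma::uvec ord(n);
    for (int i = 0; i < n; ++i) ord[i] = i;
    for (int i = n - 1; i > 0; --i) {
      int j = (int)std::floor(R::unif_rand() * (i + 1));
      std::swap(ord[i], ord[j]);
    }
    double total_loss = 0.0;
    for (int s = 0; s < n; s += batch_size) {
      const int e = std::min(s + batch_size, n) - 1;
      arma::uvec idx = ord.subvec(s, e);
      arma::mat A = X.rows(idx);
      std::vector<arma::mat> inputs(nlayers), masks(nlayers);
      for (int k = 0; k < nlayers; ++k) {
        inputs[k] = A;
        arma::mat Z = A * W[k];
        Z.each_row() += b[k];
        if (k < nlayers - 1) {
          A = Z;
          A.elem(arma::find(Z < 0)).zeros();
          if (dropout_rate > 0 && drop[k]) {
            arma::mat M(A.n_rows, A.n_cols);
            for (arma::uword ii = 0; ii < M.n_elem; ++ii) {
              M[ii] = (R::unif_rand() < keep) ? 1.0 / keep : 0.0;
            }
            A %= M;
            masks[k] = M;
          }
        } else {
          arma::vec zmax = arma::max(Z, 1);
          Z.each_col() -= zmax;
          arma::mat E = arma::exp(Z);
          arma::vec rs = arma::sum(E, 1);
          E.each_col() /= rs;
          A = E;
        }
      }
      arma::mat Yb = Y.rows(idx);
      total_loss += -arma::accu(Yb % arma::log(A + 1e-12));
      arma::mat delta = (A - Yb) / (double)idx.n_elem;
      for (int k = nlayers - 1; k >= 0; --k) {
        arma::mat gW = inputs[k].t() * delta;
        arma::rowvec gb = arma::sum(delta, 0);
        if (k > 0) {
          arma::mat dA = delta * W[k].t();
          if (masks[k - 1].n_elem > 0) dA %= masks[k - 1];
          delta = dA % arma::conv_to<arma::mat>::from(inputs[k] > 0);
        }
        vW[k] = momentum * vW[k] - lr * gW;
        vb[k] = momentum * vb[k] - lr * gb;
        W[k] += vW[k];
        b[k] += vb[k];
      }
    }
    loss_hist[epoch] = total_loss / n;
    lr_hist[epoch] = lr;
  }
  List Wout(nlayers), bout(nlayers);
  for (int k = 0; k < nlayers; ++k) {
    Wout[k] = wrap(W[k]);
    bout[k] = NumericVector(b[k].begin(), b[k].end());
  }
  return List::create(_["W"] = Wout, _["b"] = bout,
                      _["loss"] = loss_hist, _["lr"] = lr_hist);
}

// T stochastic forward passes with dropout kept on; returns an
// (n x 2 x T) cube of class probabilities. Masks draw from R's RNG.
// [[Rcpp::export]]
arma::cube cpp_mc_forward(List W_in, List b_in, const arma::mat& X, int T,
                          double dropout_rate,
                          const arma::ivec& dropout_layers) {
  const int nlayers = W_in.size();
  std::vector<arma::mat> W(nlayers);
  std::vector<arma::rowvec> b(nlayers);
  for (int k = 0; k < nlayers; ++k) {
    W[k] = as<arma::mat>(W_in[k]);
    b[k] = as<arma::rowvec>(b_in[k]);
  }
  std::vector<bool> drop(nlayers, false);
  for (arma::uword i = 0; i < dropout_layers.n_elem; ++i) {
    int l = dropout_layers[i];
    if (l >= 1 && l <= nlayers) drop[l - 1] = true;
  }
  const double keep = 1.0 - dropout_rate;
  arma::cube out(X.n_rows, 2, T);
  for (int t = 0; t < T; ++t) {
    arma::mat A = X;
    for (int k = 0; k < nlayers; ++k) {
      arma::mat Z = A * W[k];
      Z.each_row() += b[k];
      if (k < nlayers - 1) {
        A = Z;
        A.elem(arma::find(Z < 0)).zeros();
        if (dropout_rate > 0 && drop[k]) {
          for (arma::uword ii = 0; ii < A.n_elem; ++ii) {
            A[ii] *= (R::unif_rand() < keep) ? 1.0 / keep : 0.0;
          }
        }
      } else {
        arma::vec zmax = arma::max(Z, 1);
        Z.each_col() -= zmax;
        arma::mat E = arma::exp(Z);
        arma::vec rs = arma::sum(E, 1);
        E.each_col() /= rs;
        A = E;
      }
    }
    out.slice(t) = A;
  }
  return out;
}
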