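// Minibatch Adagrad trainer for the bottleneck autoencoder.
// Weight init and epoch shuffle orders are produced in R (seeded there),
// so the C++ loop is fully deterministic given its inputs.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static arma::mat forward_pass(const arma::mat& X,
                              const std::vector<arma::mat>& W,
                              const std::vector<arma::rowvec>& b,
                              std::vector<arma::mat>* acts) {
  const int L = static_cast<int>(W.size());
  arma::mat a = X;
  if (acts) (*acts)[0] = a;
  for (int l = 0; l < L; ++l) {
    arma::mat z = a * W[l];
    z.each_row() += b[l];
    if (l < L - 1) z = arma::clamp(z, 0.0, arma::datum::inf);  // ReLU hidden
    a = z;                                                     // linear output
    if (acts) (*acts)[l + 1] = a;
  }
  return a;
}

// [[Rcpp::export]]
List ae_train_cpp(const arma::mat& X, List weights, List biases,
                  int epochs, int batch_size, double learning_rate,
                  const arma::umat& orders, double adagrad_eps) {
  const int L = weights.size();
  const arma::uword n = X.n_rows;
  const double d = static_cast<double>(X.n_cols);

  std::vector<arma::mat> W(L);
  std::vector<arma::rowvec> b(L);
  std::vector<arma::mat> GW(L);
  std::vector<arma::rowvec> Gb(L);
  for (int l = 0; l < L; ++l) {
    W[l] = as<arma::mat>(weights[l]);
    b[l] = as<arma::rowvec>(biases[l]);
    GW[l].zeros(W[l].n_rows, W[l].n_cols);
    Gb[l].zeros(b[l].n_cols);
  }

  arma::vec loss_curve(epochs);
  std::vector<arma::mat> acts(L + 1);

  for (int e = 0; e < epochs; ++e) {
    const arma::uvec order = orders.col(e);
    double sse = 0.0;  // sum over frames of per-element squared error
    for (arma::uword start = 0; start < n; start += batch_size) {
      const arma::uword stop = std::min(n, start + static_cast<arma::uword>(batch_size));
      const arma::uvec idx = order.subvec(start, stop - 1);
      const arma::mat Xb = X.rows(idx);
      const double m = static_cast<double>(Xb.n_rows);

      arma::mat Yhat = forward_pass(Xb, W, b, &acts);
      arma::mat diff = Yhat - Xb;
      sse += arma::accu(arma::square(diff));

      // backprop: loss = mean over batch and dims of squared error
      arma::mat delta = (2.0 / (m * d)) * diff;
      for (int l = L - 1; l >= 0; --l) {
        arma::mat gW = acts[l].t() * delta;
        arma::rowvec gb = arma::sum(delta, 0);
        if (l > 0) {
          delta = delta * W[l].t();
          delta.elem(arma::find(acts[l] <= 0.0)).zeros();  // ReLU mask
        }
        GW[l] += arma::square(gW);
        Gb[l] += arma::square(gb);
        W[l] -= learning_rate * gW / (arma::sqrt(GW[l]) + adagrad_eps);
        b[l] -= learning_rate * gb / (arma::sqrt(Gb[l]) + adagrad_eps);
      }
    }
    const double epoch_loss = sse / (static_cast<double>(n) * d);
    if (!std::isfinite(epoch_loss)) {
      stop("divergence: non-finite training loss at epoch %d", e + 1);
    }
    loss_curve(e) = epoch_loss;
  }

  List Wout(L), bout(L);
  for (int l = 0; l < L; ++l) { Wout[l] = W[l]; bout[l] = b[l]; }
  return List::create(_["weights"] = Wout, _["biases"] = bout,
                      _["loss_curve"] = loss_curve);
}

// [[Rcpp::export]]
arma::mat ae_forward_cpp(const arma::mat& X, List weights, List biases) {
  const int L = weights.size();
  std::vector<arma::mat> W(L);
  std::vector<arma::rowvec> b(L);
  for (int l = 0; l < L; ++l) {
    W[l] = as<arma::mat>(weights[l]);
    b[l] = as<arma::rowvec>(biases[l]);
  }
  return forward_pass(X, W, b, nullptr);
}
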