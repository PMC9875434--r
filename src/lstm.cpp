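// LSTM binary classifier: the feature vector is unrolled as T timesteps
// of one feature each, followed by two ReLU fully connected layers,
// dropout, and a 2-class softmax. Trained with Adam on categorical
// cross-entropy, early stopping on validation loss, best weights kept.
// Seeded and single-threaded for reproducibility.
#include <RcppArmadillo.h>
#include <random>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;
using arma::mat;
using arma::rowvec;
using arma::uword;

struct Net {
  mat Wx, Wh, W1, W2, W3;
  rowvec b, b1, b2, b3;
};

static List net_to_list(const Net& n) {
  return List::create(_["Wx"] = n.Wx, _["Wh"] = n.Wh, _["b"] = n.b,
                      _["W1"] = n.W1, _["b1"] = n.b1,
                      _["W2"] = n.W2, _["b2"] = n.b2,
                      _["W3"] = n.W3, _["b3"] = n.b3);
}

static Net net_from_list(const List& l) {
  Net n;
  n.Wx = as<mat>(l["Wx"]); n.Wh = as<mat>(l["Wh"]); n.b = as<rowvec>(l["b"]);
  n.W1 = as<mat>(l["W1"]); n.b1 = as<rowvec>(l["b1"]);
  n.W2 = as<mat>(l["W2"]); n.b2 = as<rowvec>(l["b2"]);
  n.W3 = as<mat>(l["W3"]); n.b3 = as<rowvec>(l["b3"]);
  return n;
}

static inline mat sigm(const mat& x) { return 1.0 / (1.0 + arma::exp(-x)); }

// forward pass without dropout; returns class probabilities (B x 2)
static mat net_forward(const Net& net, const mat& X) {
  const uword B = X.n_rows, T = X.n_cols, U = net.Wh.n_rows;
  mat H(B, U, arma::fill::zeros), C(B, U, arma::fill::zeros);
  for (uword t = 0; t < T; ++t) {
    mat Z = X.col(t) * net.Wx + H * net.Wh;
    Z.each_row() += net.b;
    mat I = sigm(Z.cols(0, U - 1));
    mat F = sigm(Z.cols(U, 2 * U - 1));
    mat O = sigm(Z.cols(2 * U, 3 * U - 1));
    mat G = arma::tanh(Z.cols(3 * U, 4 * U - 1));
    C = F % C + I % G;
    H = O % arma::tanh(C);
  }
  mat A1 = H * net.W1; A1.each_row() += net.b1; A1 = arma::clamp(A1, 0.0, arma::datum::inf);
  mat A2 = A1 * net.W2; A2.each_row() += net.b2; A2 = arma::clamp(A2, 0.0, arma::datum::inf);
  mat Z3 = A2 * net.W3; Z3.each_row() += net.b3;
  Z3.each_col() -= arma::max(Z3, 1);
  mat E = arma::exp(Z3);
  E.each_col() /= arma::sum(E, 1);
  return E;
}

static double mean_ce(const mat& P, const arma::ivec& y) {
  double s = 0.0;
  for (uword i = 0; i < P.n_rows; ++i)
    s += -std::log(std::max(P(i, (uword)y[i]), 1e-12));
  return s / P.n_rows;
}

static double acc_of(const mat& P, const arma::ivec& y) {
  double s = 0.0;
  for (uword i = 0; i < P.n_rows; ++i)
    s += ((P(i, 1) >= P(i, 0)) ? 1 : 0) == y[i];
  return s / P.n_rows;
}

struct Adam {
  std::vector<mat> m, v;
  double b1 = 0.9, b2 = 0.999, eps = 1e-8;
  long t = 0;
  void init(const std::vector<mat*>& params) {
    for (auto p : params) {
      m.push_back(mat(p->n_rows, p->n_cols, arma::fill::zeros));
      v.push_back(mat(p->n_rows, p->n_cols, arma::fill::zeros));
    }
  }
  void step(std::vector<mat*>& params, const std::vector<mat>& grads, double lr) {
    ++t;
    const double c1 = 1.0 - std::pow(b1, t), c2 = 1.0 - std::pow(b2, t);
    for (size_t i = 0; i < params.size(); ++i) {
      m[i] = b1 * m[i] + (1 - b1) * grads[i];
      v[i] = b2 * v[i] + (1 - b2) * arma::square(grads[i]);
      *params[i] -= lr * (m[i] / c1) / (arma::sqrt(v[i] / c2) + eps);
    }
  }
};

// [[Rcpp::export]]
List slp_lstm_train(const arma::mat& Xtr, const arma::ivec& ytr,
                    const arma::mat& Xval, const arma::ivec& yval,
                    int units, int fc1, int fc2, double dropout,
                    double lr, int max_epochs, int patience,
                    int batch_size, int seed) {
  const uword n = Xtr.n_rows, T = Xtr.n_cols;
  const uword U = (uword)units;
  std::mt19937_64 rng(static_cast<uint64_t>(seed) * 2654435761ULL + 1ULL);
  std::uniform_real_distribution<double> unif(0.0, 1.0);
  auto runif_mat = [&](uword r, uword c, double lim) {
    mat M(r, c);
    for (uword j = 0; j < c; ++j)
      for (uword i = 0; i < r; ++i) M(i, j) = (unif(rng) * 2 - 1) * lim;
    return M;
  };

  Net net;
  net.Wx = runif_mat(1, 4 * U, std::sqrt(6.0 / (1 + U)));
  net.Wh = runif_mat(U, 4 * U, std::sqrt(6.0 / (2.0 * U)));
  net.b = rowvec(4 * U, arma::fill::zeros);
  net.b.subvec(U, 2 * U - 1).fill(1.0);  // forget-gate bias
  net.W1 = runif_mat(U, fc1, std::sqrt(6.0 / (U + fc1)));
  net.b1 = rowvec(fc1, arma::fill::zeros);
  net.W2 = runif_mat(fc1, fc2, std::sqrt(6.0 / (fc1 + (double)fc2)));
  net.b2 = rowvec(fc2, arma::fill::zeros);
  net.W3 = runif_mat(fc2, 2, std::sqrt(6.0 / (fc2 + 2.0)));
  net.b3 = rowvec(2, arma::fill::zeros);

  // biases as 1-row mats for the shared Adam updater
  mat b_ = net.b, b1_ = net.b1, b2_ = net.b2, b3_ = net.b3;
  std::vector<mat*> params = {&net.Wx, &net.Wh, &b_, &net.W1, &b1_,
                              &net.W2, &b2_, &net.W3, &b3_};
  Adam adam; adam.init(params);

  std::vector<uword> perm(n);
  for (uword i = 0; i < n; ++i) perm[i] = i;

  double best_val = arma::datum::inf;
  Net best = net;
  int best_epoch = 0, wait = 0, epochs_run = 0;
  std::vector<double> h_train, h_val, h_vacc;

  for (int ep = 1; ep <= max_epochs; ++ep) {
    std::shuffle(perm.begin(), perm.end(), rng);
    double ep_loss = 0.0; uword ep_n = 0;
    for (uword start = 0; start < n; start += batch_size) {
      const uword stop_ = std::min<uword>(start + batch_size, n) - 1;
      const uword B = stop_ - start + 1;
      arma::uvec idx(B);
      for (uword i = 0; i < B; ++i) idx[i] = perm[start + i];
      mat X = Xtr.rows(idx);
      arma::ivec y(B);
      for (uword i = 0; i < B; ++i) y[i] = ytr[idx[i]];

      net.b = b_; net.b1 = b1_; net.b2 = b2_; net.b3 = b3_;

      // forward with caches
      arma::cube cI(B, U, T), cF(B, U, T), cO(B, U, T), cG(B, U, T),
        cC(B, U, T), cHprev(B, U, T);
      mat H(B, U, arma::fill::zeros), C(B, U, arma::fill::zeros);
      for (uword t = 0; t < T; ++t) {
        cHprev.slice(t) = H;
        mat Z = X.col(t) * net.Wx + H * net.Wh;
        Z.each_row() += net.b;
        mat I = sigm(Z.cols(0, U - 1));
        mat F = sigm(Z.cols(U, 2 * U - 1));
        mat O = sigm(Z.cols(2 * U, 3 * U - 1));
        mat G = arma::tanh(Z.cols(3 * U, 4 * U - 1));
        mat Cprev = C;
        C = F % Cprev + I % G;
        H = O % arma::tanh(C);
        cI.slice(t) = I; cF.slice(t) = F; cO.slice(t) = O; cG.slice(t) = G;
        cC.slice(t) = C;
      }
      mat Z1 = H * net.W1; Z1.each_row() += net.b1;
      mat A1 = arma::clamp(Z1, 0.0, arma::datum::inf);
      mat Z2 = A1 * net.W2; Z2.each_row() += net.b2;
      mat A2 = arma::clamp(Z2, 0.0, arma::datum::inf);
      mat M(B, A2.n_cols, arma::fill::ones);
      if (dropout > 0) {
        for (uword j = 0; j < M.n_cols; ++j)
          for (uword i = 0; i < B; ++i)
            M(i, j) = (unif(rng) < dropout) ? 0.0 : 1.0 / (1.0 - dropout);
      }
      mat A2d = A2 % M;
      mat Z3 = A2d * net.W3; Z3.each_row() += net.b3;
      Z3.each_col() -= arma::max(Z3, 1);
      mat P = arma::exp(Z3);
      P.each_col() /= arma::sum(P, 1);
      double loss = mean_ce(P, y);
      if (!std::isfinite(loss))
        stop("training diverged (non-finite loss) at epoch %d", ep);
      ep_loss += loss * B; ep_n += B;

      // backward
      mat dZ3 = P;
      for (uword i = 0; i < B; ++i) dZ3(i, (uword)y[i]) -= 1.0;
      dZ3 /= (double)B;
      mat gW3 = A2d.t() * dZ3;
      mat gb3 = arma::sum(dZ3, 0);
      mat dA2 = (dZ3 * net.W3.t()) % M;
      mat dZ2 = dA2 % arma::conv_to<mat>::from(Z2 > 0.0);
      mat gW2 = A1.t() * dZ2;
      mat gb2 = arma::sum(dZ2, 0);
      mat dZ1 = (dZ2 * net.W2.t()) % arma::conv_to<mat>::from(Z1 > 0.0);
      mat gW1 = H.t() * dZ1;
      mat gb1 = arma::sum(dZ1, 0);
      mat dH = dZ1 * net.W1.t();

      mat gWx(1, 4 * U, arma::fill::zeros), gWh(U, 4 * U, arma::fill::zeros);
      mat gb(1, 4 * U, arma::fill::zeros);
      mat dC(B, U, arma::fill::zeros);
      for (uword t = T; t-- > 0;) {
        const mat& I = cI.slice(t); const mat& F = cF.slice(t);
        const mat& O = cO.slice(t); const mat& G = cG.slice(t);
        mat tC = arma::tanh(cC.slice(t));
        mat Cprev = (t == 0) ? mat(B, U, arma::fill::zeros)
                             : cC.slice(t - 1);
        mat dO = dH % tC;
        dC += dH % O % (1.0 - tC % tC);
        mat dI = dC % G, dG = dC % I, dF = dC % Cprev;
        mat dCprev = dC % F;
        mat dZ(B, 4 * U);
        dZ.cols(0, U - 1) = dI % I % (1.0 - I);
        dZ.cols(U, 2 * U - 1) = dF % F % (1.0 - F);
        dZ.cols(2 * U, 3 * U - 1) = dO % O % (1.0 - O);
        dZ.cols(3 * U, 4 * U - 1) = dG % (1.0 - G % G);
        gWx += X.col(t).t() * dZ;
        gWh += cHprev.slice(t).t() * dZ;
        gb += arma::sum(dZ, 0);
        dH = dZ * net.Wh.t();
        dC = dCprev;
      }

      std::vector<mat> grads = {gWx, gWh, gb, gW1, gb1, gW2, gb2, gW3, gb3};
      adam.step(params, grads, lr);
    }
    net.b = b_; net.b1 = b1_; net.b2 = b2_; net.b3 = b3_;
    mat Pval = net_forward(net, Xval);
    double vloss = mean_ce(Pval, yval);
    h_train.push_back(ep_loss / ep_n);
    h_val.push_back(vloss);
    h_vacc.push_back(acc_of(Pval, yval));
    epochs_run = ep;
    if (vloss < best_val - 1e-6) {
      best_val = vloss; best = net; best_epoch = ep; wait = 0;
    } else if (++wait >= patience) break;
  }

  mat Ptr = net_forward(best, Xtr);
  mat Pval = net_forward(best, Xval);
  return List::create(
    _["weights"] = net_to_list(best),
    _["best_epoch"] = best_epoch,
    _["epochs_run"] = epochs_run,
    _["train_acc"] = acc_of(Ptr, ytr),
    _["val_acc"] = acc_of(Pval, yval),
    _["val_loss"] = best_val,
    _["history"] = DataFrame::create(_["epoch"] = seq_len(epochs_run),
                                     _["train_loss"] = h_train,
                                     _["val_loss"] = h_val,
                                     _["val_acc"] = h_vacc));
}

// [[Rcpp::export]]
arma::mat slp_lstm_predict(const arma::mat& X, List weights) {
  Net net = net_from_list(weights);
  const uword n = X.n_rows, chunk = 2048;
  mat out(n, 2);
  for (uword start = 0; start < n; start += chunk) {
    uword stop_ = std::min(start + chunk, n) - 1;
    out.rows(start, stop_) = net_forward(net, X.rows(start, stop_));
  }
  return out;
}
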