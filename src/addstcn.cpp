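// Attention-based dilated depthwise-separable temporal convolutional network
// (one network per target series). Full-batch training with Adam; analytic
// gradients. All randomness (initial weights, permutations) is generated on
// the R side so results are reproducible through R's RNG alone.
//
// Architecture, for N input series of length T and target index j:
//   - input row j is pre-shifted right by one step so the autoregressive
//     channel only sees x_j[.. t-1] while exogenous channels see x_i[.. t];
//   - attention vector a (length N) multiplies each input series;
//   - L+1 depthwise causal convolutions, kernel size K, dilation c^l at
//     layer l (zero left-padding), PReLU between layers, residual connection
//     after every layer except the first;
//   - pointwise 1x1 combination across channels yields the prediction.
// Loss is mean squared error over the T positions.
//
// Parameter vector layout (length N + (L+1)*N*K + (L+1)*N + L + N + 1):
//   [ a(N) | W_0..W_L (each N*K, channel-major: W[i*K + k]) |
//     b_0..b_L (each N) | alpha_1..alpha_L | v(N) | b_out ]
// Tap k = K-1 is the most recent input position.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

namespace {

struct Dims {
  int N, T, K, L, c;
  int n_par() const { return N + (L + 1) * N * K + (L + 1) * N + L + N + 1; }
  int off_W(int l) const { return N + l * N * K; }
  int off_b(int l) const { return N + (L + 1) * N * K + l * N; }
  int off_alpha() const { return N + (L + 1) * N * K + (L + 1) * N; }
  int off_v() const { return off_alpha() + L; }
  int off_bout() const { return off_v() + N; }
  int dil(int l) const {
    int d = 1;
    for (int q = 0; q < l; ++q) d *= c;
    return d;
  }
};

inline double prelu(double z, double alpha) { return z >= 0.0 ? z : alpha * z; }

// Forward pass; optionally accumulate analytic gradient.
// X is N x T (row j NOT yet shifted; shifting happens here).
double forward_backward(const arma::mat &X, int j, const arma::vec &par,
                        const Dims &dm, bool want_grad, arma::vec &grad,
                        arma::rowvec &yhat_out, bool att_softmax) {
  const int N = dm.N, T = dm.T, K = dm.K, L = dm.L;

  // shifted input: row j lagged by one
  arma::mat Xin = X;
  for (int t = T - 1; t >= 1; --t) Xin(j, t) = X(j, t - 1);
  if (T > 0) Xin(j, 0) = 0.0;

  const double *a = par.memptr();
  const double *v = par.memptr() + dm.off_v();
  const double b_out = par(dm.off_bout());

  // effective per-channel attention weights: either the raw scores or a
  // softmax competition over them (scaled by N so the uniform weight is 1)
  arma::vec aw(N);
  if (att_softmax) {
    double mx = par(0);
    for (int i = 1; i < N; ++i) mx = std::max(mx, par(i));
    double zsum = 0.0;
    for (int i = 0; i < N; ++i) {
      aw(i) = std::exp(par(i) - mx);
      zsum += aw(i);
    }
    aw *= (double)N / zsum;
  } else {
    for (int i = 0; i < N; ++i) aw(i) = a[i];
  }

  // U = attention-scaled input
  arma::mat U(N, T);
  for (int i = 0; i < N; ++i)
    for (int t = 0; t < T; ++t) U(i, t) = aw(i) * Xin(i, t);

  // Z[l], H[l] activations (H[l] feeds conv l, l>=1)
  std::vector<arma::mat> Z(L + 1), H(L + 1);
  for (int l = 0; l <= L; ++l) {
    const double *W = par.memptr() + dm.off_W(l);
    const double *b = par.memptr() + dm.off_b(l);
    const int d = dm.dil(l);
    if (l >= 1) {
      const double alpha = par(dm.off_alpha() + (l - 1));
      H[l].set_size(N, T);
      for (int i = 0; i < N; ++i)
        for (int t = 0; t < T; ++t) H[l](i, t) = prelu(Z[l - 1](i, t), alpha);
    }
    const arma::mat &src = (l == 0) ? U : H[l];
    Z[l].set_size(N, T);
    for (int i = 0; i < N; ++i) {
      for (int t = 0; t < T; ++t) {
        double s = b[i];
        for (int k = 0; k < K; ++k) {
          const int tt = t - (K - 1 - k) * d;
          if (tt >= 0) s += W[i * K + k] * src(i, tt);
        }
        if (l >= 1) s += Z[l - 1](i, t);  // residual
        Z[l](i, t) = s;
      }
    }
  }

  // pointwise output
  arma::rowvec yhat(T);
  for (int t = 0; t < T; ++t) {
    double s = b_out;
    for (int i = 0; i < N; ++i) s += v[i] * Z[L](i, t);
    yhat(t) = s;
  }
  yhat_out = yhat;

  double loss = 0.0;
  for (int t = 0; t < T; ++t) {
    const double e = yhat(t) - X(j, t);
    loss += e * e;
  }
  loss /= (double)T;

  if (!want_grad) return loss;

  grad.zeros(dm.n_par());
  arma::rowvec g(T);
  for (int t = 0; t < T; ++t) g(t) = 2.0 * (yhat(t) - X(j, t)) / (double)T;

  // output layer
  grad(dm.off_bout()) = arma::accu(g);
  for (int i = 0; i < N; ++i)
    grad(dm.off_v() + i) = arma::dot(g, Z[L].row(i));

  arma::mat dZ(N, T);
  for (int i = 0; i < N; ++i)
    for (int t = 0; t < T; ++t) dZ(i, t) = v[i] * g(t);

  for (int l = L; l >= 1; --l) {
    const double *W = par.memptr() + dm.off_W(l);
    const int d = dm.dil(l);
    const double alpha = par(dm.off_alpha() + (l - 1));

    double *gW = grad.memptr() + dm.off_W(l);
    double *gb = grad.memptr() + dm.off_b(l);
    for (int i = 0; i < N; ++i) {
      for (int t = 0; t < T; ++t) {
        const double dz = dZ(i, t);
        gb[i] += dz;
        for (int k = 0; k < K; ++k) {
          const int tt = t - (K - 1 - k) * d;
          if (tt >= 0) gW[i * K + k] += dz * H[l](i, tt);
        }
      }
    }
    // dH then fold into dZ[l-1] (activation path + residual path)
    arma::mat dH(N, T, arma::fill::zeros);
    for (int i = 0; i < N; ++i) {
      for (int t = 0; t < T; ++t) {
        const double dz = dZ(i, t);
        for (int k = 0; k < K; ++k) {
          const int tt = t - (K - 1 - k) * d;
          if (tt >= 0) dH(i, tt) += dz * W[i * K + k];
        }
      }
    }
    double galpha = 0.0;
    arma::mat dZprev(N, T);
    for (int i = 0; i < N; ++i) {
      for (int t = 0; t < T; ++t) {
        const double zprev = Z[l - 1](i, t);
        if (zprev < 0.0) galpha += dH(i, t) * zprev;
        dZprev(i, t) = dH(i, t) * (zprev >= 0.0 ? 1.0 : alpha) + dZ(i, t);
      }
    }
    grad(dm.off_alpha() + (l - 1)) += galpha;
    dZ = dZprev;
  }

  // layer 0: conv over U, then attention
  {
    const double *W = par.memptr() + dm.off_W(0);
    double *gW = grad.memptr() + dm.off_W(0);
    double *gb = grad.memptr() + dm.off_b(0);
    arma::mat dU(N, T, arma::fill::zeros);
    for (int i = 0; i < N; ++i) {
      for (int t = 0; t < T; ++t) {
        const double dz = dZ(i, t);
        gb[i] += dz;
        for (int k = 0; k < K; ++k) {
          const int tt = t - (K - 1 - k) * 1;
          if (tt >= 0) {
            gW[i * K + k] += dz * U(i, tt);
            dU(i, tt) += dz * W[i * K + k];
          }
        }
      }
    }
    arma::vec dAw(N);
    for (int i = 0; i < N; ++i) {
      double ga = 0.0;
      for (int t = 0; t < T; ++t) ga += dU(i, t) * Xin(i, t);
      dAw(i) = ga;
    }
    if (att_softmax) {
      // aw_i = N * s_i with s = softmax(a); d aw_i / d a_k = N * s_i * (delta_ik - s_k)
      arma::vec s = aw / (double)N;
      const double dot = arma::dot(dAw, aw);  // = N * sum_i dAw_i s_i
      for (int k = 0; k < N; ++k) grad(k) = dAw(k) * aw(k) - s(k) * dot;
    } else {
      for (int i = 0; i < N; ++i) grad(i) = dAw(i);
    }
  }
  return loss;
}

}  // namespace

// [[Rcpp::export(name = ".addstcn_loss_grad")]]
List addstcn_loss_grad(const arma::mat &X, int target1, const arma::vec &par,
                       int K, int c, int L, bool want_grad = true,
                       bool att_softmax = false) {
  Dims dm{(int)X.n_rows, (int)X.n_cols, K, L, c};
  if ((int)par.n_elem != dm.n_par())
    stop("parameter vector has length %d, expected %d", (int)par.n_elem,
         dm.n_par());
  const int j = target1 - 1;
  if (j < 0 || j >= dm.N) stop("target index out of range");
  arma::vec grad;
  arma::rowvec yhat;
  const double loss =
      forward_backward(X, j, par, dm, want_grad, grad, yhat, att_softmax);
  if (want_grad)
    return List::create(_["loss"] = loss, _["grad"] = grad,
                        _["yhat"] = yhat);
  return List::create(_["loss"] = loss, _["yhat"] = yhat);
}

// [[Rcpp::export(name = ".addstcn_fit")]]
List addstcn_fit(const arma::mat &X, int target1, const arma::vec &par0,
                 int K, int c, int L, int epochs, double lr,
                 bool att_softmax = false) {
  Dims dm{(int)X.n_rows, (int)X.n_cols, K, L, c};
  if ((int)par0.n_elem != dm.n_par())
    stop("parameter vector has length %d, expected %d", (int)par0.n_elem,
         dm.n_par());
  const int j = target1 - 1;
  if (j < 0 || j >= dm.N) stop("target index out of range");
  if (epochs < 1) stop("epochs must be >= 1");
  if (!X.is_finite()) stop("input series contain non-finite values");

  arma::vec par = par0;
  arma::vec m(dm.n_par(), arma::fill::zeros), v2(dm.n_par(), arma::fill::zeros);
  const double beta1 = 0.9, beta2 = 0.999, eps = 1e-8;

  double loss_first = NA_REAL, loss = NA_REAL;
  arma::vec grad;
  arma::rowvec yhat;
  for (int ep = 1; ep <= epochs; ++ep) {
    loss = forward_backward(X, j, par, dm, true, grad, yhat, att_softmax);
    if (ep == 1) loss_first = loss;
    // Adam
    for (int p = 0; p < dm.n_par(); ++p) {
      m(p) = beta1 * m(p) + (1.0 - beta1) * grad(p);
      v2(p) = beta2 * v2(p) + (1.0 - beta2) * grad(p) * grad(p);
      const double mhat = m(p) / (1.0 - std::pow(beta1, ep));
      const double vhat = v2(p) / (1.0 - std::pow(beta2, ep));
      par(p) -= lr * mhat / (std::sqrt(vhat) + eps);
    }
  }
  // final loss with trained weights
  const double loss_final =
      forward_backward(X, j, par, dm, false, grad, yhat, att_softmax);

  // effective attention weights actually applied to the inputs
  arma::vec aw(dm.N);
  if (att_softmax) {
    double mx = par(0);
    for (int i = 1; i < dm.N; ++i) mx = std::max(mx, par(i));
    double zsum = 0.0;
    for (int i = 0; i < dm.N; ++i) {
      aw(i) = std::exp(par(i) - mx);
      zsum += aw(i);
    }
    aw *= (double)dm.N / zsum;
  } else {
    for (int i = 0; i < dm.N; ++i) aw(i) = par(i);
  }

  return List::create(_["par"] = par, _["loss_first"] = loss_first,
                      _["loss_final"] = loss_final, _["yhat"] = yhat,
                      _["attention"] = aw);
}
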