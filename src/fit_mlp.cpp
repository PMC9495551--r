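// Minibatch Adam training of the fully connected sigmoid-output classifier
// (optional batch normalization after each hidden layer, ReLU activations,
// binary cross-entropy loss). All randomness (initial weights, shuffling
// orders) is generated on the R side and passed in, so the kernel itself is
// deterministic.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

namespace {

struct BnLayer {
  rowvec gamma, beta, rmean, rvar;
};

const double BN_EPS = 1e-5;

// inference-mode forward pass returning output probabilities
vec forward_infer(const std::vector<mat>& W, const std::vector<rowvec>& b,
                  const std::vector<BnLayer>& bn, bool use_bn,
                  const mat& X) {
  mat A = X;
  const size_t L = W.size();
  for (size_t l = 0; l < L; ++l) {
    mat Z = A * W[l];
    Z.each_row() += b[l];
    if (l + 1 < L) {
      if (use_bn) {
        Z.each_row() -= bn[l].rmean;
        Z.each_row() /= sqrt(bn[l].rvar + BN_EPS);
        Z.each_row() %= bn[l].gamma;
        Z.each_row() += bn[l].beta;
      }
      A = clamp(Z, 0.0, datum::inf);
    } else {
      A = 1.0 / (1.0 + exp(-Z));
    }
  }
  return A.col(0);
}

double bce(const vec& p, const vec& y) {
  vec pc = clamp(p, 1e-12, 1.0 - 1e-12);
  return -mean(y % log(pc) + (1.0 - y) % log(1.0 - pc));
}

double acc(const vec& p, const vec& y) {
  return mean(conv_to<vec>::from((p > 0.5) == (y > 0.5)));
}

struct Adam {
  mat mW, vW;
  Adam(size_t r, size_t c) : mW(r, c, fill::zeros), vW(r, c, fill::zeros) {}
  void step(mat& theta, const mat& g, double lr, double c1, double c2) {
    mW = 0.9 * mW + 0.1 * g;
    vW = 0.999 * vW + 0.001 * square(g);
    theta -= lr * (mW / c1) / (sqrt(vW / c2) + 1e-8);
  }
};

}  // namespace

// [[Rcpp::export(name = ".fit_mlp_cpp")]]
Rcpp::List fit_mlp_cpp(Rcpp::List W0, Rcpp::List b0, Rcpp::List bn0,
                       bool use_bn, const arma::mat& X, const arma::vec& y,
                       const arma::mat& Xval, const arma::vec& yval,
                       bool has_val, const arma::imat& order, int batch_size,
                       double lr, bool record) {
  const size_t L = W0.size();
  std::vector<mat> W(L);
  std::vector<rowvec> b(L);
  std::vector<BnLayer> bn(use_bn ? L - 1 : 0);
  for (size_t l = 0; l < L; ++l) {
    W[l] = Rcpp::as<mat>(W0[l]);
    b[l] = Rcpp::as<rowvec>(b0[l]);
  }
  if (use_bn) {
    for (size_t l = 0; l + 1 < L; ++l) {
      Rcpp::List p = bn0[l];
      bn[l].gamma = Rcpp::as<rowvec>(p["gamma"]);
      bn[l].beta = Rcpp::as<rowvec>(p["beta"]);
      bn[l].rmean = Rcpp::as<rowvec>(p["mean"]);
      bn[l].rvar = Rcpp::as<rowvec>(p["var"]);
    }
  }

  std::vector<Adam> aW, ab, ag, abeta;
  for (size_t l = 0; l < L; ++l) {
    aW.emplace_back(W[l].n_rows, W[l].n_cols);
    ab.emplace_back(1, b[l].n_elem);
  }
  for (size_t l = 0; l < bn.size(); ++l) {
    ag.emplace_back(1, bn[l].gamma.n_elem);
    abeta.emplace_back(1, bn[l].beta.n_elem);
  }

  const int epochs = order.n_rows;
  const int n = X.n_rows;
  mat history(std::max(epochs, 0), 4);
  history.fill(datum::nan);
  long t_step = 0;

  std::vector<mat> A(L + 1), Zs(L), xhat(L), dummy;
  std::vector<rowvec> mu(L), v(L);

  for (int epoch = 0; epoch < epochs; ++epoch) {
    for (int start = 0; start < n; start += batch_size) {
      const int stop = std::min(start + batch_size, n) - 1;
      const int m = stop - start + 1;
      if (m < 2) continue;
      uvec idx(m);
      for (int i = 0; i < m; ++i) idx[i] = order(epoch, start + i) - 1;
      const mat Xb = X.rows(idx);
      const vec yb = y(idx);

      // forward (training mode)
      A[0] = Xb;
      for (size_t l = 0; l < L; ++l) {
        mat Z = A[l] * W[l];
        Z.each_row() += b[l];
        Zs[l] = Z;
        if (l + 1 < L) {
          if (use_bn) {
            mu[l] = mean(Z, 0);
            mat Zc = Z.each_row() - mu[l];
            v[l] = mean(square(Zc), 0);
            xhat[l] = Zc.each_row() / sqrt(v[l] + BN_EPS);
            mat Zn = xhat[l].each_row() % bn[l].gamma;
            Zn.each_row() += bn[l].beta;
            A[l + 1] = clamp(Zn, 0.0, datum::inf);
          } else {
            A[l + 1] = clamp(Z, 0.0, datum::inf);
          }
        } else {
          A[l + 1] = 1.0 / (1.0 + exp(-Z));
        }
      }

      // backward
      ++t_step;
      const double c1 = 1.0 - std::pow(0.9, (double)t_step);
      const double c2 = 1.0 - std::pow(0.999, (double)t_step);
      mat dZ = (A[L] - mat(yb)) / (double)m;
      for (int l = L - 1; l >= 0; --l) {
        const mat gW = A[l].t() * dZ;
        const rowvec gb = sum(dZ, 0);
        if (l > 0) {
          mat dA = dZ * W[l].t();
          mat relu_mask = conv_to<mat>::from(A[l] > 0);
          mat dZn = dA % relu_mask;
          if (use_bn) {
            const rowvec ggamma = sum(dZn % xhat[l - 1], 0);
            const rowvec gbeta = sum(dZn, 0);
            mat dxhat = dZn.each_row() % bn[l - 1].gamma;
            const rowvec m1 = mean(dxhat, 0);
            const rowvec m2 = mean(dxhat % xhat[l - 1], 0);
            mat tmp = dxhat.each_row() - m1;
            tmp -= xhat[l - 1].each_row() % m2;
            dZ = tmp.each_row() / sqrt(v[l - 1] + BN_EPS);
            // parameter + running-stat updates for the normalization layer
            bn[l - 1].rmean = 0.9 * bn[l - 1].rmean + 0.1 * mu[l - 1];
            bn[l - 1].rvar = 0.9 * bn[l - 1].rvar + 0.1 * v[l - 1];
            mat gmat = mat(ggamma), betmat = mat(gbeta);
            mat gam = mat(bn[l - 1].gamma), bet = mat(bn[l - 1].beta);
            ag[l - 1].step(gam, gmat, lr, c1, c2);
            abeta[l - 1].step(bet, betmat, lr, c1, c2);
            bn[l - 1].gamma = gam.row(0);
            bn[l - 1].beta = bet.row(0);
          } else {
            dZ = dZn;
          }
        }
        aW[l].step(W[l], gW, lr, c1, c2);
        mat bmat = mat(b[l]);
        ab[l].step(bmat, mat(gb), lr, c1, c2);
        b[l] = bmat.row(0);
      }
    }

    if (record || epoch == epochs - 1) {
      const vec p_tr = forward_infer(W, b, bn, use_bn, X);
      history(epoch, 0) = bce(p_tr, y);
      history(epoch, 1) = acc(p_tr, y);
      if (has_val) {
        const vec p_va = forward_infer(W, b, bn, use_bn, Xval);
        history(epoch, 2) = bce(p_va, yval);
        history(epoch, 3) = acc(p_va, yval);
      }
    }
  }

  Rcpp::List Wout(L), bout(L), bnout(bn.size());
  for (size_t l = 0; l < L; ++l) {
    Wout[l] = W[l];
    bout[l] = Rcpp::NumericVector(b[l].begin(), b[l].end());
  }
  for (size_t l = 0; l < bn.size(); ++l) {
    bnout[l] = Rcpp::List::create(
        Rcpp::Named("gamma") =
            Rcpp::NumericVector(bn[l].gamma.begin(), bn[l].gamma.end()),
        Rcpp::Named("beta") =
            Rcpp::NumericVector(bn[l].beta.begin(), bn[l].beta.end()),
        Rcpp::Named("mean") =
            Rcpp::NumericVector(bn[l].rmean.begin(), bn[l].rmean.end()),
        Rcpp::Named("var") =
            Rcpp::NumericVector(bn[l].rvar.begin(), bn[l].rvar.end()));
  }
  return Rcpp::List::create(Rcpp::Named("W") = Wout, Rcpp::Named("b") = bout,
                            Rcpp::Named("bn") = bnout,
                            Rcpp::Named("history") = history);
}
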