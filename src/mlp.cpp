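// L2-penalized softmax cross-entropy objective and gradient of a ReLU
// multilayer perceptron, evaluated full-batch.  Called from R inside the
// L-BFGS optimization loop; the parameter vector packs per layer the
// weight matrix (column-major) followed by the bias vector.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

// [[Rcpp::export(name = ".mlpLossGrad")]]
List mlpLossGrad(const arma::vec& theta, const arma::mat& X,
                 const arma::uvec& y, const arma::uvec& sizes,
                 const double alpha) {
  const int L = sizes.n_elem - 1;
  const int n = X.n_rows;

  std::vector<arma::mat> W(L);
  std::vector<arma::rowvec> b(L);
  arma::uword pos = 0;
  for (int l = 0; l < L; ++l) {
    const arma::uword fin = sizes[l], fout = sizes[l + 1];
    W[l] = arma::reshape(theta.subvec(pos, pos + fin * fout - 1), fin, fout);
    pos += fin * fout;
    b[l] = theta.subvec(pos, pos + fout - 1).t();
    pos += fout;
  }

  std::vector<arma::mat> A(L + 1);
  A[0] = X;
  for (int l = 0; l < L; ++l) {
    arma::mat Z = A[l] * W[l];
    Z.each_row() += b[l];
    if (l < L - 1) Z = arma::clamp(Z, 0.0, arma::datum::inf);
    A[l + 1] = std::move(Z);
  }

  arma::mat P = A[L];
  P.each_col() -= arma::max(P, 1);
  P = arma::exp(P);
  P.each_col() /= arma::sum(P, 1);

  double loss = 0.0;
  for (int i = 0; i < n; ++i)
    loss -= std::log(std::max(P(i, y[i]), 1e-300));
  loss /= n;
  double pen = 0.0;
  for (int l = 0; l < L; ++l) pen += arma::accu(arma::square(W[l]));
  loss += 0.5 * alpha * pen / n;

  arma::mat D = P;
  for (int i = 0; i < n; ++i) D(i, y[i]) -= 1.0;
  D /= n;

  std::vector<arma::mat> gW(L);
  std::vector<arma::rowvec> gb(L);
  for (int l = L - 1; l >= 0; --l) {
    gW[l] = A[l].t() * D + (alpha / n) * W[l];
    gb[l] = arma::sum(D, 0);
    if (l > 0) {
      D = D * W[l].t();
      D.elem(arma::find(A[l] <= 0)).zeros();  // ReLU: A[l] = max(Z, 0)
    }
  }

  arma::vec grad(theta.n_elem);
  pos = 0;
  for (int l = 0; l < L; ++l) {
    const arma::uword fin = sizes[l], fout = sizes[l + 1];
    grad.subvec(pos, pos + fin * fout - 1) = arma::vectorise(gW[l]);
    pos += fin * fout;
    grad.subvec(pos, pos + fout - 1) = gb[l].t();
    pos += fout;
  }

  return List::create(_["value"] = loss, _["gradient"] = grad);
}
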