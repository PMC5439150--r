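// Block-wise REML building blocks for the no-residual SAD animal model.
//
// Records are grouped into independent blocks given by the connected
// components of the relationship matrix restricted to recorded animals;
// within a block the phenotype covariance (before any shared group random
// effect, which is handled by a Woodbury correction on the R side) is
//   Vb[r,s] = A[an_r, an_s] * U[cell_r, cell_s] + (an_r == an_s) * P[cell_r, cell_s]
// with U the genetic and P the permanent trait-by-time covariance.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static arma::mat block_V(const arma::mat& A, const arma::ivec& an,
                         const arma::ivec& cell, const arma::mat& U,
                         const arma::mat& P) {
  const arma::uword m = an.n_elem;
  arma::mat V(m, m);
  for (arma::uword i = 0; i < m; ++i) {
    for (arma::uword j = 0; j <= i; ++j) {
      double v = A(an[i], an[j]) * U(cell[i], cell[j]);
      if (an[i] == an[j]) v += P(cell[i], cell[j]);
      V(i, j) = v;
      V(j, i) = v;
    }
  }
  return V;
}

// Accumulate log|Vb| and T' Vb^-1 T over blocks.
// T: n x k matrix (columns typically [X y Zg]); offsets: integer vector of
// length n_blocks + 1 with 0-based record offsets per block; an, cell:
// 0-based within-block animal index and trait-time cell index per record;
// Amats: list of per-block relationship submatrices.
// [[Rcpp::export]]
List reml_block_products(const arma::mat& T, const arma::ivec& offsets,
                         const arma::ivec& an, const arma::ivec& cell,
                         const List& Amats, const arma::mat& U,
                         const arma::mat& P) {
  const int nb = offsets.n_elem - 1;
  const arma::uword k = T.n_cols;
  arma::mat M(k, k, arma::fill::zeros);
  double logdet = 0.0;
  for (int b = 0; b < nb; ++b) {
    const int r0 = offsets[b], r1 = offsets[b + 1];
    const arma::mat A = as<arma::mat>(Amats[b]);
    const arma::ivec an_b = an.subvec(r0, r1 - 1);
    const arma::ivec cell_b = cell.subvec(r0, r1 - 1);
    arma::mat V = block_V(A, an_b, cell_b, U, P);
    arma::mat C;
    if (!arma::chol(C, V, "lower")) {
      return List::create(Named("ok") = false);
    }
    logdet += 2.0 * arma::accu(arma::log(C.diag()));
    arma::mat Tb = T.rows(r0, r1 - 1);
    arma::mat W = arma::solve(arma::trimatl(C), Tb);
    M += W.t() * W;
  }
  return List::create(Named("ok") = true, Named("logdet") = logdet,
                      Named("M") = M);
}

// Score kernels for the analytic REML gradient (no shared group effect):
// with K = V^-1 - V^-1 X C^-1 X' V^-1 - (Py)(Py)' the derivative of
// -2 logL w.r.t. a covariance parameter is <K, dV>.  Because dV is
// A (x) dU + I (x) dP on the block pattern, <K, dV> reduces to inner
// products of dU and dP with cell-aggregated kernels:
//   SU[c,c'] = sum_{i,j} K[i,j] A[an_i, an_j] [cell_i = c][cell_j = c']
//   SP[c,c'] = sum_{i,j: an_i = an_j} K[i,j] [cell_i = c][cell_j = c']
// T must be [X y] here (p columns of X, then y).
// [[Rcpp::export]]
List reml_block_scores(const arma::mat& T, const arma::ivec& offsets,
                       const arma::ivec& an, const arma::ivec& cell,
                       const List& Amats, const arma::mat& U,
                       const arma::mat& P, const arma::vec& beta,
                       const arma::mat& Cinv) {
  const int nb = offsets.n_elem - 1;
  const arma::uword d = U.n_rows;
  const arma::uword p = beta.n_elem;
  arma::mat SU(d, d, arma::fill::zeros), SP(d, d, arma::fill::zeros);
  for (int b = 0; b < nb; ++b) {
    const int r0 = offsets[b], r1 = offsets[b + 1];
    const arma::uword m = r1 - r0;
    const arma::mat A = as<arma::mat>(Amats[b]);
    const arma::ivec an_b = an.subvec(r0, r1 - 1);
    const arma::ivec cell_b = cell.subvec(r0, r1 - 1);
    arma::mat V = block_V(A, an_b, cell_b, U, P);
    arma::mat Vinv;
    if (!arma::inv_sympd(Vinv, V)) {
      return List::create(Named("ok") = false);
    }
    arma::mat Tb = T.rows(r0, r1 - 1);
    arma::mat Wt = Vinv * Tb;
    arma::mat Wx = Wt.cols(0, p - 1);
    arma::vec py = Wt.col(p) - Wx * beta;
    arma::mat K = Vinv - Wx * Cinv * Wx.t() - py * py.t();
    for (arma::uword i = 0; i < m; ++i) {
      for (arma::uword j = 0; j < m; ++j) {
        SU(cell_b[i], cell_b[j]) += K(i, j) * A(an_b[i], an_b[j]);
        if (an_b[i] == an_b[j]) SP(cell_b[i], cell_b[j]) += K(i, j);
      }
    }
  }
  return List::create(Named("ok") = true, Named("SU") = SU, Named("SP") = SP);
}

// Solve Vb x = rhs block-wise (rhs: n x k). Errors if a block is not PD.
// [[Rcpp::export]]
arma::mat reml_block_solve(const arma::mat& rhs, const arma::ivec& offsets,
                           const arma::ivec& an, const arma::ivec& cell,
                           const List& Amats, const arma::mat& U,
                           const arma::mat& P) {
  const int nb = offsets.n_elem - 1;
  arma::mat out(rhs.n_rows, rhs.n_cols);
  for (int b = 0; b < nb; ++b) {
    const int r0 = offsets[b], r1 = offsets[b + 1];
    const arma::mat A = as<arma::mat>(Amats[b]);
    const arma::ivec an_b = an.subvec(r0, r1 - 1);
    const arma::ivec cell_b = cell.subvec(r0, r1 - 1);
    arma::mat V = block_V(A, an_b, cell_b, U, P);
    out.rows(r0, r1 - 1) = arma::solve(V, rhs.rows(r0, r1 - 1),
                                       arma::solve_opts::likely_sympd);
  }
  return out;
}
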