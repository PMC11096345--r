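// Cross-validated PLS-DA RMSECV for a wavelength mask, evaluated from
// precomputed per-fold Gram matrices. This is the genetic algorithm's
// fitness function; it runs tens of thousands of times per selection, so
// the gather + kernel-PLS + prediction loop lives here rather than in R.

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>

using namespace arma;

// Kernel-form PLS2 (cross-product form): fills B (p x q) with the
// regression coefficients for min(ncomp, rank) components. Returns the
// number of components extracted (0 = degenerate input).
static int pls_kernel_B(const mat& XtX, const mat& XtY, int ncomp, mat& B) {
  const uword p = XtX.n_rows, q = XtY.n_cols;
  mat R(p, ncomp, fill::zeros), P(p, ncomp, fill::zeros),
      Q(q, ncomp, fill::zeros);
  mat XtYd = XtY;
  int a = 0;
  for (int c = 0; c < ncomp; ++c) {
    vec w;
    if (q == 1) {
      w = XtYd.col(0);
    } else {
      mat M = XtYd.t() * XtYd;  // q x q
      vec eval;
      mat evec;
      if (!eig_sym(eval, evec, M)) break;
      w = XtYd * evec.col(q - 1);
    }
    double nw = norm(w);
    if (!std::isfinite(nw) || nw < 1e-12) break;
    w /= nw;
    vec r = w;
    if (a > 0)
      r -= R.cols(0, a - 1) * (P.cols(0, a - 1).t() * w);
    vec XtXr = XtX * r;
    double tt = dot(r, XtXr);
    if (!std::isfinite(tt) || tt < 1e-12) break;
    P.col(a) = XtXr / tt;
    Q.col(a) = (XtYd.t() * r) / tt;
    XtYd -= XtXr * Q.col(a).t();
    R.col(a) = r;
    ++a;
  }
  if (a == 0) return 0;
  B = R.cols(0, a - 1) * Q.cols(0, a - 1).t();
  return a;
}

// XtXtr = the per-fold *training* Gram cube (total minus fold),
// XtYtr likewise; sxtr/sytr are training column sums. The mask gather,
// the rank-one mean-centering correction and the fold subtraction are
// fused into one pointer pass per fold.
// [[Rcpp::export]]
double cpp_mask_rmsecv(const arma::mat& X, const arma::mat& Y,
                       const arma::ivec& fold, const arma::cube& XtXtrc,
                       const arma::cube& XtYtrc, const arma::mat& sxtr_m,
                       const arma::mat& sytr_m, const arma::uvec& vars1,
                       int nlv, double sentinel) {
  const uword n = X.n_rows, p = X.n_cols, q = Y.n_cols,
              K = XtXtrc.n_slices;
  if (vars1.n_elem == 0) return sentinel;
  const uvec vars = vars1 - 1;  // R indices are 1-based
  const uword pm = vars.n_elem;

  double sse = 0.0;
  mat XtXtr(pm, pm), XtYtr(pm, q);
  for (uword k = 0; k < K; ++k) {
    const uvec rows = find(fold == (sword)(k + 1));
    const uword nf = rows.n_elem, ntr = n - nf;
    if (ntr < 2) return sentinel;
    const double inv_ntr = 1.0 / (double)ntr;

    vec sxtr(pm);
    const double* sxc = sxtr_m.colptr(k);
    for (uword i = 0; i < pm; ++i) sxtr[i] = sxc[vars[i]];
    const vec sytr = sytr_m.col(k);

    const double* C = XtXtrc.slice(k).memptr();
    double* O = XtXtr.memptr();
    for (uword j = 0; j < pm; ++j) {
      const double* cc = C + (size_t)vars[j] * p;
      const double cj = sxtr[j] * inv_ntr;
      double* oc = O + (size_t)j * pm;
      for (uword i = 0; i < pm; ++i)
        oc[i] = cc[vars[i]] - sxtr[i] * cj;
    }
    const double* D = XtYtrc.slice(k).memptr();
    double* OY = XtYtr.memptr();
    for (uword j = 0; j < q; ++j) {
      const double* dc = D + (size_t)j * p;
      const double yj = sytr[j] * inv_ntr;
      double* oc = OY + (size_t)j * pm;
      for (uword i = 0; i < pm; ++i)
        oc[i] = dc[vars[i]] - sxtr[i] * yj;
    }

    int A = std::min<int>(nlv, std::min<uword>(pm, ntr - 1));
    mat B;
    if (pls_kernel_B(XtXtr, XtYtr, A, B) == 0) return sentinel;
    mat Xf = X.submat(rows, vars);
    mat Yhat = Xf * B;
    const rowvec off = (sxtr.t() * inv_ntr) * B;
    const rowvec ym = sytr.t() * inv_ntr;
    Yhat.each_row() -= off;
    Yhat.each_row() += ym;
    sse += accu(square(Y.rows(rows) - Yhat));
  }
  return std::sqrt(sse / (double)(n * q));
}
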