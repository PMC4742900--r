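// Exact per-marker GLS under a fixed mixed-model covariance, dropping
// lines with a missing genotype via a block-downdate of V^{-1}.
// Mirrors the reference R implementation (.glsFit); that version remains
// the oracle in the test suite.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;

// [[Rcpp::export(name = ".glsMissingBatch")]]
Rcpp::List glsMissingBatch(const arma::mat& P, const arma::mat& X,
                           const arma::vec& y, const arma::vec& Py,
                           const arma::mat& PX, const arma::mat& XtPX,
                           const arma::vec& XtPy, const double yPy,
                           const arma::mat& G0, const arma::mat& PG,
                           const arma::mat& I0, const arma::mat& PI,
                           const bool hasInter,
                           const Rcpp::List& missIdx,
                           const bool needResid) {
  const uword n = X.n_rows, p = X.n_cols;
  const uword q = hasInter ? 2 : 1;
  const uword L = G0.n_cols;
  mat coef(p + q, L, fill::value(datum::nan));
  mat sem(p + q, L, fill::value(datum::nan));
  ivec dfv(L, fill::value(-1));
  ivec nused(L, fill::zeros);
  ivec sing(L, fill::zeros);
  mat VR, R0;
  if (needResid) { VR.zeros(n, L); R0.zeros(n, L); }

  for (uword j = 0; j < L; ++j) {
    uvec Mi = Rcpp::as<uvec>(missIdx[j]);
    Mi -= 1;                               // R indices are 1-based
    const uword m = Mi.n_elem;
    mat E0(n, q);
    E0.col(0) = G0.col(j);
    if (hasInter) E0.col(1) = I0.col(j);
    mat PE(n, q);
    PE.col(0) = PG.col(j);
    if (hasInter) PE.col(1) = PI.col(j);

    mat C_XE = PX.t() * E0;                // p x q
    mat C_EE = E0.t() * PE;                // q x q
    vec c_E = E0.t() * Py;
    mat C(p + q, p + q);
    vec cc(p + q);
    double ytVy;
    mat Q, Lc;
    vec yM;
    uvec MiU = Mi;
    if (m > 0) {
      Q = P.cols(Mi);
      mat Pmm = Q.rows(Mi);
      mat XM = X.rows(Mi);
      yM = y(Mi);
      mat XtQ = X.t() * Q;                 // p x m
      vec PyM = Py(Mi);
      mat PEM = PE.rows(Mi);               // m x q
      vec PmmyM = Pmm * yM;
      mat t1 = XtQ * XM;
      mat C_XX = XtPX - t1 - t1.t() + XM.t() * (Pmm * XM);
      C_XE -= XM.t() * PEM;
      vec c_X = XtPy - XtQ * yM - XM.t() * PyM + XM.t() * PmmyM;
      c_E -= PEM.t() * yM;
      double yPyz = yPy - 2.0 * dot(PyM, yM) + dot(yM, PmmyM);
      mat G = join_cols(XtQ - XM.t() * Pmm, PEM.t());   // (p+q) x m
      vec h = PyM - PmmyM;
      bool okc = chol(Lc, Pmm, "lower");
      if (!okc) { sing(j) = 1; continue; }
      mat A1 = solve(trimatl(Lc), G.t());  // m x (p+q)
      vec bh = solve(trimatl(Lc), h);
      C = join_cols(join_rows(C_XX, C_XE),
                    join_rows(C_XE.t(), C_EE)) - A1.t() * A1;
      cc = join_cols(c_X, c_E) - A1.t() * bh;
      ytVy = yPyz - dot(bh, bh);
    } else {
      C = join_cols(join_rows(XtPX, C_XE), join_rows(C_XE.t(), C_EE));
      cc = join_cols(XtPy, c_E);
      ytVy = yPy;
    }
    mat Cinv;
    if (!inv_sympd(Cinv, C)) { sing(j) = 1; continue; }
    vec beta = Cinv * cc;
    const int df = (int)(n - m) - (int)(p + q);
    if (df <= 0) { sing(j) = 1; continue; }
    double rss = ytVy - dot(beta, cc);
    if (rss < 0) rss = 0;
    const double sig2 = rss / df;
    coef.col(j) = beta;
    sem.col(j) = sqrt(clamp(Cinv.diag() * sig2, 0.0, datum::inf));
    dfv(j) = df;
    nused(j) = (int)(n - m);
    if (needResid) {
      vec bx = beta.head(p);
      vec bE = beta.tail(q);
      vec s;
      if (m > 0) {
        s = (Py - Q * yM) - (PX * bx - Q * (X.rows(MiU) * bx)) - PE * bE;
        vec corr = solve(trimatu(Lc.t()), solve(trimatl(Lc), s(MiU)));
        s -= Q * corr;
        s(MiU).zeros();
      } else {
        s = Py - PX * bx - PE * bE;
      }
      vec r = y - X * bx - E0 * bE;
      if (m > 0) r(MiU).zeros();
      VR.col(j) = s;
      R0.col(j) = r;
    }
  }
  Rcpp::List out = Rcpp::List::create(
    Rcpp::Named("coef") = coef, Rcpp::Named("se") = sem,
    Rcpp::Named("df") = dfv, Rcpp::Named("n_used") = nused,
    Rcpp::Named("singular") = sing);
  if (needResid) { out["VR"] = VR; out["R0"] = R0; }
  return out;
}
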