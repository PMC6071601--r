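// Profiled restricted-likelihood evaluations for the variance-component
// scans. The model is evaluated in the eigenbasis of the whole-genome
// relationship matrix G = U diag(d) U', where the covariance of the rotated
// response is
//
//   Var(U'y) = sigma2_e * ( diag(1 + thu * d) + thv * W W' )
//
// with thu = sigma2_u / sigma2_e, thv = sigma2_v / sigma2_e and W the
// rotated, centered and frequency-scaled regional marker block (n x m,
// m small). The diagonal-plus-low-rank structure makes one evaluation
// O(n m^2) via the Woodbury identity, which keeps permutation scans cheap.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

static const double LOG2PI = std::log(2.0 * M_PI);

// core evaluation; returns false on numerical failure
static bool eval_core(double lthu, double lthv,
                      const vec& d, const vec& yr, const mat& Xr, const mat& Wt,
                      bool with_region,
                      double& nll, double& s2e, vec& beta, mat& XHiX_out,
                      double& ypy_out) {
  const uword n = yr.n_elem, p = Xr.n_cols, m = Wt.n_cols;
  const double thu = std::exp(lthu);
  const double thv = with_region ? std::exp(lthv) : 0.0;

  vec a = 1.0 + thu * d;
  if (a.min() <= 0.0) return false;
  vec ai = 1.0 / a;

  mat Z(n, 1 + p);
  Z.col(0) = yr;
  Z.cols(1, p) = Xr;
  mat AZ = Z.each_col() % ai;
  double logdetH = accu(log(a));
  mat M;
  if (with_region && m > 0 && thv > 0.0) {
    mat AiW = Wt.each_col() % ai;                 // n x m
    mat T = eye(m, m) + thv * (Wt.t() * AiW);     // m x m
    mat L;
    if (!chol(L, T, "lower")) return false;
    logdetH += 2.0 * accu(log(L.diag()));
    mat WtAZ = Wt.t() * AZ;                       // m x (1+p)
    mat S = solve(trimatu(L.t()), solve(trimatl(L), WtAZ));
    M = Z.t() * AZ - thv * (WtAZ.t() * S);
  } else {
    M = Z.t() * AZ;
  }

  double yHiy = M(0, 0);
  vec XHiy = M(span(1, p), span(0, 0));
  mat XHiX = M(span(1, p), span(1, p));
  mat Lx;
  if (!chol(Lx, XHiX, "lower")) return false;
  vec bt = solve(trimatl(Lx), XHiy);
  double ypy = yHiy - dot(bt, bt);
  if (!(ypy > 0.0)) return false;
  double logdetX = 2.0 * accu(log(Lx.diag()));

  const double np = static_cast<double>(n - p);
  s2e = ypy / np;
  nll = 0.5 * (np * std::log(s2e) + logdetH + logdetX + np * (1.0 + LOG2PI));
  beta = solve(trimatu(Lx.t()), bt);
  XHiX_out = XHiX;
  ypy_out = ypy;
  return true;
}

// [[Rcpp::export]]
double reml_nll_region(double lthu, double lthv, const arma::vec& d,
                       const arma::vec& yr, const arma::mat& Xr,
                       const arma::mat& Wt) {
  double nll, s2e, ypy;
  vec beta;
  mat XHiX;
  if (!eval_core(lthu, lthv, d, yr, Xr, Wt, true, nll, s2e, beta, XHiX, ypy))
    return 1e10;
  return nll;
}

// [[Rcpp::export]]
double reml_nll_kinship(double lthu, const arma::vec& d, const arma::vec& yr,
                        const arma::mat& Xr) {
  double nll, s2e, ypy;
  vec beta;
  mat XHiX, W0(yr.n_elem, 0);
  if (!eval_core(lthu, 0.0, d, yr, Xr, W0, false, nll, s2e, beta, XHiX, ypy))
    return 1e10;
  return nll;
}

// full set of quantities at a parameter value
// [[Rcpp::export]]
Rcpp::List reml_parts(double lthu, double lthv, const arma::vec& d,
                      const arma::vec& yr, const arma::mat& Xr,
                      const arma::mat& Wt, bool with_region) {
  double nll, s2e, ypy;
  vec beta;
  mat XHiX;
  if (!eval_core(lthu, lthv, d, yr, Xr, Wt, with_region, nll, s2e, beta, XHiX,
                 ypy))
    Rcpp::stop("restricted-likelihood evaluation failed (singular system)");
  const double thu = std::exp(lthu);
  const double thv = with_region ? std::exp(lthv) : 0.0;
  mat XHiXinv = inv_sympd(XHiX);
  vec se = sqrt(s2e * XHiXinv.diag());
  return Rcpp::List::create(
      Rcpp::Named("logLik") = -nll, Rcpp::Named("sigma2_e") = s2e,
      Rcpp::Named("sigma2_u") = thu * s2e, Rcpp::Named("sigma2_v") = thv * s2e,
      Rcpp::Named("beta") = beta, Rcpp::Named("se_beta") = se,
      Rcpp::Named("theta_u") = thu, Rcpp::Named("theta_v") = thv);
}

// derivative of the profiled restricted log-likelihood with respect to thv
// at thv = 0, given thu (used to detect boundary solutions cheaply):
//   dl/dthv = 0.5 * ( (n-p) * y'P W W' P y / (y'P y) - tr(P W W') )
// with P the projected inverse of diag(1 + thu d).
// [[Rcpp::export]]
double region_score_null(double lthu, const arma::vec& d, const arma::vec& yr,
                         const arma::mat& Xr, const arma::mat& Wt) {
  const uword n = yr.n_elem, p = Xr.n_cols;
  const double thu = std::exp(lthu);
  vec ai = 1.0 / (1.0 + thu * d);
  mat AiX = Xr.each_col() % ai;                   // n x p
  mat XtAiX = Xr.t() * AiX;                       // p x p
  mat XtAiXinv = inv_sympd(XtAiX);
  // P z = Ai z - AiX (X'AiX)^{-1} (AiX)' z
  vec Aiy = yr % ai;
  vec Py = Aiy - AiX * (XtAiXinv * (AiX.t() * yr));
  double yPy = dot(yr, Py);
  mat PW = (Wt.each_col() % ai) - AiX * (XtAiXinv * (AiX.t() * Wt));
  vec u = Wt.t() * Py;                            // m
  double yPBPy = dot(u, u);
  double trPB = accu(Wt % PW);
  const double np = static_cast<double>(n - p);
  return 0.5 * (np * yPBPy / yPy - trPB);
}
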