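// Per-lesion Laplace approximation of the marginal likelihood of the
// biexponential TGI model with lognormal random effects and additive
// residual error. The inner problem (conditional mode of eta) is solved by
// a damped Newton iteration with analytic gradient and Hessian; the
// Laplace correction uses the full curvature at the mode.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static const double LOG2PI = std::log(2.0 * M_PI);

// conditional log-likelihood, gradient and Hessian over all 3 eta
// components; prior terms only for components listed in `free_idx`
// (components with omega2 ~ 0 are pinned at eta = 0).
struct CondLik {
  const arma::vec& t;
  const arma::vec& y;
  arma::vec theta;
  arma::vec omega2;
  double sigma;
  arma::uvec free_idx;

  CondLik(const arma::vec& t_, const arma::vec& y_, const arma::vec& th,
          const arma::vec& w2, double sg, const arma::uvec& fr)
    : t(t_), y(y_), theta(th), omega2(w2), sigma(sg), free_idx(fr) {}

  // value only
  double value(const arma::vec& eta) const {
    const double a = theta(0) * std::exp(eta(0));
    const double b = theta(1) * std::exp(eta(1));
    const double c = theta(2) * std::exp(eta(2));
    const int n = t.n_elem;
    double ss = 0.0;
    for (int j = 0; j < n; ++j) {
      double eb = b * t(j) < 700 ? std::exp(b * t(j)) : arma::datum::inf;
      double f = a * (eb + std::exp(-c * t(j)) - 1.0);
      if (!std::isfinite(f)) return -arma::datum::inf;
      ss += (y(j) - f) * (y(j) - f);
    }
    double l = -0.5 * n * (LOG2PI + 2.0 * std::log(sigma))
               - ss / (2.0 * sigma * sigma);
    for (arma::uword k = 0; k < free_idx.n_elem; ++k) {
      arma::uword kk = free_idx(k);
      l += -0.5 * (LOG2PI + std::log(omega2(kk)))
           - eta(kk) * eta(kk) / (2.0 * omega2(kk));
    }
    return l;
  }

  // value + gradient + Hessian (3x3, all components; fixed ones later masked)
  double deriv(const arma::vec& eta, arma::vec& g, arma::mat& H) const {
    const double a = theta(0) * std::exp(eta(0));
    const double b = theta(1) * std::exp(eta(1));
    const double c = theta(2) * std::exp(eta(2));
    const int n = t.n_elem;
    const double s2 = sigma * sigma;
    g.zeros(3); H.zeros(3, 3);
    double ss = 0.0;
    for (int j = 0; j < n; ++j) {
      double bt = b * t(j), ct = c * t(j);
      double eb = bt < 700 ? std::exp(bt) : arma::datum::inf;
      double ec = std::exp(-ct);
      double f = a * (eb + ec - 1.0);
      if (!std::isfinite(f)) { return -arma::datum::inf; }
      double r = y(j) - f;
      ss += r * r;
      arma::vec df(3);                       // df/deta
      df(0) = f;
      df(1) = a * bt * eb;
      df(2) = -a * ct * ec;
      arma::mat d2f(3, 3, arma::fill::zeros);  // second derivatives
      d2f(0, 0) = f;
      d2f(0, 1) = d2f(1, 0) = df(1);
      d2f(0, 2) = d2f(2, 0) = df(2);
      d2f(1, 1) = a * bt * eb * (1.0 + bt);
      d2f(2, 2) = -a * ct * ec * (1.0 - ct);
      g += r / s2 * df;
      H += (-df * df.t() + r * d2f) / s2;
    }
    double l = -0.5 * n * (LOG2PI + 2.0 * std::log(sigma)) - ss / (2.0 * s2);
    for (arma::uword k = 0; k < free_idx.n_elem; ++k) {
      arma::uword kk = free_idx(k);
      l += -0.5 * (LOG2PI + std::log(omega2(kk)))
           - eta(kk) * eta(kk) / (2.0 * omega2(kk));
      g(kk) += -eta(kk) / omega2(kk);
      H(kk, kk) += -1.0 / omega2(kk);
    }
    return l;
  }
};

// Damped Newton ascent of the conditional log-likelihood from a given
// start; returns the final value, leaves the point in `eta`.
static double newton_mode(const CondLik& lik, arma::vec& eta, bool& ok,
                          double tol, int maxit) {
  const arma::uvec& fr = lik.free_idx;
  const arma::uword d = fr.n_elem;
  ok = true;
  arma::vec g(3); arma::mat H(3, 3);
  double l = lik.deriv(eta, g, H);
  if (!std::isfinite(l)) { eta.zeros(3); l = lik.deriv(eta, g, H); }
  for (int it = 0; it < maxit; ++it) {
    arma::vec gf = g.elem(fr);
    if (arma::norm(gf, "inf") < tol * (1.0 + std::abs(l))) break;
    arma::mat A = -H.submat(fr, fr);
    double ridge = 0.0;
    arma::mat R;
    while (!arma::chol(R, A + ridge * arma::eye(d, d))) {
      ridge = ridge == 0.0 ? 1e-6 * (1.0 + arma::trace(A) / d) : 10.0 * ridge;
      if (!std::isfinite(ridge) || ridge > 1e12) { ok = false; break; }
    }
    if (!ok) break;
    arma::vec step = arma::solve(A + ridge * arma::eye(d, d), gf);
    double slope = arma::dot(gf, step);
    double s = 1.0;
    bool accepted = false;
    for (int h = 0; h < 40; ++h) {
      arma::vec cand = eta;
      cand.elem(fr) += s * step;
      double lc = lik.value(cand);
      if (std::isfinite(lc) && lc >= l + 1e-4 * s * slope) {
        eta = cand; accepted = true; break;
      }
      s *= 0.5;
    }
    if (!accepted) break;       // no ascent possible: treat current point as mode
    l = lik.deriv(eta, g, H);
  }
  if (arma::norm(g.elem(fr), "inf") > 1e-4 * (1.0 + std::abs(l))) ok = false;
  return l;
}

// Laplace log-marginal for one lesion; returns mode in `eta`, flag in `ok`.
static double lesion_laplace(const CondLik& lik, arma::vec& eta, bool& ok,
                             double tol, int maxit) {
  const arma::uvec& fr = lik.free_idx;
  const arma::uword d = fr.n_elem;
  ok = true;
  if (d == 0) {                 // all random effects pinned: no integral
    eta.zeros(3);
    return lik.value(eta);
  }
  double l = newton_mode(lik, eta, ok, tol, maxit);
  if (!ok && arma::norm(eta, "inf") > 0) {
    // warm start failed: retry the search from the prior mean
    arma::vec eta0(3, arma::fill::zeros);
    bool ok0 = true;
    double l0 = newton_mode(lik, eta0, ok0, tol, maxit);
    if (l0 > l || (ok0 && !ok)) { eta = eta0; l = l0; ok = ok0; }
  }
  arma::vec g(3); arma::mat H(3, 3);
  l = lik.deriv(eta, g, H);
  arma::mat A = -H.submat(fr, fr);
  arma::mat R;
  if (!arma::chol(R, A)) {      // non-PD curvature at the reported mode
    ok = false;
    double ridge = 1e-6 * (1.0 + std::abs(arma::trace(A)) / d);
    while (!arma::chol(R, A + ridge * arma::eye(d, d)) && ridge < 1e12)
      ridge *= 10.0;
    if (!arma::chol(R, A + ridge * arma::eye(d, d)))
      return -arma::datum::inf;
  }
  double logdet = 2.0 * arma::sum(arma::log(R.diag()));
  return l + 0.5 * d * LOG2PI - 0.5 * logdet;
}

// [[Rcpp::export]]
List cpp_laplace(List times, List y, NumericVector theta,
                 NumericVector omega2, double sigma,
                 NumericMatrix eta_start, double tol, int maxit) {
  const int n = times.size();
  arma::vec th(theta.begin(), 3), w2(omega2.begin(), 3);
  if (!(sigma > 0))
    return List::create(_["ofv"] = R_PosInf,
                        _["etas"] = NumericMatrix(n, 3),
                        _["lesion_loglik"] = NumericVector(n, R_NegInf),
                        _["converged"] = LogicalVector(n, false));
  arma::uvec fr = arma::find(w2 > 1e-10);
  arma::mat etas(n, 3, arma::fill::zeros);
  arma::vec ll(n);
  LogicalVector conv(n);
  double total = 0.0;
  for (int i = 0; i < n; ++i) {
    arma::vec t = as<arma::vec>(times[i]);
    arma::vec yy = as<arma::vec>(y[i]);
    CondLik lik(t, yy, th, w2, sigma, fr);
    arma::vec eta(3, arma::fill::zeros);
    for (int k = 0; k < 3; ++k) eta(k) = eta_start(i, k);
    for (arma::uword k = 0; k < 3; ++k)
      if (!arma::any(fr == k)) eta(k) = 0.0;
    bool ok;
    ll(i) = lesion_laplace(lik, eta, ok, tol, maxit);
    etas.row(i) = eta.t();
    conv[i] = ok;
    total += ll(i);
  }
  return List::create(_["ofv"] = -2.0 * total,
                      _["etas"] = wrap(etas),
                      _["lesion_loglik"] = wrap(ll),
                      _["converged"] = conv);
}
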