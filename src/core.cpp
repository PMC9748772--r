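// Numerical core: dense matrix exponential, Felsenstein pruning for Mk models,
// and state-dependent speciation-extinction (BiSSE/HiSSE-type) pruning with an
// adaptive Cash-Karp Runge-Kutta integrator for the D/E equations.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

// [[Rcpp::export]]
arma::mat cpp_expm(const arma::mat& Q, double t) {
  // scaling-and-squaring Pade via Armadillo; robust for defective Q
  // (no-reversion matrices have zero rows and are not diagonalizable)
  return arma::expmat(Q * t);
}

// Transition probability matrices for a set of branch lengths.
// [[Rcpp::export]]
arma::cube cpp_branch_pmats(const arma::mat& Q, const arma::vec& lens) {
  const arma::uword k = Q.n_rows, ne = lens.n_elem;
  arma::cube P(k, k, ne);
  for (arma::uword e = 0; e < ne; ++e) {
    P.slice(e) = arma::expmat(Q * lens(e));
    // clamp tiny negative round-off
    P.slice(e).transform([](double x) { return x < 0.0 ? 0.0 : x; });
  }
  return P;
}

// Pruning log-likelihood for an Mk model.
// edge: (parent, child) 1-based node ids in ape postorder; tips are 1..ntip.
// tipL: ntip x k matrix of tip partial likelihoods (indicator rows, or
//       uniform rows for ambiguous tips).
// [[Rcpp::export]]
double cpp_mk_loglik(const arma::imat& edge, const arma::vec& lens, int ntip,
                     const arma::mat& tipL, const arma::mat& Q,
                     const arma::vec& pi) {
  const int k = Q.n_rows;
  const int nnode = ntip + (int)edge.n_rows; // upper bound on node ids
  arma::mat L(nnode + 1, k, arma::fill::ones);
  arma::vec logsc(nnode + 1, arma::fill::zeros);
  for (int i = 0; i < ntip; ++i) L.row(i + 1) = tipL.row(i);

  for (arma::uword e = 0; e < edge.n_rows; ++e) {
    const int p = edge(e, 0), c = edge(e, 1);
    arma::mat P = arma::expmat(Q * lens(e));
    arma::rowvec v = L.row(c) * P.t(); // v_s = sum_j P(s,j) L_c(j)
    double m = v.max();
    if (!(m > 0.0)) return R_NegInf;
    L.row(p) %= v / m;
    logsc(p) += logsc(c) + std::log(m);
  }
  const int root = edge(edge.n_rows - 1, 0);
  double lik = arma::dot(L.row(root).t(), pi);
  if (!(lik > 0.0)) return R_NegInf;
  return std::log(lik) + logsc(root);
}

// ---- SSE machinery -------------------------------------------------------

struct SseParams {
  arma::vec lambda, mu, rowq;
  arma::mat Qr; // off-diagonal transition rates between regimes, diag 0
};

static inline void sse_deriv(const SseParams& P, const arma::vec& y,
                             arma::vec& dy) {
  const arma::uword m = P.lambda.n_elem;
  const arma::vec E = y.head(m), D = y.tail(m);
  arma::vec qE = P.Qr * E, qD = P.Qr * D;
  for (arma::uword i = 0; i < m; ++i) {
    const double tot = P.lambda(i) + P.mu(i) + P.rowq(i);
    dy(i) = P.mu(i) - tot * E(i) + P.lambda(i) * E(i) * E(i) + qE(i);
    dy(m + i) = -tot * D(i) + 2.0 * P.lambda(i) * E(i) * D(i) + qD(i);
  }
}

// Cash-Karp RK4(5) over one branch; y holds (E, D) stacked.
static bool sse_integrate(const SseParams& P, arma::vec& y, double len,
                          double rtol, double atol) {
  const arma::uword n = y.n_elem;
  static const double b21 = 1.0 / 5.0;
  static const double b31 = 3.0 / 40.0, b32 = 9.0 / 40.0;
  static const double b41 = 3.0 / 10.0, b42 = -9.0 / 10.0, b43 = 6.0 / 5.0;
  static const double b51 = -11.0 / 54.0, b52 = 2.5, b53 = -70.0 / 27.0,
                      b54 = 35.0 / 27.0;
  static const double b61 = 1631.0 / 55296.0, b62 = 175.0 / 512.0,
                      b63 = 575.0 / 13824.0, b64 = 44275.0 / 110592.0,
                      b65 = 253.0 / 4096.0;
  static const double c1 = 37.0 / 378.0, c3 = 250.0 / 621.0,
                      c4 = 125.0 / 594.0, c6 = 512.0 / 1771.0;
  static const double d1 = c1 - 2825.0 / 27648.0, d3 = c3 - 18575.0 / 48384.0,
                      d4 = c4 - 13525.0 / 55296.0, d5 = -277.0 / 14336.0,
                      d6 = c6 - 0.25;
  double t = 0.0, h = len;
  arma::vec k1(n), k2(n), k3(n), k4(n), k5(n), k6(n), yt(n), yerr(n), ynew(n);
  int steps = 0;
  while (t < len) {
    if (t + h > len) h = len - t;
    sse_deriv(P, y, k1);
    yt = y + h * b21 * k1;
    sse_deriv(P, yt, k2);
    yt = y + h * (b31 * k1 + b32 * k2);
    sse_deriv(P, yt, k3);
    yt = y + h * (b41 * k1 + b42 * k2 + b43 * k3);
    sse_deriv(P, yt, k4);
    yt = y + h * (b51 * k1 + b52 * k2 + b53 * k3 + b54 * k4);
    sse_deriv(P, yt, k5);
    yt = y + h * (b61 * k1 + b62 * k2 + b63 * k3 + b64 * k4 + b65 * k5);
    sse_deriv(P, yt, k6);
    ynew = y + h * (c1 * k1 + c3 * k3 + c4 * k4 + c6 * k6);
    yerr = h * (d1 * k1 + d3 * k3 + d4 * k4 + d5 * k5 + d6 * k6);
    double errmax = 0.0;
    for (arma::uword i = 0; i < n; ++i) {
      double sc = atol + rtol * std::max(std::abs(y(i)), std::abs(ynew(i)));
      errmax = std::max(errmax, std::abs(yerr(i)) / sc);
    }
    if (errmax <= 1.0) {
      t += h;
      y = ynew;
      h *= std::min(5.0, 0.9 * std::pow(std::max(errmax, 1e-12), -0.2));
    } else {
      h *= std::max(0.1, 0.9 * std::pow(errmax, -0.25));
    }
    if (++steps > 1000000 || h < 1e-14 * len) return false;
  }
  return true;
}

// SSE pruning log-likelihood.
// tipD: ntip x m matrix of initial D values (regime indicator expansion).
// root_type: 0 = weight by conditional likelihoods (obs), 1 = equal, 2 = pi.
// [[Rcpp::export]]
List cpp_sse_loglik(const arma::imat& edge, const arma::vec& lens, int ntip,
                    const arma::mat& tipD, const arma::vec& lambda,
                    const arma::vec& mu, const arma::mat& Qr, double rtol,
                    double atol, int root_type, const arma::vec& root_pi,
                    bool condition) {
  const arma::uword m = lambda.n_elem;
  SseParams P;
  P.lambda = lambda;
  P.mu = mu;
  P.Qr = Qr;
  P.Qr.diag().zeros();
  P.rowq = arma::sum(P.Qr, 1);

  const int nnode = ntip + (int)edge.n_rows;
  arma::mat D(nnode + 1, m, arma::fill::ones), E(nnode + 1, m,
                                                 arma::fill::zeros);
  arma::vec logsc(nnode + 1, arma::fill::zeros);
  arma::ivec seen(nnode + 1, arma::fill::zeros);
  for (int i = 0; i < ntip; ++i) D.row(i + 1) = tipD.row(i);

  for (arma::uword e = 0; e < edge.n_rows; ++e) {
    const int p = edge(e, 0), c = edge(e, 1);
    arma::vec y(2 * m);
    y.head(m) = E.row(c).t();
    y.tail(m) = D.row(c).t();
    if (!sse_integrate(P, y, lens(e), rtol, atol))
      return List::create(_["logL"] = R_NegInf, _["ok"] = false,
                          _["branch"] = (int)e + 1);
    y.transform([](double x) { return x < 0.0 ? 0.0 : x; });
    for (arma::uword i = 0; i < m; ++i)
      if (y(i) > 1.0) y(i) = 1.0; // E stays in [0,1]
    double mx = y.tail(m).max();
    if (!(mx > 0.0))
      return List::create(_["logL"] = R_NegInf, _["ok"] = true,
                          _["branch"] = (int)e + 1);
    if (seen(p) == 0) {
      D.row(p) = (y.tail(m) / mx).t();
      E.row(p) = y.head(m).t();
      seen(p) = 1;
    } else {
      D.row(p) %= (y.tail(m) / mx).t() % lambda.t();
      E.row(p) = 0.5 * (E.row(p) + y.head(m).t());
    }
    logsc(p) += logsc(c) + std::log(mx);
  }
  const int root = edge(edge.n_rows - 1, 0);
  arma::vec d = D.row(root).t(), Er = E.row(root).t();
  if (condition)
    for (arma::uword i = 0; i < m; ++i) {
      double denom = lambda(i) * (1.0 - Er(i)) * (1.0 - Er(i));
      d(i) = denom > 0 ? d(i) / denom : 0.0;
    }
  double lik;
  if (root_type == 0) {
    double s = arma::accu(d);
    lik = s > 0 ? arma::dot(d, d) / s : 0.0;
  } else if (root_type == 1) {
    lik = arma::mean(d);
  } else {
    lik = arma::dot(root_pi, d);
  }
  if (!(lik > 0.0))
    return List::create(_["logL"] = R_NegInf, _["ok"] = true,
                        _["branch"] = 0);
  return List::create(_["logL"] = std::log(lik) + logsc(root),
                      _["ok"] = true, _["branch"] = 0,
                      _["rootE"] = Er, _["rootD"] = d);
}
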