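// Likelihood kernels for the joint latent class mixed model:
//  - marginal multivariate-normal log-density of a course's DAS28 vector
//    (random intercept + slope integrated analytically), per latent class
//  - Weibull log-hazard with class-specific log-linear/log-quadratic time
//    effects, fixed covariates, and a time-varying dichotomised-dose term;
//    cumulative hazard by 15-node Gauss-Legendre per constant-dose segment.
// Time is in YEARS throughout.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// 15-point Gauss-Legendre nodes/weights on [-1, 1]
static const double GL_X[15] = {
  -0.9879925180204854, -0.9372733924007059, -0.8482065834104272,
  -0.7244177313601700, -0.5709721726085388, -0.3941513470775634,
  -0.2011940939974345,  0.0,                 0.2011940939974345,
   0.3941513470775634,  0.5709721726085388,  0.7244177313601700,
   0.8482065834104272,  0.9372733924007059,  0.9879925180204854 };
static const double GL_W[15] = {
  0.0307532419961173, 0.0703660474881081, 0.1071592204671719,
  0.1395706779261543, 0.1662692058169939, 0.1861610000155622,
  0.1984314853271116, 0.2025782419255613, 0.1984314853271116,
  0.1861610000155622, 0.1662692058169939, 0.1395706779261543,
  0.1071592204671719, 0.0703660474881081, 0.0307532419961173 };

// \int_a^b kappa * rho^kappa * t^(kappa-1) * exp(g1*t + g2*t^2) dt
// For a segment starting at 0 the substitution u = t^kappa removes the
// t^(kappa-1) endpoint singularity (and is exact when g1 = g2 = 0):
//   I = rho^kappa * \int_0^{b^kappa} exp(g1 u^{1/kappa} + g2 u^{2/kappa}) du
static double haz_integral(double a, double b, double kappa, double rho,
                           double g1, double g2) {
  if (b <= a) return 0.0;
  const double lk = std::log(kappa) + kappa * std::log(rho);
  double s = 0.0;
  if (a <= 0.0) {
    const double ub = std::pow(b, kappa);
    const double mid = 0.5 * ub, half = 0.5 * ub;
    for (int j = 0; j < 15; ++j) {
      const double u = mid + half * GL_X[j];
      const double t = std::pow(u, 1.0 / kappa);
      s += GL_W[j] * std::exp(g1 * t + g2 * t * t);
    }
    return half * s * std::pow(rho, kappa);
  }
  const double mid = 0.5 * (a + b), half = 0.5 * (b - a);
  for (int j = 0; j < 15; ++j) {
    const double t = mid + half * GL_X[j];
    s += GL_W[j] * std::exp(lk + (kappa - 1.0) * std::log(t) + g1 * t + g2 * t * t);
  }
  return half * s;
}

// moments out[] = { I, \int t f, \int t^2 f, dI/dkappa } over [a, b] with
// f(t) = kappa rho^kappa t^(kappa-1) exp(g1 t + g2 t^2).  Same quadrature
// (including the u = t^kappa substitution at t = 0) as haz_integral, so
// likelihood and gradient agree to machine precision; the kappa derivative
// differentiates the quadrature formula itself.
static void seg_moments(double a, double b, double kappa, double rho,
                        double g1, double g2, double out[4]) {
  out[0] = out[1] = out[2] = out[3] = 0.0;
  if (b <= a) return;
  if (a <= 0.0) {
    const double ub = std::pow(b, kappa);
    const double half = 0.5 * ub;
    const double rk = std::pow(rho, kappa);
    const double lb = std::log(b);
    double dk_nodes = 0.0;
    for (int j = 0; j < 15; ++j) {
      const double u = half + half * GL_X[j];
      const double t = std::pow(u, 1.0 / kappa);
      const double f = GL_W[j] * std::exp(g1 * t + g2 * t * t);
      out[0] += f; out[1] += f * t; out[2] += f * t * t;
      // node motion: dt/dkappa = (t / kappa) * log(b / t)
      dk_nodes += f * (g1 + 2.0 * g2 * t) * (t / kappa) * (lb - std::log(t));
    }
    for (int k = 0; k < 3; ++k) out[k] *= half * rk;
    out[3] = out[0] * (std::log(rho) + lb) + half * rk * dk_nodes;
    return;
  }
  const double lk = std::log(kappa) + kappa * std::log(rho);
  const double mid = 0.5 * (a + b), half = 0.5 * (b - a);
  double logmom = 0.0;
  for (int j = 0; j < 15; ++j) {
    const double t = mid + half * GL_X[j];
    const double lt = std::log(t);
    const double f = GL_W[j] * std::exp(lk + (kappa - 1.0) * lt + g1 * t + g2 * t * t);
    out[0] += f; out[1] += f * t; out[2] += f * t * t; logmom += f * lt;
  }
  for (int k = 0; k < 3; ++k) out[k] *= half;
  logmom *= half;
  out[3] = (1.0 / kappa + std::log(rho)) * out[0] + logmom;
}

// Cumulative hazard over piecewise-constant dose segments [a_k, b_k] with
// low-dose flags; linear predictor eta (covariates), delta on 1[dose <= 0.5].
// [[Rcpp::export]]
double jlcm_cumhaz_cpp(NumericVector seg_a, NumericVector seg_b,
                       IntegerVector seg_low, double kappa, double rho,
                       double g1, double g2, double eta, double delta) {
  double L = 0.0;
  for (int k = 0; k < seg_a.size(); ++k)
    L += std::exp(eta + delta * seg_low[k]) *
         haz_integral(seg_a[k], seg_b[k], kappa, rho, g1, g2);
  return L;
}

// Joint log-likelihood with analytic gradient in the natural parameters.
// Gradient of log sum_g pi_g exp(a_ig) is the posterior-weighted score:
// sum_g w_ig * da_ig/dtheta, with w_ig the class posterior of course i.
// Longitudinal scores use dl/dV = (V^-1 r r' V^-1 - V^-1)/2 chained to the
// random-effects covariance and residual variance; survival scores carry
// the extra Gauss-Legendre moments  int t^m log(t)^k f(t) dt  needed for
// the Weibull shape/scale and the log-hazard time coefficients.
// Returned gradient layout:
//   [ dpi (G) | dbeta (q1*G) | dB11 dB12 dB22 | dsigma2 | dkappa | drho |
//     dgamma (2*G, per class: t, t^2) | dbeta_s (p) | ddelta ]
// [[Rcpp::export]]
List jlcm_nll_grad_cpp(NumericVector y, NumericVector t, IntegerVector long_ptr,
                       NumericMatrix X, NumericVector Tev, IntegerVector d,
                       NumericVector seg_a, NumericVector seg_b,
                       IntegerVector seg_low, IntegerVector seg_ptr,
                       NumericVector pi, NumericMatrix Beta,
                       NumericMatrix Bmat, double sigma2, double kappa,
                       double rho, NumericMatrix Gam, NumericVector beta_s,
                       double delta) {
  const int n = long_ptr.size() - 1, G = Beta.ncol(), q1 = Beta.nrow(),
            p = X.ncol();
  const double LOG2PI = 1.8378770664093453;
  const double lk = std::log(kappa) + kappa * std::log(rho);
  arma::mat B(2, 2);
  B(0,0) = Bmat(0,0); B(0,1) = Bmat(0,1); B(1,0) = Bmat(1,0); B(1,1) = Bmat(1,1);

  const int npar = G + q1 * G + 3 + 1 + 2 + 2 * G + p + 1;
  arma::vec grad(npar, arma::fill::zeros);
  const int o_pi = 0, o_beta = G, o_B = G + q1 * G, o_s2 = o_B + 3,
            o_k = o_s2 + 1, o_r = o_k + 1, o_g = o_r + 1,
            o_bs = o_g + 2 * G, o_del = o_bs + p;
  double loglik = 0.0;

  arma::vec a(G), dbeta_g(q1);
  arma::mat dbeta(q1, G);
  for (int i = 0; i < n; ++i) {
    a.zeros();
    // per-class pieces collected before the posterior weighting
    arma::vec M11(G, arma::fill::zeros), M12(G, arma::fill::zeros),
              M22(G, arma::fill::zeros), trQ(G, arma::fill::zeros),
              dkap(G, arma::fill::zeros), drho_(G, arma::fill::zeros),
              dg1(G, arma::fill::zeros), dg2(G, arma::fill::zeros),
              deta(G, arma::fill::zeros), ddel(G, arma::fill::zeros);
    dbeta.zeros();

    const int m = long_ptr[i + 1] - long_ptr[i];
    if (m > 0) {
      arma::vec ti(m), yi(m);
      for (int j = 0; j < m; ++j) {
        ti[j] = t[long_ptr[i] + j];
        yi[j] = y[long_ptr[i] + j];
      }
      arma::mat Z(m, 2);
      Z.col(0).ones(); Z.col(1) = ti;
      arma::mat V = arma::symmatu(Z * B * Z.t());
      V.diag() += sigma2;
      if (!V.is_finite()) stop("invalid parameters");
      arma::mat L;
      if (!arma::chol(L, V, "lower"))
        stop("longitudinal covariance not positive definite");
      const double ldet = 2.0 * arma::accu(arma::log(L.diag()));
      arma::mat Vinv = arma::inv_sympd(V);
      const double trVinv = arma::trace(Vinv);
      arma::mat ZtVinvZ = Z.t() * Vinv * Z;   // shared across classes
      arma::mat P(m, q1);
      for (int j = 0; j < m; ++j) {
        double pw = 1.0;
        for (int k = 0; k < q1; ++k) { P(j, k) = pw; pw *= ti[j]; }
      }
      for (int g = 0; g < G; ++g) {
        arma::vec mu(m, arma::fill::zeros);
        for (int k = 0; k < q1; ++k) mu += Beta(k, g) * P.col(k);
        arma::vec r = yi - mu;
        arma::vec u = Vinv * r;
        a[g] += -0.5 * (m * LOG2PI + ldet + arma::dot(r, u));
        dbeta.col(g) = P.t() * u;
        const double zu0 = arma::accu(u), zu1 = arma::dot(ti, u);
        M11[g] = 0.5 * (zu0 * zu0 - ZtVinvZ(0, 0));
        M12[g] = 0.5 * (zu0 * zu1 - ZtVinvZ(0, 1));
        M22[g] = 0.5 * (zu1 * zu1 - ZtVinvZ(1, 1));
        trQ[g] = arma::dot(u, u) - trVinv;
      }
    }
    // survival: per-class cumulative hazard and its parameter moments
    double eta = 0.0;
    for (int k = 0; k < p; ++k) eta += beta_s[k] * X(i, k);
    const int s0 = seg_ptr[i], s1 = seg_ptr[i + 1];
    const double Ti = Tev[i];
    const int lowT = (s1 > s0) ? seg_low[s1 - 1] : 0;
    for (int g = 0; g < G; ++g) {
      const double g1 = Gam(0, g), g2 = Gam(1, g);
      double Lam = 0, Jt = 0, Jt2 = 0, Jkap = 0, Jdel = 0;
      for (int k = s0; k < s1; ++k) {
        const double c = std::exp(eta + delta * seg_low[k]);
        double mom[4];
        seg_moments(seg_a[k], seg_b[k], kappa, rho, g1, g2, mom);
        Lam += c * mom[0]; Jt += c * mom[1]; Jt2 += c * mom[2];
        Jkap += c * mom[3];
        Jdel += seg_low[k] * c * mom[0];
      }
      a[g] += -Lam;
      dkap[g] = -Jkap;
      drho_[g] = -(kappa / rho) * Lam;
      dg1[g] = -Jt; dg2[g] = -Jt2;
      deta[g] = -Lam; ddel[g] = -Jdel;
      if (d[i] == 1) {
        if (Ti <= 0) stop("invalid event time");
        const double lT = std::log(Ti);
        a[g] += lk + (kappa - 1.0) * lT + g1 * Ti + g2 * Ti * Ti +
                eta + delta * lowT;
        dkap[g] += 1.0 / kappa + std::log(rho) + lT;
        drho_[g] += kappa / rho;
        dg1[g] += Ti; dg2[g] += Ti * Ti;
        deta[g] += 1.0; ddel[g] += lowT;
      }
    }
    // posterior weights and accumulation
    double amax = -arma::datum::inf;
    for (int g = 0; g < G; ++g)
      amax = std::max(amax, a[g] + std::log(pi[g]));
    double S = 0.0;
    arma::vec w(G);
    for (int g = 0; g < G; ++g) {
      w[g] = pi[g] * std::exp(a[g] + std::log(pi[g]) - amax - std::log(pi[g]));
      S += w[g];
    }
    loglik += amax + std::log(S);
    w /= S;
    double wM11 = 0, wM12 = 0, wM22 = 0, wtrQ = 0, weta = 0;
    for (int g = 0; g < G; ++g) {
      grad[o_pi + g] += w[g] / pi[g];
      for (int k = 0; k < q1; ++k)
        grad[o_beta + g * q1 + k] += w[g] * dbeta(k, g);
      wM11 += w[g] * M11[g]; wM12 += w[g] * M12[g]; wM22 += w[g] * M22[g];
      wtrQ += w[g] * trQ[g];
      grad[o_k] += w[g] * dkap[g];
      grad[o_r] += w[g] * drho_[g];
      grad[o_g + 2 * g] += w[g] * dg1[g];
      grad[o_g + 2 * g + 1] += w[g] * dg2[g];
      weta += w[g] * deta[g];
      grad[o_del] += w[g] * ddel[g];
    }
    grad[o_B] += wM11; grad[o_B + 1] += 2.0 * wM12; grad[o_B + 2] += wM22;
    grad[o_s2] += 0.5 * wtrQ;
    for (int k = 0; k < p; ++k) grad[o_bs + k] += weta * X(i, k);
  }
  return List::create(_["loglik"] = loglik, _["grad"] = grad);
}

// Per-course, per-class longitudinal and survival log-likelihood cells.
// y, t: stacked DAS28 observations; long_ptr: 0-based course offsets (n+1).
// X: n x p fixed survival covariates; Tev: event/censoring times; d: 0/1.
// seg_*: stacked constant-dose segments covering [0, Tev] per course,
// seg_ptr 0-based offsets (n+1).  Beta: (q+1) x G trajectory coefficients;
// Gam: 2 x G hazard time coefficients.
// [[Rcpp::export]]
List jlcm_cells_cpp(NumericVector y, NumericVector t, IntegerVector long_ptr,
                    NumericMatrix X, NumericVector Tev, IntegerVector d,
                    NumericVector seg_a, NumericVector seg_b,
                    IntegerVector seg_low, IntegerVector seg_ptr,
                    NumericMatrix Beta, NumericMatrix Bmat, double sigma2,
                    double kappa, double rho, NumericMatrix Gam,
                    NumericVector beta_s, double delta) {
  const int n = long_ptr.size() - 1, G = Beta.ncol(), q1 = Beta.nrow(),
            p = X.ncol();
  arma::mat llL(n, G, arma::fill::zeros), llS(n, G, arma::fill::zeros);
  arma::mat B(2, 2);
  B(0,0) = Bmat(0,0); B(0,1) = Bmat(0,1); B(1,0) = Bmat(1,0); B(1,1) = Bmat(1,1);
  const double LOG2PI = 1.8378770664093453;

  for (int i = 0; i < n; ++i) {
    // ---- longitudinal part (covariance shared across classes) ----
    const int m = long_ptr[i + 1] - long_ptr[i];
    if (m > 0) {
      arma::vec ti(m), yi(m);
      for (int j = 0; j < m; ++j) {
        ti[j] = t[long_ptr[i] + j];
        yi[j] = y[long_ptr[i] + j];
      }
      arma::mat Z(m, 2);
      Z.col(0).ones(); Z.col(1) = ti;
      arma::mat V = arma::symmatu(Z * B * Z.t());
      V.diag() += sigma2;
      if (!V.is_finite()) stop("invalid parameters");
      arma::mat L;
      if (!arma::chol(L, V, "lower"))
        stop("longitudinal covariance not positive definite");
      const double ldet = 2.0 * arma::accu(arma::log(L.diag()));
      // polynomial design
      arma::mat P(m, q1);
      for (int j = 0; j < m; ++j) {
        double pw = 1.0;
        for (int k = 0; k < q1; ++k) { P(j, k) = pw; pw *= ti[j]; }
      }
      for (int g = 0; g < G; ++g) {
        arma::vec mu(m, arma::fill::zeros);
        for (int k = 0; k < q1; ++k) mu += Beta(k, g) * P.col(k);
        arma::vec r = arma::solve(arma::trimatl(L), yi - mu);
        llL(i, g) = -0.5 * (m * LOG2PI + ldet + arma::dot(r, r));
      }
    }
    // ---- survival part ----
    double eta = 0.0;
    for (int k = 0; k < p; ++k) eta += beta_s[k] * X(i, k);
    const int s0 = seg_ptr[i], s1 = seg_ptr[i + 1];
    const double Ti = Tev[i];
    for (int g = 0; g < G; ++g) {
      const double g1 = Gam(0, g), g2 = Gam(1, g);
      double Lam = 0.0;
      for (int k = s0; k < s1; ++k)
        Lam += std::exp(eta + delta * seg_low[k]) *
               haz_integral(seg_a[k], seg_b[k], kappa, rho, g1, g2);
      double ll = -Lam;
      if (d[i] == 1) {
        if (Ti <= 0) stop("invalid event time");
        const int lowT = (s1 > s0) ? seg_low[s1 - 1] : 0;
        ll += std::log(kappa) + kappa * std::log(rho) +
              (kappa - 1.0) * std::log(Ti) + g1 * Ti + g2 * Ti * Ti +
              eta + delta * lowT;
      }
      llS(i, g) = ll;
    }
  }
  return List::create(_["ll_long"] = llL, _["ll_surv"] = llS);
}
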