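// Numerical core: bivariate-normal quadrant probabilities, tetrachoric
// root-finding, and the vectorized NWADH candidate scan.
//
// Quadrant probabilities use the Plackett identity
//   P(Z1 > h, Z2 > k; rho) = Phi(-h) Phi(-k) + int_0^rho phi2(h, k; r) dr,
// with the substitution r = sin(theta), which removes the 1/sqrt(1 - r^2)
// endpoint singularity and leaves a smooth integrand handled to machine
// precision by fixed Gauss-Legendre quadrature.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

namespace {

// Gauss-Legendre nodes/weights on [-1, 1], computed once per order by
// Newton iteration on the Legendre polynomial.
void gauss_legendre(int n, std::vector<double>& x, std::vector<double>& w) {
  x.assign(n, 0.0);
  w.assign(n, 0.0);
  const int m = (n + 1) / 2;
  for (int i = 0; i < m; ++i) {
    double z = std::cos(M_PI * (i + 0.75) / (n + 0.5));
    double pp = 0.0;
    for (int it = 0; it < 100; ++it) {
      double p1 = 1.0, p2 = 0.0;
      for (int j = 0; j < n; ++j) {
        double p3 = p2;
        p2 = p1;
        p1 = ((2.0 * j + 1.0) * z * p2 - j * p3) / (j + 1.0);
      }
      pp = n * (z * p1 - p2) / (z * z - 1.0);
      double z1 = z;
      z = z1 - p1 / pp;
      if (std::fabs(z - z1) < 1e-15) break;
    }
    x[i] = -z;
    x[n - 1 - i] = z;
    w[i] = 2.0 / ((1.0 - z * z) * pp * pp);
    w[n - 1 - i] = w[i];
  }
}

const int GL_N = 48;
std::vector<double> gl_x, gl_w;

void ensure_gl() {
  if ((int)gl_x.size() != GL_N) gauss_legendre(GL_N, gl_x, gl_w);
}

// int_0^asin(rho) exp(-(h^2 + k^2 - 2 h k sin(t)) / (2 cos^2(t))) dt / (2 pi)
double bvn_integral(double h, double k, double rho) {
  ensure_gl();
  const double up = std::asin(rho);
  const double c1 = 0.5 * up, c2 = 0.5 * up;  // map [-1,1] -> [0, up]
  double s = 0.0;
  for (int i = 0; i < GL_N; ++i) {
    const double t = c1 * gl_x[i] + c2;
    const double st = std::sin(t);
    const double ct2 = std::cos(t) * std::cos(t);
    s += gl_w[i] * std::exp(-(h * h + k * k - 2.0 * h * k * st) / (2.0 * ct2));
  }
  return c1 * s / (2.0 * M_PI);
}

double bvn_upper(double h, double k, double rho) {
  if (rho > 0.999999999) rho = 0.999999999;
  if (rho < -0.999999999) rho = -0.999999999;
  return R::pnorm(-h, 0.0, 1.0, 1, 0) * R::pnorm(-k, 0.0, 1.0, 1, 0) +
         bvn_integral(h, k, rho);
}

// Symmetric-table tetrachoric: thresholds tau = tau1 = tau2 follow from the
// margin m1 = P(alpha = 1); the replication table gives p11 = m2 = E[p-hat^2].
// Solve bvn_upper(tau, tau, rho) = m2 for rho; degenerate margins map to 1.
double tetra_sym(double m1, double m2) {
  const double eps = 1e-10;
  if (m1 <= eps || m1 >= 1.0 - eps) return 1.0;
  const double tau = R::qnorm(1.0 - m1, 0.0, 1.0, 1, 0);
  const double indep = m1 * m1;
  const double target = m2 - indep;  // = integral term at the solution
  const double lo = -1.0 + 1e-9, hi = 1.0 - 1e-9;
  if (target >= bvn_integral(tau, tau, hi)) return 1.0;
  if (target <= bvn_integral(tau, tau, lo)) return -1.0;
  // safeguarded Newton: f(rho) = bvn_integral - target, f' = phi2(tau,tau;rho)
  double a = lo, b = hi, rho = 0.0;
  double f = bvn_integral(tau, tau, rho) - target;
  for (int it = 0; it < 100; ++it) {
    if (std::fabs(f) < 1e-12) break;
    if (f > 0) b = rho; else a = rho;
    const double omr2 = 1.0 - rho * rho;
    const double fp = std::exp(-tau * tau / (1.0 + rho)) /
                      (2.0 * M_PI * std::sqrt(omr2));
    double step = rho - f / fp;
    if (step <= a || step >= b) step = 0.5 * (a + b);  // bisection fallback
    rho = step;
    f = bvn_integral(tau, tau, rho) - target;
  }
  return rho;
}

}  // namespace

//' @noRd
// [[Rcpp::export]]
double cpp_bvn_upper(double h, double k, double rho) {
  return bvn_upper(h, k, rho);
}

// [[Rcpp::export]]
NumericVector cpp_tetrachoric_sym(NumericVector m1, NumericVector m2) {
  const int n = m1.size();
  NumericVector out(n);
  for (int i = 0; i < n; ++i) out[i] = tetra_sym(m1[i], m2[i]);
  return out;
}

// One NWADH scan: for every candidate item i, compute the mean absolute
// deviation d_i^{J+1} between the reliability targets and the attribute
// reliabilities obtained after appending i to the current selection.
//
//   w       N x C   posterior over the 2^K states (rows sum to 1)
//   A       C x K   state-by-attribute mastery indicators
//   P       C x ncand  candidate state-probability columns P_i(alpha_c)
//   X       N x ncand  calibration responses to the candidates (0/1)
//   targets K       target attribute reliabilities
//
// The posterior update for candidate i multiplies examinee e's posterior by
// P_i(alpha_c) when x_ei = 1 and 1 - P_i(alpha_c) otherwise; the per-attribute
// marginal mastery moments needed by the replication table (E[p-hat] and
// E[p-hat^2]) then reduce to matrix products, so the whole pool is scored with
// K + 1 GEMMs rather than ncand separate refits.
// [[Rcpp::export]]
List cpp_candidate_deviations(const arma::mat& w, const arma::mat& A,
                              const arma::mat& P, const arma::mat& X,
                              const arma::vec& targets) {
  const arma::uword N = w.n_rows, K = A.n_cols, ncand = P.n_cols;
  const arma::mat B = w * P;            // N x ncand: responder normalizers
  const arma::mat phat0 = w * A;        // N x K: current marginals
  const arma::mat Xc = 1.0 - X;
  const arma::mat denom = X % B + Xc % (1.0 - B);
  arma::vec d(ncand, arma::fill::zeros);
  arma::mat rho(K, ncand);
  for (arma::uword k = 0; k < K; ++k) {
    arma::mat Pk = P.each_col() % A.col(k);       // C x ncand
    arma::mat Nk = w * Pk;                        // N x ncand
    arma::mat num = X % Nk + Xc % (arma::repmat(phat0.col(k), 1, ncand) - Nk);
    arma::mat phat = num / denom;
    arma::rowvec m1 = arma::mean(phat, 0);
    arma::rowvec m2 = arma::mean(phat % phat, 0);
    for (arma::uword i = 0; i < ncand; ++i) {
      const double r = tetra_sym(m1(i), m2(i));
      rho(k, i) = r;
      d(i) += std::fabs(targets(k) - r);
    }
  }
  d /= (double)K;
  (void)N;
  return List::create(_["d"] = d, _["reliability"] = rho);
}
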