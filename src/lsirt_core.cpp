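// Log posterior and gradient for the latent space Rasch model on the
// expanded slow/fast matrix, in the sampler's unconstrained parameterization
// (log scales for gamma, sigma_theta, sigma_c, with Jacobians included),
// plus a leapfrog-trajectory driver so Hamiltonian updates run at C++ speed
// while all randomness stays in R.
//
// Parameter vector layout (length P + nc + 4 + (P+J)*k):
//   [ theta(P) | c(nc) | log_gamma | mu_c | log_sigma_theta | log_sigma_c |
//     a(P*k, column-major) | b(J*k, column-major) ]
// nc = I for the constrained model (easiness tied across slow/fast), 2I
// otherwise; itemmap (0-based, length J) maps pseudo-item -> easiness index.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static const double ETA_CLIP = 35.0;
static const double DIST_EPS = 1e-12;
static const double LOG2PI = 1.8378770664093454836;

// numerically stable log(sigmoid(x))
static inline double log_sigmoid(double x) {
  if (x >= 0.0) return -std::log1p(std::exp(-x));
  return x - std::log1p(std::exp(x));
}

struct LsirtModel {
  const IntegerMatrix& Y;
  const IntegerVector& itemmap;
  int P, J, k, nc;
  int off_c, off_lg, off_mu, off_lst, off_lsc, off_a, off_b, npar;
  double gamma_sd, mu_c_sd, theta_sd_scale, easiness_sd_scale;

  LsirtModel(const IntegerMatrix& Y_, const IntegerVector& itemmap_, int k_,
             double gsd, double musd, double tsd, double esd)
    : Y(Y_), itemmap(itemmap_), P(Y_.nrow()), J(Y_.ncol()), k(k_),
      gamma_sd(gsd), mu_c_sd(musd), theta_sd_scale(tsd),
      easiness_sd_scale(esd) {
    nc = 0;
    for (int j = 0; j < J; ++j) nc = std::max(nc, itemmap[j] + 1);
    off_c = P;
    off_lg = P + nc;
    off_mu = off_lg + 1;
    off_lst = off_mu + 1;
    off_lsc = off_lst + 1;
    off_a = off_lsc + 1;
    off_b = off_a + P * k;
    npar = off_b + J * k;
  }

  // lp (with Jacobians); grad filled when want_grad; loglik_out optional
  double lp_grad(const arma::vec& par, arma::vec& grad, bool want_grad,
                 double* loglik_out = nullptr) const {
    const arma::vec theta = par.subvec(0, P - 1);
    const arma::vec cc = par.subvec(off_c, off_c + nc - 1);
    const double log_gamma = par[off_lg];
    const double gamma = std::exp(log_gamma);
    const double mu_c = par[off_mu];
    const double sig_t = std::exp(par[off_lst]);
    const double sig_c = std::exp(par[off_lsc]);
    const arma::mat A(const_cast<double*>(par.memptr()) + off_a, P, k,
                      false, true);
    const arma::mat B(const_cast<double*>(par.memptr()) + off_b, J, k,
                      false, true);

    if (want_grad) grad.zeros(npar);
    arma::mat gA(want_grad ? grad.memptr() + off_a : nullptr, P, k,
                 false, true);
    arma::mat gB(want_grad ? grad.memptr() + off_b : nullptr, J, k,
                 false, true);

    double ll = 0.0;
    double g_gamma_nat = 0.0;

    for (int j = 0; j < J; ++j) {
      const int m = itemmap[j];
      const double cj = cc[m];
      double colsum_r = 0.0;
      for (int p = 0; p < P; ++p) {
        const int y = Y(p, j);
        if (y == NA_INTEGER) continue;
        double d2 = 0.0;
        for (int t = 0; t < k; ++t) {
          const double diff = A(p, t) - B(j, t);
          d2 += diff * diff;
        }
        const double d = std::sqrt(d2);
        double eta = theta[p] + cj - gamma * d;
        if (eta > ETA_CLIP) eta = ETA_CLIP;
        if (eta < -ETA_CLIP) eta = -ETA_CLIP;
        ll += (y == 1) ? log_sigmoid(eta) : log_sigmoid(-eta);
        if (!want_grad) continue;
        const double mu = 1.0 / (1.0 + std::exp(-eta));
        const double r = (double)y - mu;
        grad[p] += r;
        colsum_r += r;
        g_gamma_nat -= r * d;
        const double w = -gamma * r / std::max(d, DIST_EPS);
        for (int t = 0; t < k; ++t) {
          const double diff = A(p, t) - B(j, t);
          gA(p, t) += w * diff;
          gB(j, t) -= w * diff;
        }
      }
      if (want_grad) grad[off_c + m] += colsum_r;
    }
    if (loglik_out) *loglik_out = ll;

    // ---- priors (all normalizing constants included) ----
    const double st2 = sig_t * sig_t, sc2 = sig_c * sig_c;
    double lp = ll;
    lp += -0.5 * P * LOG2PI - P * std::log(sig_t) -
          arma::dot(theta, theta) / (2.0 * st2);
    arma::vec cdev = cc - mu_c;
    lp += -0.5 * nc * LOG2PI - nc * std::log(sig_c) -
          arma::dot(cdev, cdev) / (2.0 * sc2);
    lp += std::log(2.0) - 0.5 * LOG2PI - std::log(gamma_sd) -
          gamma * gamma / (2.0 * gamma_sd * gamma_sd) + log_gamma;
    lp += -0.5 * (P + J) * k * LOG2PI -
          0.5 * (arma::accu(A % A) + arma::accu(B % B));
    lp += -0.5 * LOG2PI - std::log(mu_c_sd) -
          mu_c * mu_c / (2.0 * mu_c_sd * mu_c_sd);
    const double s1 = theta_sd_scale, s2 = easiness_sd_scale;
    lp += std::log(2.0 / (M_PI * s1)) - std::log1p(st2 / (s1 * s1)) +
          par[off_lst];
    lp += std::log(2.0 / (M_PI * s2)) - std::log1p(sc2 / (s2 * s2)) +
          par[off_lsc];

    if (want_grad) {
      for (int p = 0; p < P; ++p) grad[p] -= theta[p] / st2;
      for (int m = 0; m < nc; ++m) grad[off_c + m] -= cdev[m] / sc2;
      grad[off_lg] = gamma * (g_gamma_nat - gamma / (gamma_sd * gamma_sd)) + 1.0;
      grad[off_mu] = arma::accu(cdev) / sc2 - mu_c / (mu_c_sd * mu_c_sd);
      grad[off_lst] = -P + arma::dot(theta, theta) / st2 -
                      2.0 * st2 / (s1 * s1 + st2) + 1.0;
      grad[off_lsc] = -nc + arma::dot(cdev, cdev) / sc2 -
                      2.0 * sc2 / (s2 * s2 + sc2) + 1.0;
      gA -= A;
      gB -= B;
    }
    return lp;
  }
};

// [[Rcpp::export(name = ".lsirt_lp_grad")]]
List lsirt_lp_grad(const arma::vec& par,
                   const IntegerMatrix& Y,
                   const IntegerVector& itemmap,
                   int k,
                   double gamma_sd, double mu_c_sd,
                   double theta_sd_scale, double easiness_sd_scale,
                   bool want_grad = true) {
  LsirtModel model(Y, itemmap, k, gamma_sd, mu_c_sd, theta_sd_scale,
                   easiness_sd_scale);
  if ((int)par.n_elem != model.npar) stop("parameter vector has wrong length");
  arma::vec grad;
  double ll = 0.0;
  double lp = model.lp_grad(par, grad, want_grad, &ll);
  if (!want_grad) grad.zeros(1);
  return List::create(Named("lp") = lp, Named("grad") = grad,
                      Named("loglik") = ll);
}

// One full leapfrog trajectory. q: full parameter vector; mom: momentum on
// the free coordinates; free_idx 0-based. Returns the proposal, its lp and
// final momentum; divergence when lp becomes non-finite mid-trajectory.
// [[Rcpp::export(name = ".lsirt_leapfrog")]]
List lsirt_leapfrog(const arma::vec& q0, const arma::vec& mom0,
                    const IntegerVector& free_idx, double eps, int L,
                    const arma::vec& inv_mass,
                    const IntegerMatrix& Y, const IntegerVector& itemmap,
                    int k, double gamma_sd, double mu_c_sd,
                    double theta_sd_scale, double easiness_sd_scale) {
  LsirtModel model(Y, itemmap, k, gamma_sd, mu_c_sd, theta_sd_scale,
                   easiness_sd_scale);
  if ((int)q0.n_elem != model.npar) stop("parameter vector has wrong length");
  const int nf = free_idx.size();
  arma::vec q = q0, p = mom0, grad(model.npar);

  double lp = model.lp_grad(q, grad, true);
  bool diverged = !std::isfinite(lp);
  if (!diverged) {
    for (int f = 0; f < nf; ++f) p[f] += 0.5 * eps * grad[free_idx[f]];
    for (int l = 0; l < L; ++l) {
      for (int f = 0; f < nf; ++f)
        q[free_idx[f]] += eps * inv_mass[f] * p[f];
      lp = model.lp_grad(q, grad, true);
      if (!std::isfinite(lp)) { diverged = true; break; }
      const double scale = (l < L - 1) ? eps : 0.5 * eps;
      for (int f = 0; f < nf; ++f) p[f] += scale * grad[free_idx[f]];
    }
  }
  return List::create(Named("q") = q, Named("p") = p, Named("lp") = lp,
                      Named("diverged") = diverged);
}

// Per-draw Euclidean distances for selected (person, pseudo-item) pairs.
// draws: n_draws x npar matrix in the layout above.
// [[Rcpp::export(name = ".lsirt_distance_draws")]]
NumericMatrix lsirt_distance_draws(const NumericMatrix& draws,
                                   int off_a, int off_b, int P, int J, int k,
                                   const IntegerVector& p_idx,   // 0-based
                                   const IntegerVector& j_idx) { // 0-based
  const int n = draws.nrow();
  const int m = p_idx.size();
  NumericMatrix out(n, m);
  for (int d = 0; d < n; ++d) {
    for (int q = 0; q < m; ++q) {
      const int p = p_idx[q], j = j_idx[q];
      double d2 = 0.0;
      for (int t = 0; t < k; ++t) {
        const double diff = draws(d, off_a + t * P + p) -
                            draws(d, off_b + t * J + j);
        d2 += diff * diff;
      }
      out(d, q) = std::sqrt(d2);
    }
  }
  return out;
}
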