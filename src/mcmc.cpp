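// Likelihood and adaptive Metropolis-within-Gibbs sampler for the
// inheritance-matrix model. The data are five summary statistics (the
// interdivision-time variance and the mother-daughter, grandmother,
// sister and cousin correlations); the log-likelihood is the negative sum
// of squared standardised residuals, with a flat prior restricted to
// spectral radius(theta) < 1 and a PSD noise covariance.
//
// Parameter layouts (natural coordinates):
//   N = 1:  (theta, var1)            + (r2) when the sister noise
//           cross-covariance S2 = r2 * var1 is free
//   N = 2:  (th11, th21, th12, th22, var1, var2, r)   with S2 fixed to 0
//           and S1 = [[v1, r*sqrt(v1 v2)], [., v2]]
//
// All randomness comes from R's RNG, so chains are reproducible from
// set.seed() on the R side.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// spectral radius for N <= 2 without a general eigensolver
static double spec_radius(const mat& th) {
  if (th.n_rows == 1) return std::abs(th(0, 0));
  double tr = th(0, 0) + th(1, 1);
  double dt = th(0, 0) * th(1, 1) - th(0, 1) * th(1, 0);
  double disc = tr * tr - 4.0 * dt;
  if (disc < 0.0) return std::sqrt(dt);          // complex pair: |lambda|^2 = det
  double s = std::sqrt(disc);
  return std::max(std::abs((tr + s) / 2.0), std::abs((tr - s) / 2.0));
}

struct ModelPar {
  mat theta, s1, s2;
  bool ok;
};

static ModelPar unpack(const vec& par, int n_factors, bool s2_free) {
  ModelPar mp;
  mp.ok = false;
  if (n_factors == 1) {
    mp.theta = mat(1, 1, fill::none);
    mp.theta(0, 0) = par(0);
    double v = par(1);
    if (v <= 0.0) return mp;
    mp.s1 = mat(1, 1, fill::none);
    mp.s1(0, 0) = v;
    mp.s2 = mat(1, 1, fill::zeros);
    if (s2_free) {
      double r2 = par(2);
      if (std::abs(r2) > 1.0) return mp;
      mp.s2(0, 0) = r2 * v;
    }
  } else {
    mp.theta = reshape(mat(par.subvec(0, 3)), 2, 2); // column-major
    double v1 = par(4), v2 = par(5), r = par(6);
    if (v1 <= 0.0 || v2 <= 0.0 || std::abs(r) > 1.0) return mp;
    mp.s1 = mat(2, 2, fill::none);
    mp.s1(0, 0) = v1;
    mp.s1(1, 1) = v2;
    mp.s1(0, 1) = mp.s1(1, 0) = r * std::sqrt(v1 * v2);
    mp.s2 = mat(2, 2, fill::zeros);
  }
  if (spec_radius(mp.theta) >= 1.0) return mp;
  mp.ok = true;
  return mp;
}

// stationary covariance: vec(Sigma) = (I - theta (x) theta)^{-1} vec(S1)
static bool lyapunov(const mat& theta, const mat& s1, mat& sigma) {
  uword n = theta.n_rows;
  mat a = eye(n * n, n * n) - kron(theta, theta);
  vec s;
  if (!solve(s, a, vectorise(s1), solve_opts::no_approx)) return false;
  sigma = reshape(s, n, n);
  sigma = (sigma + sigma.t()) / 2.0;
  return true;
}

// (s_tau, rho(1,0), rho(2,0), rho(1,1), rho(2,2))
static bool model_stats(const ModelPar& mp, const vec& alpha, vec& out) {
  mat sigma;
  if (!lyapunov(mp.theta, mp.s1, sigma)) return false;
  double s_tau = as_scalar(alpha.t() * sigma * alpha);
  if (!(s_tau > 0.0)) return false;
  const mat& th = mp.theta;
  mat th2 = th * th;
  out.set_size(5);
  out(0) = s_tau;
  out(1) = as_scalar(alpha.t() * th * sigma * alpha) / s_tau;
  out(2) = as_scalar(alpha.t() * th2 * sigma * alpha) / s_tau;
  out(3) = as_scalar(alpha.t() * (th * sigma * th.t() + mp.s2) * alpha) / s_tau;
  out(4) = as_scalar(alpha.t() * (th2 * sigma * th2.t() +
                                  th * mp.s2 * th.t()) * alpha) / s_tau;
  return true;
}

static double loglik(const vec& par, int n_factors, bool s2_free,
                     const vec& alpha, const vec& data, const vec& sds) {
  ModelPar mp = unpack(par, n_factors, s2_free);
  if (!mp.ok) return -datum::inf;
  vec stats;
  if (!model_stats(mp, alpha, stats)) return -datum::inf;
  double nll = 0.0;
  for (uword i = 0; i < 5; ++i) {
    double z = (data(i) - stats(i)) / sds(i);
    nll += z * z;
  }
  return -nll;
}

// [[Rcpp::export]]
Rcpp::NumericVector cpp_model_stats(Rcpp::NumericVector par, int n_factors,
                                    bool s2_free, Rcpp::NumericVector alpha) {
  ModelPar mp = unpack(vec(par.begin(), par.size()), n_factors, s2_free);
  if (!mp.ok) Rcpp::stop("parameter vector outside the prior support");
  vec stats;
  if (!model_stats(mp, vec(alpha.begin(), alpha.size()), stats))
    Rcpp::stop("degenerate model statistics");
  return Rcpp::NumericVector(stats.begin(), stats.end());
}

// [[Rcpp::export]]
double cpp_loglik(Rcpp::NumericVector par, int n_factors, bool s2_free,
                  Rcpp::NumericVector alpha, Rcpp::NumericVector data,
                  Rcpp::NumericVector sds) {
  return loglik(vec(par.begin(), par.size()), n_factors, s2_free,
                vec(alpha.begin(), alpha.size()),
                vec(data.begin(), data.size()),
                vec(sds.begin(), sds.size()));
}

// [[Rcpp::export]]
bool cpp_in_support(Rcpp::NumericVector par, int n_factors, bool s2_free) {
  return unpack(vec(par.begin(), par.size()), n_factors, s2_free).ok;
}

// Adaptive Metropolis-within-Gibbs. One coordinate is updated per step
// with a Gaussian proposal; the per-coordinate proposal scale adapts in
// batches of 50 updates toward the target acceptance rate during burn-in
// and is frozen afterwards (preserving detailed balance for the retained
// part of the chain).
// [[Rcpp::export]]
Rcpp::List cpp_mcmc(Rcpp::NumericVector init, int n_factors, bool s2_free,
                    Rcpp::NumericVector alpha_, Rcpp::NumericVector data_,
                    Rcpp::NumericVector sds_, int n_samples, int n_burnin,
                    int thin, double target_accept,
                    Rcpp::NumericVector prop_sd_init) {
  vec par(init.begin(), init.size());
  vec alpha(alpha_.begin(), alpha_.size());
  vec data(data_.begin(), data_.size());
  vec sds(sds_.begin(), sds_.size());
  const int p = par.n_elem;
  vec log_sd(p);
  for (int c = 0; c < p; ++c) log_sd(c) = std::log(prop_sd_init[c]);

  double ll = loglik(par, n_factors, s2_free, alpha, data, sds);
  if (!std::isfinite(ll) && ll != -datum::inf)
    Rcpp::stop("invalid initial state");
  if (ll == -datum::inf)
    Rcpp::stop("initial state outside the prior support");

  int n_keep = (n_samples - n_burnin + thin - 1) / thin;
  mat chain(n_keep, p);
  vec keep_ll(n_keep);
  ivec batch_acc(p, fill::zeros), batch_n(p, fill::zeros),
       batch_id(p, fill::ones);
  ivec post_acc(p, fill::zeros), post_n(p, fill::zeros);
  int kept = 0;

  for (int t = 0; t < n_samples; ++t) {
    int c = t % p;
    double old = par(c);
    par(c) = old + std::exp(log_sd(c)) * norm_rand();
    double ll_new = loglik(par, n_factors, s2_free, alpha, data, sds);
    bool accept = std::log(unif_rand()) < (ll_new - ll);
    if (accept) {
      ll = ll_new;
    } else {
      par(c) = old;
    }
    if (t < n_burnin) {
      batch_n(c) += 1;
      if (accept) batch_acc(c) += 1;
      if (batch_n(c) == 50) {
        double rate = batch_acc(c) / 50.0;
        double delta = std::min(0.05, 1.0 / std::sqrt((double)batch_id(c)));
        log_sd(c) += (rate > target_accept) ? delta : -delta;
        batch_n(c) = 0;
        batch_acc(c) = 0;
        batch_id(c) += 1;
      }
    } else {
      post_n(c) += 1;
      if (accept) post_acc(c) += 1;
      if ((t - n_burnin) % thin == 0) {
        chain.row(kept) = par.t();
        keep_ll(kept) = ll;
        ++kept;
      }
    }
    if (t % 65536 == 0) Rcpp::checkUserInterrupt();
  }

  vec acc_rate(p);
  for (int c = 0; c < p; ++c)
    acc_rate(c) = post_n(c) > 0 ? (double)post_acc(c) / post_n(c) : NA_REAL;

  return Rcpp::List::create(
    Rcpp::Named("chain") = chain.rows(0, kept - 1),
    Rcpp::Named("log_lik") = Rcpp::NumericVector(keep_ll.begin(),
                                                 keep_ll.begin() + kept),
    Rcpp::Named("accept_rate") = Rcpp::NumericVector(acc_rate.begin(),
                                                     acc_rate.end()),
    Rcpp::Named("prop_sd") = Rcpp::NumericVector(log_sd.begin(),
                                                 log_sd.end()));
}
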