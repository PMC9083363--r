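#include <Rcpp.h>
#include "rng-utils.h"

using namespace Rcpp;
using speedmix::rpg1;
using speedmix::rtnorm_lb;
using speedmix::rtnorm_ab;
using speedmix::rinvgamma;
using speedmix::dnorm_log_v;

// Full-conditional updates for the rapid-guessing mixture model. Item and
// ability updates are the Polya-gamma augmented conditionals; sums run over
// solution-behavior (eta = 0) cells only, because rapid-guess cells carry no
// information about (a, b, theta) or the solution-time parameters.

static void check_finite(const NumericVector& x, const char* step) {
  for (int i = 0; i < x.size(); ++i)
    if (!R_finite(x[i])) stop("non-finite value produced in %s", step);
}

// stable log P(Y=1) and log P(Y=0) for the 2PL with linear predictor x
static inline void logistic_logpq(double x, double& lp1, double& lp0) {
  if (x > 0) {
    double e = std::exp(-x);
    lp1 = -std::log1p(e);
    lp0 = -x + lp1;
  } else {
    double e = std::exp(x);
    lp0 = -std::log1p(e);
    lp1 = x + lp0;
  }
}

// ---- step cores -----------------------------------------------------------

static void core_step_W(const IntegerMatrix& eta, const NumericVector& a,
                        const NumericVector& b, const NumericVector& theta,
                        NumericMatrix& W) {
  int N = eta.nrow(), J = eta.ncol();
  for (int j = 0; j < J; ++j)
    for (int i = 0; i < N; ++i)
      if (eta(i, j) == 0) W(i, j) = rpg1(a[j] * (theta[i] - b[j]));
}

static void core_step_a(const IntegerMatrix& Y, const IntegerMatrix& eta,
                        const NumericMatrix& W, const NumericVector& theta,
                        const NumericVector& b, double mu_a, double s2_a,
                        NumericVector& a) {
  int N = Y.nrow(), J = Y.ncol();
  for (int j = 0; j < J; ++j) {
    double sw = 0.0, sk = 0.0;
    for (int i = 0; i < N; ++i) {
      if (eta(i, j) != 0) continue;
      double d = theta[i] - b[j];
      sw += W(i, j) * d * d;
      sk += (Y(i, j) - 0.5) * d;
    }
    double v = 1.0 / (1.0 / s2_a + sw);
    double m = v * (mu_a / s2_a + sk);
    a[j] = rtnorm_lb(m, std::sqrt(v), 0.0);
  }
}

static void core_step_b(const IntegerMatrix& Y, const IntegerMatrix& eta,
                        const NumericMatrix& W, const NumericVector& theta,
                        const NumericVector& a, double mu_b, double s2_b,
                        NumericVector& b) {
  int N = Y.nrow(), J = Y.ncol();
  for (int j = 0; j < J; ++j) {
    double aj = a[j], sw = 0.0, sm = 0.0;
    for (int i = 0; i < N; ++i) {
      if (eta(i, j) != 0) continue;
      sw += aj * aj * W(i, j);
      sm += aj * aj * theta[i] * W(i, j) - aj * (Y(i, j) - 0.5);
    }
    double v = 1.0 / (1.0 / s2_b + sw);
    double m = v * (mu_b / s2_b + sm);
    b[j] = R::rnorm(m, std::sqrt(v));
  }
}

static void core_step_theta(const IntegerMatrix& Y, const IntegerMatrix& eta,
                            const NumericMatrix& W, const NumericVector& a,
                            const NumericVector& b, const NumericVector& tau,
                            double s_tt, double s2_t, NumericVector& theta) {
  int N = Y.nrow(), J = Y.ncol();
  double pv = 1.0 - s_tt * s_tt / s2_t;  // var(theta | tau), sigma2_theta = 1
  for (int i = 0; i < N; ++i) {
    double pm = s_tt / s2_t * tau[i];
    double sw = 0.0, sm = 0.0;
    for (int j = 0; j < J; ++j) {
      if (eta(i, j) != 0) continue;
      double aj = a[j];
      sw += aj * aj * W(i, j);
      sm += aj * (Y(i, j) - 0.5) + aj * aj * b[j] * W(i, j);
    }
    double v = 1.0 / (1.0 / pv + sw);
    double m = v * (pm / pv + sm);
    theta[i] = R::rnorm(m, std::sqrt(v));
  }
}

static int core_step_eta(const IntegerMatrix& Y, const NumericMatrix& logT,
                         const NumericVector& a, const NumericVector& b,
                         const NumericVector& g, const NumericVector& lam,
                         const NumericVector& s2, const NumericVector& theta,
                         const NumericVector& tau, const NumericVector& pi,
                         double mu_c, double s2_c, IntegerMatrix& eta) {
  int N = Y.nrow(), J = Y.ncol(), clamped = 0;
  std::vector<double> lpi1(N), lpi0(N);
  for (int i = 0; i < N; ++i) {
    lpi1[i] = std::log(pi[i]);
    lpi0[i] = std::log1p(-pi[i]);
  }
  double ldc = -0.5 * std::log(2.0 * M_PI * s2_c), i2c = 0.5 / s2_c;
  for (int j = 0; j < J; ++j) {
    double lg1 = std::log(g[j]), lg0 = std::log1p(-g[j]);
    double ldj = -0.5 * std::log(2.0 * M_PI * s2[j]), i2j = 0.5 / s2[j];
    for (int i = 0; i < N; ++i) {
      double lt = logT(i, j);
      double lp1, lp0;
      logistic_logpq(a[j] * (theta[i] - b[j]), lp1, lp0);
      bool y1 = (Y(i, j) == 1);
      double dc = lt - mu_c, dj = lt - lam[j] + tau[i];
      double l1 = lpi1[i] + (y1 ? lg1 : lg0) + ldc - dc * dc * i2c;
      double l0 = lpi0[i] + (y1 ? lp1 : lp0) + ldj - dj * dj * i2j;
      double d = l1 - l0;
      if (d > 700.0) { d = 700.0; ++clamped; }
      if (d < -700.0) { d = -700.0; ++clamped; }
      double p = 1.0 / (1.0 + std::exp(-d));
      eta(i, j) = (unif_rand() < p) ? 1 : 0;
    }
  }
  return clamped;
}

static void core_step_pi(const IntegerMatrix& eta, double i1, double i2,
                         NumericVector& pi) {
  int N = eta.nrow(), J = eta.ncol();
  for (int i = 0; i < N; ++i) {
    int s = 0;
    for (int j = 0; j < J; ++j) s += eta(i, j);
    pi[i] = R::rbeta(i1 + s, i2 + J - s);
  }
}

static void core_step_g(const IntegerMatrix& Y, const IntegerMatrix& eta,
                        double i3, double i4, NumericVector& g) {
  int N = Y.nrow(), J = Y.ncol();
  for (int j = 0; j < J; ++j) {
    int s = 0, sy = 0;
    for (int i = 0; i < N; ++i) {
      s += eta(i, j);
      sy += eta(i, j) * Y(i, j);
    }
    g[j] = R::rbeta(i3 + sy, i4 + s - sy);
  }
}

static void core_step_tau(const NumericMatrix& logT, const IntegerMatrix& eta,
                          const NumericVector& lam, const NumericVector& s2,
                          const NumericVector& theta, double s_tt, double s2_t,
                          NumericVector& tau) {
  int N = logT.nrow(), J = logT.ncol();
  double pv = s2_t - s_tt * s_tt;  // var(tau | theta)
  for (int i = 0; i < N; ++i) {
    double pm = s_tt * theta[i];
    double prec = 1.0 / pv, sm = pm / pv;
    for (int j = 0; j < J; ++j) {
      if (eta(i, j) != 0) continue;
      prec += 1.0 / s2[j];
      sm += (lam[j] - logT(i, j)) / s2[j];
    }
    double v = 1.0 / prec;
    tau[i] = R::rnorm(v * sm, std::sqrt(v));
  }
}

static void core_step_lambda(const NumericMatrix& logT, const IntegerMatrix& eta,
                             const NumericVector& tau, const NumericVector& s2,
                             double mu_l, double s2_l, NumericVector& lam) {
  int N = logT.nrow(), J = logT.ncol();
  for (int j = 0; j < J; ++j) {
    double n0 = 0.0, s = 0.0;
    for (int i = 0; i < N; ++i) {
      if (eta(i, j) != 0) continue;
      n0 += 1.0;
      s += logT(i, j) + tau[i];
    }
    double v = 1.0 / (1.0 / s2_l + n0 / s2[j]);
    double m = v * (mu_l / s2_l + s / s2[j]);
    lam[j] = R::rnorm(m, std::sqrt(v));
  }
}

static void core_step_sigma2(const NumericMatrix& logT, const IntegerMatrix& eta,
                             const NumericVector& tau, const NumericVector& lam,
                             double ups1, double om1, NumericVector& s2) {
  int N = logT.nrow(), J = logT.ncol();
  for (int j = 0; j < J; ++j) {
    double n0 = 0.0, ss = 0.0;
    for (int i = 0; i < N; ++i) {
      if (eta(i, j) != 0) continue;
      n0 += 1.0;
      double d = logT(i, j) - lam[j] + tau[i];
      ss += d * d;
    }
    s2[j] = rinvgamma(ups1 + 0.5 * n0, om1 + 0.5 * ss);
  }
}

// returns 1 when the update was skipped (no rapid-guess cells)
static int core_step_guess_rt(const NumericMatrix& logT, const IntegerMatrix& eta,
                              double ups2, double om2, double& mu_c,
                              double& s2_c) {
  int N = logT.nrow(), J = logT.ncol();
  double n1 = 0.0, s = 0.0;
  for (int j = 0; j < J; ++j)
    for (int i = 0; i < N; ++i)
      if (eta(i, j) == 1) {
        n1 += 1.0;
        s += logT(i, j);
      }
  if (n1 < 1.0) return 1;
  mu_c = R::rnorm(s / n1, std::sqrt(s2_c / n1));
  double ss = 0.0;
  for (int j = 0; j < J; ++j)
    for (int i = 0; i < N; ++i)
      if (eta(i, j) == 1) {
        double d = logT(i, j) - mu_c;
        ss += d * d;
      }
  s2_c = rinvgamma(ups2 + 0.5 * n1, om2 + 0.5 * ss);
  return 0;
}

// sum_i log p(tau_i | theta_i) under N(s_tt * theta_i, s2_t - s_tt^2)
static double cov_loglik(const NumericVector& theta, const NumericVector& tau,
                         double s_tt, double s2_t) {
  double v = s2_t - s_tt * s_tt;
  if (v <= 0.0) return R_NegInf;
  int N = theta.size();
  double ll = -0.5 * N * std::log(2.0 * M_PI * v);
  for (int i = 0; i < N; ++i) {
    double d = tau[i] - s_tt * theta[i];
    ll -= 0.5 * d * d / v;
  }
  return ll;
}

static inline double log_trunc_mass(double lo, double hi, double center,
                                    double sd) {
  double m = R::pnorm(hi, center, sd, 1, 0) - R::pnorm(lo, center, sd, 1, 0);
  return std::log(std::max(m, 1e-300));
}

// Metropolis-Hastings updates of the constrained person covariance:
// the covariance sigma_thetatau on (-p01, p01) with p01 = sigma_tau (the
// positive-definiteness boundary, since sigma2_theta = 1), then sigma2_tau
// on (p0, Inf) with p0 = sigma_thetatau^2. The truncation bounds keep the
// 2x2 person covariance positive definite at every iteration.
static void core_mh_cov(const NumericVector& theta, const NumericVector& tau,
                        double s01, double s02, double kappa, double vartheta,
                        double& s_tt, double& s2_t, int& acc1, int& acc2) {
  // covariance, flat prior over the constraint region: prior ratio cancels
  double p01 = std::sqrt(s2_t);
  double prop = rtnorm_ab(s_tt, s01, -p01, p01);
  {
    double la = cov_loglik(theta, tau, prop, s2_t) -
                cov_loglik(theta, tau, s_tt, s2_t) +
                log_trunc_mass(-p01, p01, s_tt, s01) -
                log_trunc_mass(-p01, p01, prop, s01);
    if (std::log(unif_rand()) < la) {
      s_tt = prop;
      ++acc1;
    }
  }
  // speed variance, inverse-gamma prior IG(kappa, vartheta)
  double p0 = s_tt * s_tt;
  double prop2 = rtnorm_ab(s2_t, s02, p0, R_PosInf);
  if (prop2 > p0) {
    double la = cov_loglik(theta, tau, s_tt, prop2) -
                cov_loglik(theta, tau, s_tt, s2_t) +
                (-(kappa + 1.0) * std::log(prop2) - vartheta / prop2) -
                (-(kappa + 1.0) * std::log(s2_t) - vartheta / s2_t) +
                std::log(std::max(R::pnorm(p0, s2_t, s02, 0, 0), 1e-300)) -
                std::log(std::max(R::pnorm(p0, prop2, s02, 0, 0), 1e-300));
    if (std::log(unif_rand()) < la) {
      s2_t = prop2;
      ++acc2;
    }
  }
}

// per-cell log-likelihood (mixture decomposition, conditional on eta)
static double cell_ll_one(int y, double lt, int e, double a, double b,
                          double g, double lam, double s2, double theta,
                          double tau, double pi, double mu_c, double s2_c) {
  if (e == 1) {
    return std::log(pi) + (y == 1 ? std::log(g) : std::log1p(-g)) +
           dnorm_log_v(lt, mu_c, s2_c) - lt;
  }
  double lp1, lp0;
  logistic_logpq(a * (theta - b), lp1, lp0);
  return std::log1p(-pi) + (y == 1 ? lp1 : lp0) +
         dnorm_log_v(lt, lam - tau, s2) - lt;
}

// ---- exported single-step wrappers (used by the oracle tests) -------------

// [[Rcpp::export(name = "cpp_step_W")]]
NumericMatrix cpp_step_W(IntegerMatrix eta, NumericVector a, NumericVector b,
                         NumericVector theta, NumericMatrix W) {
  NumericMatrix Wn = clone(W);
  core_step_W(eta, a, b, theta, Wn);
  return Wn;
}

// [[Rcpp::export(name = "cpp_step_a")]]
NumericVector cpp_step_a(IntegerMatrix Y, IntegerMatrix eta, NumericMatrix W,
                         NumericVector theta, NumericVector b, double mu_a,
                         double s2_a) {
  NumericVector a(Y.ncol());
  core_step_a(Y, eta, W, theta, b, mu_a, s2_a, a);
  return a;
}

// [[Rcpp::export(name = "cpp_step_b")]]
NumericVector cpp_step_b(IntegerMatrix Y, IntegerMatrix eta, NumericMatrix W,
                         NumericVector theta, NumericVector a, double mu_b,
                         double s2_b) {
  NumericVector b(Y.ncol());
  core_step_b(Y, eta, W, theta, a, mu_b, s2_b, b);
  return b;
}

// [[Rcpp::export(name = "cpp_step_theta")]]
NumericVector cpp_step_theta(IntegerMatrix Y, IntegerMatrix eta, NumericMatrix W,
                             NumericVector a, NumericVector b, NumericVector tau,
                             double s_tt, double s2_t) {
  NumericVector theta(Y.nrow());
  core_step_theta(Y, eta, W, a, b, tau, s_tt, s2_t, theta);
  return theta;
}

// [[Rcpp::export(name = "cpp_step_eta")]]
List cpp_step_eta(IntegerMatrix Y, NumericMatrix logT, NumericVector a,
                  NumericVector b, NumericVector g, NumericVector lam,
                  NumericVector s2, NumericVector theta, NumericVector tau,
                  NumericVector pi, double mu_c, double s2_c) {
  IntegerMatrix eta(Y.nrow(), Y.ncol());
  int clamped = core_step_eta(Y, logT, a, b, g, lam, s2, theta, tau, pi, mu_c,
                              s2_c, eta);
  return List::create(_["eta"] = eta, _["clamped"] = clamped);
}

// [[Rcpp::export(name = "cpp_step_pi")]]
NumericVector cpp_step_pi(IntegerMatrix eta, double i1, double i2) {
  NumericVector pi(eta.nrow());
  core_step_pi(eta, i1, i2, pi);
  return pi;
}

// [[Rcpp::export(name = "cpp_step_g")]]
NumericVector cpp_step_g(IntegerMatrix Y, IntegerMatrix eta, double i3,
                         double i4) {
  NumericVector g(Y.ncol());
  core_step_g(Y, eta, i3, i4, g);
  return g;
}

// [[Rcpp::export(name = "cpp_step_tau")]]
NumericVector cpp_step_tau(NumericMatrix logT, IntegerMatrix eta,
                           NumericVector lam, NumericVector s2,
                           NumericVector theta, double s_tt, double s2_t) {
  NumericVector tau(logT.nrow());
  core_step_tau(logT, eta, lam, s2, theta, s_tt, s2_t, tau);
  return tau;
}

// [[Rcpp::export(name = "cpp_step_lambda")]]
NumericVector cpp_step_lambda(NumericMatrix logT, IntegerMatrix eta,
                              NumericVector tau, NumericVector s2, double mu_l,
                              double s2_l) {
  NumericVector lam(logT.ncol());
  core_step_lambda(logT, eta, tau, s2, mu_l, s2_l, lam);
  return lam;
}

// [[Rcpp::export(name = "cpp_step_sigma2")]]
NumericVector cpp_step_sigma2(NumericMatrix logT, IntegerMatrix eta,
                              NumericVector tau, NumericVector lam, double ups1,
                              double om1) {
  NumericVector s2(logT.ncol());
  core_step_sigma2(logT, eta, tau, lam, ups1, om1, s2);
  return s2;
}

// [[Rcpp::export(name = "cpp_step_guess_rt")]]
List cpp_step_guess_rt(NumericMatrix logT, IntegerMatrix eta, double mu_c,
                       double s2_c, double ups2, double om2) {
  int skipped = core_step_guess_rt(logT, eta, ups2, om2, mu_c, s2_c);
  return List::create(_["mu_c"] = mu_c, _["sigma2_c"] = s2_c,
                      _["skipped"] = skipped);
}

// [[Rcpp::export(name = "cpp_mh_cov")]]
List cpp_mh_cov(NumericVector theta, NumericVector tau, double s_tt,
                double s2_t, double s01, double s02, double kappa,
                double vartheta) {
  int a1 = 0, a2 = 0;
  core_mh_cov(theta, tau, s01, s02, kappa, vartheta, s_tt, s2_t, a1, a2);
  return List::create(_["sigma_thetatau"] = s_tt, _["sigma2_tau"] = s2_t,
                      _["acc_cov"] = a1, _["acc_var"] = a2);
}

// [[Rcpp::export(name = "cpp_cell_loglik")]]
NumericMatrix cpp_cell_loglik(IntegerMatrix Y, NumericMatrix logT,
                              IntegerMatrix eta, NumericVector a,
                              NumericVector b, NumericVector g,
                              NumericVector lam, NumericVector s2,
                              NumericVector theta, NumericVector tau,
                              NumericVector pi, double mu_c, double s2_c) {
  int N = Y.nrow(), J = Y.ncol();
  NumericMatrix out(N, J);
  for (int j = 0; j < J; ++j)
    for (int i = 0; i < N; ++i)
      out(i, j) = cell_ll_one(Y(i, j), logT(i, j), eta(i, j), a[j], b[j], g[j],
                              lam[j], s2[j], theta[i], tau[i], pi[i], mu_c,
                              s2_c);
  return out;
}

// ---- chain runner ---------------------------------------------------------

// [[Rcpp::export(name = "cpp_gibbs_run")]]
List cpp_gibbs_run(IntegerMatrix Y, NumericMatrix logT, List prior, List init,
                   int iter, int burnin, int thin, bool mixture,
                   bool update_hyper, bool store_person, bool store_cell_ll,
                   bool adapt, bool compute_ll) {
  int N = Y.nrow(), J = Y.ncol();
  if (iter <= burnin) stop("iter must exceed burnin");

  // priors
  double mu_a = prior["mu_a"], s2_a = prior["sigma2_a"];
  double mu_b = prior["mu_b"], s2_b = prior["sigma2_b"];
  double i1 = prior["iota1"], i2 = prior["iota2"];
  double i3 = prior["iota3"], i4 = prior["iota4"];
  double mu_l = prior["mu_lambda"], s2_l = prior["sigma2_lambda"];
  double ups1 = prior["upsilon1"], om1 = prior["omega1"];
  double ups2 = prior["upsilon2"], om2 = prior["omega2"];
  double kappa = prior["kappa"], vartheta = prior["vartheta"];
  double s01 = prior["s01"], s02 = prior["s02"];

  // state
  NumericVector a = clone(as<NumericVector>(init["a"]));
  NumericVector b = clone(as<NumericVector>(init["b"]));
  NumericVector g = clone(as<NumericVector>(init["g"]));
  NumericVector lam = clone(as<NumericVector>(init["lambda"]));
  NumericVector s2 = clone(as<NumericVector>(init["sigma2"]));
  NumericVector theta = clone(as<NumericVector>(init["theta"]));
  NumericVector tau = clone(as<NumericVector>(init["tau"]));
  NumericVector pi = clone(as<NumericVector>(init["pi"]));
  double mu_c = init["mu_c"], s2_c = init["sigma2_c"];
  double s_tt = init["sigma_thetatau"], s2_t = init["sigma2_tau"];
  IntegerMatrix eta = clone(as<IntegerMatrix>(init["eta"]));
  NumericMatrix W(N, J);
  std::fill(W.begin(), W.end(), 0.25);

  int M = (iter - burnin) / thin;
  int npar = 5 * J + 4;
  NumericMatrix draws(M, npar);
  NumericMatrix person_draws(store_person ? M : 0,
                             store_person ? 3 * N : 0);
  NumericMatrix cell_ll(store_cell_ll ? M : 0,
                        store_cell_ll ? N * J : 0);
  NumericVector ll_draws(M);
  NumericMatrix eta_sum(N, J);
  NumericMatrix person_sum(N, 3), person_sumsq(N, 3);
  // streaming accumulators for log CPO: running max of -loglik and the
  // rescaled sum of exp(-loglik - max), per cell
  NumericMatrix cpo_max(N, J), cpo_sum(N, J);
  std::fill(cpo_max.begin(), cpo_max.end(), R_NegInf);

  int acc1 = 0, acc2 = 0, att = 0, clamped = 0, skipped = 0;
  int batch_acc1 = 0, batch_acc2 = 0, batch_n = 0;
  int stored = 0;

  for (int r = 1; r <= iter; ++r) {
    core_step_W(eta, a, b, theta, W);
    core_step_a(Y, eta, W, theta, b, mu_a, s2_a, a);
    check_finite(a, "discrimination update (step 2)");
    core_step_b(Y, eta, W, theta, a, mu_b, s2_b, b);
    check_finite(b, "difficulty update (step 3)");
    core_step_theta(Y, eta, W, a, b, tau, s_tt, s2_t, theta);
    check_finite(theta, "ability update (step 4)");
    if (mixture) {
      clamped += core_step_eta(Y, logT, a, b, g, lam, s2, theta, tau, pi,
                               mu_c, s2_c, eta);
      core_step_pi(eta, i1, i2, pi);
      core_step_g(Y, eta, i3, i4, g);
    }
    core_step_tau(logT, eta, lam, s2, theta, s_tt, s2_t, tau);
    check_finite(tau, "speed update (step 8)");
    core_step_lambda(logT, eta, tau, s2, mu_l, s2_l, lam);
    check_finite(lam, "time-intensity update (step 9)");
    core_step_sigma2(logT, eta, tau, lam, ups1, om1, s2);
    check_finite(s2, "time-variance update (step 10)");
    if (mixture && update_hyper)
      skipped += core_step_guess_rt(logT, eta, ups2, om2, mu_c, s2_c);
    if (update_hyper) {
      int a1 = acc1, a2 = acc2;
      core_mh_cov(theta, tau, s01, s02, kappa, vartheta, s_tt, s2_t, acc1,
                  acc2);
      ++att;
      batch_acc1 += acc1 - a1;
      batch_acc2 += acc2 - a2;
      ++batch_n;
      if (!R_finite(s_tt) || !R_finite(s2_t))
        stop("non-finite value produced in covariance update (steps 13-14)");
      // Robbins-Monro style proposal-scale adaptation, burn-in only
      if (adapt && r <= burnin && batch_n == 50) {
        double step = std::min(0.25, 1.0 / std::sqrt((double)r / 50.0));
        double r1 = batch_acc1 / 50.0, r2 = batch_acc2 / 50.0;
        if (r1 > 0.40) s01 *= std::exp(step);
        if (r1 < 0.25) s01 *= std::exp(-step);
        if (r2 > 0.40) s02 *= std::exp(step);
        if (r2 < 0.25) s02 *= std::exp(-step);
        // floor: near the positive-definiteness boundary the acceptance
        // rate stays low at any scale, and ever-shrinking proposals would
        // freeze movement along the boundary ridge
        if (s01 < 0.01) s01 = 0.01;
        if (s02 < 0.01) s02 = 0.01;
        batch_acc1 = batch_acc2 = batch_n = 0;
      }
    }

    if (r > burnin && (r - burnin) % thin == 0 && stored < M) {
      int m = stored++;
      int c = 0;
      for (int j = 0; j < J; ++j) draws(m, c++) = a[j];
      for (int j = 0; j < J; ++j) draws(m, c++) = b[j];
      for (int j = 0; j < J; ++j) draws(m, c++) = g[j];
      for (int j = 0; j < J; ++j) draws(m, c++) = lam[j];
      for (int j = 0; j < J; ++j) draws(m, c++) = s2[j];
      draws(m, c++) = mu_c;
      draws(m, c++) = s2_c;
      draws(m, c++) = s_tt;
      draws(m, c++) = s2_t;
      for (int i = 0; i < N; ++i) {
        person_sum(i, 0) += theta[i];
        person_sum(i, 1) += tau[i];
        person_sum(i, 2) += pi[i];
        person_sumsq(i, 0) += theta[i] * theta[i];
        person_sumsq(i, 1) += tau[i] * tau[i];
        person_sumsq(i, 2) += pi[i] * pi[i];
      }
      if (store_person) {
        for (int i = 0; i < N; ++i) {
          person_draws(m, i) = theta[i];
          person_draws(m, N + i) = tau[i];
          person_draws(m, 2 * N + i) = pi[i];
        }
      }
      for (int j = 0; j < J; ++j)
        for (int i = 0; i < N; ++i) eta_sum(i, j) += eta(i, j);
      if (compute_ll) {
        double tot = 0.0;
        for (int j = 0; j < J; ++j)
          for (int i = 0; i < N; ++i) {
            double l = cell_ll_one(Y(i, j), logT(i, j), eta(i, j), a[j], b[j],
                                   g[j], lam[j], s2[j], theta[i], tau[i],
                                   pi[i], mu_c, s2_c);
            tot += l;
            double u = -l;
            if (u > cpo_max(i, j)) {
              cpo_sum(i, j) = cpo_sum(i, j) * std::exp(cpo_max(i, j) - u) + 1.0;
              cpo_max(i, j) = u;
            } else {
              cpo_sum(i, j) += std::exp(u - cpo_max(i, j));
            }
            if (store_cell_ll) cell_ll(m, i + N * j) = l;
          }
        if (!R_finite(tot))
          stop("non-finite value produced in the stored log-likelihood");
        ll_draws[m] = tot;
      }
    }
  }

  for (int i = 0; i < N; ++i)
    for (int k = 0; k < 3; ++k) {
      double mn = person_sum(i, k) / M;
      double vr = person_sumsq(i, k) / M - mn * mn;
      person_sum(i, k) = mn;
      person_sumsq(i, k) = std::sqrt(std::max(vr, 0.0) * M / std::max(M - 1, 1));
    }
  for (int j = 0; j < J; ++j)
    for (int i = 0; i < N; ++i) eta_sum(i, j) /= M;

  List state = List::create(
      _["a"] = a, _["b"] = b, _["g"] = g, _["lambda"] = lam, _["sigma2"] = s2,
      _["theta"] = theta, _["tau"] = tau, _["pi"] = pi, _["mu_c"] = mu_c,
      _["sigma2_c"] = s2_c, _["sigma_thetatau"] = s_tt, _["sigma2_tau"] = s2_t,
      _["eta"] = eta);

  return List::create(
      _["draws"] = draws, _["person_eap"] = person_sum,
      _["person_sd"] = person_sumsq, _["person_draws"] = person_draws,
      _["eta_prob"] = eta_sum, _["loglik"] = ll_draws,
      _["cpo_max"] = cpo_max, _["cpo_sum"] = cpo_sum, _["cell_loglik"] = cell_ll,
      _["state"] = state,
      _["mh"] = List::create(_["acc_cov"] = acc1, _["acc_var"] = acc2,
                             _["attempts"] = att, _["s01"] = s01,
                             _["s02"] = s02),
      _["clamped"] = clamped, _["skipped_guess_updates"] = skipped,
      _["n_stored"] = stored);
}
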