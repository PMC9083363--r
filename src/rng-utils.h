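#ifndef SPEEDMIX_RNG_UTILS_H
#define SPEEDMIX_RNG_UTILS_H

#include <Rcpp.h>

// Sampling primitives used by the Gibbs kernel. All draws go through R's
// RNG (norm_rand/unif_rand/exp_rand), so set.seed() on the R side makes
// every chain reproducible.

namespace speedmix {

// ---- Polya-gamma PG(1, z), exact Devroye-type rejection sampler ----
//
// PG(1, z) is sampled as X/4 with X ~ J*(1, z/2), the tilted Jacobi
// distribution. J*(1, c) is drawn by the alternating-series rejection
// method: a mixture proposal (truncated inverse-Gaussian left of the
// cutoff, exponential right of it) and partial-sum acceptance.

const double PG_TRUNC = 0.64;  // proposal cutoff for the two-piece envelope

// n-th alternating-series coefficient a_n(x) of the J*(1,0) density
inline double pg_acoef(int n, double x) {
  double np5 = n + 0.5;
  if (x > PG_TRUNC)
    return M_PI * np5 * std::exp(-np5 * np5 * M_PI * M_PI * 0.5 * x);
  return std::pow(2.0 / (M_PI * x), 1.5) * M_PI * np5 *
         std::exp(-2.0 * np5 * np5 / x);
}

// P(choose the exponential piece) for tilt c >= 0
inline double pg_mass_texpon(double c) {
  double t = PG_TRUNC;
  double K = M_PI * M_PI * 0.125 + c * c * 0.5;
  double ub = std::sqrt(1.0 / t) * (t * c - 1.0);
  double lb = -std::sqrt(1.0 / t) * (t * c + 1.0);
  double x0 = std::log(K) + K * t;
  double xb = x0 - c + R::pnorm(ub, 0.0, 1.0, 1, 1);
  double xa = x0 + c + R::pnorm(lb, 0.0, 1.0, 1, 1);
  double qdivp = 4.0 / M_PI * (std::exp(xb) + std::exp(xa));
  return 1.0 / (1.0 + qdivp);
}

// inverse-Gaussian(mu = 1/c, lambda = 1) truncated to (0, PG_TRUNC)
inline double pg_rtigauss(double c) {
  double t = PG_TRUNC;
  double x = t + 1.0;
  if (c < 1.0 / t) {  // mu > t: sample 1/X-ish via chi-square rejection
    double alpha = 0.0;
    while (unif_rand() > alpha) {
      double e1 = exp_rand(), e2 = exp_rand();
      while (e1 * e1 > 2.0 * e2 / t) {
        e1 = exp_rand();
        e2 = exp_rand();
      }
      x = t / ((1.0 + t * e1) * (1.0 + t * e1));
      alpha = std::exp(-0.5 * c * c * x);
    }
  } else {  // mu <= t: draw IG until it lands below t
    double mu = 1.0 / c;
    while (x > t) {
      double y = norm_rand();
      y = y * y;
      double muy = mu * y;
      x = mu + 0.5 * mu * muy - 0.5 * mu * std::sqrt(4.0 * muy + muy * muy);
      if (unif_rand() > mu / (mu + x)) x = mu * mu / x;
    }
  }
  return x;
}

// one draw from J*(1, c), c >= 0
inline double pg_jstar(double c) {
  double K = M_PI * M_PI * 0.125 + c * c * 0.5;
  double ratio = pg_mass_texpon(c);
  for (;;) {
    double x;
    if (unif_rand() < ratio)
      x = PG_TRUNC + exp_rand() / K;
    else
      x = pg_rtigauss(c);
    double s = pg_acoef(0, x);
    double y = unif_rand() * s;
    int n = 0;
    for (;;) {
      ++n;
      if (n % 2 == 1) {
        s -= pg_acoef(n, x);
        if (y <= s) return x;
      } else {
        s += pg_acoef(n, x);
        if (y > s) break;
      }
    }
  }
}

// one draw from PG(1, z); symmetric in z
inline double rpg1(double z) {
  double c = 0.5 * std::fabs(z);
  return 0.25 * pg_jstar(c);
}

// ---- truncated normals ----

// N(mean, sd^2) truncated to (lower, Inf). Plain rejection when the bound
// is not deep in the tail, Robert's exponential envelope otherwise.
inline double rtnorm_lb(double mean, double sd, double lower) {
  double alpha = (lower - mean) / sd;
  if (alpha < 0.45) {
    for (;;) {
      double z = norm_rand();
      if (z >= alpha) return mean + sd * z;
    }
  }
  double lam = 0.5 * (alpha + std::sqrt(alpha * alpha + 4.0));
  for (;;) {
    double z = alpha + exp_rand() / lam;
    double d = z - lam;
    if (unif_rand() <= std::exp(-0.5 * d * d)) return mean + sd * z;
  }
}

// N(mean, sd^2) truncated to (a, b) by inverse-CDF; adequate for the
// random-walk proposals where (a, b) always straddles the current value.
inline double rtnorm_ab(double mean, double sd, double a, double b) {
  double pa = R::pnorm(a, mean, sd, 1, 0);
  double pb = R::pnorm(b, mean, sd, 1, 0);
  double u = pa + unif_rand() * (pb - pa);
  double x = R::qnorm(u, mean, sd, 1, 0);
  if (x < a) x = a;
  if (x > b) x = b;
  return x;
}

// ---- inverse gamma IG(shape, rate): density ~ x^-(shape+1) exp(-rate/x)
inline double rinvgamma(double shape, double rate) {
  return 1.0 / R::rgamma(shape, 1.0 / rate);
}

// log N(x; mean, var)
inline double dnorm_log_v(double x, double mean, double var) {
  double d = x - mean;
  return -0.5 * (std::log(2.0 * M_PI * var) + d * d / var);
}

}  // namespace speedmix

#endif
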