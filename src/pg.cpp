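#include <Rcpp.h>
#include "rng-utils.h"

using namespace Rcpp;

// [[Rcpp::export(name = "cpp_rpg")]]
NumericVector cpp_rpg(int n, NumericVector z) {
  NumericVector out(n);
  int nz = z.size();
  for (int i = 0; i < n; ++i) {
    double zi = z[i % nz];
    if (ISNAN(zi)) stop("NaN tilt parameter passed to the PG sampler");
    out[i] = speedmix::rpg1(zi);
  }
  return out;
}

// [[Rcpp::export(name = "cpp_rtnorm_lb")]]
NumericVector cpp_rtnorm_lb(int n, double mean, double sd, double lower) {
  NumericVector out(n);
  for (int i = 0; i < n; ++i) out[i] = speedmix::rtnorm_lb(mean, sd, lower);
  return out;
}

// [[Rcpp::export(name = "cpp_rtnorm_ab")]]
NumericVector cpp_rtnorm_ab(int n, double mean, double sd, double a, double b) {
  NumericVector out(n);
  for (int i = 0; i < n; ++i) out[i] = speedmix::rtnorm_ab(mean, sd, a, b);
  return out;
}
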