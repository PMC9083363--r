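#' Prior and proposal configuration
#'
#' Hyperparameters of the prior distributions and the Metropolis-Hastings
#' proposal scales. The defaults are the diffuse choices used throughout
#' the package's simulation studies: a truncated-normal N(0, 1e5)I(a>0)
#' prior on discriminations, N(0, 1e5) on difficulties and time
#' intensities, Beta(5, 17) on guessing success, Beta(1, 5) on the
#' rapid-guessing propensity, inverse-gamma IG(1e-4, 1e-4) on every
#' variance parameter, a flat prior on the guessing-time mean, and a
#' uniform prior on the ability-speed covariance over the interval
#' (-sigma2_tau, sigma2_tau) enforced by the sampler's truncation.
#'
#' @param mu_a,sigma2_a truncated-normal prior for discriminations.
#' @param mu_b,sigma2_b normal prior for difficulties.
#' @param iota1,iota2 Beta prior for the guessing propensity pi.
#' @param iota3,iota4 Beta prior for the guessing-success probability g.
#' @param mu_lambda,sigma2_lambda normal prior for time intensities.
#' @param upsilon1,omega1 inverse-gamma prior for the item log-time
#'   variances.
#' @param upsilon2,omega2 inverse-gamma prior for the guessing-time
#'   variance.
#' @param kappa,vartheta inverse-gamma prior for the speed variance.
#' @param s01,s02 random-walk proposal standard deviations for the
#'   covariance and speed-variance Metropolis-Hastings updates.
#' @return a named list of class `"speedmix_priors"`.
#' @export
speedmix_priors <- function(mu_a = 0, sigma2_a = 1e5,
                            mu_b = 0, sigma2_b = 1e5,
                            iota1 = 1, iota2 = 5,
                            iota3 = 5, iota4 = 17,
                            mu_lambda = 0, sigma2_lambda = 1e5,
                            upsilon1 = 1e-4, omega1 = 1e-4,
                            upsilon2 = 1e-4, omega2 = 1e-4,
                            kappa = 1e-4, vartheta = 1e-4,
                            s01 = 0.05, s02 = 0.05) {
  p <- list(mu_a = mu_a, sigma2_a = sigma2_a, mu_b = mu_b, sigma2_b = sigma2_b,
            iota1 = iota1, iota2 = iota2, iota3 = iota3, iota4 = iota4,
            mu_lambda = mu_lambda, sigma2_lambda = sigma2_lambda,
            upsilon1 = upsilon1, omega1 = omega1,
            upsilon2 = upsilon2, omega2 = omega2,
            kappa = kappa, vartheta = vartheta, s01 = s01, s02 = s02)
  pos <- c("sigma2_a", "sigma2_b", "iota1", "iota2", "iota3", "iota4",
           "sigma2_lambda", "upsilon1", "omega1", "upsilon2", "omega2",
           "kappa", "vartheta", "s01", "s02")
  bad <- pos[vapply(p[pos], function(x) !is.finite(x) || x <= 0, logical(1))]
  if (length(bad))
    stop("prior hyperparameters must be positive: ", paste(bad, collapse = ", "))
  structure(p, class = "speedmix_priors")
}
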