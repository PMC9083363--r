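#' Two-parameter logistic response probability
#'
#' Probability of a correct response under solution behavior: a logistic
#' function of ability with item discrimination `a` and difficulty `b`,
#' \eqn{P(Y=1) = \exp[a(\theta-b)] / (1 + \exp[a(\theta-b)])}. Computed
#' through [stats::plogis()], so it is numerically stable for extreme
#' linear predictors.
#'
#' @param theta ability (numeric, vectorized).
#' @param a item discrimination, must be positive.
#' @param b item difficulty.
#' @return probabilities in (0, 1).
#' @examples
#' p_correct_2pl(0.7, a = 2, b = 0.7)  # theta at the difficulty: 0.5
#' @export
p_correct_2pl <- function(theta, a, b) {
  if (any(a <= 0)) stop("discrimination 'a' must be positive")
  plogis(a * (theta - b))
}

#' Mixture response probability
#'
#' Correct-response probability under the behavior mixture: the 2PL
#' probability when `eta = 0` (solution behavior) and the item-specific
#' guessing-success probability `g` when `eta = 1` (rapid guessing).
#'
#' @inheritParams p_correct_2pl
#' @param g guessing-success probability in (0, 1).
#' @param eta behavior indicator, 0 or 1 (vectorized).
#' @return probabilities in (0, 1).
#' @export
mixture_response_prob <- function(theta, a, b, g, eta) {
  if (!all(eta %in% c(0, 1))) stop("'eta' must be 0 or 1")
  if (any(g <= 0 | g >= 1)) stop("'g' must lie strictly in (0, 1)")
  ifelse(eta == 1, g + 0 * theta, p_correct_2pl(theta, a, b))
}

#' Lognormal response-time log-density
#'
#' Log-density of a positive response time whose logarithm is normal with
#' the given mean and variance. Used for both solution times (mean
#' \eqn{\lambda_j - \tau_i}, variance \eqn{\sigma_j^2}) and rapid-guess
#' times (mean \eqn{\mu_c}, variance \eqn{\sigma_c^2}).
#'
#' @param t response time in minutes, positive.
#' @param mean log-scale mean.
#' @param var log-scale variance, positive.
#' @return log-density values.
#' @export
log_rt_density <- function(t, mean, var) {
  if (any(t <= 0)) stop("response times must be positive")
  if (any(var <= 0)) stop("log-time variance must be positive")
  dlnorm(t, meanlog = mean, sdlog = sqrt(var), log = TRUE)
}

#' Per-cell log-likelihood of the mixture model
#'
#' Log-likelihood of one (person, item) observation conditional on the
#' behavior indicator: for `eta = 1` the rapid-guessing branch
#' \eqn{\pi_i g_j^{Y}(1-g_j)^{1-Y} h(T)}, for `eta = 0` the solution branch
#' \eqn{(1-\pi_i) P(Y|\theta,a,b)^{Y}\ldots f(T)}. All arguments are
#' vectorized over cells.
#'
#' A degenerate propensity (`pi` exactly 0 or 1) that conflicts with the
#' supplied `eta` yields `-Inf` with a warning rather than a silent clamp.
#'
#' @param y binary response.
#' @param t response time in minutes.
#' @param eta behavior indicator, 0 or 1.
#' @param theta,tau person ability and speed.
#' @param pi rapid-guessing propensity in \[0, 1\].
#' @param a,b,g,lambda,sigma2 item parameters (discrimination, difficulty,
#'   guessing success, time intensity, log-time variance).
#' @param mu_c,sigma2_c log-scale mean and variance of rapid-guess times.
#' @return log-likelihood values; `-Inf` where a branch has zero mass.
#' @export
cell_loglik <- function(y, t, eta, theta, tau, pi, a, b, g, lambda, sigma2,
                        mu_c, sigma2_c) {
  if (!all(y %in% c(0, 1))) stop("'y' must be 0 or 1")
  if (!all(eta %in% c(0, 1))) stop("'eta' must be 0 or 1")
  n <- length(y)
  conflict <- (eta == 1 & pi == 0) | (eta == 0 & pi == 1)
  if (any(conflict))
    warning("degenerate guessing propensity conflicts with 'eta'; ",
            "returning -Inf for ", sum(conflict), " cell(s)")
  guess <- log(pi) + ifelse(y == 1, log(g), log1p(-g)) +
    log_rt_density(t, mu_c, sigma2_c)
  p1 <- plogis(a * (theta - b), log.p = TRUE)
  p0 <- plogis(-(a * (theta - b)), log.p = TRUE)
  sol <- log1p(-pi) + ifelse(y == 1, p1, p0) +
    log_rt_density(t, lambda - tau, sigma2)
  ifelse(rep_len(eta, n) == 1, guess, sol)
}

#' Observed response and response-time data
#'
#' Bundles and validates an N x J binary response matrix and an N x J
#' matrix of positive response times (minutes).
#'
#' @param Y binary response matrix.
#' @param time positive response-time matrix with the same dimensions.
#' @return an object of class `"response_data"` with elements `Y`, `time`,
#'   `N`, `J`.
#' @export
response_data <- function(Y, time) {
  Y <- as.matrix(Y)
  time <- as.matrix(time)
  if (!identical(dim(Y), dim(time)))
    stop("response matrix is ", nrow(Y), " x ", ncol(Y),
         " but time matrix is ", nrow(time), " x ", ncol(time))
  if (anyNA(Y) || anyNA(time))
    stop("missing values are not supported")
  if (!all(Y %in% c(0, 1))) stop("responses must be 0 or 1")
  if (any(time <= 0)) stop("all response times must be positive")
  storage.mode(Y) <- "integer"
  storage.mode(time) <- "double"
  structure(list(Y = Y, time = time, N = nrow(Y), J = ncol(Y)),
            class = "response_data")
}

#' @export
print.response_data <- function(x, ...) {
  cat("Response data:", x$N, "persons x", x$J, "items\n")
  cat("  mean proportion correct:", round(mean(x$Y), 3), "\n")
  cat("  median response time:", round(median(x$time), 3), "min\n")
  invisible(x)
}

#' Population-level person and guessing-time parameters
#'
#' The free population parameters of the model. Identification fixes the
#' ability mean at 0, the ability variance at 1 and the speed mean at 0;
#' these are stored structurally and are never sampled.
#'
#' The default covariance (0.5 with speed variance 0.25) makes ability and
#' speed perfectly correlated -- a deliberately degenerate reference
#' condition in which speed determines ability exactly. Singular
#' (semi-definite) covariances are accepted here because they describe
#' valid, if degenerate, person populations for data generation; the
#' sampler itself always keeps the estimated covariance strictly positive
#' definite.
#'
#' @param sigma_thetatau ability-speed covariance; its square may not
#'   exceed `sigma2_tau` (equality gives a singular, perfectly correlated
#'   population).
#' @param sigma2_tau speed variance, positive.
#' @param mu_c log-scale mean of rapid-guess times.
#' @param sigma2_c log-scale variance of rapid-guess times, positive.
#' @return an object of class `"population_params"`.
#' @export
population_params <- function(sigma_thetatau = 0.5, sigma2_tau = 0.25,
                              mu_c = -2, sigma2_c = 0.25) {
  if (sigma2_tau <= 0) stop("sigma2_tau must be positive")
  if (sigma2_c <= 0) stop("sigma2_c must be positive")
  if (sigma_thetatau^2 > sigma2_tau)
    stop("person covariance is not positive semi-definite: ",
         "sigma_thetatau^2 must not exceed sigma2_tau")
  enforce_identification(structure(
    list(mu_theta = 0, sigma2_theta = 1, mu_tau = 0,
         sigma_thetatau = sigma_thetatau, sigma2_tau = sigma2_tau,
         mu_c = mu_c, sigma2_c = sigma2_c),
    class = "population_params"))
}

#' Apply the identification constraints
#'
#' Resets the structurally fixed components (ability mean 0, ability
#' variance 1, speed mean 0) of a set of population parameters, leaving
#' the free parameters untouched. Idempotent; round-trips through
#' serialization keep the fixed values.
#'
#' @param pop a `"population_params"` object (or a bare list with the same
#'   fields).
#' @return the object with `mu_theta = 0`, `sigma2_theta = 1`,
#'   `mu_tau = 0`.
#' @export
enforce_identification <- function(pop) {
  pop$mu_theta <- 0
  pop$sigma2_theta <- 1
  pop$mu_tau <- 0
  pop
}
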