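#' Deviance information criterion
#'
#' DIC from per-draw log-likelihoods: with
#' \eqn{\bar{D} = -\frac{2}{M}\sum_m \log f^{(m)}} and
#' \eqn{\hat{D} = -2 \max_m \log f^{(m)}},
#' \eqn{\mathrm{DIC} = \hat{D} + 2 p_D}, \eqn{p_D = \bar{D} - \hat{D}}.
#' The plug-in uses the best (maximum total log-likelihood) draw, so
#' \eqn{p_D \ge 0} always. Smaller DIC indicates better fit.
#'
#' @param x either a fitted [speedmix] object or a numeric matrix of
#'   per-draw cell log-likelihoods (M draws in rows, cells in columns; a
#'   vector is treated as per-draw totals).
#' @param ... unused.
#' @return a named list with `dic`, `pD`, `dev_bar`, `dev_hat`.
#' @examples
#' dic(matrix(c(-10, -12), nrow = 2))  # Dev_bar 22, Dev_hat 20, DIC 24
#' @export
dic <- function(x, ...) UseMethod("dic")

#' @export
dic.default <- function(x, ...) {
  tot <- if (is.matrix(x)) rowSums(x) else as.numeric(x)
  if (!length(tot)) stop("at least one draw is required")
  dev_bar <- -2 * mean(tot)
  dev_hat <- -2 * max(tot)
  pD <- dev_bar - dev_hat
  list(dic = dev_hat + 2 * pD, pD = pD, dev_bar = dev_bar, dev_hat = dev_hat)
}

#' @export
dic.speedmix <- function(x, ...) {
  if (!isTRUE(x$has_loglik))
    stop("fit was run with compute_loglik = FALSE; refit to assess it")
  dic.default(unlist(x$loglik))
}

#' Log conditional predictive ordinates
#'
#' Monte Carlo estimate of the per-cell log CPO from posterior draws,
#' using the stabilized harmonic-mean form: with
#' \eqn{U = \max_m(-\log f^{(m)})} per cell,
#' \eqn{\log \mathrm{CPO} = -U - \log[\frac{1}{M}\sum_m
#'   \exp(-\log f^{(m)} - U)]}. Any draw with `-Inf` log-likelihood makes
#' that cell's CPO `-Inf` (flagged with a warning).
#'
#' @param x a fitted [speedmix] object or a numeric matrix of per-draw
#'   cell log-likelihoods (M x cells).
#' @param ... unused.
#' @return for a matrix, a vector of per-cell log CPO values; for a fit,
#'   an N x J matrix.
#' @export
log_cpo <- function(x, ...) UseMethod("log_cpo")

#' @export
log_cpo.default <- function(x, ...) {
  x <- as.matrix(x)
  if (!nrow(x)) stop("at least one draw is required")
  if (any(x == -Inf))
    warning("draws with zero likelihood: affected cells have -Inf log CPO")
  u <- apply(-x, 2, max)
  out <- -u - log(colMeans(exp(sweep(-x, 2, u))))
  out[!is.finite(u)] <- -Inf
  out
}

#' @export
log_cpo.speedmix <- function(x, ...) {
  if (!isTRUE(x$has_loglik))
    stop("fit was run with compute_loglik = FALSE; refit to assess it")
  acc <- merge_cpo(x$cpo)
  -(acc$max + log(acc$sum / acc$M))
}

# merge per-chain streaming (max, rescaled-sum) CPO accumulators
merge_cpo <- function(cpo_list) {
  mx <- cpo_list[[1]]$max
  sm <- cpo_list[[1]]$sum
  M <- cpo_list[[1]]$M
  for (ch in cpo_list[-1]) {
    new_mx <- pmax(mx, ch$max)
    sm <- sm * exp(mx - new_mx) + ch$sum * exp(ch$max - new_mx)
    mx <- new_mx
    M <- M + ch$M
  }
  list(max = mx, sum = sm, M = M)
}

#' Log pseudomarginal likelihood
#'
#' Sum of the per-cell log CPO values. Larger LPML indicates better fit.
#'
#' @param x a fitted [speedmix] object, or a matrix/vector of log CPO
#'   values.
#' @param ... unused.
#' @return a single number.
#' @export
lpml <- function(x, ...) UseMethod("lpml")

#' @export
lpml.default <- function(x, ...) sum(x)

#' @export
lpml.speedmix <- function(x, ...) sum(log_cpo(x))

#' Bayesian model assessment summary
#'
#' DIC and CPO/LPML statistics of a fit, computed from the per-draw
#' log-likelihoods accumulated during sampling (conditioning on each
#' draw's behavior indicators, as the mixture likelihood factorizes).
#'
#' @param fit a fitted [speedmix] object.
#' @return an object of class `"speedmix_assessment"`: list with `dic`,
#'   `pD`, `dev_bar`, `dev_hat`, `lpml`, `log_cpo` (N x J matrix).
#' @export
assess <- function(fit) {
  stopifnot(inherits(fit, "speedmix"))
  d <- dic(fit)
  lc <- log_cpo(fit)
  structure(c(d, list(lpml = sum(lc), log_cpo = lc, model = fit$model)),
            class = "speedmix_assessment")
}

#' @export
print.speedmix_assessment <- function(x, ...) {
  cat("Model assessment (", x$model, " model)\n", sep = "")
  cat(sprintf("  DIC  = %.3f  (pD = %.2f, Dev_bar = %.3f, Dev_hat = %.3f)\n",
              x$dic, x$pD, x$dev_bar, x$dev_hat))
  cat(sprintf("  LPML = %.3f\n", x$lpml))
  invisible(x)
}
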