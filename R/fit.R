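#' Fit the rapid-guessing mixture model by Polya-gamma Gibbs sampling
#'
#' Fits the mixture hierarchical model for binary responses and response
#' times: solution behavior follows a 2PL response model and a lognormal
#' response-time model with person speed, rapid guesses succeed with an
#' item-specific probability `g_j` and share a common lognormal time
#' distribution, and a per-person propensity `pi_i` governs the mixture.
#' Ability and speed are bivariate normal with the identification
#' constraints mean 0 / ability variance 1; the free covariance elements
#' are updated by Metropolis-Hastings under the positive-definiteness
#' constraint. `model = "nonmixture"` fits the hierarchical
#' response/response-time model without the guessing component (the
#' behavior indicators are structurally zero and the guessing updates are
#' skipped).
#'
#' Each iteration executes the 14 updates in a fixed scan order: the
#' Polya-gamma auxiliaries, discriminations, difficulties, abilities, the
#' behavior indicators, propensities, guessing-success probabilities,
#' speeds, time intensities, item time variances, the guessing-time mean
#' and variance, and the two Metropolis-Hastings covariance updates.
#' Chains are reproducible: the same `seed` yields bit-identical draws.
#'
#' @param Y binary response matrix (N x J), or a [response_data] object
#'   (in which case `time` is ignored).
#' @param time positive response-time matrix in minutes (N x J).
#' @param model `"mixture"` (default) or `"nonmixture"`.
#' @param chains number of MCMC chains, run sequentially.
#' @param iter total iterations per chain.
#' @param burnin burn-in iterations discarded from the front.
#' @param thin keep every `thin`-th post-burn-in draw.
#' @param priors a [speedmix_priors()] configuration.
#' @param inits optional named list overriding the default starting
#'   values (fields as in the returned `state`).
#' @param seed integer seed; all chain randomness flows from it.
#' @param adapt adapt the Metropolis-Hastings proposal scales during
#'   burn-in toward a 25-40% acceptance rate (frozen afterwards).
#' @param overdispersed jitter the starting values independently per
#'   chain (default when `chains > 1`), for convergence diagnosis.
#' @param store_person_draws keep full posterior draws of the person
#'   parameters (memory-heavy for large N); their running posterior means
#'   and SDs are always available.
#' @param store_cell_loglik keep the per-draw per-cell log-likelihood
#'   matrix (memory-heavy; the DIC/LPML accumulators are always kept).
#' @param compute_loglik evaluate and accumulate the per-draw
#'   log-likelihood needed for [assess()] (default). Disable to save time
#'   in studies that only use the parameter estimates.
#' @return an object of class `"speedmix"`; see Details. Use
#'   [summary.speedmix()], [coef.speedmix()], [assess()], [psrf()] on it.
#' @seealso [simulate_speeded()] to generate data, [assess()] for
#'   DIC/LPML, [summary.speedmix()] for posterior summaries.
#' @examples
#' sim <- simulate_speeded(sim_design(N = 80, J = 8), seed = 7)
#' fit <- speedmix(sim$Y, sim$time, iter = 200, burnin = 100, seed = 1)
#' coef(fit)[1:8]
#' @export
speedmix <- function(Y, time = NULL, model = c("mixture", "nonmixture"),
                     chains = 1, iter = 2000, burnin = floor(iter / 2),
                     thin = 1, priors = speedmix_priors(), inits = NULL,
                     seed = NULL, adapt = TRUE, overdispersed = chains > 1,
                     store_person_draws = FALSE, store_cell_loglik = FALSE,
                     compute_loglik = TRUE) {
  model <- match.arg(model)
  data <- if (inherits(Y, "response_data")) Y else response_data(Y, time)
  if (!inherits(priors, "speedmix_priors")) priors <- do.call(speedmix_priors, priors)
  if (iter <= burnin) stop("'iter' must exceed 'burnin'")
  if (!is.null(seed)) set.seed(seed)
  logT <- log(data$time)
  mixture <- model == "mixture"

  base_init <- default_inits(data, logT, mixture)
  if (!is.null(inits)) base_init[names(inits)] <- inits

  res <- vector("list", chains)
  for (ch in seq_len(chains)) {
    ci <- if (overdispersed) jitter_inits(base_init, mixture) else base_init
    res[[ch]] <- cpp_gibbs_run(data$Y, logT, unclass(priors), ci,
                               as.integer(iter), as.integer(burnin),
                               as.integer(thin), mixture, TRUE,
                               store_person_draws, store_cell_loglik, adapt,
                               compute_loglik)
  }

  lab <- par_labels(data$J)
  for (ch in seq_len(chains)) {
    colnames(res[[ch]]$draws) <- lab
    colnames(res[[ch]]$person_eap) <- c("theta", "tau", "pi")
    colnames(res[[ch]]$person_sd) <- c("theta", "tau", "pi")
  }

  structure(list(
    draws = lapply(res, `[[`, "draws"),
    person_eap = lapply(res, `[[`, "person_eap"),
    person_sd = lapply(res, `[[`, "person_sd"),
    person_draws = if (store_person_draws) lapply(res, `[[`, "person_draws"),
    eta_prob = lapply(res, `[[`, "eta_prob"),
    loglik = lapply(res, `[[`, "loglik"),
    cpo = lapply(res, function(r)
      list(max = r$cpo_max, sum = r$cpo_sum, M = r$n_stored)),
    cell_loglik = if (store_cell_loglik) lapply(res, `[[`, "cell_loglik"),
    state = lapply(res, `[[`, "state"),
    mh = lapply(res, `[[`, "mh"),
    clamped = sum(vapply(res, `[[`, numeric(1), "clamped")),
    skipped_guess_updates =
      sum(vapply(res, `[[`, numeric(1), "skipped_guess_updates")),
    has_loglik = compute_loglik,
    model = model, N = data$N, J = data$J, data = data, priors = priors,
    settings = list(chains = chains, iter = iter, burnin = burnin,
                    thin = thin, seed = seed, adapt = adapt,
                    overdispersed = overdispersed),
    call = match.call()), class = "speedmix")
}

par_labels <- function(J) {
  c(paste0("a[", 1:J, "]"), paste0("b[", 1:J, "]"), paste0("g[", 1:J, "]"),
    paste0("lambda[", 1:J, "]"), paste0("sigma2[", 1:J, "]"),
    "mu_c", "sigma2_c", "sigma_thetatau", "sigma2_tau")
}

# starting values: crude moment-based person estimates, neutral item values
default_inits <- function(data, logT, mixture) {
  pc <- pmin(pmax(rowMeans(data$Y), 0.02), 0.98)
  theta0 <- as.numeric(scale(qlogis(pc)))
  # person speed at its natural scale: the centered negative row-mean
  # log-time estimates tau_i directly under the lognormal RT model
  tau0 <- -(rowMeans(logT) - mean(rowMeans(logT)))
  # covariance block starts at the method-of-moments values of the crude
  # person estimates; with strongly correlated populations the posterior
  # is ridge-shaped near the positive-definiteness boundary, and a
  # data-driven start anchors the weakly identified ability scale
  s2t0 <- max(var(tau0), 0.05)
  # disattenuate the covariance for measurement error in the ability
  # proxy, using Cronbach's alpha of the responses as its reliability
  cv <- colMeans(data$Y) * (1 - colMeans(data$Y))
  alpha <- max(0.3, min(1, data$J / (data$J - 1) *
                             (1 - sum(cv) / max(var(rowSums(data$Y)), 1e-8))))
  stt0 <- cov(theta0, tau0) / sqrt(alpha)
  stt0 <- max(min(stt0, 0.95 * sqrt(s2t0)), -0.95 * sqrt(s2t0))
  list(a = rep(1, data$J), b = rep(0, data$J), g = rep(0.25, data$J),
       lambda = colMeans(logT), sigma2 = rep(0.5, data$J),
       theta = theta0, tau = tau0,
       pi = rep(if (mixture) 0.05 else 0, data$N),
       mu_c = min(colMeans(logT)) - 1, sigma2_c = 0.25,
       sigma_thetatau = stt0, sigma2_tau = s2t0,
       eta = matrix(0L, data$N, data$J))
}

jitter_inits <- function(init, mixture) {
  J <- length(init$a); N <- length(init$theta)
  init$a <- init$a * exp(rnorm(J, 0, 0.3))
  init$b <- init$b + rnorm(J, 0, 0.5)
  init$lambda <- init$lambda + rnorm(J, 0, 0.3)
  init$sigma2 <- init$sigma2 * exp(rnorm(J, 0, 0.3))
  init$theta <- init$theta + rnorm(N, 0, 0.5)
  init$tau <- init$tau + rnorm(N, 0, 0.15)
  if (mixture) {
    init$g <- plogis(qlogis(init$g) + rnorm(J, 0, 0.3))
    init$pi <- plogis(qlogis(pmin(pmax(init$pi, 1e-3), 1 - 1e-3)) +
                        rnorm(N, 0, 0.3))
    init$mu_c <- init$mu_c + rnorm(1, 0, 0.3)
    init$sigma2_c <- init$sigma2_c * exp(rnorm(1, 0, 0.3))
  }
  # the covariance block starts from the common defaults: near the
  # positive-definiteness boundary it moves slowly, and overdispersing it
  # would confound that geometry with measurement-model convergence
  init
}

#' Pooled posterior draws of the scalar parameters
#'
#' @param x a fitted `"speedmix"` object.
#' @param ... unused.
#' @return a matrix with one row per retained draw (chains stacked) and
#'   one labelled column per item or population parameter.
#' @export
as.matrix.speedmix <- function(x, ...) do.call(rbind, x$draws)

#' @export
print.speedmix <- function(x, ...) {
  s <- x$settings
  cat("Rapid-guessing", x$model, "model fit (Polya-gamma Gibbs)\n")
  cat("  data: ", x$N, " persons x ", x$J, " items\n", sep = "")
  cat("  chains: ", s$chains, ", iterations: ", s$iter, " (burn-in ",
      s$burnin, ", thin ", s$thin, ")\n", sep = "")
  if (x$model == "mixture")
    cat("  posterior mean guessing rate:",
        round(mean(vapply(x$eta_prob, mean, numeric(1))), 4), "\n")
  acc <- mh_acceptance(x)
  cat("  MH acceptance (covariance, speed variance):",
      paste(round(acc, 3), collapse = ", "), "\n")
  invisible(x)
}

mh_acceptance <- function(fit) {
  att <- sum(vapply(fit$mh, `[[`, numeric(1), "attempts"))
  c(cov = sum(vapply(fit$mh, `[[`, numeric(1), "acc_cov")) / att,
    var = sum(vapply(fit$mh, `[[`, numeric(1), "acc_var")) / att)
}

#' Posterior mean estimates
#'
#' @param object a fitted `"speedmix"` object.
#' @param ... unused.
#' @return named vector of EAP estimates of the item and population
#'   parameters. Person EAPs are in `object$person_eap`.
#' @export
coef.speedmix <- function(object, ...) colMeans(as.matrix(object))

#' Posterior summary table
#'
#' One row per scalar parameter: EAP (posterior mean), posterior SD, 95%
#' highest-posterior-density interval, and, when the fit has at least two
#' chains, the Gelman-Rubin potential scale reduction factor.
#'
#' @param object a fitted `"speedmix"` object.
#' @param prob HPD interval mass.
#' @param ... unused.
#' @return a data.frame of class `"summary.speedmix"` with columns
#'   `parameter`, `eap`, `sd`, `hpdi_low`, `hpdi_high` and possibly `psrf`.
#' @export
summary.speedmix <- function(object, prob = 0.95, ...) {
  pooled <- as.matrix(object)
  out <- do.call(rbind, lapply(colnames(pooled), function(p)
    eap_summary(pooled[, p], prob = prob, label = p)))
  if (object$settings$chains >= 2)
    out$psrf <- vapply(seq_len(ncol(pooled)), function(k)
      psrf(lapply(object$draws, function(d) d[, k])), numeric(1))
  class(out) <- c("summary.speedmix", "data.frame")
  out
}

#' @export
print.summary.speedmix <- function(x, digits = 4, n = 12, ...) {
  cat("Posterior summaries (", nrow(x), " parameters)\n", sep = "")
  print.data.frame(head(as.data.frame(x), n), digits = digits,
                   row.names = FALSE)
  if (nrow(x) > n) cat("... and", nrow(x) - n, "more rows\n")
  invisible(x)
}

#' Trace plots of selected parameters
#'
#' @param x a fitted `"speedmix"` object.
#' @param pars character vector of parameter labels (see
#'   `colnames(as.matrix(x))`); defaults to the first discrimination,
#'   difficulty and the population parameters.
#' @param ... passed to [graphics::matplot()].
#' @export
plot.speedmix <- function(x, pars = NULL, ...) {
  if (is.null(pars))
    pars <- intersect(c("a[1]", "b[1]", "sigma_thetatau", "sigma2_tau"),
                      colnames(x$draws[[1]]))
  old <- par(mfrow = c(length(pars), 1), mar = c(2.5, 4, 1.5, 1))
  on.exit(par(old))
  for (p in pars) {
    series <- sapply(x$draws, function(d) d[, p])
    matplot(series, type = "l", lty = 1, ylab = p, xlab = "", ...)
  }
  invisible(x)
}

#' Simulate speeded-test data from a fitted model
#'
#' Generates replicate datasets using the posterior-mean item and
#' population parameters of a fit: new persons are drawn from the
#' estimated ability-speed distribution, responses and times from the
#' fitted measurement models, and (for a mixture fit) rapid guessing is
#' induced by the supplied time limit through the backward-replacement
#' mechanism.
#'
#' @param object a fitted `"speedmix"` object.
#' @param nsim number of datasets.
#' @param seed optional seed.
#' @param time_limit test time limit in minutes; `Inf` disables speeding.
#' @param N number of simulated persons (defaults to the fitted N).
#' @param ... unused.
#' @return a list of `nsim` simulated datasets (class `"speedmix_sim"`).
#' @export
simulate.speedmix <- function(object, nsim = 1, seed = NULL,
                              time_limit = Inf, N = object$N, ...) {
  if (!is.null(seed)) set.seed(seed)
  est <- coef(object)
  J <- object$J
  item <- list(a = unname(est[paste0("a[", 1:J, "]")]),
               b = unname(est[paste0("b[", 1:J, "]")]),
               g = unname(est[paste0("g[", 1:J, "]")]),
               lambda = unname(est[paste0("lambda[", 1:J, "]")]),
               sigma2 = unname(est[paste0("sigma2[", 1:J, "]")]))
  pop <- population_params(
    sigma_thetatau = min(unname(est["sigma_thetatau"]),
                         0.99 * sqrt(est["sigma2_tau"])),
    sigma2_tau = unname(est["sigma2_tau"]),
    mu_c = unname(est["mu_c"]), sigma2_c = unname(est["sigma2_c"]))
  design <- sim_design(N = N, J = J, time_limit = time_limit)
  lapply(seq_len(nsim), function(k) {
    person <- draw_persons(N, pop)
    truth <- list(item = item, person = person, pop = pop)
    sol <- simulate_solution_phase(truth)
    apply_time_limit(sol$Y, sol$time, truth, time_limit, design = design)
  })
}
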