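#' Parameter-recovery study
#'
#' Replicated simulate-and-refit study: for each replication a fresh
#' dataset is generated from the design, the mixture model is fitted, and
#' EAP estimates are compared against the generating truth. Bias
#' (mean of estimate minus truth) and MSE (mean squared error) are
#' averaged over items or persons within a replication and then over
#' replications, one row per parameter block.
#'
#' @param design a [sim_design()] object.
#' @param reps number of replications; replication `r` is seeded with
#'   `seed + r` so runs are reproducible and extensible.
#' @param iter,burnin,thin chain settings passed to [speedmix()].
#' @param seed base seed.
#' @param priors prior configuration.
#' @return a data.frame with columns `parameter`, `bias`, `mse` and one
#'   row per block (`a`, `b`, `g`, `lambda`, `sigma2`, `theta`, `tau`,
#'   `mu_c`, `sigma2_c`, `sigma_thetatau`, `sigma2_tau`), plus attribute
#'   `"per_rep"` holding the per-replication values.
#' @export
study_recovery <- function(design, reps = 10, iter = 3000,
                           burnin = 1000, thin = 1, seed = 1,
                           priors = speedmix_priors()) {
  blocks <- c("a", "b", "g", "lambda", "sigma2", "theta", "tau",
              "mu_c", "sigma2_c", "sigma_thetatau", "sigma2_tau")
  per_rep <- array(NA_real_, c(reps, length(blocks), 2),
                   dimnames = list(NULL, blocks, c("bias", "mse")))
  for (r in seq_len(reps)) {
    sim <- simulate_speeded(design, seed = seed + r)
    fit <- speedmix(sim$Y, sim$time, iter = iter, burnin = burnin,
                    thin = thin, priors = priors, seed = seed + r,
                    compute_loglik = FALSE)
    err <- recovery_errors(fit, sim$truth)
    per_rep[r, , ] <- as.matrix(err[blocks, c("bias", "mse")])
  }
  out <- data.frame(parameter = blocks,
                    bias = apply(per_rep[, , "bias", drop = FALSE], 2, mean),
                    mse = apply(per_rep[, , "mse", drop = FALSE], 2, mean),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "per_rep") <- per_rep
  out
}

# bias/MSE of EAP estimates against a truth list, per parameter block
recovery_errors <- function(fit, truth) {
  est <- coef(fit)
  J <- fit$J
  pick <- function(stub) unname(est[paste0(stub, "[", 1:J, "]")])
  pe <- fit$person_eap[[1]]
  if (fit$settings$chains > 1) {
    pe <- Reduce(`+`, fit$person_eap) / fit$settings$chains
  }
  pairs <- list(
    a = list(pick("a"), truth$item$a),
    b = list(pick("b"), truth$item$b),
    g = list(pick("g"), truth$item$g),
    lambda = list(pick("lambda"), truth$item$lambda),
    sigma2 = list(pick("sigma2"), truth$item$sigma2),
    theta = list(pe[, "theta"], truth$person$theta),
    tau = list(pe[, "tau"], truth$person$tau),
    mu_c = list(unname(est["mu_c"]), truth$pop$mu_c),
    sigma2_c = list(unname(est["sigma2_c"]), truth$pop$sigma2_c),
    sigma_thetatau = list(unname(est["sigma_thetatau"]),
                          truth$pop$sigma_thetatau),
    sigma2_tau = list(unname(est["sigma2_tau"]), truth$pop$sigma2_tau))
  out <- t(vapply(pairs, function(p) {
    d <- p[[1]] - p[[2]]
    c(bias = mean(d), mse = mean(d^2))
  }, numeric(2)))
  as.data.frame(out)
}

#' Model-selection study (mixture vs non-mixture)
#'
#' Replicated model-comparison study: datasets are generated from the
#' chosen true model, both the mixture and the non-mixture model are
#' fitted to each, and DIC and LPML are recorded. Reports quartiles
#' across replications per fitted model, and how often each criterion
#' selects the true model.
#'
#' @param true_model generating model, `"mixture"` or `"nonmixture"`.
#' @param rho ability-speed correlation of the generator.
#' @param speededness `"lsl"` or `"hsl"`.
#' @param N,J data dimensions.
#' @param reps number of replications (seeded `seed + r`).
#' @param iter,burnin chain settings for both fits.
#' @param seed base seed.
#' @return a list with `quartiles` (data.frame: fitted model x criterion,
#'   Q1/median/Q3), `per_rep` (data.frame of per-replication DIC/LPML),
#'   and `selection_rate` (named vector: fraction of replications in
#'   which DIC and LPML each select the true model).
#' @export
study_model_selection <- function(true_model = c("mixture", "nonmixture"),
                                  rho = 0.3, speededness = "lsl",
                                  N = 1000, J = 40, reps = 10,
                                  iter = 1500, burnin = 500, seed = 1) {
  true_model <- match.arg(true_model)
  per <- data.frame()
  for (r in seq_len(reps)) {
    sim <- simulate_study2(rho = rho, speededness = speededness,
                           generator_model = true_model, N = N, J = J,
                           seed = seed + r)
    row <- list(rep = r)
    for (m in c("mixture", "nonmixture")) {
      fit <- speedmix(sim$Y, sim$time, model = m, iter = iter,
                      burnin = burnin, seed = seed + r)
      a <- assess(fit)
      row[[paste0("dic_", m)]] <- a$dic
      row[[paste0("lpml_", m)]] <- a$lpml
    }
    per <- rbind(per, as.data.frame(row))
  }
  q <- function(x) quantile(x, c(0.25, 0.5, 0.75), names = FALSE)
  quart <- do.call(rbind, lapply(c("mixture", "nonmixture"), function(m)
    data.frame(fitted = m,
               criterion = c("DIC", "LPML"),
               rbind(q(per[[paste0("dic_", m)]]),
                     q(per[[paste0("lpml_", m)]])))))
  names(quart)[3:5] <- c("q1", "median", "q3")
  dic_pick <- ifelse(per$dic_mixture < per$dic_nonmixture,
                     "mixture", "nonmixture")
  lpml_pick <- ifelse(per$lpml_mixture > per$lpml_nonmixture,
                      "mixture", "nonmixture")
  list(quartiles = quart, per_rep = per,
       selection_rate = c(dic = mean(dic_pick == true_model),
                          lpml = mean(lpml_pick == true_model)))
}
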