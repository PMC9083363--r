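test_that("chains are bit-identical given the seed", {
  sim <- small_sim()
  f1 <- small_fit(sim, seed = 99)
  f2 <- small_fit(sim, seed = 99)
  expect_identical(as.matrix(f1), as.matrix(f2))
  expect_identical(f1$person_eap, f2$person_eap)
  expect_identical(f1$loglik, f2$loglik)
  f3 <- small_fit(sim, seed = 100)
  expect_false(identical(as.matrix(f1), as.matrix(f3)))
})

test_that("fit object has the documented shape and labels", {
  sim <- small_sim(N = 60, J = 5)
  fit <- speedmix(sim$Y, sim$time, iter = 200, burnin = 80, thin = 3,
                  seed = 2, store_person_draws = TRUE)
  M <- (200 - 80) %/% 3
  expect_equal(nrow(fit$draws[[1]]), M)
  expect_equal(ncol(fit$draws[[1]]), 5 * 5 + 4)
  expect_true(all(c("a[1]", "b[5]", "g[3]", "lambda[2]", "sigma2[4]",
                    "mu_c", "sigma2_c", "sigma_thetatau", "sigma2_tau") %in%
                    colnames(fit$draws[[1]])))
  expect_equal(dim(fit$person_draws[[1]]), c(M, 3 * 60))
  expect_equal(dim(fit$eta_prob[[1]]), c(60, 5))
  expect_true(all(fit$eta_prob[[1]] >= 0 & fit$eta_prob[[1]] <= 1))
  # person EAP accumulators agree with the stored person draws
  expect_equal(fit$person_eap[[1]][, "theta"],
               colMeans(fit$person_draws[[1]][, 1:60]), tolerance = 1e-10)
  expect_error(speedmix(sim$Y, sim$time, iter = 100, burnin = 100), "exceed")
  expect_output(print(fit), "mixture model fit")
})

test_that("non-mixture fit keeps the behavior indicators structurally zero", {
  sim <- small_sim()
  fit <- speedmix(sim$Y, sim$time, model = "nonmixture", iter = 250,
                  burnin = 100, seed = 3)
  expect_true(all(fit$eta_prob[[1]] == 0))
  expect_true(all(fit$person_eap[[1]][, "pi"] == 0))
  expect_equal(fit$skipped_guess_updates, 0)
})

test_that("mixture and non-mixture fits agree on data without rapid guessing", {
  # well-identified items (discriminations bounded away from zero) so that
  # difficulty estimates are stable in both fits
  set.seed(8)
  N <- 400; J <- 10
  pop <- population_params(sigma_thetatau = 0.25, sigma2_tau = 0.25)
  truth <- list(
    item = list(a = runif(J, 0.7, 1.6), b = runif(J, -1.5, 1.5),
                g = rep(0.25, J), lambda = runif(J, -0.25, 0.25),
                sigma2 = rep(0.25, J)),
    person = speedmix:::draw_persons(N, pop),
    pop = pop)
  sol <- simulate_solution_phase(truth)
  sim <- apply_time_limit(sol$Y, sol$time, truth, Inf)
  expect_true(all(sim$eta == 0))
  # propensity prior concentrated near zero: the mixture nests the
  # standard hierarchical model and the behavior indicators stay off
  fm <- speedmix(sim$Y, sim$time, iter = 600, burnin = 300, seed = 4,
                 priors = speedmix_priors(iota1 = 1, iota2 = 100))
  fn <- speedmix(sim$Y, sim$time, model = "nonmixture", iter = 600,
                 burnin = 300, seed = 5)
  expect_lt(mean(fm$eta_prob[[1]]), 0.02)
  cm <- coef(fm); cn <- coef(fn)
  ab <- c(paste0("a[", 1:10, "]"), paste0("b[", 1:10, "]"))
  expect_lt(mean(abs(cm[ab] - cn[ab])), 0.1)
  expect_gt(cor(cm[ab], c(truth$item$a, truth$item$b)), 0.95)
  expect_gt(cor(cn[ab], c(truth$item$a, truth$item$b)), 0.95)
})

test_that("successive-conditional cycles preserve the prior marginals (Geweke)", {
  set.seed(37)
  N <- 5; J <- 3
  pr <- list(mu_a = 1, sigma2_a = 0.25, mu_b = 0, sigma2_b = 0.25,
             iota1 = 2, iota2 = 10, iota3 = 5, iota4 = 17,
             mu_lambda = 0, sigma2_lambda = 0.25,
             upsilon1 = 6, omega1 = 2.5, upsilon2 = 6, omega2 = 2.5,
             kappa = 1e-4, vartheta = 1e-4, s01 = 0.05, s02 = 0.05)
  stt <- 0.2; s2t <- 0.5; mu_c <- -2; s2_c <- 0.25
  draw_prior <- function() {
    tau <- rnorm(N, 0, sqrt(s2t))
    pi <- rbeta(N, pr$iota1, pr$iota2)
    list(a = as.numeric(speedmix:::cpp_rtnorm_lb(J, pr$mu_a,
                                                 sqrt(pr$sigma2_a), 0)),
         b = rnorm(J, pr$mu_b, sqrt(pr$sigma2_b)),
         g = rbeta(J, pr$iota3, pr$iota4),
         lambda = rnorm(J, pr$mu_lambda, sqrt(pr$sigma2_lambda)),
         sigma2 = 1 / rgamma(J, pr$upsilon1, rate = pr$omega1),
         theta = rnorm(N, stt / s2t * tau, sqrt(1 - stt^2 / s2t)),
         tau = tau, pi = pi, mu_c = mu_c, sigma2_c = s2_c,
         sigma_thetatau = stt, sigma2_tau = s2t,
         eta = rbern_rows(pi, J))
  }
  gen_data <- function(st) {
    A <- matrix(st$a, N, J, byrow = TRUE); B <- matrix(st$b, N, J, byrow = TRUE)
    G <- matrix(st$g, N, J, byrow = TRUE)
    L <- matrix(st$lambda, N, J, byrow = TRUE)
    S <- matrix(st$sigma2, N, J, byrow = TRUE)
    Pmix <- ifelse(st$eta == 1, G, plogis(A * (st$theta - B)))
    Y <- matrix(rbinom(N * J, 1, Pmix), N, J)
    storage.mode(Y) <- "integer"
    mu <- ifelse(st$eta == 1, st$mu_c, L - st$tau)
    sdv <- ifelse(st$eta == 1, sqrt(st$sigma2_c), sqrt(S))
    list(Y = Y, logT = matrix(rnorm(N * J, mu, sdv), N, J))
  }
  one_scan <- function(st, d) {
    st$eta <- matrix(as.integer(st$eta), N, J)
    speedmix:::cpp_gibbs_run(d$Y, d$logT, pr, st, 1L, 0L, 1L, TRUE, FALSE,
                             FALSE, FALSE, FALSE, FALSE)$state
  }
  M <- 4000
  rec <- matrix(NA_real_, M, 6)
  st <- draw_prior()
  for (m in 1:M) {
    d <- gen_data(st)
    st <- one_scan(st, d)
    rec[m, ] <- c(st$a[1], st$b[1], st$g[1], st$lambda[1], st$sigma2[1],
                  mean(st$pi))
  }
  # analytic prior moments
  al <- -2; h <- dnorm(al) / (1 - pnorm(al))
  a_mean <- 1 + 0.5 * h; a_var <- 0.25 * (1 + al * h - h^2)
  targets <- rbind(
    c(a_mean, a_var),                   # truncated-normal discrimination
    c(0, 0.25),                         # difficulty
    c(5 / 22, 5 * 17 / (22^2 * 23)),    # guessing success Beta(5,17)
    c(0, 0.25),                         # time intensity
    c(0.5, 0.0625),                     # IG(6, 2.5) log-time variance
    c(2 / 12, (2 * 10 / (12^2 * 13)) / N))  # mean propensity
  for (k in 1:6) {
    expect_lt(abs(mean(rec[, k]) - targets[k, 1]),
              4.5 * sqrt(targets[k, 2] / 900) + 0.01)
    expect_lt(abs(var(rec[, k]) / targets[k, 2] - 1), 0.30)
  }
})

test_that("probability clamp and skip counters are reported", {
  sim <- small_sim(N = 50, J = 4, speededness = "lsl")
  fit <- small_fit(sim, iter = 150, burnin = 50, seed = 6)
  expect_gte(fit$clamped, 0)
  expect_gte(fit$skipped_guess_updates, 0)
  expect_equal(fit$mh[[1]]$attempts, 150)
})
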