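# Each full conditional is checked against an independent oracle: exact
# conjugate arithmetic where the update is conjugate, a grid-normalized
# density of the exact unnormalized conditional otherwise (the PG-augmented
# item/ability steps are validated through a two-step sub-Gibbs whose
# stationary marginal is the augmentation-free conditional).

ks_crit <- function(n, alpha = 0.01) sqrt(-0.5 * log(alpha / 2)) / sqrt(n)

test_that("propensity update is the exact Beta conjugate", {
  set.seed(21)
  N <- 4000; J <- 20
  eta <- matrix(0L, N, J); eta[, 1:5] <- 1L  # every person guessed 5 items
  draws <- speedmix:::cpp_step_pi(eta, 1, 5)  # Beta(6, 20)
  expect_lt(abs(mean(draws) - 6 / 26), 0.01)
  expect_lt(abs(var(draws) - 6 * 20 / (26^2 * 27)), 2e-4)
  # no guessing: reduces to Beta(iota1, iota2 + J)
  d0 <- speedmix:::cpp_step_pi(matrix(0L, N, J), 1, 5)
  expect_lt(abs(mean(d0) - 1 / 26), 0.005)
  expect_true(all(draws > 0 & draws < 1))
})

test_that("guessing-success update is the exact Beta conjugate", {
  set.seed(22)
  N <- 50; J <- 3000
  # per item: 10 guessers of whom 3 correct -> Beta(5+3, 17+7) = Beta(8, 24)
  eta <- matrix(0L, N, J); eta[1:10, ] <- 1L
  Y <- matrix(0L, N, J); Y[1:3, ] <- 1L
  g <- speedmix:::cpp_step_g(Y, eta, 5, 17)
  expect_lt(abs(mean(g) - 8 / 32), 0.005)
  expect_lt(abs(var(g) - 8 * 24 / (32^2 * 33)), 3e-4)
  expect_true(all(g > 0 & g < 1))
  # no guessers anywhere: prior Beta(5, 17)
  g0 <- speedmix:::cpp_step_g(Y, matrix(0L, N, J), 5, 17)
  expect_lt(abs(mean(g0) - 5 / 22), 0.005)
})

test_that("item and person updates reduce to their priors with no active cells", {
  set.seed(23)
  N <- 5; R <- 4000
  eta1 <- matrix(1L, N, 1)  # item fully guessed / person fully guessing
  Y <- matrix(0L, N, 1); W <- matrix(0.25, N, 1)
  logT <- matrix(-2, N, 1)
  theta <- rnorm(N); tau <- rnorm(N)
  a <- replicate(R, speedmix:::cpp_step_a(Y, eta1, W, theta, 0, 0.8, 0.09))
  # truncated normal N(0.8, 0.3^2) I(>0) moments
  al <- (0 - 0.8) / 0.3
  tn_mean <- 0.8 + 0.3 * dnorm(al) / (1 - pnorm(al))
  expect_lt(abs(mean(a) - tn_mean), 0.02)
  expect_true(all(a > 0))
  b <- replicate(R, speedmix:::cpp_step_b(Y, eta1, W, theta, 1, 0.3, 0.04))
  expect_lt(abs(mean(b) - 0.3), 0.015)
  expect_lt(abs(sd(b) - 0.2), 0.012)
  lam <- replicate(R, speedmix:::cpp_step_lambda(logT, eta1, tau, 0.5,
                                                 0.4, 0.09))
  expect_lt(abs(mean(lam) - 0.4), 0.02)
  s2 <- replicate(R, speedmix:::cpp_step_sigma2(logT, eta1, tau, 0, 6, 2.5))
  expect_lt(abs(mean(s2) - 0.5), 0.02)  # IG(6, 2.5) mean
  # person with every item guessed: conditional priors
  etaP <- matrix(1L, 1, 20)
  tau1 <- 0.6
  th <- replicate(R, speedmix:::cpp_step_theta(
    matrix(0L, 1, 20), etaP, matrix(0.25, 1, 20), rep(1, 20), rep(0, 20),
    tau1, 0.2, 0.5))
  expect_lt(abs(mean(th) - 0.2 / 0.5 * tau1), 0.06)
  expect_lt(abs(var(th) - (1 - 0.2^2 / 0.5)), 0.06)
  ta <- replicate(R, speedmix:::cpp_step_tau(
    matrix(0, 1, 20), etaP, rep(0, 20), rep(0.5, 20), 0.6, 0.2, 0.5))
  expect_lt(abs(mean(ta) - 0.2 * 0.6), 0.045)
  expect_lt(abs(var(ta) - (0.5 - 0.04)), 0.04)
})

test_that("discrimination sub-Gibbs matches the grid oracle of the exact conditional", {
  fx <- fixture_2pl()
  set.seed(24)
  a <- 1
  draws <- numeric(4000)
  for (r in seq_along(draws)) {
    W <- speedmix:::cpp_step_W(fx$eta, a, fx$b, fx$theta, fx$W)
    a <- speedmix:::cpp_step_a(fx$Y, fx$eta, W, fx$theta, fx$b, 0, 100)
    draws[r] <- a
  }
  thin <- draws[seq(400, 4000, by = 6)]
  grid <- seq(0.01, 6, length.out = 3000)
  logd <- vapply(grid, function(aa)
    sum(dbinom(fx$Y, 1, plogis(aa * (fx$theta - fx$b)), log = TRUE)) +
      dnorm(aa, 0, 10, log = TRUE), numeric(1))
  expect_lt(ks_against_grid(thin, grid, logd), ks_crit(length(thin)))
  expect_true(all(draws > 0))
})

test_that("difficulty sub-Gibbs matches the grid oracle", {
  fx <- fixture_2pl()
  set.seed(25)
  b <- 0
  draws <- numeric(4000)
  for (r in seq_along(draws)) {
    W <- speedmix:::cpp_step_W(fx$eta, fx$a, b, fx$theta, fx$W)
    b <- speedmix:::cpp_step_b(fx$Y, fx$eta, W, fx$theta, fx$a, 0, 100)
    draws[r] <- b
  }
  thin <- draws[seq(400, 4000, by = 6)]
  grid <- seq(-4, 4, length.out = 3000)
  logd <- vapply(grid, function(bb)
    sum(dbinom(fx$Y, 1, plogis(fx$a * (fx$theta - bb)), log = TRUE)) +
      dnorm(bb, 0, 10, log = TRUE), numeric(1))
  expect_lt(ks_against_grid(thin, grid, logd), ks_crit(length(thin)))
})

test_that("with all-correct responses and a diffuse prior, difficulty sits below mean ability", {
  set.seed(26)
  N <- 30
  theta <- rnorm(N)
  Y1 <- matrix(1L, N, 1)
  eta <- matrix(0L, N, 1)
  b <- 0; acc <- numeric(2000)
  for (r in seq_along(acc)) {
    W <- speedmix:::cpp_step_W(eta, 1.3, b, theta, matrix(0.25, N, 1))
    b <- speedmix:::cpp_step_b(Y1, eta, W, theta, 1.3, 0, 100)
    acc[r] <- b
  }
  expect_lt(mean(acc[500:2000]), mean(theta))
})

test_that("ability sub-Gibbs matches the grid oracle on a 20-item fixture", {
  set.seed(27)
  J <- 20
  a <- rexp(J) + 0.3; b <- rnorm(J); tau1 <- 0.4
  th_true <- 0.8
  Y <- matrix(rbinom(J, 1, plogis(a * (th_true - b))), 1, J)
  eta <- matrix(0L, 1, J)
  stt <- 0.2; s2t <- 0.5
  th <- 0
  draws <- numeric(4000)
  for (r in seq_along(draws)) {
    W <- speedmix:::cpp_step_W(eta, a, b, th, matrix(0.25, 1, J))
    th <- speedmix:::cpp_step_theta(Y, eta, W, a, b, tau1, stt, s2t)
    draws[r] <- th
  }
  thin <- draws[seq(400, 4000, by = 6)]
  grid <- seq(-6, 6, length.out = 3000)
  pm <- stt / s2t * tau1; pv <- 1 - stt^2 / s2t
  logd <- vapply(grid, function(tt)
    sum(dbinom(Y[1, ], 1, plogis(a * (tt - b)), log = TRUE)) +
      dnorm(tt, pm, sqrt(pv), log = TRUE), numeric(1))
  expect_lt(ks_against_grid(thin, grid, logd), ks_crit(length(thin)))
})

test_that("speed update matches the grid oracle and reacts to fast responses", {
  set.seed(28)
  J <- 20
  lam <- runif(J, -0.25, 0.25); s2 <- rep(0.25, J)
  logT <- matrix(rnorm(J, lam - 0.4, 0.5), 1, J)
  eta <- matrix(0L, 1, J)
  stt <- 0.2; s2t <- 0.5; th1 <- 0.5
  draws <- replicate(4000, speedmix:::cpp_step_tau(logT, eta, lam, s2, th1,
                                                   stt, s2t))
  grid <- seq(-3, 3, length.out = 3000)
  logd <- vapply(grid, function(tt)
    sum(dnorm(logT[1, ], lam - tt, sqrt(s2), log = TRUE)) +
      dnorm(tt, stt * th1, sqrt(s2t - stt^2), log = TRUE), numeric(1))
  expect_lt(ks_against_grid(draws, grid, logd), ks_crit(length(draws)))
  # faster observed times (below lambda) pull the posterior mean up
  logT_fast <- logT - 1
  d2 <- replicate(2000, speedmix:::cpp_step_tau(logT_fast, eta, lam, s2, th1,
                                                stt, s2t))
  expect_gt(mean(d2), mean(draws))
})

test_that("time-intensity update matches the grid oracle", {
  set.seed(29)
  N <- 40
  tau <- rnorm(N, 0, 0.5)
  lam_true <- 0.3
  logT <- matrix(rnorm(N, lam_true - tau, 0.5), N, 1)
  eta <- matrix(0L, N, 1)
  draws <- replicate(4000, speedmix:::cpp_step_lambda(logT, eta, tau,
                                                      rep(0.25, 1), 0, 100))
  grid <- seq(-2, 2.5, length.out = 3000)
  logd <- vapply(grid, function(l)
    sum(dnorm(logT[, 1], l - tau, 0.5, log = TRUE)) +
      dnorm(l, 0, 10, log = TRUE), numeric(1))
  expect_lt(ks_against_grid(draws, grid, logd), ks_crit(length(draws)))
})

test_that("log-time variance update has the exact inverse-gamma form", {
  set.seed(30)
  N <- 100
  tau <- rnorm(N, 0, 0.5)
  lam <- 0.1
  logT <- matrix(rnorm(N, lam - tau, 0.7), N, 1)
  eta <- matrix(0L, N, 1)
  ss <- sum((logT[, 1] - lam + tau)^2)
  draws <- replicate(4000, speedmix:::cpp_step_sigma2(logT, eta, tau,
                                                      rep(lam, 1), 1, 1))
  # IG(1 + 50, 1 + ss/2): mean rate/(shape-1)
  expect_lt(abs(mean(draws) - (1 + ss / 2) / 50), 0.02)
})

test_that("behavior-indicator probabilities equal the normalized two-branch likelihoods", {
  set.seed(31)
  N <- 60
  theta <- rnorm(N); tau <- rnorm(N, 0, 0.5); pi <- runif(N, 0.05, 0.6)
  Y <- matrix(rbinom(N, 1, 0.5), N, 1)
  logT <- matrix(rnorm(N, -1, 0.7), N, 1)
  a <- 1.2; b <- 0.3; g <- 0.25; lam <- 0.1; s2 <- 0.4
  emp <- rowMeans(replicate(4000, speedmix:::cpp_step_eta(
    Y, logT, a, b, g, lam, s2, theta, tau, pi, -2, 0.3)$eta[, 1]))
  l1 <- log(pi) + ifelse(Y[, 1] == 1, log(g), log(1 - g)) +
    dnorm(logT[, 1], -2, sqrt(0.3), log = TRUE)
  l0 <- log(1 - pi) +
    ifelse(Y[, 1] == 1, plogis(a * (theta - b), log.p = TRUE),
           plogis(-a * (theta - b), log.p = TRUE)) +
    dnorm(logT[, 1], lam - tau, sqrt(s2), log = TRUE)
  exact <- 1 / (1 + exp(l0 - l1))
  expect_lt(max(abs(emp - exact)), 0.035)
})

test_that("degenerate propensities force the behavior indicator", {
  set.seed(32)
  N <- 20
  Y <- matrix(rbinom(N, 1, 0.5), N, 1)
  logT <- matrix(rnorm(N, -1, 0.7), N, 1)
  theta <- rnorm(N); tau <- rnorm(N, 0, 0.5)
  e0 <- speedmix:::cpp_step_eta(Y, logT, 1, 0, 0.25, 0, 0.5, theta, tau,
                                rep(0, N), -2, 0.25)$eta
  expect_true(all(e0 == 0L))
  e1 <- speedmix:::cpp_step_eta(Y, logT, 1, 0, 0.25, 0, 0.5, theta, tau,
                                rep(1, N), -2, 0.25)$eta
  expect_true(all(e1 == 1L))
})

test_that("auxiliary-variable step touches only solution cells; means follow the tilt", {
  set.seed(33)
  N <- 2000
  eta <- matrix(c(rep(0L, N), rep(1L, N)), N, 2)
  W0 <- matrix(-99, N, 2)
  theta <- rep(0, N)
  W <- speedmix:::cpp_step_W(eta, c(1, 1), c(0, 0), theta, W0)
  expect_true(all(W[, 2] == -99))           # rapid-guess cells untouched
  expect_true(all(W[, 1] > 0))
  expect_lt(abs(mean(W[, 1]) - 0.25), 0.015)  # PG(1, 0) mean
  # larger tilt magnitude gives a smaller mean
  W3 <- speedmix:::cpp_step_W(eta, c(1, 1), c(-3, -3), theta, W0)
  expect_lt(mean(W3[, 1]), mean(W[, 1]))
  expect_lt(abs(mean(W3[, 1]) - pg_mean(3)), 0.01)
})

test_that("guessing-time updates: one-cell posterior, skip rule, and recovery", {
  set.seed(34)
  # single guessed cell with log time -2: posterior mean of mu_c is -2
  logT1 <- matrix(exp(0), 2, 2); logT1[1, 1] <- -2
  eta1 <- matrix(0L, 2, 2); eta1[1, 1] <- 1L
  mus <- replicate(3000, speedmix:::cpp_step_guess_rt(
    logT1, eta1, 0, 0.25, 1e-4, 1e-4)$mu_c)
  expect_lt(abs(mean(mus) - (-2)), 0.04)
  expect_lt(abs(sd(mus) - 0.5), 0.03)    # sd = sqrt(sigma2_c / 1)
  # no guessed cells: values retained, skip flagged
  st <- speedmix:::cpp_step_guess_rt(logT1, matrix(0L, 2, 2), -1.5, 0.4,
                                     1e-4, 1e-4)
  expect_equal(st$mu_c, -1.5)
  expect_equal(st$sigma2_c, 0.4)
  expect_equal(st$skipped, 1L)
  # joint recovery on many synthetic guessing times log t ~ N(-2, 0.25)
  N <- 60; J <- 40
  eta <- matrix(1L, N, J)
  logT <- matrix(rnorm(N * J, -2, 0.5), N, J)
  mu <- 0; s2 <- 1
  mus <- s2s <- numeric(2000)
  for (r in 1:2000) {
    st <- speedmix:::cpp_step_guess_rt(logT, eta, mu, s2, 1e-4, 1e-4)
    mu <- st$mu_c; s2 <- st$sigma2_c
    mus[r] <- mu; s2s[r] <- s2
  }
  expect_lt(abs(mean(mus[500:2000]) - (-2)), 0.02)
  expect_lt(abs(mean(s2s[500:2000]) - 0.25), 0.02)
})

test_that("covariance MH preserves positive definiteness and recovers truth", {
  set.seed(35)
  N <- 5000
  stt_true <- 0.25; s2t_true <- 0.25
  xi <- MASS::mvrnorm(N, c(0, 0), matrix(c(1, stt_true, stt_true, s2t_true), 2))
  theta <- xi[, 1]; tau <- xi[, 2]
  stt <- 0.05; s2t <- 0.6
  keep <- matrix(NA_real_, 3000, 2)
  acc <- 0
  for (r in 1:3000) {
    st <- speedmix:::cpp_mh_cov(theta, tau, stt, s2t, 0.02, 0.02, 1e-4, 1e-4)
    stt <- st$sigma_thetatau; s2t <- st$sigma2_tau
    acc <- acc + st$acc_cov
    keep[r, ] <- c(stt, s2t)
    expect_lt(stt^2, s2t)  # positive definiteness at every iteration
  }
  expect_gt(acc, 0)
  post <- keep[1000:3000, ]
  # MC error of the posterior mean at N = 5000: sd(hat) ~ 1/sqrt(N) scale
  expect_lt(abs(mean(post[, 1]) - stt_true), 0.035)
  expect_lt(abs(mean(post[, 2]) - s2t_true), 0.035)
})

test_that("single steps are deterministic given the seed", {
  fx <- fixture_2pl()
  set.seed(36)
  a1 <- speedmix:::cpp_step_a(fx$Y, fx$eta, fx$W, fx$theta, fx$b, 0, 100)
  set.seed(36)
  a2 <- speedmix:::cpp_step_a(fx$Y, fx$eta, fx$W, fx$theta, fx$b, 0, 100)
  expect_identical(a1, a2)
})
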