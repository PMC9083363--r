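# Shared fixture builders. Everything is generated in code at test time.

# small speeded dataset plus a quick mixture fit
small_sim <- function(N = 80, J = 8, speededness = "hsl", seed = 7) {
  simulate_speeded(sim_design(N = N, J = J, speededness = speededness),
                   seed = seed)
}

small_fit <- function(sim = small_sim(), iter = 300, burnin = 150, seed = 1,
                      ...) {
  speedmix(sim$Y, sim$time, iter = iter, burnin = burnin, seed = seed, ...)
}

# empirical CDF vs grid-normalized density: KS distance of draws against
# the exact unnormalized log-density evaluated on a grid
ks_against_grid <- function(draws, grid, logdens) {
  w <- exp(logdens - max(logdens))
  cdf <- cumsum(w) / sum(w)
  s <- sort(draws)
  Fg <- approx(grid, cdf, xout = s, rule = 2)$y
  max(abs(Fg - seq_along(s) / length(s)))
}

# one-item 2PL fixture for the item-step oracles: all solution behavior
fixture_2pl <- function(N = 40, a = 1.2, b = 0.3, seed = 42) {
  set.seed(seed)
  theta <- rnorm(N)
  Y <- matrix(rbinom(N, 1, plogis(a * (theta - b))), N, 1)
  list(N = N, a = a, b = b, theta = theta, Y = Y,
       eta = matrix(0L, N, 1), W = matrix(0.25, N, 1))
}

# per-row Bernoulli(p_i) indicator matrix
rbern_rows <- function(p, J) {
  matrix(rbinom(length(p) * J, 1, rep(p, J)), length(p), J)
}
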