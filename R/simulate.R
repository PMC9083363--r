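#' Simulation design for speeded-test data
#'
#' Describes the data-generating conditions of the built-in simulator:
#' test length, sample size, the speededness level (the range of the item
#' time-intensity parameters), the test time limit, and the true
#' measurement and population parameters. Defaults follow the package's
#' reference simulation study: `lsl` draws time intensities from
#' U(-0.25, 0.25) and `hsl` from U(0.25, 0.75); the limit is 2 minutes
#' per item (40 min for 20 items, 80 min for 40); guessing success is
#' 0.25 on every item; log solution times have variance 0.25 (SD 0.5);
#' rapid-guess log times are N(-2, 0.25); and ability/speed are bivariate
#' normal with variances (1, 0.25) and covariance 0.5 -- a singular,
#' perfectly correlated person population (see [population_params()]).
#'
#' @param N number of examinees.
#' @param J number of items.
#' @param speededness `"lsl"` (low) or `"hsl"` (high); sets
#'   `lambda_range` unless that is given explicitly.
#' @param time_limit test time limit in minutes; `Inf` disables speeding.
#' @param lambda_range length-2 range for the uniform time-intensity draw.
#' @param g true guessing-success probability (scalar or length J).
#' @param sigma2 true log solution-time variance (scalar or length J).
#' @param pop a [population_params()] object with the true population
#'   values.
#' @return an object of class `"speedmix_design"`.
#' @export
sim_design <- function(N = 1000, J = 20, speededness = c("lsl", "hsl"),
                       time_limit = 2 * J, lambda_range = NULL,
                       g = 0.25, sigma2 = 0.25,
                       pop = population_params()) {
  speededness <- match.arg(speededness)
  if (is.null(lambda_range))
    lambda_range <- if (speededness == "lsl") c(-0.25, 0.25) else c(0.25, 0.75)
  if (time_limit <= 0) stop("time_limit must be positive")
  structure(list(N = N, J = J, speededness = speededness,
                 time_limit = time_limit, lambda_range = lambda_range,
                 g = rep_len(g, J), sigma2 = rep_len(sigma2, J),
                 pop = enforce_identification(pop)),
            class = "speedmix_design")
}

#' Draw true parameter values for a simulation design
#'
#' Item discriminations are truncated standard normal (positive),
#' difficulties standard normal, time intensities uniform over the
#' design's speededness range; guessing success and log-time variances are
#' the design constants. Persons are bivariate normal in (ability, speed)
#' with the design's population covariance.
#'
#' @param design a [sim_design()] object.
#' @return list with elements `item`, `person`, `pop`.
#' @export
draw_true_parameters <- function(design) {
  J <- design$J
  item <- list(a = cpp_rtnorm_lb(J, 0, 1, 0),
               b = rnorm(J),
               g = design$g,
               lambda = runif(J, design$lambda_range[1], design$lambda_range[2]),
               sigma2 = design$sigma2)
  person <- draw_persons(design$N, design$pop)
  list(item = item, person = person, pop = design$pop)
}

draw_persons <- function(N, pop) {
  Sigma <- matrix(c(pop$sigma2_theta, pop$sigma_thetatau,
                    pop$sigma_thetatau, pop$sigma2_tau), 2, 2)
  xi <- MASS::mvrnorm(N, mu = c(pop$mu_theta, pop$mu_tau), Sigma = Sigma)
  list(theta = xi[, 1], tau = xi[, 2])
}

#' Simulate the solution phase (no time limit)
#'
#' Responses from the 2PL and response times from the lognormal model,
#' as if every examinee engaged every item with solution behavior.
#'
#' @param truth a truth list as returned by [draw_true_parameters()].
#' @return list with `Y` (binary matrix) and `time` (minutes).
#' @export
simulate_solution_phase <- function(truth) {
  it <- truth$item; pe <- truth$person
  N <- length(pe$theta); J <- length(it$a)
  P <- p_correct_2pl(matrix(pe$theta, N, J),
                     matrix(it$a, N, J, byrow = TRUE),
                     matrix(it$b, N, J, byrow = TRUE))
  Y <- matrix(as.integer(runif(N * J) < P), N, J)
  mu <- outer(-pe$tau, it$lambda, `+`)
  time <- exp(mu + matrix(rnorm(N * J, 0, rep(sqrt(it$sigma2), each = N)),
                          N, J))
  list(Y = Y, time = time)
}

#' Impose the test time limit by backward item replacement
#'
#' Examinees whose total solution time exceeds the limit switch to rapid
#' guessing from the last item backward: each switched item's time is
#' replaced by a fresh draw from the common guessing-time distribution and
#' its response by a Bernoulli(g_j) draw, the running total being
#' recomputed after every replacement until it fits within the limit.
#' The induced behavior indicators therefore form a contiguous suffix of
#' the test for every speeded examinee.
#'
#' @param Y_sol,T_sol solution-phase responses and times.
#' @param truth the generating truth list.
#' @param limit time limit in minutes.
#' @param design optional [sim_design()] recorded in the output.
#' @return an object of class `"speedmix_sim"`: elements `Y`, `time`,
#'   `eta` (true behavior indicators), `unfinished` (logical, per person:
#'   solution-phase total exceeded the limit), `truth`, `design`.
#' @export
apply_time_limit <- function(Y_sol, T_sol, truth, limit, design = NULL) {
  if (limit <= 0) stop("limit must be positive")
  N <- nrow(Y_sol); J <- ncol(Y_sol)
  eta <- matrix(0L, N, J)
  Y <- Y_sol; time <- T_sol
  pop <- truth$pop
  total <- rowSums(T_sol)
  unfinished <- total > limit
  for (i in which(unfinished)) {
    tot <- total[i]
    j <- J
    while (tot > limit && j >= 1) {
      cij <- exp(rnorm(1, pop$mu_c, sqrt(pop$sigma2_c)))
      tot <- tot - time[i, j] + cij
      time[i, j] <- cij
      eta[i, j] <- 1L
      Y[i, j] <- as.integer(runif(1) < truth$item$g[j])
      j <- j - 1
    }
  }
  structure(list(Y = Y, time = time, eta = eta, unfinished = unfinished,
                 truth = truth, design = design,
                 time_limit = limit),
            class = "speedmix_sim")
}

#' @export
print.speedmix_sim <- function(x, ...) {
  cat("Simulated speeded-test data:", nrow(x$Y), "persons x", ncol(x$Y),
      "items\n")
  cat("  time limit:", x$time_limit, "min;",
      round(100 * mean(x$unfinished), 1), "% unfinished;",
      round(100 * mean(x$eta), 2), "% of cells rapid-guessed\n")
  invisible(x)
}

#' Simulate one speeded-test dataset
#'
#' Composes [draw_true_parameters()], [simulate_solution_phase()] and
#' [apply_time_limit()] for a design.
#'
#' @param design a [sim_design()] object.
#' @param seed optional seed.
#' @return a `"speedmix_sim"` object.
#' @examples
#' sim <- simulate_speeded(sim_design(N = 200, J = 20, speededness = "hsl"),
#'                         seed = 1)
#' mean(sim$eta)
#' @export
simulate_speeded <- function(design, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  truth <- draw_true_parameters(design)
  sol <- simulate_solution_phase(truth)
  apply_time_limit(sol$Y, sol$time, truth, design$time_limit, design = design)
}

#' Speededness statistics of simulated datasets
#'
#' Averages, over a list of simulated datasets, the proportion of
#' examinees whose solution-phase total time exceeds the limit and the
#' proportion of all person-item cells answered by rapid guessing.
#'
#' @param datasets list of `"speedmix_sim"` objects (a single object is
#'   accepted).
#' @return named numeric vector `c(prop_unfinished, prop_guessed)`.
#' @export
table1_stats <- function(datasets) {
  if (inherits(datasets, "speedmix_sim")) datasets <- list(datasets)
  if (!length(datasets)) stop("at least one dataset is required")
  c(prop_unfinished = mean(vapply(datasets, function(d) mean(d$unfinished),
                                  numeric(1))),
    prop_guessed = mean(vapply(datasets, function(d) mean(d$eta),
                               numeric(1))))
}

#' Simulate data for the model-comparison study
#'
#' Generates a dataset under either the mixture (speeded) or the
#' non-mixture (no time pressure) generating model, with ability and
#' speed drawn from a unit-variance bivariate normal with correlation
#' `rho`. The mixture generator applies the time limit through the
#' backward-replacement mechanism; the non-mixture generator emits pure
#' solution-phase data.
#'
#' @param rho ability-speed correlation (e.g. 0.3 for weak, 0.8 for
#'   strong).
#' @param speededness `"lsl"` or `"hsl"`.
#' @param generator_model `"mixture"` or `"nonmixture"`.
#' @param N,J data dimensions.
#' @param seed optional seed.
#' @return a `"speedmix_sim"` object (for the non-mixture generator,
#'   `eta` is all zero and `unfinished` all `FALSE`).
#' @export
simulate_study2 <- function(rho = 0.3, speededness = c("lsl", "hsl"),
                            generator_model = c("mixture", "nonmixture"),
                            N = 1000, J = 40, seed = NULL) {
  speededness <- match.arg(speededness)
  generator_model <- match.arg(generator_model)
  if (!is.null(seed)) set.seed(seed)
  pop <- population_params(sigma_thetatau = rho, sigma2_tau = 1)
  design <- sim_design(N = N, J = J, speededness = speededness, pop = pop)
  truth <- draw_true_parameters(design)
  sol <- simulate_solution_phase(truth)
  limit <- if (generator_model == "mixture") design$time_limit else Inf
  out <- apply_time_limit(sol$Y, sol$time, truth, limit, design = design)
  out
}
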