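#' Gelman-Rubin potential scale reduction factor
#'
#' PSRF for one scalar parameter from multiple chains, in the
#' between/within variance-ratio form
#' \eqn{\sqrt{(M-1)/M + B/(MW)}}, where `B` is the between-chain and `W`
#' the within-chain variance of `M` retained draws. Values near 1
#' indicate convergence; the package's simulation studies use the
#' conventional threshold 1.2. PSRF is invariant to jointly affine
#' transformations of all chains. For a fitted model, [psrf.speedmix()]
#' returns one value per stored scalar parameter.
#'
#' @param x a list of numeric vectors (one per chain), a C x M matrix of
#'   draws (chains in rows), or a fitted [speedmix] object with at least
#'   two chains.
#' @param ... unused.
#' @return a single PSRF (or a named vector for a fit).
#' @export
psrf <- function(x, ...) UseMethod("psrf")

#' @export
psrf.default <- function(x, ...) {
  chains <- if (is.matrix(x)) lapply(seq_len(nrow(x)), function(i) x[i, ]) else x
  C <- length(chains)
  if (C < 2) stop("PSRF needs at least two chains")
  M <- unique(lengths(chains))
  if (length(M) != 1) stop("chains must have equal length")
  if (M < 10) stop("chains are too short for PSRF")
  means <- vapply(chains, mean, numeric(1))
  W <- mean(vapply(chains, var, numeric(1)))
  B <- M * var(means)
  if (W == 0) return(if (B == 0) 1 else Inf)
  sqrt((M - 1) / M + B / (M * W))
}

#' @rdname psrf
#' @export
psrf.speedmix <- function(x, ...) {
  if (x$settings$chains < 2) stop("PSRF needs at least two chains")
  lab <- colnames(x$draws[[1]])
  out <- vapply(seq_along(lab), function(k)
    psrf.default(lapply(x$draws, function(d) d[, k])), numeric(1))
  names(out) <- lab
  out
}

#' Highest posterior density interval
#'
#' Shortest interval containing a given posterior mass, computed by the
#' shortest-interval-of-sorted-draws method (Chen-Shao). For unimodal
#' posteriors its width is at most that of the equal-tailed interval.
#'
#' @param x numeric vector of posterior draws.
#' @param prob interval mass (default 0.95).
#' @return numeric vector `c(lower, upper)`.
#' @export
hpdi <- function(x, prob = 0.95) {
  x <- sort(x)
  n <- length(x)
  if (n < 2) return(c(x[1], x[1]))
  k <- max(1, min(n - 1, ceiling(prob * n)))
  widths <- x[(k + 1):n] - x[1:(n - k)]
  i <- which.min(widths)
  c(x[i], x[i + k])
}

#' Posterior summary of one parameter
#'
#' Mean (EAP), SD, and highest-posterior-density interval bounds of a
#' vector of draws.
#'
#' @param x numeric vector of posterior draws (at least one).
#' @param prob HPD interval mass.
#' @param label parameter label recorded in the output.
#' @return a one-row data.frame with columns `parameter`, `eap`, `sd`,
#'   `hpdi_low`, `hpdi_high`.
#' @export
eap_summary <- function(x, prob = 0.95, label = "parameter") {
  h <- hpdi(x, prob)
  data.frame(parameter = label, eap = mean(x),
             sd = if (length(x) > 1) sd(x) else 0,
             hpdi_low = h[1], hpdi_high = h[2],
             stringsAsFactors = FALSE)
}

#' Tidy long-format table of posterior draws
#'
#' One row per (parameter, chain, iteration), ordered by parameter then
#' chain then iteration; suitable for external trace plotting and for
#' round-tripping through delimited files.
#'
#' @param fit a fitted [speedmix] object.
#' @param pars parameter labels to include (default: all stored scalars).
#' @return a data.frame with columns `parameter`, `chain`, `iteration`,
#'   `value`.
#' @export
trace_df <- function(fit, pars = NULL) {
  lab <- colnames(fit$draws[[1]])
  if (is.null(pars)) pars <- lab
  miss <- setdiff(pars, lab)
  if (length(miss)) stop("unknown parameters: ", paste(miss, collapse = ", "))
  out <- do.call(rbind, lapply(pars, function(p)
    do.call(rbind, lapply(seq_along(fit$draws), function(ch)
      data.frame(parameter = p, chain = ch,
                 iteration = seq_len(nrow(fit$draws[[ch]])),
                 value = fit$draws[[ch]][, p],
                 stringsAsFactors = FALSE)))))
  rownames(out) <- NULL
  out
}
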