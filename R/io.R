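#' Read response and response-time matrices from CSV files
#'
#' Each file holds one N x J numeric matrix, comma-separated, with an
#' optional header row of item labels (detected automatically unless
#' `header` is given). Missing values are rejected.
#'
#' @param y_file path to the binary response CSV.
#' @param t_file path to the response-time CSV (minutes).
#' @param header logical, or `NA` to auto-detect (header assumed when the
#'   first row is not fully numeric).
#' @return a validated [response_data] object.
#' @export
read_response_data <- function(y_file, t_file, header = NA) {
  read_one <- function(path) {
    if (!file.exists(path)) stop("file not found: ", path)
    hdr <- header
    if (is.na(hdr)) {
      first <- strsplit(readLines(path, n = 1), ",")[[1]]
      hdr <- anyNA(suppressWarnings(as.numeric(first)))
    }
    as.matrix(read.csv(path, header = hdr))
  }
  response_data(read_one(y_file), read_one(t_file))
}

#' Write fit artifacts to a directory
#'
#' Writes one CSV of retained draws per chain (`chain-<k>.csv`, one
#' labelled column per scalar parameter, one row per retained
#' iteration), a posterior summary table (`summary.csv`, EAP/SD/HPDI and
#' PSRF when available), an assessment report (`assessment.json` with
#' dic, pD, dev_bar, dev_hat, lpml), and a short run log with the
#' Metropolis-Hastings acceptance rates (`run-log.txt`).
#'
#' @param fit a fitted [speedmix] object.
#' @param dir output directory, created if needed.
#' @return invisibly, the paths written.
#' @export
write_speedmix <- function(fit, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  for (ch in seq_along(fit$draws)) {
    p <- file.path(dir, sprintf("chain-%d.csv", ch))
    write.csv(as.data.frame(fit$draws[[ch]]), p, row.names = FALSE)
    paths <- c(paths, p)
  }
  p <- file.path(dir, "summary.csv")
  write.csv(as.data.frame(summary(fit)), p, row.names = FALSE)
  paths <- c(paths, p)
  a <- assess(fit)
  p <- file.path(dir, "assessment.json")
  jsonlite::write_json(a[c("dic", "pD", "dev_bar", "dev_hat", "lpml")],
                       p, auto_unbox = TRUE, digits = NA)
  paths <- c(paths, p)
  p <- file.path(dir, "run-log.txt")
  acc <- mh_acceptance(fit)
  writeLines(c(
    sprintf("model: %s", fit$model),
    sprintf("data: %d x %d", fit$N, fit$J),
    sprintf("chains: %d, iter: %d, burnin: %d, thin: %d",
            fit$settings$chains, fit$settings$iter, fit$settings$burnin,
            fit$settings$thin),
    sprintf("seed: %s", deparse(fit$settings$seed)),
    sprintf("MH acceptance: covariance %.3f, speed variance %.3f",
            acc["cov"], acc["var"]),
    sprintf("probability clamps in behavior update: %d", fit$clamped),
    sprintf("skipped guessing-time updates (no eta=1 cells): %d",
            fit$skipped_guess_updates)), p)
  paths <- c(paths, p)
  invisible(paths)
}
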