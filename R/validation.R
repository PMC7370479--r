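## Performance metrics for the simulation-validation study: estimation
## errors (point estimate minus simulated true prevalence), per-scenario
## interval coverage, interval lengths, and the comparative statistics --
## Pearson correlation, Deming (errors-in-variables) regression, and an
## exploratory regression of residual errors on the design variables.

#' Estimation errors against the simulated truth
#'
#' Joins an estimates table to the scenario table and computes, for every
#' (data set, method) pair, the estimation error `point - pi_true`.  The
#' case label is carried through when present, enabling the subgroup
#' analysis by truncation case.
#'
#' @param estimates long table from [estimate_frequentist()] and/or
#'   [fit_bayes_bulk()] (columns `scenario_id`, `replicate_id`, `method`,
#'   `point`, optionally `case`).
#' @param scenarios scenario table with `scenario_id` and `pi_true`.
#' @return data.frame: `scenario_id`, `replicate_id`, `method`, `error`,
#'   `case` (NA when unavailable).
#' @export
estimation_errors <- function(estimates, scenarios) {
  idx <- match(estimates$scenario_id, scenarios$scenario_id)
  if (anyNA(idx)) {
    stop("estimates reference scenario_id values absent from the ",
         "scenario table", call. = FALSE)
  }
  data.frame(
    scenario_id = estimates$scenario_id,
    replicate_id = estimates$replicate_id,
    method = estimates$method,
    error = estimates$point - scenarios$pi_true[idx],
    case = if ("case" %in% names(estimates)) estimates$case else NA
  )
}

#' Per-scenario interval coverage
#'
#' For each scenario and method, the fraction of replicate data sets
#' whose interval contains the true prevalence (non-strict inequalities
#' at the endpoints).  Excluded replicates never enter the estimates
#' table, so the denominator is the number of retained replicates;
#' rows with missing interval limits are also dropped from it.
#'
#' @inheritParams estimation_errors
#' @return data.frame: `scenario_id`, `method`, `coverage`,
#'   `n_replicates_used`.
#' @export
coverage_by_scenario <- function(estimates, scenarios) {
  idx <- match(estimates$scenario_id, scenarios$scenario_id)
  if (anyNA(idx)) {
    stop("estimates reference scenario_id values absent from the ",
         "scenario table", call. = FALSE)
  }
  pi_true <- scenarios$pi_true[idx]
  ok <- !is.na(estimates$lower) & !is.na(estimates$upper)
  hit <- estimates$lower <= pi_true & pi_true <= estimates$upper
  dt <- data.table::data.table(
    scenario_id = estimates$scenario_id[ok],
    method = estimates$method[ok],
    hit = hit[ok]
  )
  res <- dt[, list(coverage = mean(hit),
                   n_replicates_used = .N),
            by = c("scenario_id", "method")]
  as.data.frame(res)
}

#' Interval lengths by method and case
#'
#' @inheritParams estimation_errors
#' @return data.frame: `scenario_id`, `replicate_id`, `method`, `case`,
#'   `length`.
#' @export
interval_lengths <- function(estimates) {
  data.frame(
    scenario_id = estimates$scenario_id,
    replicate_id = estimates$replicate_id,
    method = estimates$method,
    case = if ("case" %in% names(estimates)) estimates$case else NA,
    length = estimates$upper - estimates$lower
  )
}

#' Deming (errors-in-variables) regression
#'
#' Fits `y = intercept + slope * x` when both variables are measured
#' with error, with known error-variance ratio
#' `delta = var(err_y) / var(err_x)`.  With `delta = 1` this is
#' orthogonal regression: it minimises the summed squared orthogonal
#' distances to the line.  Closed form:
#' `slope = (s_yy - delta*s_xx + sqrt((s_yy - delta*s_xx)^2 +
#' 4*delta*s_xy^2)) / (2*s_xy)`, intercept through the means.  The slope
#' confidence interval is a leave-one-out jackknife (normal-theory on
#' the pseudo-values), and the Pearson correlation of the point pairs is
#' reported alongside.
#'
#' @param xs,ys numeric vectors (>= 3 points, non-zero covariance).
#' @param variance_ratio error-variance ratio `delta`, default 1.
#' @param level confidence level of the jackknife slope CI.
#' @return list of class `deming_fit`: `slope`, `intercept`, `slope_ci`
#'   (length 2), `r`, `n`.
#' @export
deming_fit <- function(xs, ys, variance_ratio = 1, level = 0.95) {
  stopifnot(length(xs) == length(ys), length(xs) >= 3L,
            variance_ratio > 0)
  keep <- is.finite(xs) & is.finite(ys)
  xs <- xs[keep]
  ys <- ys[keep]
  n <- length(xs)
  slope_from_sums <- function(sxx, syy, sxy, d) {
    if (abs(sxy) < .Machine$double.eps * sqrt(sxx * syy + 1)) {
      stop("degenerate fit: zero covariance between xs and ys",
           call. = FALSE)
    }
    (syy - d * sxx + sqrt((syy - d * sxx)^2 + 4 * d * sxy^2)) / (2 * sxy)
  }
  mx <- mean(xs)
  my <- mean(ys)
  cx <- xs - mx
  cy <- ys - my
  sxx <- sum(cx^2)
  syy <- sum(cy^2)
  sxy <- sum(cx * cy)
  slope <- slope_from_sums(sxx, syy, sxy, variance_ratio)
  intercept <- my - slope * mx
  # leave-one-out slopes via downdated sums (vectorised)
  sx <- sum(xs)
  sy <- sum(ys)
  mx_i <- (sx - xs) / (n - 1)
  my_i <- (sy - ys) / (n - 1)
  sxx_i <- (sxx + mx^2 * n) - xs^2 - (n - 1) * mx_i^2
  syy_i <- (syy + my^2 * n) - ys^2 - (n - 1) * my_i^2
  sxy_i <- (sxy + mx * my * n) - xs * ys - (n - 1) * mx_i * my_i
  d <- variance_ratio
  disc <- (syy_i - d * sxx_i)^2 + 4 * d * sxy_i^2
  slope_i <- (syy_i - d * sxx_i + sqrt(disc)) / (2 * sxy_i)
  pseudo <- n * slope - (n - 1) * slope_i
  se_jack <- sqrt(sum((pseudo - mean(pseudo))^2) / (n * (n - 1)))
  z <- qnorm(1 - (1 - level) / 2)
  structure(list(slope = slope, intercept = intercept,
                 slope_ci = c(slope - z * se_jack, slope + z * se_jack),
                 r = cor(xs, ys), n = n),
            class = "deming_fit")
}

#' @export
print.deming_fit <- function(x, ...) {
  cat(sprintf(
    "Deming regression (n = %d)\n  slope     %.4f  [%.4f, %.4f]\n  intercept %.4f\n  Pearson r %.4f\n",
    x$n, x$slope, x$slope_ci[1L], x$slope_ci[2L], x$intercept, x$r))
  invisible(x)
}

#' Regression of estimation errors on standardised design variables
#'
#' Exploratory check of whether the residual estimation error after
#' misclassification adjustment depends on the study conditions: per
#' method, an ordinary least-squares fit of the error on the
#' z-transformed statistical and design variables (`pi_true`, `se_true`,
#' `sp_true`, `n`, `n_se`, `n_sp`) and all of their pairwise
#' interactions (6 main effects + 15 interactions + intercept = 22
#' coefficients).
#'
#' @param errors table from [estimation_errors()].
#' @param scenarios scenario table.
#' @return data.frame with one row per (method, term): `method`, `term`,
#'   `estimate`, `std_error`, `r_squared` (the whole-model R^2, repeated
#'   within a method; 0 when the errors have no variance).
#' @export
residual_error_regression <- function(errors, scenarios) {
  idx <- match(errors$scenario_id, scenarios$scenario_id)
  vars <- c("pi_true", "se_true", "sp_true", "n", "n_se", "n_sp")
  out <- lapply(unique(errors$method), function(m) {
    rows <- errors$method == m
    zd <- as.data.frame(scale(scenarios[idx[rows], vars]))
    zd$error <- errors$error[rows]
    fit <- lm(error ~ (pi_true + se_true + sp_true + n + n_se + n_sp)^2,
              data = zd)
    cf <- coef(fit)
    if (anyNA(cf)) {
      warning("rank-deficient design in residual error regression for ",
              "method ", m)
    }
    sm <- summary(fit)
    r2 <- sm$r.squared
    if (!is.finite(r2)) r2 <- 0
    std <- sm$coefficients[match(names(cf), rownames(sm$coefficients)),
                           "Std. Error"]
    data.frame(method = m, term = names(cf), estimate = unname(cf),
               std_error = unname(std), r_squared = r2, row.names = NULL)
  })
  do.call(rbind, out)
}
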