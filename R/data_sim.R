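## Simulation of replicate count data sets per scenario, maximum-likelihood
## proportion estimates, and the case classification that drives the
## downstream analysis:
##
##   excluded : 1 - Sp_hat >= Se_hat  (test no better than chance; the
##              misclassification adjustment is undefined/meaningless)
##   case2    : retained, raw Rogan-Gladen estimate < 0
##   case3    : retained, raw Rogan-Gladen estimate > 1
##   case1    : retained, raw estimate already inside [0, 1]

CASE_LEVELS <- c("case1", "case2", "case3", "excluded")

#' Simulate replicate count data sets for one scenario
#'
#' Draws `n_replicates` independent data sets from the scenario's binomial
#' sampling model: `x_se ~ Bin(n_se, se_true)` (validation of sensitivity),
#' `x_sp ~ Bin(n_sp, sp_true)` (validation of specificity), and
#' `x ~ Bin(n, AP)` positives in the field application, where `AP` is the
#' true apparent prevalence [apparent_prevalence()].
#'
#' Replicates for a scenario are drawn from that scenario's own "data"
#' substream in a fixed order, so the whole replicate block of any one
#' scenario can be regenerated in isolation.
#'
#' @param scenario single-row data.frame as returned by [draw_scenarios()].
#' @param n_replicates number of data sets (>= 1).
#' @param seed integer root seed (the same root used for the scenario draw
#'   gives non-overlapping streams).
#' @return data.frame with columns `scenario_id`, `replicate_id`, `x_se`,
#'   `x_sp`, `x`.
#' @export
draw_counts <- function(scenario, n_replicates, seed) {
  stopifnot(is.data.frame(scenario), nrow(scenario) == 1L)
  if (length(n_replicates) != 1L || !is.finite(n_replicates) ||
      n_replicates < 1 || n_replicates != round(n_replicates)) {
    stop("`n_replicates` must be a positive integer", call. = FALSE)
  }
  n_replicates <- as.integer(n_replicates)
  k <- as.integer(scenario$scenario_id)
  stream <- rng_substreams(seed, k, stage = "data")[[k]]
  ap <- apparent_prevalence(scenario$pi_true, scenario$se_true,
                            scenario$sp_true)
  draws <- with_rng_state(stream, {
    x_se <- rbinom(n_replicates, scenario$n_se, scenario$se_true)
    x_sp <- rbinom(n_replicates, scenario$n_sp, scenario$sp_true)
    x <- rbinom(n_replicates, scenario$n, ap)
    list(x_se = x_se, x_sp = x_sp, x = x)
  })
  data.frame(
    scenario_id = k,
    replicate_id = seq_len(n_replicates),
    x_se = draws$x_se, x_sp = draws$x_sp, x = draws$x
  )
}

#' Maximum-likelihood proportion estimates
#'
#' The MLEs of sensitivity, specificity and apparent prevalence are the
#' observed proportions `x_se / n_se`, `x_sp / n_sp` and `x / n`.
#'
#' @param x_se,n_se positives / size of the sensitivity validation study.
#' @param x_sp,n_sp negatives / size of the specificity validation study.
#' @param x,n positives / size of the field application.
#' @return data.frame with columns `se_hat`, `sp_hat`, `ap_hat`.
#' @export
mle_estimates <- function(x_se, n_se, x_sp, n_sp, x, n) {
  stopifnot(all(x_se >= 0 & x_se <= n_se),
            all(x_sp >= 0 & x_sp <= n_sp),
            all(x >= 0 & x <= n))
  data.frame(se_hat = x_se / n_se, sp_hat = x_sp / n_sp, ap_hat = x / n)
}

#' Classify data sets by their raw Rogan-Gladen estimate
#'
#' A data set is `excluded` when `1 - sp_hat >= se_hat` (strict inequality
#' is required of a usable test).  Retained data sets are `case2` when the
#' raw Rogan-Gladen estimate is negative (`ap_hat < 1 - sp_hat`), `case3`
#' when it exceeds one (`ap_hat > se_hat`), and `case1` otherwise.  The
#' boundaries `ap_hat == 1 - sp_hat` and `ap_hat == se_hat` give estimates
#' of exactly 0 or 1, which are valid proportions, hence `case1`.
#'
#' @param se_hat,sp_hat,ap_hat MLE proportions (vectorised).
#' @return character vector with values in
#'   `c("case1", "case2", "case3", "excluded")`.
#' @export
classify_case <- function(se_hat, sp_hat, ap_hat) {
  stopifnot(length(se_hat) == length(sp_hat),
            length(se_hat) == length(ap_hat))
  # the same numerator/denominator arithmetic as the Rogan-Gladen
  # estimate, so labels and raw estimates can never disagree
  denom <- se_hat - (1 - sp_hat)
  num <- ap_hat - (1 - sp_hat)
  out <- rep("case1", length(se_hat))
  excluded <- denom <= 0
  out[!excluded & num < 0] <- "case2"
  out[!excluded & num > denom] <- "case3"
  out[excluded] <- "excluded"
  out
}

#' Simulate the full data table for a set of scenarios
#'
#' Runs [draw_counts()] for every scenario, attaches the MLEs and the case
#' classification, and returns one long table (one row per data set).
#' Excluded data sets are kept in the table, labelled `excluded`; all
#' estimators skip them.
#'
#' @param scenarios data.frame from [draw_scenarios()].
#' @param n_replicates replicate data sets per scenario.
#' @param seed integer root seed.
#' @return data.frame with columns `scenario_id`, `replicate_id`, `x_se`,
#'   `x_sp`, `x`, `se_hat`, `sp_hat`, `ap_hat`, `case`.
#' @export
simulate_datasets <- function(scenarios, n_replicates, seed) {
  stopifnot(is.data.frame(scenarios), nrow(scenarios) >= 1L)
  ids <- as.integer(scenarios$scenario_id)
  streams <- rng_substreams(seed, max(ids), stage = "data")
  pieces <- vector("list", nrow(scenarios))
  for (i in seq_len(nrow(scenarios))) {
    sc <- scenarios[i, ]
    ap <- apparent_prevalence(sc$pi_true, sc$se_true, sc$sp_true)
    draws <- with_rng_state(streams[[ids[i]]], {
      x_se <- rbinom(n_replicates, sc$n_se, sc$se_true)
      x_sp <- rbinom(n_replicates, sc$n_sp, sc$sp_true)
      x <- rbinom(n_replicates, sc$n, ap)
      list(x_se = x_se, x_sp = x_sp, x = x)
    })
    pieces[[i]] <- data.frame(
      scenario_id = ids[i], replicate_id = seq_len(n_replicates),
      x_se = draws$x_se, x_sp = draws$x_sp, x = draws$x,
      se_hat = draws$x_se / sc$n_se, sp_hat = draws$x_sp / sc$n_sp,
      ap_hat = draws$x / sc$n
    )
  }
  out <- as.data.frame(data.table::rbindlist(pieces))
  out$case <- classify_case(out$se_hat, out$sp_hat, out$ap_hat)
  out
}

#' Write / read the data table as CSV
#'
#' @param data data.frame as returned by [simulate_datasets()].
#' @param path file path.
#' @return `path`, invisibly (writer); the data.frame (reader).
#' @export
write_datasets <- function(data, path) {
  write_table_csv(data, path)
}

#' @rdname write_datasets
#' @export
read_datasets <- function(path) {
  req <- c("scenario_id", "replicate_id", "x_se", "x_sp", "x",
           "se_hat", "sp_hat", "ap_hat", "case")
  read_table_csv(path, req)
}
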