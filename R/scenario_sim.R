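## Simulation of "true" parameter scenarios.
##
## A scenario couples the three statistical parameters of a diagnostic
## testing study -- true prevalence pi, test sensitivity Se and test
## specificity Sp -- with the three design parameters: the application
## sample size n and the sizes n_se, n_sp of the validation studies that
## characterised the test against a gold standard.

# sample sizes offered for the sensitivity / specificity validation studies
VALIDATION_SIZES <- c(50L, 100L, 200L, 500L, 1000L, 2000L, 5000L)

#' Draw random true-parameter scenarios
#'
#' Generates `n_scenarios` independent parameter sets for the
#' simulation-validation study.  Statistical parameters are drawn from
#' continuous uniform distributions -- sensitivity and specificity from
#' U(0.6, 1) (a test should beat chance comfortably), prevalence from
#' U(0, 1) -- and design parameters from discrete uniforms: the validation
#' sizes `n_se`, `n_sp` from \{50, 100, 200, 500, 1000, 2000, 5000\} and
#' the application size `n` from the integers 50..2000.  No correlation is
#' imposed between any of the parameters.
#'
#' Each scenario is drawn from its own random substream, so scenario `k`
#' is identical for a given `seed` no matter how many scenarios are
#' requested.
#'
#' @param n_scenarios number of parameter sets to draw (>= 1).
#' @param seed integer root seed.
#' @return data.frame with columns `scenario_id`, `se_true`, `sp_true`,
#'   `pi_true`, `n_se`, `n_sp`, `n`.
#' @examples
#' sc <- draw_scenarios(5, seed = 1)
#' apparent_prevalence(sc$pi_true, sc$se_true, sc$sp_true)
#' @export
draw_scenarios <- function(n_scenarios, seed) {
  if (length(n_scenarios) != 1L || !is.finite(n_scenarios) ||
      n_scenarios < 1 || n_scenarios != round(n_scenarios)) {
    stop("`n_scenarios` must be a positive integer", call. = FALSE)
  }
  n_scenarios <- as.integer(n_scenarios)
  streams <- rng_substreams(seed, n_scenarios, stage = "scenario")
  out <- matrix(0, nrow = n_scenarios, ncol = 6L)
  for (k in seq_len(n_scenarios)) {
    out[k, ] <- with_rng_state(streams[[k]], {
      c(runif(1, 0.6, 1),                        # se_true
        runif(1, 0.6, 1),                        # sp_true
        runif(1, 0, 1),                          # pi_true
        sample(VALIDATION_SIZES, 1L),            # n_se
        sample(VALIDATION_SIZES, 1L),            # n_sp
        sample(50:2000, 1L))                     # n
    })
  }
  data.frame(
    scenario_id = seq_len(n_scenarios),
    se_true = out[, 1L], sp_true = out[, 2L], pi_true = out[, 3L],
    n_se = as.integer(out[, 4L]), n_sp = as.integer(out[, 5L]),
    n = as.integer(out[, 6L])
  )
}

#' Apparent prevalence implied by true parameters
#'
#' The apparent prevalence is the probability that a randomly sampled
#' individual tests positive:
#' `AP = Se * pi + (1 - Sp) * (1 - pi)`.
#' It equals the true prevalence only for a perfect test, and always lies
#' between `1 - Sp` and `Se` whenever `Se + Sp > 1`.
#'
#' @param pi true prevalence (vectorised).
#' @param se test sensitivity, Pr(T+ | D+).
#' @param sp test specificity, Pr(T- | D-).
#' @return numeric vector of apparent prevalences.
#' @export
apparent_prevalence <- function(pi, se, sp) {
  stopifnot(all(is.finite(pi)), all(is.finite(se)), all(is.finite(sp)),
            all(pi >= 0 & pi <= 1), all(se >= 0 & se <= 1),
            all(sp >= 0 & sp <= 1))
  se * pi + (1 - sp) * (1 - pi)
}

#' Write / read a scenario table as CSV
#'
#' Columns mirror the scenario layout: scenario_id, se_true, sp_true,
#' pi_true, n_se, n_sp, n.  Full precision is preserved on round trip.
#'
#' @param scenarios data.frame as returned by [draw_scenarios()].
#' @param path file path.
#' @return `path`, invisibly (writer); the scenario data.frame (reader).
#' @export
write_scenarios <- function(scenarios, path) {
  write_table_csv(scenarios, path)
}

#' @rdname write_scenarios
#' @export
read_scenarios <- function(path) {
  req <- c("scenario_id", "se_true", "sp_true", "pi_true", "n_se", "n_sp", "n")
  read_table_csv(path, req)
}
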