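## Orchestration and configuration: run the four pipeline stages in
## order (scenario simulation -> data simulation -> estimation ->
## validation), persist every stage boundary as CSV, and record a run
## manifest.  Each stage can also be re-run in isolation from the
## persisted CSVs through the exported stage functions.

#' Build a run configuration
#'
#' The `"full"` preset is the complete study design: 1,000 scenarios
#' with 1,000 replicate data sets each.  The `"reduced"` preset (200
#' scenarios x 100 replicates, shortened chains) exercises the identical
#' code path at a fraction of the cost and is the default.  Any field
#' can be overridden explicitly.
#'
#' @param preset `"reduced"` or `"full"`.
#' @param n_scenarios,n_replicates design size (override the preset).
#' @param seed root seed for every source of randomness.
#' @param level confidence/credible level.
#' @param methods estimation methods to run; `"bayes_hdi"` enables the
#'   Bayesian model.
#' @param mcmc `mcmc_config` for the Bayesian model (defaults depend on
#'   the preset: full-length chains for `"full"`, 3 x (1,000 burn-in +
#'   4,000 retained) for `"reduced"`).
#' @param outdir output directory for stage CSVs and the manifest.
#' @return list of class `run_config`.
#' @export
run_config <- function(preset = c("reduced", "full"),
                       n_scenarios = NULL, n_replicates = NULL,
                       seed = 1L, level = 0.95,
                       methods = c(FREQ_METHODS, "bayes_hdi"),
                       mcmc = NULL, outdir = "trueprev-run") {
  preset <- match.arg(preset)
  defaults <- switch(preset,
    full = list(n_scenarios = 1000L, n_replicates = 1000L,
                mcmc = mcmc_config(seed = seed)),
    reduced = list(n_scenarios = 200L, n_replicates = 100L,
                   mcmc = mcmc_config(n_burnin = 1000L,
                                      n_samples = 4000L, seed = seed)))
  methods <- match.arg(methods, c(FREQ_METHODS, "bayes_hdi"),
                       several.ok = TRUE)
  structure(list(
    preset = preset,
    n_scenarios = as.integer(n_scenarios %||% defaults$n_scenarios),
    n_replicates = as.integer(n_replicates %||% defaults$n_replicates),
    seed = as.integer(seed), level = level, methods = methods,
    mcmc = mcmc %||% defaults$mcmc, outdir = outdir
  ), class = "run_config")
}

#' Read a run configuration from a flat YAML or JSON file
#'
#' Recognised keys mirror [run_config()]: `preset`, `n_scenarios`,
#' `n_replicates`, `seed`, `level`, `methods`, `outdir`, and the MCMC
#' settings `chains`, `burnin`, `samples`, `psrf_threshold`.
#'
#' @param path path to a `.yaml`/`.yml` or `.json` file.
#' @return `run_config` list.
#' @export
read_run_config <- function(path) {
  ext <- tolower(tools::file_ext(path))
  cfg <- if (ext %in% c("yaml", "yml")) {
    if (!requireNamespace("yaml", quietly = TRUE)) {
      stop("the 'yaml' package is required to read YAML configs",
           call. = FALSE)
    }
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  base <- run_config(preset = cfg$preset %||% "reduced",
                     n_scenarios = cfg$n_scenarios,
                     n_replicates = cfg$n_replicates,
                     seed = cfg$seed %||% 1L,
                     level = cfg$level %||% 0.95,
                     methods = cfg$methods %||% c(FREQ_METHODS, "bayes_hdi"),
                     outdir = cfg$outdir %||% "trueprev-run")
  if (!is.null(cfg$chains) || !is.null(cfg$burnin) ||
      !is.null(cfg$samples) || !is.null(cfg$psrf_threshold)) {
    base$mcmc <- mcmc_config(
      n_chains = cfg$chains %||% base$mcmc$n_chains,
      n_burnin = cfg$burnin %||% base$mcmc$n_burnin,
      n_samples = cfg$samples %||% base$mcmc$n_samples,
      psrf_threshold = cfg$psrf_threshold %||% base$mcmc$psrf_threshold,
      seed = base$seed)
  }
  base
}

#' Run the complete simulation-validation pipeline
#'
#' Executes the four stages in order, writing each stage boundary to
#' `cfg$outdir`: `scenarios.csv`, `data.csv`, `estimates.csv`, the five
#' validation summaries (`errors.csv`, `coverage_by_scenario.csv`,
#' `lengths.csv`, `deming_results.csv`,
#' `regression_coefficients.csv`) and a `manifest.json` recording the
#' configuration, row counts and exclusion count.  Partially written
#' outputs are removed if a stage fails.
#'
#' @param cfg `run_config`.
#' @param quiet suppress per-stage progress messages.
#' @return the manifest, invisibly (a named list).
#' @export
run_pipeline <- function(cfg = run_config(), quiet = FALSE) {
  stopifnot(inherits(cfg, "run_config"))
  dir.create(cfg$outdir, recursive = TRUE, showWarnings = FALSE)
  written <- character(0)
  ok <- FALSE
  on.exit(if (!ok) unlink(written), add = TRUE)
  say <- function(...) if (!quiet) message(...)
  path <- function(f) file.path(cfg$outdir, f)

  say("stage 1/4: simulating ", cfg$n_scenarios, " parameter sets")
  scenarios <- draw_scenarios(cfg$n_scenarios, cfg$seed)
  written <- c(written, write_scenarios(scenarios, path("scenarios.csv")))

  say("stage 2/4: simulating ", cfg$n_scenarios, " x ", cfg$n_replicates,
      " data sets")
  data <- simulate_datasets(scenarios, cfg$n_replicates, cfg$seed)
  written <- c(written, write_datasets(data, path("data.csv")))
  n_excluded <- sum(data$case == "excluded")

  say("stage 3/4: estimating prevalence (",
      paste(cfg$methods, collapse = ", "), ")")
  freq_methods <- intersect(cfg$methods, FREQ_METHODS)
  est_list <- list()
  if (length(freq_methods)) {
    est_list$freq <- estimate_frequentist(data, scenarios, freq_methods,
                                          cfg$level)
  }
  if ("bayes_hdi" %in% cfg$methods) {
    bay <- fit_bayes_bulk(data, scenarios, cfg$mcmc, mass = cfg$level)
    nc <- sum(!bay$converged)
    if (nc > 0) {
      bad <- bay[!bay$converged, c("scenario_id", "replicate_id")]
      warning("non-converged Bayesian fits (psrf >= threshold) for ",
              nc, " data set(s): ",
              paste(sprintf("(%d, %d)", bad$scenario_id,
                            bad$replicate_id), collapse = " "))
    }
    est_list$bayes <- data.frame(
      scenario_id = bay$scenario_id, replicate_id = bay$replicate_id,
      method = bay$method, point_raw = bay$point, point = bay$point,
      lower = bay$lower, upper = bay$upper, length = bay$length,
      case = bay$case)
  }
  estimates <- do.call(rbind, unname(est_list))
  written <- c(written, write_table_csv(estimates, path("estimates.csv")))

  say("stage 4/4: validating estimates")
  errors <- estimation_errors(estimates, scenarios)
  coverage <- coverage_by_scenario(estimates, scenarios)
  lengths <- interval_lengths(estimates)
  written <- c(written,
               write_table_csv(errors, path("errors.csv")),
               write_table_csv(coverage, path("coverage_by_scenario.csv")),
               write_table_csv(lengths, path("lengths.csv")))
  deming_rows <- list()
  if ("bayes_hdi" %in% estimates$method) {
    deming_rows <- pipeline_deming(estimates, errors, lengths)
  }
  if (length(deming_rows)) {
    written <- c(written, write_table_csv(do.call(rbind, deming_rows),
                                          path("deming_results.csv")))
  }
  regression <- residual_error_regression(errors, scenarios)
  written <- c(written, write_table_csv(regression,
                                        path("regression_coefficients.csv")))

  manifest <- list(
    package_version = as.character(utils::packageVersion("trueprev")),
    r_version = as.character(getRversion()),
    preset = cfg$preset, seed = cfg$seed, level = cfg$level,
    n_scenarios = cfg$n_scenarios, n_replicates = cfg$n_replicates,
    methods = cfg$methods,
    mcmc = unclass(cfg$mcmc),
    n_datasets_total = cfg$n_scenarios * cfg$n_replicates,
    n_excluded = n_excluded,
    n_datasets_retained = cfg$n_scenarios * cfg$n_replicates - n_excluded,
    n_estimate_rows = nrow(estimates),
    files = basename(written)
  )
  jsonlite::write_json(manifest, path("manifest.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  ok <- TRUE
  invisible(manifest)
}

# Deming comparisons of the Bayesian estimator against the Rogan-Gladen
# frequentist reference: estimation errors (vs the truncated RGE carried
# by any frequentist method) and interval lengths (vs Lang-Reiczigel).
pipeline_deming <- function(estimates, errors, lengths) {
  rows <- list()
  freq_present <- intersect(unique(errors$method), FREQ_METHODS)
  if ("bayes_hdi" %in% errors$method && length(freq_present)) {
    ref <- freq_present[1L]          # all carry the same truncated RGE
    m <- merge(errors[errors$method == ref,
                      c("scenario_id", "replicate_id", "error")],
               errors[errors$method == "bayes_hdi",
                      c("scenario_id", "replicate_id", "error")],
               by = c("scenario_id", "replicate_id"),
               suffixes = c("_rge", "_bayes"))
    fit <- deming_fit(m$error_rge, m$error_bayes)
    rows$errors <- data.frame(
      comparison = "bayes_error_on_rge_error", slope = fit$slope,
      intercept = fit$intercept, slope_ci_low = fit$slope_ci[1L],
      slope_ci_high = fit$slope_ci[2L], r = fit$r, n = fit$n)
  }
  if (all(c("bayes_hdi", "lang_reiczigel") %in% lengths$method)) {
    m <- merge(lengths[lengths$method == "lang_reiczigel",
                       c("scenario_id", "replicate_id", "length")],
               lengths[lengths$method == "bayes_hdi",
                       c("scenario_id", "replicate_id", "length")],
               by = c("scenario_id", "replicate_id"),
               suffixes = c("_lr", "_bayes"))
    keep <- is.finite(m$length_lr) & is.finite(m$length_bayes)
    fit <- deming_fit(m$length_lr[keep], m$length_bayes[keep])
    rows$lengths <- data.frame(
      comparison = "hdi_length_on_lr_length", slope = fit$slope,
      intercept = fit$intercept, slope_ci_low = fit$slope_ci[1L],
      slope_ci_high = fit$slope_ci[2L], r = fit$r, n = fit$n)
  }
  rows
}

#' Estimate prevalence for a single user-supplied data set
#'
#' Applies every requested method to one set of counts -- typically real
#' data: `x` positives among `n` tested, plus the validation-study
#' counts that characterise the diagnostic test.  If the estimated test
#' accuracy violates the usability condition `1 - sp_hat < se_hat`, no
#' adjusted estimate is produced: an error advises against adjusting for
#' misclassification with an apparently uninformative test, since this
#' usually signals that the validation data do not fit the application.
#'
#' @inheritParams wald_rogan_gladen_ci
#' @param methods methods to run (default: all five frequentist plus the
#'   Bayesian model).
#' @param level confidence/credible level, default 0.95.
#' @param mcmc `mcmc_config` for the Bayesian fit.
#' @return data.frame with one row per method: `method`, `point_raw`,
#'   `point`, `lower`, `upper`, `length`.
#' @examples
#' estimate_single(x = 129, n = 323, x_se = 74, n_se = 100,
#'                 x_sp = 193, n_sp = 200,
#'                 methods = c("clopper_pearson", "lang_reiczigel"))
#' @export
estimate_single <- function(x, n, x_se, n_se, x_sp, n_sp,
                            methods = c(FREQ_METHODS, "bayes_hdi"),
                            level = 0.95, mcmc = mcmc_config()) {
  methods <- match.arg(methods, c(FREQ_METHODS, "bayes_hdi"),
                       several.ok = TRUE)
  m <- mle_estimates(x_se, n_se, x_sp, n_sp, x, n)
  if ((1 - m$sp_hat) >= m$se_hat) {
    stop("estimated test accuracy violates 1 - sp_hat < se_hat: the ",
         "test does not discriminate better than chance on these ",
         "validation data. Refrain from adjusting for ",
         "misclassification until the reliability and relevance of the ",
         "diagnostic's accuracy parameters are clarified.",
         call. = FALSE)
  }
  scenarios <- data.frame(scenario_id = 1L, se_true = NA_real_,
                          sp_true = NA_real_, pi_true = NA_real_,
                          n_se = n_se, n_sp = n_sp, n = n)
  data <- data.frame(scenario_id = 1L, replicate_id = 1L,
                     x_se = x_se, x_sp = x_sp, x = x,
                     se_hat = m$se_hat, sp_hat = m$sp_hat,
                     ap_hat = m$ap_hat, case = classify_case(
                       m$se_hat, m$sp_hat, m$ap_hat))
  out <- list()
  freq <- intersect(methods, FREQ_METHODS)
  if (length(freq)) {
    est <- estimate_frequentist(data, scenarios, freq, level)
    out$freq <- est[, c("method", "point_raw", "point", "lower", "upper",
                        "length")]
  }
  if ("bayes_hdi" %in% methods) {
    s <- fit_bayes(x, n, x_se, n_se, x_sp, n_sp, mcmc, mass = level)
    out$bayes <- data.frame(method = "bayes_hdi", point_raw = s$mean_pi,
                            point = s$mean_pi, lower = s$hdi_low,
                            upper = s$hdi_high,
                            length = s$hdi_high - s$hdi_low)
  }
  res <- do.call(rbind, unname(out))
  rownames(res) <- NULL
  res
}
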