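# Shared fixtures built in code.

# The first exemplary parameter set of the simulation design, with its
# first and fourth replicate data sets (counts and hand-checked MLEs).
example_scenario <- function() {
  data.frame(scenario_id = 1L, se_true = 0.7479478, sp_true = 0.9332674,
             pi_true = 0.4459405, n_se = 100L, n_sp = 200L, n = 323L)
}

example_counts <- function() {
  data.frame(
    scenario_id = 1L, replicate_id = c(1L, 4L),
    x_se = c(74L, 73L), x_sp = c(193L, 191L), x = c(129L, 109L)
  )
}

# small complete data table (counts + MLE + case) for estimator tests
example_data_table <- function() {
  cnt <- example_counts()
  sc <- example_scenario()
  m <- mle_estimates(cnt$x_se, sc$n_se, cnt$x_sp, sc$n_sp, cnt$x, sc$n)
  cbind(cnt, m, case = classify_case(m$se_hat, m$sp_hat, m$ap_hat))
}
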