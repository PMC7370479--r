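# helper: exact HDI of a Beta distribution by shrinking the tail split
beta_hdi_exact <- function(a, b, mass = 0.95) {
  width <- function(t) qbeta(t + mass, a, b) - qbeta(t, a, b)
  t <- optimize(width, c(0, 1 - mass))$minimum
  c(qbeta(t, a, b), qbeta(t + mass, a, b))
}

test_that("prior specification encodes the validation counts", {
  p <- prior_spec(74, 100, 193, 200)
  expect_equal(p$pi, c(1, 1))
  expect_equal(p$se, c(75, 27))
  expect_equal(p$sp, c(194, 8))
  expect_error(prior_spec(101, 100, 0, 10))
})

test_that("a near-perfect-test prior reduces to the conjugate posterior", {
  # with Se = Sp = 1 the model is x ~ Bin(n, pi) and the posterior is
  # Beta(x + 1, n - x + 1)
  prior <- prior_spec(1e6, 1e6, 1e6, 1e6)
  cfg <- mcmc_config(n_burnin = 1000L, n_samples = 4000L, seed = 5)
  draws <- gibbs_sample(129, 323, prior, cfg)
  s <- summarize_posterior(draws)
  expect_lt(abs(s$mean_pi - 130 / 325), 0.004)   # Beta(130, 195) mean
  exact <- beta_hdi_exact(130, 195)
  expect_lt(abs(s$hdi_low - exact[1]), 0.01)
  expect_lt(abs(s$hdi_high - exact[2]), 0.01)

  # x = 0: posterior Beta(1, n + 1), mean 1 / (n + 2)
  draws0 <- gibbs_sample(0, 50, prior, cfg)
  expect_lt(abs(mean(draws0$pi) - 1 / 52), 0.005)
})

test_that("the posterior respects the disease/non-disease relabelling
          symmetry", {
  cfg <- mcmc_config(n_burnin = 1000L, n_samples = 4000L, seed = 9)
  a <- gibbs_sample(30, 100, prior_spec(80, 100, 180, 200), cfg)
  b <- gibbs_sample(70, 100, prior_spec(180, 200, 80, 100), cfg)
  expect_lt(abs(mean(a$pi) - (1 - mean(b$pi))), 0.01)
  expect_lt(abs(sd(a$pi) - sd(b$pi)), 0.01)
})

test_that("Gibbs posterior matches brute-force grid integration on a toy
          problem", {
  x <- 7L; n <- 20L; x_se <- 16L; n_se <- 20L; x_sp <- 18L; n_sp <- 20L
  # unnormalised posterior on a 101^3 grid, marginalised over (Se, Sp)
  g <- seq(0.005, 0.995, length.out = 101)
  prior_se <- dbeta(g, x_se + 1, n_se - x_se + 1)
  prior_sp <- dbeta(g, x_sp + 1, n_sp - x_sp + 1)
  marg <- vapply(g, function(pi) {
    ap <- outer(g, g, function(se, sp) se * pi + (1 - sp) * (1 - pi))
    lik <- dbinom(x, n, ap)
    sum(lik * outer(prior_se, prior_sp))
  }, numeric(1))
  marg <- marg / sum(marg)
  grid_mean <- sum(g * marg)
  # discrete highest-density region containing 95% of the mass
  ord <- order(marg, decreasing = TRUE)
  sel <- ord[cumsum(marg[ord]) <= 0.95]
  grid_hdi <- range(g[c(sel, ord[length(sel) + 1L])])

  cfg <- mcmc_config(n_burnin = 1000L, n_samples = 7000L, seed = 21)
  draws <- gibbs_sample(x, n, prior_spec(x_se, n_se, x_sp, n_sp), cfg)
  s <- summarize_posterior(draws)
  expect_lt(abs(s$mean_pi - grid_mean), 0.01)
  expect_lt(abs(s$hdi_low - grid_hdi[1]), 0.02)
  expect_lt(abs(s$hdi_high - grid_hdi[2]), 0.02)
})

test_that("PSRF distinguishes mixed from unmixed chains", {
  set.seed(3)
  mixed <- matrix(rnorm(3e4), ncol = 3)
  r <- psrf(mixed)
  expect_gt(r, 0.99)
  expect_lt(r, 1.02)
  # disjoint chains
  bad <- cbind(rnorm(1000, 0.2, 0.001), rnorm(1000, 0.8, 0.001))
  expect_gt(psrf(bad), 10)
  # duplicated chains: no between-chain variance
  ch <- rnorm(5000)
  expect_lt(abs(psrf(cbind(ch, ch)) - 1), 0.001)
  expect_error(psrf(matrix(rnorm(100), ncol = 1)), "two chains")
})

test_that("PSRF agrees with the coda implementation", {
  skip_if_not_installed("coda")
  set.seed(14)
  draws <- matrix(rnorm(6000) + rep(c(0, 0.05, 0.1), each = 2000),
                  ncol = 3)
  mine <- psrf(draws)
  ref <- coda::gelman.diag(coda::mcmc.list(apply(draws, 2, coda::mcmc,
                                                 simplify = FALSE)),
                           autoburnin = FALSE)$psrf[1, 1]
  expect_lt(abs(mine - ref), 0.02)
})

test_that("the HDI is the shortest mass-covering window", {
  expect_equal(hdi(rep(0.4, 200)), c(0.4, 0.4))
  set.seed(6)
  u <- runif(1e6)
  h <- hdi(u, 0.95)
  expect_lt(abs((h[2] - h[1]) - 0.95), 0.005)
  b <- rbeta(1e6, 130, 195)
  h <- hdi(b, 0.95)
  exact <- beta_hdi_exact(130, 195)
  expect_lt(abs(h[1] - exact[1]), 0.005)
  expect_lt(abs(h[2] - exact[2]), 0.005)
  # deterministic tie-break: lowest starting index
  expect_equal(hdi(c(1, 2, 3, 4), mass = 0.5), c(1, 2))
  expect_error(hdi(numeric(0)), "empty")
})

test_that("effective sample size is sane for iid and autocorrelated
          draws", {
  skip_if_not_installed("coda")
  set.seed(8)
  iid <- matrix(rnorm(9000), ncol = 3)
  expect_gt(ess(iid), 6000)
  ar <- matrix(as.numeric(arima.sim(list(ar = 0.8), n = 9000)), ncol = 3)
  mine <- ess(ar)
  ref <- sum(apply(ar, 2, function(ch) coda::effectiveSize(coda::mcmc(ch))))
  expect_lt(mine, 3000)              # strong autocorrelation cuts ESS
  expect_lt(abs(mine - ref) / ref, 0.5)
})

test_that("posterior summaries stay inside the unit interval", {
  cfg <- mcmc_config(n_burnin = 500L, n_samples = 2000L, seed = 2)
  for (counts in list(c(0L, 50L), c(50L, 50L), c(10L, 500L))) {
    s <- fit_bayes(counts[1], counts[2], 45, 50, 48, 50, cfg)
    expect_true(s$mean_pi > 0 && s$mean_pi < 1)
    expect_true(s$hdi_low >= 0 && s$hdi_high <= 1)
    expect_lte(s$hdi_low, s$hdi_high)
  }
})

test_that("bulk fitting agrees with single-data-set fits and is
          deterministic", {
  sc <- draw_scenarios(4, seed = 17)
  dat <- simulate_datasets(sc, 3, seed = 17)
  cfg <- mcmc_config(n_burnin = 1000L, n_samples = 4000L, seed = 17)
  bulk <- fit_bayes_bulk(dat, sc, cfg)
  expect_equal(nrow(bulk), sum(dat$case != "excluded"))
  expect_identical(bulk, fit_bayes_bulk(dat, sc, cfg))
  d <- merge(dat, sc)
  d <- d[order(d$scenario_id, d$replicate_id), ]
  for (i in c(1L, 7L)) {
    s <- fit_bayes(d$x[i], d$n[i], d$x_se[i], d$n_se[i], d$x_sp[i],
                   d$n_sp[i], cfg)
    row <- bulk[bulk$scenario_id == d$scenario_id[i] &
                bulk$replicate_id == d$replicate_id[i], ]
    expect_lt(abs(row$point - s$mean_pi), 0.01)
    expect_lt(abs(row$lower - s$hdi_low), 0.02)
    expect_lt(abs(row$upper - s$hdi_high), 0.02)
  }
})

test_that("parameter recovery: posterior mean is unbiased at large
          sample sizes", {
  sc <- data.frame(scenario_id = 1L, se_true = 0.85, sp_true = 0.9,
                   pi_true = 0.3, n_se = 5000L, n_sp = 5000L, n = 2000L)
  dat <- simulate_datasets(sc, 100, seed = 23)
  cfg <- mcmc_config(n_burnin = 500L, n_samples = 2000L, seed = 23)
  bulk <- fit_bayes_bulk(dat, sc, cfg)
  bias <- mean(bulk$point) - 0.3
  # 4 MC standard errors: per-fit sampling SD ~ 0.015 at these sizes
  expect_lt(abs(bias), 0.006)
})
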