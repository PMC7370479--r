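test_that("Rogan-Gladen estimate inverts the misclassification map", {
  expect_equal(rogan_gladen(0.3993808, 0.74, 0.965), 0.5168522,
               tolerance = 1e-6)
  # endpoints of the admissible apparent-prevalence range
  expect_equal(rogan_gladen(0.035, 0.74, 0.965), 0)
  expect_equal(rogan_gladen(0.74, 0.74, 0.965), 1)
  # a perfect test needs no adjustment
  expect_equal(rogan_gladen(0.37, 1, 1), 0.37)
  expect_error(rogan_gladen(0.4, 0.5, 0.5), "degenerate")
})

test_that("unit truncation clamps and rejects non-finite input", {
  expect_equal(truncate_unit(-0.1), 0)
  expect_equal(truncate_unit(1.2), 1)
  expect_equal(truncate_unit(0.517), 0.517)
  expect_equal(truncate_unit(c(-2, 0.5, 7)), c(0, 0.5, 1))
  expect_error(truncate_unit(NaN), "non-finite")
  expect_error(truncate_unit(Inf), "non-finite")
})

test_that("Clopper-Pearson interval matches closed forms and binom.test", {
  ci <- exact_binomial_ci(0, 20)
  expect_equal(ci$lower, 0)
  expect_equal(ci$upper, 1 - 0.025^(1 / 20), tolerance = 1e-9)
  # vectorised; x = n gives upper = 1
  ci <- exact_binomial_ci(c(20, 129), c(20, 323))
  expect_equal(ci$upper[1], 1)
  # independent exact implementation as oracle
  bt <- binom.test(129, 323)$conf.int
  expect_equal(ci$lower[2], bt[1], tolerance = 1e-6)
  expect_equal(ci$upper[2], bt[2], tolerance = 1e-6)
})

test_that("all three exact orderings hit the boundary cases", {
  for (m in c("clopper_pearson", "sterne", "blaker")) {
    ci <- exact_binomial_ci(20, 20, method = m)
    expect_equal(ci$upper, 1, info = m)
    ci <- exact_binomial_ci(0, 20, method = m)
    expect_equal(ci$lower, 0, info = m)
  }
})

test_that("Clopper-Pearson coverage is conservative at every parameter", {
  level <- 0.95
  for (n in c(5L, 13L, 25L)) {
    x <- 0:n
    ci <- exact_binomial_ci(x, n, level)
    p_grid <- seq(0.001, 0.999, length.out = 999)
    cov <- vapply(p_grid, function(p) {
      sum(dbinom(x, n, p)[ci$lower <= p & p <= ci$upper])
    }, numeric(1))
    expect_true(all(cov >= level - 1e-12))
  }
})

test_that("Blaker interval is contained in Clopper-Pearson", {
  for (n in c(10L, 37L, 100L)) {
    for (x in 0:n) {
      cp <- exact_binomial_ci(x, n)
      bl <- exact_binomial_ci(x, n, method = "blaker")
      expect_gte(bl$lower, cp$lower - 1e-7)
      expect_lte(bl$upper, cp$upper + 1e-7)
    }
  }
})

test_that("Sterne interval encloses the exact acceptance set", {
  # independent oracle: dense scan of the full-support p-value
  pval_full <- function(x, n, p) {
    d <- dbinom(0:n, n, p)
    sum(d[d <= d[x + 1] * (1 + 1e-7)])
  }
  for (case in list(c(3L, 17L), c(129L, 323L))) {
    x <- case[1]; n <- case[2]
    ci <- exact_binomial_ci(x, n, method = "sterne")
    grid <- seq(1e-4, 1 - 1e-4, by = 1e-4)
    accepted <- grid[vapply(grid, function(p) pval_full(x, n, p) >= 0.05,
                            logical(1))]
    expect_lt(abs(ci$lower - min(accepted)), 3e-4)
    expect_lt(abs(ci$upper - max(accepted)), 3e-4)
  }
})

test_that("apparent-prevalence intervals transform to the prevalence scale", {
  # admissible endpoints map to [0, 1]
  tr <- transform_ap_interval(1 - 0.965, 0.74, 0.74, 0.965)
  expect_equal(tr$lower, 0)
  expect_equal(tr$upper, 1)
  # perfect test: identity
  tr <- transform_ap_interval(0.35, 0.45, 1, 1)
  expect_equal(tr$lower, 0.35)
  expect_equal(tr$upper, 0.45)
  # hand-computed linear map
  tr <- transform_ap_interval(0.35, 0.45, 0.74, 0.965)
  expect_equal(tr$lower, 0.44681, tolerance = 1e-4)
  expect_equal(tr$upper, 0.58865, tolerance = 1e-4)
  expect_error(transform_ap_interval(0.3, 0.4, 0.5, 0.5), "degenerate")
})

test_that("truncation commutes with reporting for transformed intervals", {
  set.seed(77)
  for (i in 1:50) {
    se <- runif(1, 0.6, 1); sp <- runif(1, 0.6, 1)
    lo <- runif(1); hi <- lo + runif(1, 0, 1 - lo)
    tr <- transform_ap_interval(lo, hi, se, sp)
    raw_lo <- (lo - (1 - sp)) / (se + sp - 1)
    raw_hi <- (hi - (1 - sp)) / (se + sp - 1)
    expect_equal(tr$lower, min(max(raw_lo, 0), 1))
    expect_equal(tr$upper, min(max(raw_hi, 0), 1))
    expect_lte(tr$lower, tr$upper)
  }
})

test_that("Wald-Rogan-Gladen interval matches its variance formula", {
  w <- wald_rogan_gladen_ci(129, 323, 74, 100, 193, 200)
  # independent recomputation of the plug-in Wald variance
  se <- 0.74; sp <- 0.965; ap <- 129 / 323
  pt <- (ap - (1 - sp)) / (se + sp - 1)
  v <- (ap * (1 - ap) / 323) / (se + sp - 1)^2
  expect_equal(w$point, pt, tolerance = 1e-10)
  expect_equal(w$upper - w$lower, 2 * qnorm(0.975) * sqrt(v),
               tolerance = 1e-8)
  # containment after truncation, on random retained data sets
  sc <- draw_scenarios(30, seed = 8)
  dat <- simulate_datasets(sc, 5, seed = 8)
  dat <- dat[dat$case != "excluded", ]
  d <- merge(dat, sc)
  w <- wald_rogan_gladen_ci(d$x, d$n, d$x_se, d$n_se, d$x_sp, d$n_sp)
  expect_true(all(w$lower <= w$point & w$point <= w$upper))
  expect_true(all(w$lower >= 0 & w$upper <= 1))
})

test_that("a perfect test reduces the Wald interval to the plain
          proportion interval", {
  w <- wald_rogan_gladen_ci(129, 323, 100, 100, 100, 100)
  ap <- 129 / 323
  expect_equal(w$point, ap)
  expect_equal(w$upper - w$lower,
               2 * qnorm(0.975) * sqrt(ap * (1 - ap) / 323),
               tolerance = 1e-8)
})

test_that("Lang-Reiczigel interval behaves at its limits", {
  # converges to the Wald-RG interval as all samples grow (the
  # pseudo-counts and the validation-variance terms both vanish)
  big <- 1e7
  lr <- lang_reiczigel_ci(round(0.4 * big), big, round(0.9 * big), big,
                          round(0.95 * big), big)
  w <- wald_rogan_gladen_ci(round(0.4 * big), big, round(0.9 * big), big,
                            round(0.95 * big), big)
  expect_equal(lr$lower, w$lower, tolerance = 1e-3)
  expect_equal(lr$upper, w$upper, tolerance = 1e-3)
  # zero positives: truncation pins the lower limit at 0
  lr0 <- lang_reiczigel_ci(0, 50, 90, 100, 95, 100)
  expect_equal(lr0$lower, 0)
  expect_true(all(lr0$upper <= 1))
})

test_that("estimate_frequentist returns a consistent long table", {
  sc <- example_scenario()
  dat <- example_data_table()
  est <- estimate_frequentist(dat, sc, level = 0.95)
  expect_setequal(unique(est$method),
                  c("clopper_pearson", "sterne", "blaker",
                    "wald_rogan_gladen", "lang_reiczigel"))
  expect_equal(nrow(est), 2L * 5L)
  # all methods share the truncated RGE point estimate
  r1 <- est[est$replicate_id == 1L, ]
  expect_true(all(abs(r1$point - 0.5168522) < 1e-6))
  expect_true(all(r1$lower <= r1$point & r1$point <= r1$upper))
  expect_equal(est$length, est$upper - est$lower)
})
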