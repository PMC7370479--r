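## Bayesian misclassification model for true prevalence.
##
## Model: pi ~ Beta(a_pi, b_pi); Se ~ Beta(a_se, b_se); Sp ~ Beta(a_sp,
## b_sp); x ~ Binomial(n, Se * pi + (1 - Sp) * (1 - pi)).  The prevalence
## prior is the non-informative Beta(1, 1); the sensitivity and
## specificity priors encode the validation-study counts,
## Beta(x_se + 1, n_se - x_se + 1) and Beta(x_sp + 1, n_sp - x_sp + 1).
##
## The posterior is sampled by a data-augmented Gibbs sampler.  Latent
## counts split the observed test results by true disease status:
## T1 = true positives among the x test-positives, T2 = diseased among
## the n - x test-negatives.  Given (pi, Se, Sp) these are independent
## binomials, and given (T1, T2) all three parameters have conjugate Beta
## full conditionals -- no tuning, and the updates vectorise across
## thousands of data sets.

#' Prior specification for the misclassification model
#'
#' Builds the default priors: uniform Beta(1, 1) for prevalence and
#' validation-informed Beta posteriors-as-priors for sensitivity and
#' specificity.
#'
#' @param x_se,n_se sensitivity validation counts.
#' @param x_sp,n_sp specificity validation counts.
#' @param pi_shape length-2 Beta shapes for the prevalence prior.
#' @return list with components `pi`, `se`, `sp`, each a length-2 vector
#'   of Beta shapes.
#' @export
prior_spec <- function(x_se, n_se, x_sp, n_sp, pi_shape = c(1, 1)) {
  stopifnot(x_se >= 0, x_se <= n_se, x_sp >= 0, x_sp <= n_sp,
            length(pi_shape) == 2L, all(pi_shape > 0))
  list(pi = as.numeric(pi_shape),
       se = c(x_se + 1, n_se - x_se + 1),
       sp = c(x_sp + 1, n_sp - x_sp + 1))
}

#' MCMC configuration
#'
#' Defaults: 3 chains, 5,000 burn-in iterations per chain (covering both
#' warm-up and adaptation), and 6,667 retained iterations per chain --
#' about 20,000 pooled draws.  Convergence is declared when the
#' Gelman-Rubin potential scale reduction factor for prevalence is below
#' `psrf_threshold`; a non-converged fit is re-run once with twice the
#' retained length before being flagged.
#'
#' @param n_chains number of chains (>= 2 for convergence checking).
#' @param n_burnin discarded iterations per chain.
#' @param n_samples retained iterations per chain.
#' @param psrf_threshold convergence threshold for the PSRF.
#' @param seed integer seed for the sampler.
#' @return list of class `mcmc_config`.
#' @export
mcmc_config <- function(n_chains = 3L, n_burnin = 5000L, n_samples = 6667L,
                        psrf_threshold = 1.05, seed = 1L) {
  stopifnot(n_chains >= 1, n_burnin >= 0, n_samples >= 1,
            psrf_threshold > 1)
  structure(list(n_chains = as.integer(n_chains),
                 n_burnin = as.integer(n_burnin),
                 n_samples = as.integer(n_samples),
                 psrf_threshold = psrf_threshold,
                 seed = as.integer(seed)),
            class = "mcmc_config")
}

# overdispersed prevalence starting points, recycled over chains
GIBBS_PI_INITS <- c(0.1, 0.5, 0.9)

#' Data-augmented Gibbs sampler for one data set
#'
#' Samples the joint posterior of (prevalence, sensitivity, specificity).
#' Per iteration, with `p1 = pi*Se / (pi*Se + (1-pi)*(1-Sp))` and
#' `p2 = pi*(1-Se) / (pi*(1-Se) + (1-pi)*Sp)`:
#' `T1 ~ Bin(x, p1)`, `T2 ~ Bin(n - x, p2)`, then
#' `pi ~ Beta(a_pi + T1 + T2, b_pi + n - T1 - T2)`,
#' `Se ~ Beta(a_se + T1, b_se + T2)`,
#' `Sp ~ Beta(a_sp + n - x - T2, b_sp + x - T1)`.
#' Chains start from overdispersed prevalence values (0.1, 0.5, 0.9,
#' recycled) with sensitivity and specificity at their prior means.
#'
#' @param x,n positives / size of the field application.
#' @param prior list as returned by [prior_spec()].
#' @param config list as returned by [mcmc_config()].
#' @return object of class `posterior_draws`: list with matrices `pi`,
#'   `se`, `sp` (retained iterations x chains) and the `config`.
#' @export
gibbs_sample <- function(x, n, prior, config = mcmc_config()) {
  stopifnot(length(x) == 1L, length(n) == 1L, x >= 0, x <= n)
  nc <- config$n_chains
  stream <- rng_substreams(config$seed, 1L, stage = "mcmc")[[1L]]
  chain <- seq_len(nc)
  pi0 <- GIBBS_PI_INITS[(chain - 1L) %% length(GIBBS_PI_INITS) + 1L]
  se0 <- rep(prior$se[1] / sum(prior$se), nc)
  sp0 <- rep(prior$sp[1] / sum(prior$sp), nc)
  res <- with_rng_state(stream, {
    gibbs_kernel(x = rep(x, nc), n = rep(n, nc),
                 a_pi = prior$pi[1], b_pi = prior$pi[2],
                 a_se = prior$se[1], b_se = prior$se[2],
                 a_sp = prior$sp[1], b_sp = prior$sp[2],
                 pi = pi0, se = se0, sp = sp0,
                 n_burnin = config$n_burnin, n_samples = config$n_samples,
                 keep_all = TRUE)
  })
  structure(list(pi = res$pi, se = res$se, sp = res$sp, config = config),
            class = "posterior_draws")
}

# Core vectorised Gibbs kernel.  All count/prior arguments are vectors
# over "units" (one unit = one chain of one data set); returns retained
# draws as (n_samples x units) matrices (pi only unless keep_all).
gibbs_kernel <- function(x, n, a_pi, b_pi, a_se, b_se, a_sp, b_sp,
                         pi, se, sp, n_burnin, n_samples,
                         keep_all = FALSE) {
  units <- length(x)
  nx <- n - x
  keep_pi <- matrix(NA_real_, n_samples, units)
  keep_se <- if (keep_all) matrix(NA_real_, n_samples, units)
  keep_sp <- if (keep_all) matrix(NA_real_, n_samples, units)
  total <- n_burnin + n_samples
  for (it in seq_len(total)) {
    num1 <- pi * se
    p1 <- num1 / (num1 + (1 - pi) * (1 - sp))
    t1 <- rbinom(units, x, p1)
    num2 <- pi * (1 - se)
    p2 <- num2 / (num2 + (1 - pi) * sp)
    t2 <- rbinom(units, nx, p2)
    td <- t1 + t2
    pi <- rbeta(units, a_pi + td, b_pi + n - td)
    se <- rbeta(units, a_se + t1, b_se + t2)
    sp <- rbeta(units, a_sp + nx - t2, b_sp + x - t1)
    if (it > n_burnin) {
      keep_pi[it - n_burnin, ] <- pi
      if (keep_all) {
        keep_se[it - n_burnin, ] <- se
        keep_sp[it - n_burnin, ] <- sp
      }
    }
  }
  list(pi = keep_pi, se = keep_se, sp = keep_sp)
}

#' Gelman-Rubin potential scale reduction factor
#'
#' Standard between/within-chain variance ratio: with `m` chains of
#' length `N`, `W` the mean within-chain variance and `B/N` the variance
#' of chain means, `PSRF = sqrt(((N-1)/N * W + B/N) / W)`.  Values close
#' to 1 indicate that the chains have mixed.
#'
#' @param draws matrix of draws (iterations x chains), or a
#'   `posterior_draws` object (the prevalence component is used).
#' @return the PSRF, a scalar.
#' @export
psrf <- function(draws) {
  if (inherits(draws, "posterior_draws")) draws <- draws$pi
  stopifnot(is.matrix(draws))
  if (ncol(draws) < 2L) {
    stop("PSRF requires at least two chains", call. = FALSE)
  }
  n <- nrow(draws)
  w <- mean(apply(draws, 2L, var))
  b_over_n <- var(colMeans(draws))
  sqrt(((n - 1) / n * w + b_over_n) / w)
}

#' Highest density interval from posterior draws
#'
#' The shortest contiguous window of the sorted draws containing
#' `ceiling(mass * N)` of the `N` draws.  For a unimodal posterior this
#' converges to the interval whose interior density everywhere exceeds
#' the density outside.  Ties between equal-width windows are broken by
#' the lowest starting index, which makes the result deterministic.
#'
#' @param samples numeric vector of draws (>= 1; at least 100 recommended).
#' @param mass probability mass of the interval, default 0.95.
#' @return numeric vector `c(lower, upper)`.
#' @export
hdi <- function(samples, mass = 0.95) {
  if (!length(samples)) stop("empty sample in hdi()", call. = FALSE)
  stopifnot(mass > 0, mass < 1)
  s <- sort(samples)
  n <- length(s)
  m <- min(ceiling(mass * n), n)
  if (m == n) return(c(s[1L], s[n]))
  widths <- s[m:n] - s[1:(n - m + 1L)]
  i <- which.min(widths)             # which.min takes the first minimum
  c(s[i], s[i + m - 1L])
}

#' Effective sample size of pooled chains
#'
#' Autocorrelation-sum estimator: per chain, autocorrelations are summed
#' using Geyer's initial positive sequence (successive lag-pair sums are
#' accumulated while positive), then averaged over chains;
#' `ESS = (m * N) / (1 + 2 * sum(rho))`.
#'
#' @param draws matrix (iterations x chains) or `posterior_draws` object.
#' @param max_lag largest lag considered.
#' @return estimated effective sample size of the pooled draws.
#' @export
ess <- function(draws, max_lag = 200L) {
  if (inherits(draws, "posterior_draws")) draws <- draws$pi
  if (!is.matrix(draws)) draws <- matrix(draws, ncol = 1L)
  n <- nrow(draws)
  max_lag <- min(max_lag, n - 2L)
  rho <- vapply(seq_len(ncol(draws)), function(j) {
    a <- acf(draws[, j], lag.max = max_lag, plot = FALSE,
             demean = TRUE)$acf[-1L, 1L, 1L]
    # Geyer initial positive sequence on lag pairs
    s <- 0
    k <- 1L
    while (k < length(a)) {
      pair <- a[k] + a[k + 1L]
      if (pair <= 0) break
      s <- s + pair
      k <- k + 2L
    }
    s
  }, numeric(1L))
  n * ncol(draws) / (1 + 2 * mean(rho))
}

#' Summarise posterior draws of the prevalence
#'
#' Pools all chains and reports the posterior mean (the minimum
#' mean-square-error point estimate), the 95% highest density interval,
#' the Gelman-Rubin PSRF and the effective sample size.
#'
#' @param draws `posterior_draws` object from [gibbs_sample()].
#' @param config the `mcmc_config` used (defaults to the one stored in
#'   `draws`).
#' @param mass credible mass for the HDI, default 0.95.
#' @return one-row data.frame: `mean_pi`, `hdi_low`, `hdi_high`,
#'   `psrf_pi`, `ess_pi`, `converged`.
#' @export
summarize_posterior <- function(draws, config = draws$config,
                                mass = 0.95) {
  stopifnot(inherits(draws, "posterior_draws"))
  pooled <- as.vector(draws$pi)
  h <- hdi(pooled, mass)
  r <- if (ncol(draws$pi) >= 2L) psrf(draws$pi) else NA_real_
  data.frame(mean_pi = mean(pooled), hdi_low = h[1L], hdi_high = h[2L],
             psrf_pi = r, ess_pi = ess(draws$pi),
             converged = is.na(r) || r < config$psrf_threshold)
}

#' Fit the Bayesian model to one data set
#'
#' Convenience wrapper: builds the default priors from the validation
#' counts, runs the Gibbs sampler, and summarises the prevalence
#' posterior.  If the PSRF is at or above the threshold the retained
#' length is doubled once and the fit re-run; a still-failing fit is
#' returned with `converged = FALSE` rather than dropped.
#'
#' @inheritParams wald_rogan_gladen_ci
#' @param config `mcmc_config`.
#' @param mass credible mass for the HDI, default 0.95.
#' @return one-row data.frame as [summarize_posterior()], plus the draws
#'   as attribute `"draws"`.
#' @export
fit_bayes <- function(x, n, x_se, n_se, x_sp, n_sp,
                      config = mcmc_config(), mass = 0.95) {
  prior <- prior_spec(x_se, n_se, x_sp, n_sp)
  draws <- gibbs_sample(x, n, prior, config)
  s <- summarize_posterior(draws, config, mass)
  if (!s$converged) {
    config2 <- config
    config2$n_samples <- 2L * config$n_samples
    draws <- gibbs_sample(x, n, prior, config2)
    s <- summarize_posterior(draws, config2, mass)
  }
  attr(s, "draws") <- draws
  s
}

#' Fit the Bayesian model to every retained data set of a table
#'
#' Vectorised bulk fitting: all data sets of a batch are advanced through
#' the Gibbs iterations simultaneously (one vector element per chain per
#' data set), which makes the simulation-validation study feasible in
#' plain R.  Per data set the posterior mean, 95% HDI and PSRF are
#' returned; data sets whose PSRF fails the threshold are re-run once
#' with doubled retained length and flagged if still failing.  The
#' effective sample size is not computed in bulk (set `compute_ess =
#' TRUE` to add it).
#'
#' @param data data.frame from [simulate_datasets()].
#' @param scenarios scenario table supplying the design sizes.
#' @param config `mcmc_config`; `config$seed` drives the sampler.
#' @param mass credible mass of the HDI, default 0.95.
#' @param batch_size data sets advanced simultaneously (memory/speed
#'   trade-off).
#' @param compute_ess also estimate the pooled effective sample size per
#'   data set (slower).
#' @return data.frame: `scenario_id`, `replicate_id`, `method`
#'   (`"bayes_hdi"`), `point` (posterior mean), `lower`, `upper`,
#'   `length`, `psrf`, `ess`, `converged`.
#' @export
fit_bayes_bulk <- function(data, scenarios, config = mcmc_config(),
                           mass = 0.95, batch_size = 2500L,
                           compute_ess = FALSE) {
  d <- join_design(data, scenarios)
  d <- d[d$case != "excluded", , drop = FALSE]
  if (!nrow(d)) stop("no retained data sets to estimate", call. = FALSE)
  nb <- ceiling(nrow(d) / batch_size)
  batch_of <- rep(seq_len(nb), each = batch_size, length.out = nrow(d))
  streams <- rng_substreams(config$seed, nb, stage = "mcmc")
  pieces <- vector("list", nb)
  for (b in seq_len(nb)) {
    db <- d[batch_of == b, , drop = FALSE]
    pieces[[b]] <- gibbs_batch(db, config, mass, streams[[b]],
                               compute_ess)
  }
  out <- do.call(rbind, pieces)
  rownames(out) <- NULL
  out
}

# run one batch of data sets through the vectorised kernel and summarise
gibbs_batch <- function(db, config, mass, stream, compute_ess) {
  ndat <- nrow(db)
  nc <- config$n_chains
  # units are laid out data set-major within chain blocks:
  # unit index (chain - 1) * ndat + dataset
  run <- function(dsets, n_samples) {
    nd <- length(dsets)
    idx <- rep(dsets, times = nc)
    chain <- rep(seq_len(nc), each = nd)
    pi0 <- GIBBS_PI_INITS[(chain - 1L) %% length(GIBBS_PI_INITS) + 1L]
    a_se <- db$x_se[idx] + 1
    b_se <- db$n_se[idx] - db$x_se[idx] + 1
    a_sp <- db$x_sp[idx] + 1
    b_sp <- db$n_sp[idx] - db$x_sp[idx] + 1
    with_rng_state(stream, {
      gibbs_kernel(x = db$x[idx], n = db$n[idx],
                   a_pi = 1, b_pi = 1,
                   a_se = a_se, b_se = b_se, a_sp = a_sp, b_sp = b_sp,
                   pi = pi0, se = a_se / (a_se + b_se),
                   sp = a_sp / (a_sp + b_sp),
                   n_burnin = config$n_burnin, n_samples = n_samples)$pi
    })
  }
  keep <- run(seq_len(ndat), config$n_samples)
  s <- summarize_batch(keep, ndat, nc, mass, compute_ess)
  s$converged <- is.na(s$psrf) | s$psrf < config$psrf_threshold
  retry <- which(!s$converged)
  if (length(retry)) {
    keep2 <- run(retry, 2L * config$n_samples)
    s2 <- summarize_batch(keep2, length(retry), nc, mass, compute_ess)
    s2$converged <- is.na(s2$psrf) | s2$psrf < config$psrf_threshold
    s[retry, ] <- s2
  }
  data.frame(scenario_id = db$scenario_id, replicate_id = db$replicate_id,
             method = "bayes_hdi", point = s$mean, lower = s$lower,
             upper = s$upper, length = s$upper - s$lower,
             psrf = s$psrf, ess = s$ess, converged = s$converged,
             case = db$case)
}

# per-data set mean / HDI / PSRF from a (samples x (ndat*nc)) draw matrix
summarize_batch <- function(keep, ndat, nc, mass, compute_ess) {
  ns <- nrow(keep)
  cm <- colMeans(keep)
  cv <- colMeans(keep^2) - cm^2
  cv <- cv * ns / (ns - 1)
  mu <- matrix(cm, ndat, nc)
  vv <- matrix(cv, ndat, nc)
  w <- rowMeans(vv)
  b_over_n <- apply(mu, 1L, var)
  r <- if (nc >= 2L) sqrt(((ns - 1) / ns * w + b_over_n) / w)
       else rep(NA_real_, ndat)
  res <- data.frame(mean = rowMeans(mu), lower = NA_real_,
                    upper = NA_real_, psrf = r, ess = NA_real_,
                    converged = NA)
  for (dset in seq_len(ndat)) {
    cols <- dset + (seq_len(nc) - 1L) * ndat
    pooled <- as.vector(keep[, cols])
    h <- hdi(pooled, mass)
    res$lower[dset] <- h[1L]
    res$upper[dset] <- h[2L]
    if (compute_ess) res$ess[dset] <- ess(keep[, cols, drop = FALSE])
  }
  res
}
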