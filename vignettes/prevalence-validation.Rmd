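---
title: "Prevalence estimation under misclassification: models, methods and validation design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Prevalence estimation under misclassification: models, methods and validation design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

# The estimation problem

A binary diagnostic test is characterised by its sensitivity
$Se = \Pr(T^+ \mid D^+)$ and specificity $Sp = \Pr(T^- \mid D^-)$.
Applied to a population with true prevalence $\pi$, the probability of
a positive result — the *apparent prevalence* — is

$$AP = Se\,\pi + (1 - Sp)(1 - \pi).$$

Field data give $\widehat{AP} = x/n$; validation studies against a
gold standard give $\widehat{Se} = x_{Se}/n_{Se}$ and
$\widehat{Sp} = x_{Sp}/n_{Sp}$. Inverting the relation at the plug-in
estimates yields the Rogan–Gladen estimate

$$RGE = \frac{\widehat{AP} - (1 - \widehat{Sp})}
             {\widehat{Se} - (1 - \widehat{Sp})},$$

which is reported truncated to $[0, 1]$. A usable estimate requires
three conditions: (a) $1 - \widehat{Sp} < \widehat{Se}$ — the test
discriminates better than chance; (b)
$1 - \widehat{Sp} \le \widehat{AP}$, else $RGE < 0$; (c)
$\widehat{AP} \le \widehat{Se}$, else $RGE > 1$. Data sets violating
(a) are *excluded* from estimation — in practice such a test would
not be applied, and the adjustment is meaningless; violations of (b)
or (c) label the data set *case 2* / *case 3* (truncation needed),
with the benign remainder being *case 1*.

**Boundary handling.** Conditions (b) and (c) are non-strict:
$RGE$ exactly 0 or 1 is a valid proportion and classified case 1.
Condition (a) is strict: equality is excluded, which also protects
the downstream division. `classify_case()` and `rogan_gladen()` use
the *same* floating-point expressions for numerator and denominator,
so a label can never disagree with the sign or magnitude of the raw
estimate it describes.

# Confidence intervals on the prevalence scale

Five 95% two-sided constructions are implemented
(`estimate_frequentist()`), all reporting the truncated $RGE$ as the
point estimate:

* **Clopper–Pearson**, **Sterne**, **Blaker** — exact intervals for
  the binomial proportion $AP$, mapped through the (increasing)
  Rogan–Gladen transformation with $\widehat{Se}, \widehat{Sp}$
  treated as known, then truncated to $[0,1]$. Clopper–Pearson uses
  the Beta-quantile closed form. Sterne (minimum-likelihood acceptance
  regions) and Blaker (combined-tails acceptability) are inverted by
  bisection to an absolute tolerance of $10^{-8}$ on the proportion;
  the upper limit uses the binomial symmetry
  $p\text{-val}(x, n, p) = p\text{-val}(n-x, n, 1-p)$. Sterne's
  acceptance set can in principle be non-contiguous in $p$; the
  enclosing interval is returned. Sterne's $p$-value sum is trimmed to
  the central $1 - 2\times10^{-10}$ of the support for speed, adding
  error far below the inversion tolerance.
* **Wald–Rogan–Gladen** — normal approximation around the truncated
  $RGE$ with the plug-in variance
  $\widehat{AP}(1-\widehat{AP})/\big(n\,(\widehat{Se}+\widehat{Sp}-1)^2\big)$:
  the Wald variance of the apparent prevalence pushed through the
  linear adjustment, with $\widehat{Se}, \widehat{Sp}$ treated as
  known like the exact methods do. A delta-method variance that *adds*
  the two validation-study terms was considered and rejected as the
  definition of this method: with those terms the interval is simply
  the Lang–Reiczigel construction without its pseudo-counts — it
  covers at ≈95% and matches LR's length on this design, which
  contradicts the empirically established profile of the traditional
  Wald interval this method represents (clear under-coverage,
  distinctly shorter than LR). The plug-in form reproduces that
  profile; the validation-propagating Wald niche is filled by
  Lang–Reiczigel.
* **Lang–Reiczigel** — an adjusted Wald interval: the apparent
  prevalence receives $z^2/2$ pseudo-successes and failures
  (Agresti–Coull), sensitivity and specificity receive one of each (a
  $\mathrm{Beta}(1,1)$ posterior-mean update), and the delta-method
  standard error is evaluated at the adjusted values with adjusted
  denominators. The pseudo-count constants live in one internal
  function (`lr_adjusted_components()`) so they can be changed
  without touching callers; the package's own full-design coverage
  simulation (95.5% mean per-scenario coverage) supports the choice.
  With extreme shrinkage the *adjusted* $\widehat{Se}+\widehat{Sp}$
  can dip below 1 for a retained borderline data set; such rows
  return `NA` with a warning rather than a sign-flipped interval.

# The Bayesian misclassification model

$$\pi \sim \mathrm{Beta}(1, 1), \quad
  Se \sim \mathrm{Beta}(x_{Se}+1,\, n_{Se}-x_{Se}+1), \quad
  Sp \sim \mathrm{Beta}(x_{Sp}+1,\, n_{Sp}-x_{Sp}+1),$$
$$x \sim \mathrm{Binomial}\!\left(n,\ Se\,\pi + (1-Sp)(1-\pi)\right).$$

The prevalence prior is uniform; the accuracy priors are the
posteriors implied by the validation counts under uniform priors. All
three parameters are proportions with full posterior mass in $[0,1]$,
so the point estimate (posterior mean, the minimum-MSE choice) and the
95% highest density interval can never leave the unit interval — the
truncation problem disappears by construction.

**Sampler.** A data-augmented Gibbs sampler (`gibbs_sample()`,
vectorised across data sets in `fit_bayes_bulk()`). Latent counts
split the observations by true disease status: $T_1$, the diseased
among the $x$ test-positives, and $T_2$, the diseased among the
$n - x$ test-negatives. Given the parameters these are independent
binomials with success probabilities
$\pi Se / (\pi Se + (1-\pi)(1-Sp))$ and
$\pi(1-Se) / (\pi(1-Se) + (1-\pi)Sp)$; given $(T_1, T_2)$ all three
parameters have conjugate Beta full conditionals. This gives exact
conditional updates with no tuning, and every update is a vectorised
`rbinom`/`rbeta` call across thousands of data sets simultaneously —
the property that makes a million-data set validation feasible in
plain R. A generic MCMC engine was deliberately not used: the
conjugate structure is exact, and the sampler is ~50 lines that the
test suite can verify against brute-force grid integration.

**Defaults.** 3 chains; 5,000 burn-in per chain (covering warm-up and
what an adaptive sampler would spend on adaptation); 6,667 retained
per chain, i.e. ~20,000 pooled draws, read as a pooled target (the
run-length convention is stated ambiguously in the literature this
design follows; the pooled reading is the cheaper and, with an exact
conjugate sampler, entirely sufficient one). Chains start from
overdispersed prevalence values $\{0.1, 0.5, 0.9\}$ with $Se, Sp$ at
their prior means, so the Gelman–Rubin diagnostic is meaningful.
Convergence is declared at PSRF $< 1.05$ on $\pi$; a failing fit is
re-run once with doubled retained length and otherwise flagged
`converged = FALSE` (never silently dropped). In the validation runs
below, no data set failed the doubled re-check.

**HDI.** Shortest contiguous window of the sorted pooled draws
containing $\lceil 0.95 N \rceil$ draws; ties broken at the lowest
start index (deterministic). The window estimator is slightly biased
short at finite $N$ — see *Limitations*.

**Effective sample size** uses the per-chain autocorrelation sum with
Geyer's initial-positive-sequence truncation, averaged over chains.
It is reported, never used for gating. With fixed-length conjugate
Gibbs the pooled ESS on typical data sets is roughly 1,500–4,000 out
of 20,000 — smaller than what an adaptively lengthened sampler would
report, with correspondingly larger (but still negligible for the
posterior mean) MC error.

# The simulation-validation design

The generator (`draw_scenarios()`, `simulate_datasets()`) emulates a
study design in which every scenario couples statistical parameters
$Se, Sp \sim U(0.6, 1)$ and $\pi \sim U(0, 1)$ with design parameters
$n_{Se}, n_{Sp}$ drawn equiprobably from
$\{50, 100, 200, 500, 1000, 2000, 5000\}$ and $n$ uniform on the
integers $50..2000$ — all independent. The full design is 1,000
scenarios × 1,000 replicate data sets; counts are drawn per the three
binomials above. "$U(50, 2000)$, discrete" is read as uniform over
the integers 50..2000 inclusive (rounding a continuous draw would
half-weight the endpoints), and the seven validation sizes are taken
as equiprobable since no weighting is stated anywhere.

Reproducibility uses L'Ecuyer–CMRG streams: scenario $k$ always owns
stream $k$ of the root seed, with disjoint substreams for the
scenario draw, the replicate data draw and MCMC — so any scenario and
its replicate block can be regenerated in isolation regardless of the
run size, and reruns are byte-identical (stage CSVs serialise doubles
with 17 significant digits for exact round trips).

Under this design roughly 4.4% of retained data sets yield a raw
$RGE$ outside $[0,1]$ (the truncation cases of interest) and
condition-(a) exclusions occur at a rate of order $10^{-5}$ (single
digits per million; an independent re-simulation of the design in
another language gives the same order).

**What the generator does not emulate:** clustered or stratified
sampling, overdispersion, finite-population effects, correlated
accuracy parameters, pooled testing, or validation panels
unrepresentative of the application population. Passing validation
here shows the estimators behave as intended *under the stated
binomial design*; it cannot certify them for data violating these
assumptions — in particular the representativeness of the validation
panels is an untestable prerequisite shared by every method in the
package.

# Validation metrics

* **Estimation error** `point − pi_true` per data set and method,
  with the case label carried for subgroup analysis. Consistency
  shows as error distributions centred at zero; in the truncation
  subsets (cases 2/3) the truncated $RGE$'s error distribution is
  asymmetric by construction while the Bayesian error remains roughly
  symmetric.
* **Per-scenario coverage**: the fraction of a scenario's retained
  replicates whose interval contains $\pi$ (non-strict endpoint
  comparison; the zero-probability tie at a truncated zero-width
  interval counts as covering). Excluded replicates never enter the
  denominator.
* **Interval length** by method and case.
* **Deming regression** (`deming_fit()`): closed-form
  errors-in-variables slope at a given error-variance ratio (1 =
  orthogonal regression), intercept through the means, Pearson $r$ on
  the same pairs. The slope CI is a leave-one-out jackknife (computed
  in O(n) by downdating the sufficient statistics): deterministic and
  standard for Deming fits, though not necessarily the method behind
  any published CI width, so point estimates — not CI widths — are
  the comparable quantity.
* **Residual-error regression**: per estimator, OLS of the error on
  the six z-transformed design variables and all 15 pairwise
  interactions (22 coefficients), with whole-model $R^2$; under this
  design the effects are minor ($R^2$ small), i.e. the adjustment
  leaves no strong residual dependence on the study conditions.

# Problem sizes used in tests and the acceptance script

Frequentist-only quantities (truncation rate, exclusion count,
Lang–Reiczigel coverage) are computed on the full 1,000 × 1,000
design — everything vectorises. The MCMC comparisons use reduced
designs run through the identical code path: 200 scenarios × 100
replicates for the error/length comparisons and 100 × 200 for HDI
coverage, with 3 chains × (1,000 burn-in + 4,000 retained) per data
set. These sizes keep each summary's Monte-Carlo error small relative
to its tolerance while completing in minutes on one CPU.

Two caveats at reduced scale, measured across independent root seeds:
the Deming slopes comparing Bayesian and Rogan–Gladen quantities have
an effective sample size limited by the number of *scenarios*, giving
an across-seed spread of ±0.02–0.03; and the shortest-window HDI
length carries MC noise from 12,000 autocorrelated draws, which
attenuates the length–length correlation by about 0.02 relative to a
full-scale run. The error-based comparisons (slope ≈ 0.94,
$r$ ≈ 0.92) reproduce their full-scale reference values within ±0.02;
the length-based slope and correlation land near 0.91/0.95 and should
be read with the above attenuation in mind.

# Known limitations

* The exact-interval transformations treat $\widehat{Se},
  \widehat{Sp}$ as known; their under-coverage on the prevalence
  scale is a finding, not a defect.
* The shortest-window HDI estimator is biased slightly short at
  finite sample size; with ~12,000 pooled draws the bias is of order
  $10^{-3}$–$10^{-2}$ on the length, visible only in aggregate
  length comparisons (above).
* Sterne intervals report the enclosing interval of a possibly
  non-contiguous acceptance set.
* The Gibbs sampler assumes conditionally independent binomial
  sampling; it does not fit latent-class models without a gold
  standard, multi-test designs, or informative expert priors beyond
  Beta shapes (though `prior_spec()` accepts arbitrary positive
  shapes).
* `fit_bayes_bulk()` draws all chains of a batch from one RNG
  substream; results are deterministic given data and configuration,
  but a bulk row follows a different random path than a standalone
  `fit_bayes()` of the same data set (they agree within MC error).
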