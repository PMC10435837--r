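---
title: "Methods: small-area mortality estimation and disparity summarisation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: small-area mortality estimation and disparity summarisation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`countymort` estimates cause-specific mortality rates by county,
racial–ethnic group, sex, age group and year from stratified death and
population counts, and summarises disparities between groups. This
vignette documents the statistical model, the preprocessing and
calibration stages around it, the synthetic-data generator used for
validation, and the numerical and design choices a user should know
about.

## The estimation problem

County × racial–ethnic group × year cells are small: even a common
cancer produces zero or single-digit death counts in most cells, so the
direct rate D/P is dominated by Poisson noise and is undefined or
useless exactly where disparities are of most interest. Small-area
estimation addresses this by borrowing strength across neighbouring
counties, adjacent age groups and years, and between groups, estimating
the underlying mortality rate while smoothing out stochastic noise.

Three features of death-registration data complicate the task and are
handled by dedicated stages:

* a substantial fraction of deaths (around a quarter) carry an
  underlying-cause code that is intermediate, implausible or
  insufficiently specific ("garbage codes") and must be redistributed
  to plausible true causes before modelling;
* the racial–ethnic group recorded on death certificates disagrees
  with self-identification at rates that differ by group, biasing
  group-specific rates; published misclassification ratios (deaths by
  self-report over deaths by certificate) quantify this;
* group-specific and cause-specific estimates must remain mutually
  consistent: causes should sum to all-cause mortality and groups
  should reproduce the total-population surface that misclassification
  adjustment would otherwise distort.

## Model

For deaths $D_{jrat}$ and person-years $P_{jrat}$ in county $j$, race
$r$, age group $a$, year $t$ (one model per sex and cause):

$$D \sim \text{Poisson}(P\,m), \qquad
\log m = \beta_{0r} + X_j\gamma + u_j + v_a + w_t + z_{jr}$$

* $\beta_{0r}$: race-specific intercepts (fixed effects);
* $\gamma$: coefficients of county-level covariates, which are centred
  and scaled to unit variance before fitting (zero-variance covariates
  are dropped with a warning);
* $u \sim \text{ICAR}(\tau_u)$: intrinsic conditional autoregressive
  spatial effect with structure matrix $Q = D_{\deg} - W$ over the
  county adjacency graph; sum-to-zero per connected component;
* $v \sim \text{RW1}(\tau_v)$, $w \sim \text{RW1}(\tau_w)$: first-order
  random walks over the ordered age groups and calendar years,
  sum-to-zero;
* $z_{jr} \sim \text{N}(0, 1/\tau_z)$: exchangeable county × race
  effect, sum-to-zero within race, dropped for single-race (total
  population) fits;
* $\log\tau_k \sim \text{N}(0, 3^2)$ hyperpriors, weakly informative
  enough to keep the mode finite on sparse toys.

Strata with $P = 0$ contribute no likelihood but are still predicted
from the linear predictor, so rates remain defined for aggregation.
Death counts may be real-valued (they are, after garbage-code
redistribution); the Poisson objective
$\sum P m - D \log(Pm)$ is well defined for real $D \ge 0$.

The total population ("Total") surface per cause, and the all-cause
surface for both the races and the total, are fit as their own models;
they provide the margins that the raking stage calibrates against.

### Fitting: MAP effects, empirical-Bayes precisions

All random effects are parameterised in an orthonormal basis of their
sum-to-zero subspace (per graph component for $u$, per race for $z$),
which removes the null directions of the ICAR/RW1 structure matrices
and makes the curvature positive definite at the mode.

A single joint mode over effects *and* log-precisions is degenerate in
this model class: the prior normaliser contributes
$-\tfrac{\text{rank}}{2}\log\tau$, which grows linearly in $\log\tau$,
while the hyperprior only resists quadratically — so wherever the data
only weakly inform a random-effect block, the joint mode runs off to
enormous precisions and collapses the block entirely. `fit_map()`
therefore profiles the effects out: for each candidate $\theta = \log\tau$
the effects are optimised by Newton iteration with the analytic Hessian
$H_x = M^\top \text{diag}(\mu) M + \text{blockdiag}(\tau_k \tilde Q_k)$,
and $\theta$ maximises the Laplace-approximate marginal posterior
$-\log p(\theta \mid D) \approx f(x^*(\theta), \theta) +
\tfrac12 \log\det H_x$. The log-determinant term restores the curvature
penalty that the joint mode ignores. Convergence is declared when the
effect-gradient max-norm falls below `tol` (default `1e-6`) and the
outer optimiser reports success.

Uncertainty is propagated by simulation: `draw_posterior()` draws
parameters from $\text{N}(x^*, H_x^{-1})$ with the precisions plugged
in (standard empirical-Bayes practice; hyperparameter uncertainty is
not propagated), maps each draw through the linear predictor, and
exponentiates. The default 1000 draws are the currency of every
downstream stage: means give point estimates, the 2.5th/97.5th
percentiles give 95% uncertainty intervals.

## Preprocessing and calibration stages

**Garbage-code redistribution** (`redistribute_garbage()`): within each
pool — by default the cells sharing county, sex, coarse age bracket
(the ordered age groups split into 3 consecutive brackets) and year —
garbage deaths are reallocated to the non-garbage causes in proportion
to the pool's observed cause composition. Pools with no non-garbage
signal fall back to the parent pool (drop county, then race); if no
ancestor has signal the allocation is uniform with a warning. Totals
are conserved exactly at every level containing a pool, output counts
may be non-integer, and the operation is idempotent. This is a
deliberately simple, locally informed stand-in for regression-based
redistribution machinery: it preserves the two properties the pipeline
relies on (conservation and locally plausible cause composition).
Because race is not in the default pool scope, redistribution slightly
attenuates race contrasts in cause composition; users who consider
race-specific coding differentials important should add `race` to
`redistribute_scope`.

**Misclassification adjustment** (`adjust_draws()`): rate draws are
multiplied by the group's ratio, uniformly over ages and years
(optionally by sex) — matching the resolution at which all-cause
ratios are published. Adjustment happens after modelling, on draws,
and before raking, so the subsequent calibration guarantees that it
does not change any county's total mortality surface. Variation of
misclassification by cause is a documented limitation, not modelled.

**Two-stage raking** (`rake_two_stage()`): stage 1 scales the
race-specific all-cause draws by a single factor per draw × county ×
sex × age × year so their population-weighted sum equals the
total-population all-cause rate, and scales the cause-specific
total-population draws so causes sum to all-cause. Stage 2 runs
classical iterative proportional fitting on the races × causes array of
expected deaths (rate × population) per cell and draw, with the stage-1
results as margins, alternating row and column scaling until the
maximum relative margin error is below `tol` (default `1e-10`, at most
200 sweeps; non-convergence and inconsistent margins are errors).
Raking acts on expected counts, not rates, because IPF needs an
additive array; draws are matched by index across cubes, which
preserves between-draw correlation and keeps interval widths coherent;
cells with zero population contribute nothing to margins and structural
zeros are preserved.

## Summaries

* Age-standardised rates: $\text{ASR} = \sum_a w_a m_a$ per draw, with
  standard weights summing to 1 (the full-scale analysis uses the 2010
  US Census age structure; synthetic scenarios declare their own).
* Aggregation: population-weighted mean of age-specific rates,
  performed before age-standardisation; the two orders agree by
  construction and a test asserts it.
* Intervals: percentiles use linear interpolation between order
  statistics (`quantile` type 7), fixed for reproducibility.
* Percent change between years is computed draw-wise,
  $100(m_{t_1}-m_{t_0})/m_{t_0}$, and declines are presented as
  positive percent declines.
* Disparities: draw-wise differences (absolute) and ratios (relative)
  against a reference group. A comparison is statistically significant
  when $P(\text{diff}>0) \ge 0.975$ or $P(\text{diff}<0) \ge 0.975$,
  with strict inequalities so that draws tied at exactly zero support
  neither side (identical surfaces are never significant). This is the
  two-sided posterior-probability rule at $\alpha = 0.05$.
* Masking: county × group cells whose mean annual population (over
  years, summing sexes and ages) is strictly below 1000 persons are
  blanked in every year. 999.4 is masked; exactly 1000 is not. For
  comparisons, a county is censused only if *both* groups are
  unmasked.
* Disparity census: among unmasked counties, the count and percentage
  (one decimal) with point ratio above 1, and with ratio above 1 and
  significance.
* Reporting: rates are held per person-year internally and multiplied
  by 100,000 only at the reporting edge.

## The synthetic-data generator

`simulate_scenario()` produces scenarios with fully known truth:

* geography: a rook-adjacency grid (default 6 × 6 = 36 counties) or a
  connected random planar graph;
* population: log-uniform county sizes (default 1,000–100,000
  persons), county-specific Dirichlet race shares (White-majority by
  default), a declining age pyramid, smooth county-specific annual
  growth in −1% to +2%; integer apportionment keeps strata sums exactly
  equal to county totals;
* truth: log-rates drawn from the model family above (ICAR county
  effects at $\tau_u = 25$, RW1 age effects at $\tau_v = 2$, RW1 year
  effects at $\tau_w = 100$, one standard-normal county covariate with
  effect 0.15 on stomach cancer); intercepts put stomach cancer near
  4–7 deaths per 100,000 and the residual "other" cause near the
  all-cause scale of 850–950 per 100,000, so that all-cause margins
  behave like real ones. The truth surface carries no county × race
  interaction by default; an optional `misspec_shock_sd` adds one
  outside the estimator's assumptions for robustness probes;
* observation: Poisson deaths; race misreporting by binomial
  donor/multinomial receiver flows calibrated to misclassification
  ratios (defaults 1.05 for the minority group, 0.98 for the majority),
  conserving cell totals exactly; garbage coding of each death with
  probability 0.27, the middle of the 25.5–29.4% range observed across
  racial–ethnic groups in US data.

What the generator does *not* emulate: realistic US geography and
demography, migration, cause-specific misclassification, within-group
heterogeneity, and regression-structured garbage coding. Passing tests
therefore demonstrate that the pipeline's logic is correct under its
own assumptions (plus the stated observation degradations), not that
the model is adequate for any particular real dataset.

Determinism: every stage is a pure function of its inputs and a seed;
one root seed deterministically spawns per-stage seeds, so whole
pipeline runs are bit-reproducible (`run_pipeline()` writes a manifest
recording them).

## Problem sizes and tolerances used in validation

The default validation scenario is 36 counties × 2 races × 1 sex ×
5 age groups × 10 years × 2 modelled causes (3,600 strata per
race-stratified fit, 125 free parameters) with 1000 posterior draws —
chosen so a full pipeline run completes in about a minute on a single
CPU while leaving 720 county × race × year age-standardised strata for
coverage checks. Unit tests use a 9-county variant. Oracle comparisons
pin the Poisson objective to a brute-force direct summation at
`1e-10` and IPF to a brute-force alternating scaler at `1e-8`; raking
margins are verified below `1e-8` relative across all draws.

On well-specified data (fully cause-coded, correctly race-classified
deaths from the default scenario) the 95% uncertainty intervals for
age-standardised rates cover the generative truth for approximately
95% of strata, as the acceptance suite asserts; the plug-in
empirical-Bayes treatment of the precisions and the estimator's extra
county × race term (absent from the default truth) leave the intervals
slightly conservative at this data density.

## Known limitations

* Hyperparameter uncertainty is not propagated into the draws
  (empirical Bayes); intervals can be anti-conservative where a
  precision is poorly identified, and conservative where the model
  allows structure the data lack.
* Separate fits per sex and cause ignore cross-cause and cross-sex
  correlation; raking restores additive consistency but not joint
  uncertainty.
* Proportional garbage-code redistribution is cause-agnostic within a
  pool; a per-garbage-code restriction of admissible target causes is
  not implemented.
* Misclassification ratios are treated as known constants; errors in
  them propagate directly into group-specific rates and disparities.
* The significance rule is a per-comparison posterior-probability
  statement; no multiplicity control is applied across counties.
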