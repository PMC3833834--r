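---
title: "Counterfactual mortality under dynamic ART-initiation rules: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Counterfactual mortality under dynamic ART-initiation rules: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

# The problem

When should a young child living with HIV start antiretroviral therapy
(ART)? Observational cohort data could answer this, but a naive regression
of mortality on time-varying treatment is confounded by indication: the CD4
count, CD4 percentage and weight-for-age z-score (WAZ) all predict both the
decision to start ART and the risk of dying, and are themselves affected by
past treatment. Conditioning on these time-dependent confounders in an
outcome regression blocks part of the treatment effect; ignoring them
biases the treatment effect towards harm, because the sickest children are
treated first.

`artgcomp` implements the parametric g-formula (g-computation) for this
setting: fit models for how confounders and mortality evolve given history,
then *simulate* every child forward under a hypothetical treatment rule —
"start ART immediately", "start when CD4 falls below 750 cells/mm3 or CD4%
below 25%", "below 500 or 20%", "below 250 or 15%", or "never" — and read
counterfactual cumulative mortality off the simulated population.
Because the package targets a setting where no public individual-level data
exist, it ships a synthetic cohort generator with a known structural causal
model, so every estimate can be compared against exact ground truth.

# The discrete-time panel

Follow-up is discretised to the clinic visit grid t = 0, 1, 3, 6, ..., 36
months after the first visit. Each nominal time owns the window between the
midpoints with its neighbours (half-open on the left; the enrolment window
is exactly {0}; the last window extends 1.5 months past the horizon). When
several observations compete for a window, the one closest to the nominal
time is used; on ties the earlier observation wins, which is deterministic
and favours less post-hoc information. Deaths and ART starts between grid
times are assigned to the *next* nominal time, so the panel columns read:
`art[t]` = on ART by t, `death[t]` = died in the interval ending at t.

Eligibility mirrors the target cohort: age 24–60 months at enrolment
(inclusive), ART-naive at entry, at least one follow-up visit. A child with
no clinic contact for more than 9 months before database closure is lost to
follow-up (LTFU) and censored at the first grid time after the last
contact; recorded deaths are never censored.

Missing follow-up values of CD4, CD4% and WAZ are first filled by carrying
the last observation forward for at most 9 months (flagged `carried_*`).
Cells still missing — and missing baseline values — go to multiple
imputation.

# Model indexing: why death at t is modelled on the state at t−1

The death model is described in the source algorithm as regressing death on
"the confounders at time t" together with disease-progression history. A
child who dies during the interval (t−1, t] never attends the visit at t,
so a literal time-t covariate does not exist for any case. The package
therefore models death in the interval ending at t on the confounders at
the interval's *start* (the previous grid time), the baseline markers, the
demographics, and the on-ART indicator at the interval start (absorbing,
intention-to-treat). The confounder models regress each marker at t on the
same interval-start information. This indexing matches the order in which
the forward simulation generates data, and every covariate in it is
observable for dying and surviving children alike.

# The fitted models

Each confounder model is an additive linear model; the death model is an
additive logistic model. Continuous covariates (lagged sqrt-CD4, CD4%, WAZ;
baseline sqrt-CD4, CD4%, WAZ, HAZ; age) enter through penalized B-splines:
cubic bases on 8 equally spaced knots with a second-order difference
penalty, a sum-to-zero constraint absorbed into the basis, and linear
extrapolation outside the fitted range. CD4 is handled on the square-root
scale wherever it appears (response or covariate). Sex and region enter
parametrically.

Smoothing weights are chosen per term by a golden-section search on
log10(lambda), one coordinate sweep by default (the centred smooths are
near-orthogonal, so further sweeps rarely move the optimum), against
`GCV = n RSS / (n − edf)^2` for the linear models. For the logistic model
the search alternates penalized IRLS with a known-scale (UBRE/AIC-type)
score on the frozen working model, `RSS_w + 2 * 1.4 * edf`: the n-scaled
GCV denominator applies essentially no charge per degree of freedom when
events are rare and n is large, whereas the AIC-type charge with the
standard gamma = 1.4 inflation keeps the rare-event fit from chasing noise.
Interactions — each lagged-marker smooth varying by baseline-CD4 tertile or
by region — can be explored (`explore_interactions = TRUE`) and are kept
only when they strictly lower the score; the default leaves them off
because the synthetic study conditions contain no interactions and the
exploration roughly doubles the fitting cost.

The death model uses Firth's bias-reduced scoring by default. Deaths are
rare (a few percent of children over three years), and the ordinary MLE of
a rare-event logistic model with tens of coefficients is biased away from
zero; that bias propagates directly into the counterfactual curves of the
always-treat arm. The modified-score iteration (with a logistf-style step
cap) removes the leading-order bias and tames separation as a side effect.

**Per-time fits and the pooled fallback.** The algorithm calls for separate
fits at each of the 12 follow-up times. That is the default for the three
confounder models whenever a time point has at least 25 complete rows. For
the death model the package requires 25 *deaths* per time point before
fitting per-time; below the floor a single model pooled across intervals
with a smooth time effect is used. The rationale is events-per-coefficient:
with ~60 columns and a handful of deaths per time point, a per-time
logistic model is always separated, and the original cohort scale (tens of
deaths in total) makes the pooled fit the only defensible choice there.

# Multiple imputation

Remaining missing values are imputed in the expectation-maximisation (EM)
bootstrap style. The panel is reshaped to one row per child with
time-indexed columns (`cd4s_0, ..., cd4s_36`, similarly CD4% and WAZ, on
top of age, sex, region indicators, baseline HAZ, the mortality indicator,
follow-up time and the carried-forward fraction), so cross-time
correlations are modelled directly; in this layout every variable's lag and
lead are its neighbouring columns, and arbitrary nonlinear time trends are
automatic because each time point has its own mean. Duplicating lag/lead
columns explicitly would make the covariance singular, so none are added.

For each of m imputations (default 10): resample children with replacement,
run EM for the multivariate-normal parameters to a relative parameter
tolerance of 1e-4 (at most 500 iterations), and draw the original data's
missing cells from the estimated conditional normal given each child's
observed cells. The bootstrap re-estimation is what propagates parameter
uncertainty. Back-transformation squares the sqrt-CD4 draws after
truncation at 0 and clamps CD4% to [0, 100]. Observed cells are never
altered. Diagnostics record per-replicate iteration counts, final
log-likelihood changes and an overimputation RMSE (10% of observed cells
masked and re-imputed).

Two stabilisers guard the M-step. The spec-level ridge (1e-4 trace/p added
to the covariance diagonal) handles near-singularity; on top of it a
diagonal inverse-Wishart-style shrinkage prior with p + 2
pseudo-observations keeps the MAP covariance positive definite when the
number of children is not large relative to the ~50 wide columns — the
observed-data likelihood of the MVN with missing data is otherwise
unbounded, which we observed as covariance condition numbers of 1e13 and
non-convergence at a few hundred children. Both stabilisers can be set to
zero, recovering the textbook EM (used in the monotonicity tests).
Binary and categorical columns (sex, region, mortality) are fully observed
under the study conditions and are never imputed.

Scalar results are combined across imputations by Rubin's rules: pooled
estimate = mean, total variance = mean within-variance +
(1 + 1/m) x between-variance.

# The engine

For each imputed panel the model set is fitted, and every child is
simulated forward from their observed (post-imputation) enrolment state: at
each grid time the rule decides treatment from the *simulated* current
marker values (absorbing; strict inequalities, "falls below"); death over
the interval is a Bernoulli draw from the fitted logistic model; surviving
children's markers are drawn from normal distributions with the fitted
means and residual SDs, truncated/clamped to their natural ranges. There is
no censoring in the simulated world. Cumulative mortality at t is the
fraction of trajectories dead by t. The point-estimate simulations can run
`mc_factor` trajectories per child to shrink Monte-Carlo noise; bootstrap
replicates always simulate one trajectory per resampled child, folding that
noise into the distribution the percentile bounds summarise.

Random draws are made for every trajectory at every step, dead or alive, so
two regimes simulated with the same seed share their random numbers —
regime contrasts are computed on common random numbers, and the same
simulation stream is reused across imputations, which makes duplicated
imputations exactly reproduce the single-imputation estimate. All fits of a
model set share one set of spline knots (built from the full fitting
table), so the simulator evaluates each variable's basis once per step.

Point curves are the Rubin mean of the per-imputation full-data estimates.
Confidence bounds are percentile bootstrap: B child-level resamples per
imputation (whole trajectories, never rows), models refitted on each
resample, all B x m bootstrap curves pooled, bounds at the 2.5th/97.5th
percentiles. Bootstrap refits keep knots, constraints and smoothing weights
frozen at the full-data fit and re-estimate coefficients only
(`refit_lambda = TRUE` restores per-replicate re-tuning); re-tuning lambda
in every replicate multiplies the engine cost several-fold without visibly
moving percentile bounds at the problem sizes used. A failed replicate is
redrawn (at most 5 retries). Everything is deterministic given the seed,
with sub-streams derived for (bootstrap, replicate) so results do not
depend on evaluation order.

# The synthetic study conditions

The generator encodes a structural causal model whose observable corner
matches the published profile of a Southern-African paediatric cohort, and
whose counterfactual corner is computable exactly by brute force
(`true_regime_mortality`: force the rule, drop the observation process,
average 50,000 trajectories).

* **Baselines.** Latent Gaussian (sqrt-CD4, CD4%, WAZ, HAZ) with medians
  592 cells/mm3, 16%, −1.4, −2.6 and SDs implied by the published
  quartiles (8.19 on the sqrt-CD4 scale, 9.4, 1.33, 1.41), correlation 0.6
  between the immune markers, 0.25/0.5 with the growth markers; truncated
  to natural ranges. Age is a Beta(1.4, 1.9) on [2, 5] years (median 3.3);
  51.2% male; regions 76/9/10/5% (SA-urban, SA-rural, Malawi, Zimbabwe).
* **Transitions.** First-order autoregressions on (sqrt-CD4, CD4%, WAZ)
  with lag 0.85 and residual SDs chosen stationarity-consistent with the
  baseline SDs, so marker dispersion neither shrinks nor grows over
  follow-up. One AR step per grid interval regardless of interval width.
* **Treatment assignment** (observational world only): per-interval
  logistic start probability with intercept 1.1 and slopes −0.12 (sqrt-CD4),
  −0.06 (CD4%), −0.45 (WAZ) — currently sick children start almost surely,
  currently healthy ones rarely; ~76% ever start within 3 years.
* **Death.** Per-interval logistic hazard with intercept −1.8 and slopes
  −0.30, −0.09, −0.90 on the interval-start state, times `art_effect` on
  the odds while on ART. The default `art_effect = 0.4` is strongly
  protective; factual 3-year mortality is ~2.5%. Under these conditions a
  baseline-adjusted pooled-logistic regression of death on time-varying ART
  yields a hazard ratio near 1.8 — treatment looks harmful — while the true
  effect is protective: the generator genuinely embodies confounding by
  indication.
* **ART acts on mortality directly.** The transition ART terms default to
  zero (settable), so `art_effect = 1` is a genuinely null world in which
  all five rules share one counterfactual curve; with an ART-on-CD4 pathway
  a "null" direct effect would still separate the rules.
* **Observation process**, applied only after outcomes are drawn: visit
  jitter (±1 month, ±0.4 at month 1), missing-at-random recording gaps
  (per-visit rates scaled from `missing_rate`, with a logit shift in the
  last *previously observed* WAZ only — never the value being missed),
  per-interval LTFU hazard 0.02, 3% prior-ART records, 5% no-follow-up
  records. Each child owns a reproducible sub-stream of the master seed, so
  cohorts are identical under subsetting and ground truth is untouched by
  observation parameters.

What the generator does *not* emulate: calendar time and guideline eras,
site-level heterogeneity beyond the region factor, informative (outcome-
dependent) dropout, WHO staging events, virological failure or regimen
switches, and measurement error in the markers themselves. Passing tests
therefore show that the estimator recovers the truth when its structural
assumptions hold and the observation process is MAR — not that those
assumptions hold in any particular real cohort.

# Pre-ART time-to-threshold estimators

For children presenting at or above both criteria (CD4 >= 750 cells/mm3 and
CD4% >= 25%), the probability of falling below either criterion is
estimated two ways. The Kaplan-Meier version censors ART initiation, death
and LTFU and reports 1 − S(t) with Greenwood bounds. The competing-risk
version treats those events as competing: the Aalen-Johansen cumulative
incidence of crossing divided by one minus the cumulative incidence of a
competing event by t (capped at 1; undefined where the denominator
vanishes), with child-level bootstrap percentile bounds. The denominator is
time-varying, following the conditional reading of "before the threshold
was reached". Crossing times are assigned to the grid time at which the
below-threshold value is recorded. Both estimators run on pre-ART rows
only.

The package also exposes the diagnostic that motivates the causal
machinery: `naive_art_association` fits a pooled discrete-time logistic
hazard of death on time-varying ART, baseline severity, demographics and a
natural-spline time trend, and returns the exponentiated ART coefficient
as a hazard-ratio approximation (valid at the low per-interval event rates
in scope). Contrast it with the g-computation ordering to see confounding
by indication at work.

# Numerical choices and degenerate inputs

* Golden-section tolerance 0.05 on log10(lambda) over [−3, 8]; ties in
  model selection go to the earliest candidate.
* Constant covariates are dropped from the smooth set with a warning;
  a panel with no deaths yields a flat empirical hazard model; logistic
  non-convergence falls back to a small-ridge refit with a warning.
* Bootstrap percentile bounds with B = 1 collapse to the single draw.
* EM requires at least 2 observed values per column; all-missing and
  constant wide columns are dropped with a warning.
* Seeds are combined with small integer indices through a fixed
  linear-congruential map into [1, 2^31), so every sub-stream is
  reproducible and independent of loop order.

# Problem sizes used by the test suite

The acceptance-style checks run the full pipeline at n = 5,000 children
(oracle curves at 50,000 Monte-Carlo trajectories; B = 20 bootstrap
resamples over m = 2 imputations for the null-preservation check; 10 seeds
for the regime-ordering check; 200 replications of the bivariate
imputation-coverage experiment at n = 2,000). These sizes were chosen so
that each structural property is tested with meaningful power while the
whole suite stays comfortably runnable on a laptop; the vignette-level
analysis in the README uses the cohort-scale n = 2,934.

# Known limitations

* The per-time death model is rarely identifiable at realistic death
  counts; the pooled fallback with a smooth time effect is a deliberate
  bias-variance trade.
* The conditional-normal imputation model treats bounded, skewed markers
  as Gaussian after transformation; imputations are truncated/clamped
  rather than drawn from a truncated model.
* The percentile interval pools bootstrap draws across imputations; it
  reflects sampling plus imputation noise jointly rather than applying
  Rubin's variance decomposition to the bounds themselves.
* The naive hazard-ratio diagnostic approximates a hazard ratio by an odds
  ratio; the approximation degrades if per-interval death probabilities
  leave the rare-event range.
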