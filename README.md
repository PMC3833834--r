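# artgcomp

Counterfactual cumulative mortality under dynamic antiretroviral-therapy
(ART) initiation rules in longitudinal paediatric HIV cohorts, estimated by
the parametric g-formula (g-computation).

## The problem

In children aged 2–5 years living with HIV, should ART start immediately,
or can it be deferred until the CD4 count or CD4 percentage falls below a
threshold? Observational cohorts could answer this, but the question is
confounded by indication over time: CD4 count, CD4% and weight-for-age
z-score (WAZ) predict both the decision to treat and the risk of death, and
are themselves affected by earlier treatment. A conventional hazard
regression on time-varying treatment is biased towards harm — the sickest
children are treated first — and adjusting for the time-dependent markers
in the outcome model blocks part of the effect being estimated.

`artgcomp` implements the g-computation answer. Writing `L_t` for the
time-dependent confounders (CD4, CD4%, WAZ) on the visit grid
t = 0, 1, 3, 6, ..., 36 months, `A_t` for the absorbing on-ART indicator
and `Y_t` for death in the interval ending at t:

1. fit, per follow-up time, additive linear models
   `L_t ~ L_{t-1} + A_{t-1} + V` (V: baseline markers and demographics)
   with penalized-spline smooths selected by generalized cross-validation,
   and a logistic additive model for `Y_t` on the same covariates;
2. simulate every child forward from the observed enrolment state, setting
   `A_{t-1}` by the rule of interest g applied to the *simulated* current
   markers — e.g. g = "treat when CD4 < 750 cells/mm3 or CD4% < 25%" —
   drawing `L_t` from the fitted normals and `Y_t` from the fitted
   Bernoulli;
3. average the simulated deaths: the counterfactual cumulative mortality
   under g;
4. repeat over rules, over B child-level bootstrap resamples (percentile
   95% intervals), and over m multiply-imputed datasets (Rubin's rules).

The supporting machinery is part of the package: interval discretisation of
irregular visits, last-observation-carried-forward limited to 9 months,
loss-to-follow-up censoring, EM-bootstrap longitudinal multiple imputation,
pre-ART time-to-threshold estimators (Kaplan-Meier and competing-risk
conditional cumulative incidence), and the naive pooled-logistic hazard
comparison that shows what goes wrong without the causal machinery.

Because individual-level data of this kind are not public, the package
ships a synthetic cohort generator (`sim_params()`, `generate_cohort()`)
whose structural causal model is known, plus a brute-force oracle
(`true_regime_mortality()`) that computes the exact counterfactual curves —
so every estimate in the test suite is checked against ground truth.

## Worked example

```r
library(artgcomp)

params <- sim_params(n_children = 2934, seed = 1)   # cohort-scale defaults
raw    <- generate_cohort(params)
elig   <- filter_eligible(raw)
panel  <- flag_ltfu(apply_locf(discretise(elig$cohort)))
imp    <- impute_panel(panel, m = 2, seed = 2)

fit <- run_gcomputation(imp, regimes = standard_regimes(),
                        B = 40, seed = 1, mc_factor = 2)
print(fit)
```

```
G-computation estimate of counterfactual cumulative mortality
  2692 children, 2 imputation(s), 40 bootstrap resamples each
            12   24   36
immediate 1.24 1.73 2.64
t750      1.24 1.73 2.63
t500      1.24 1.73 2.62
t250      1.25 1.74 2.65
never     2.36 3.30 5.16
```

The columns are months of follow-up, the entries cumulative mortality in
percent. Immediate ART and the CD4-threshold deferral rules are essentially
indistinguishable (most children already sit below the thresholds at
enrolment, and those above them cross quickly), while never treating
roughly doubles three-year mortality.
`summary(fit)` adds the percentile-bootstrap bounds; `plot(fit)` draws the
curves with dashed bounds.

The naive comparison on the same panel illustrates the confounding:

```r
naive_art_association(imp$panels[[1]])$hazard_ratio
#> [1] 1.2999
```

ART *appears* to raise the death hazard, while the generating truth (and
the g-computation estimate above) is strongly protective — the signature of
confounding by indication.

```r
tail(true_regime_mortality(params, regime("never"), n_mc = 50000), 2)
#>    time mortality
#> 13   33   0.04474
#> 14   36   0.04724
```

The brute-force oracle confirms the scale of the no-ART counterfactual.

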