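# Shared fixtures: hand-built raw cohorts and panels, and small generator
# presets used across the suite.

## A raw cohort assembled by hand (bypassing the generator) for the
## preparation-module examples.
hand_cohort <- function(baseline, visits, events) {
  structure(list(baseline = baseline, visits = visits, events = events),
            grid = visit_grid(), class = "raw_cohort")
}

## Minimal baseline row; age in years.
brow <- function(id, age = 3, sex = "male", region = "SA-urban",
                 cd4 = 600, cd4pct = 20, waz = -1, haz = -2) {
  data.frame(id = id, age = age, sex = sex, region = region, cd4 = cd4,
             cd4pct = cd4pct, waz = waz, haz = haz)
}

vrow <- function(id, time, cd4 = 600, cd4pct = 20, waz = -1) {
  data.frame(id = id, time = time, cd4 = cd4, cd4pct = cd4pct, waz = waz)
}

erow <- function(id, art_start = NA_real_, death = NA_real_,
                 last_contact = 36) {
  data.frame(id = id, art_start = art_start, death = death,
             last_contact = last_contact)
}

## Generator preset with the observation process switched off (visits on the
## grid, fully recorded, everyone retained).
clean_params <- function(n, seed, ...) {
  sim_params(n_children = n, missing_rate = 0, ltfu_hazard = 0,
             prior_art_prob = 0, no_followup_prob = 0, jitter = FALSE,
             seed = seed, ...)
}

## Randomised-treatment preset: assignment independent of the markers.
randomised_params <- function(n, seed, p_start = 0.13, ...) {
  sim_params(n_children = n,
             assignment_coefs = c(intercept = qlogis(p_start), sqrt_cd4 = 0,
                                  cd4pct = 0, waz = 0),
             seed = seed, ...)
}

## Fit a small model set once per session for engine tests.
cached_model_set <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      p <- clean_params(600, seed = 42)
      raw <- generate_cohort(p)
      pan <- flag_ltfu(apply_locf(discretise(filter_eligible(raw)$cohort)))
      cache <<- list(params = p, panel = pan, models = fit_model_set(pan))
    }
    cache
  }
})
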