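# Pre-ART time-to-threshold estimators and the naive hazard comparison.

## Panel where every child starts above both thresholds; `spec` gives per
## child either the crossing time (type "cross"), a competing-event time
## ("compete": ART here), or NULL for administrative end at 12 months.
threshold_panel <- function(spec) {
  rows <- list(); events <- list()
  for (i in seq_along(spec)) {
    s <- spec[[i]]
    tt <- c(0, 3, 6, 9, 12)
    cd4 <- rep(900, 5); art <- rep(0L, 5)
    if (!is.null(s)) {
      keep <- tt <= s$time
      tt <- tt[keep]; cd4 <- cd4[keep]; art <- art[keep]
      if (s$type == "cross") cd4[length(cd4)] <- 400
      if (s$type == "compete") art[length(art)] <- 1L
    }
    rows[[i]] <- data.frame(
      id = i, t = tt, cd4 = cd4, cd4pct = 30, waz = -1,
      carried_cd4 = FALSE, carried_cd4pct = FALSE, carried_waz = FALSE,
      art = art, death = 0L, cens = 0L, cens_reason = "none",
      age = 3, sex = "male", region = "SA-urban",
      cd4_0 = 900, cd4pct_0 = 30, waz_0 = -1, haz_0 = -2)
    events[[i]] <- data.frame(id = i, art_start = NA_real_,
                              death = NA_real_, last_contact = max(tt))
  }
  structure(do.call(rbind, rows), grid = visit_grid(), horizon = 36,
            events = do.call(rbind, events),
            class = c("interval_panel", "data.frame"))
}

test_that("the crossing curve reproduces a hand Kaplan-Meier computation", {
  ## 3 children: crossings at 3 and 9, censoring (ART) at 6
  pan <- threshold_panel(list(list(time = 3, type = "cross"),
                              list(time = 6, type = "compete"),
                              list(time = 9, type = "cross")))
  km <- km_threshold_crossing(pan, 750, 25)
  ## S(3) = 2/3; at t=9 one at risk, event: S = 0
  expect_equal(km$estimate[km$time == 3], 1 / 3, tolerance = 1e-12)
  expect_equal(km$estimate[km$time == 9], 1, tolerance = 1e-12)
})

test_that("no crossings give a flat zero curve", {
  pan <- threshold_panel(list(NULL, NULL, NULL))
  km <- km_threshold_crossing(pan, 750, 25)
  expect_true(all(km$estimate == 0))
})

test_that("without censoring the curve is the crossing-time ECDF", {
  pan <- threshold_panel(list(list(time = 3, type = "cross"),
                              list(time = 6, type = "cross"),
                              list(time = 6, type = "cross"),
                              list(time = 9, type = "cross")))
  km <- km_threshold_crossing(pan, 750, 25)
  expect_equal(km$estimate[km$time == 3], 0.25, tolerance = 1e-12)
  expect_equal(km$estimate[km$time == 6], 0.75, tolerance = 1e-12)
  expect_equal(km$estimate[km$time == 9], 1, tolerance = 1e-12)
})

test_that("eligibility requires starting at or above both thresholds", {
  pan <- threshold_panel(list(NULL))
  pan$cd4_0 <- 500
  pan$cd4[pan$t == 0] <- 500
  expect_error(km_threshold_crossing(pan, 750, 25), "no children")
})

test_that("with no competing events the conditional CIF equals the KM curve", {
  pan <- threshold_panel(list(list(time = 3, type = "cross"),
                              list(time = 6, type = "cross"), NULL, NULL))
  km <- km_threshold_crossing(pan, 750, 25)
  cif <- cif_threshold_crossing(pan, 750, 25, n_boot = 10, seed = 1)
  for (tt in km$time)
    expect_equal(cif$estimate[cif$time == tt][1],
                 km$estimate[km$time == tt][1], tolerance = 1e-12)
})

test_that("universal competition gives a zero numerator", {
  pan <- threshold_panel(list(list(time = 3, type = "compete"),
                              list(time = 6, type = "compete")))
  expect_warning(cif <- cif_threshold_crossing(pan, 750, 25, n_boot = 5,
                                               seed = 1),
                 "denominator")
  expect_true(all(cif$estimate[!is.na(cif$estimate)] == 0))
})

test_that("Aalen-Johansen state probabilities conserve mass", {
  set.seed(10)
  spec <- replicate(60, {
    u <- runif(1)
    if (u < 0.4) list(time = sample(c(3, 6, 9), 1), type = "cross")
    else if (u < 0.7) list(time = sample(c(3, 6, 9), 1), type = "compete")
    else NULL
  }, simplify = FALSE)
  pan <- threshold_panel(spec)
  ev <- artgcomp:::crossing_events(pan, 750, 25)
  st <- factor(ev$type, levels = 0:2,
               labels = c("censor", "cross", "compete"))
  sf <- survival::survfit(survival::Surv(ev$time, st) ~ 1)
  expect_true(all(abs(rowSums(sf$pstate) - 1) < 1e-12))
})

test_that("the conditional CIF matches a two-hazard closed form", {
  ## per interval: cross w.p. 0.05, else compete w.p. 0.05/(1-0.05)*0.95=0.05
  set.seed(11)
  n <- 2000
  spec <- vector("list", n)
  for (i in 1:n) {
    s <- NULL
    for (tt in c(3, 6, 9)) {
      u <- runif(1)
      if (u < 0.05) { s <- list(time = tt, type = "cross"); break }
      if (u < 0.10) { s <- list(time = tt, type = "compete"); break }
    }
    spec[[i]] <- s
  }
  pan <- threshold_panel(spec)
  cif <- cif_threshold_crossing(pan, 750, 25, n_boot = 100, seed = 3)
  ## closed form: CIF_cross(t_k) = 0.05 * sum_{j<=k} 0.9^(j-1); same for
  ## competing events; conditional estimate is their ratio complement
  for (k in 1:3) {
    tt <- c(3, 6, 9)[k]
    cf <- 0.05 * sum(0.9^(0:(k - 1)))
    want <- cf / (1 - cf)
    row <- cif[cif$time == tt, ]
    expect_gte(want, row$lower - 1e-9)
    expect_lte(want, row$upper + 1e-9)
    expect_lt(abs(row$estimate - want), 0.04)
  }
})

test_that("competing events tied to imminent crossing push the conditional
           estimate above the Kaplan-Meier estimate", {
  ## children drift towards the threshold; once close, a competing event
  ## (ART start) becomes much more likely, so censoring is informative
  set.seed(12)
  spec <- replicate(600, {
    cd4 <- 900
    out <- NULL
    for (tt in c(3, 6, 9)) {
      cd4 <- cd4 - rexp(1, rate = 1 / 60)
      p_comp <- if (cd4 < 800) 0.45 else 0.02
      if (runif(1) < p_comp) { out <- list(time = tt, type = "compete"); break }
      if (cd4 < 750) { out <- list(time = tt, type = "cross"); break }
    }
    out
  }, simplify = FALSE)
  pan <- threshold_panel(spec)
  km <- km_threshold_crossing(pan, 750, 25)
  cif <- cif_threshold_crossing(pan, 750, 25, n_boot = 20, seed = 2)
  t_last <- max(km$time)
  expect_gte(cif$estimate[cif$time == t_last],
             km$estimate[km$time == t_last] - 1e-9)
})

test_that("randomised null treatment gives a near-unit naive hazard ratio", {
  p <- randomised_params(8000, seed = 121, art_effect = 1,
                         missing_rate = 0, ltfu_hazard = 0,
                         prior_art_prob = 0, no_followup_prob = 0,
                         jitter = FALSE)
  raw <- generate_cohort(p)
  pan <- flag_ltfu(apply_locf(discretise(filter_eligible(raw)$cohort)))
  na <- naive_art_association(pan)
  expect_gt(na$hazard_ratio, 0.72)
  expect_lt(na$hazard_ratio, 1.38)
  expect_true(na$conf_int[1] < 1 && na$conf_int[2] > 1)
})

test_that("randomised doubled hazard is recovered by the naive model", {
  p <- randomised_params(8000, seed = 131, p_start = 0.3, art_effect = 2,
                         missing_rate = 0, ltfu_hazard = 0,
                         prior_art_prob = 0, no_followup_prob = 0,
                         jitter = FALSE)
  raw <- generate_cohort(p)
  pan <- flag_ltfu(apply_locf(discretise(filter_eligible(raw)$cohort)))
  na <- naive_art_association(pan)
  expect_gt(na$hazard_ratio, 1.5)
  expect_lt(na$hazard_ratio, 2.6)
})

test_that("a panel with no deaths cannot be analysed naively", {
  pan <- threshold_panel(list(NULL, NULL))
  expect_error(naive_art_association(pan), "no deaths")
})
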