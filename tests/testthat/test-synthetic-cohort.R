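# Synthetic cohort generator and its brute-force counterfactual oracle.

test_that("generation is deterministic and reproducible under subsetting", {
  p <- sim_params(n_children = 60, seed = 7)
  a <- generate_cohort(p)
  b <- generate_cohort(p)
  expect_identical(a$visits, b$visits)
  expect_identical(a$events, b$events)
  ## child-level streams: the first 30 children of a larger cohort match the
  ## cohort of size 30
  p30 <- sim_params(n_children = 30, seed = 7)
  c30 <- generate_cohort(p30)
  expect_identical(c30$visits, a$visits[a$visits$id <= 30, ])
  expect_identical(c30$baseline, a$baseline[a$baseline$id <= 30, ])
})

test_that("an empty cohort has valid empty tables", {
  raw <- generate_cohort(sim_params(n_children = 0, seed = 1))
  expect_identical(nrow(raw$baseline), 0L)
  expect_identical(nrow(raw$visits), 0L)
  expect_identical(nrow(raw$events), 0L)
  expect_named(raw$visits, c("id", "time", "cd4", "cd4pct", "waz"))
})

test_that("parameter validation rejects bad inputs", {
  expect_error(sim_params(n_children = -1), "non-negative")
  expect_error(sim_params(missing_rate = 1.5), "probability")
  expect_error(sim_params(horizon_months = 35), "multiple of 3|grid")
  expect_error(sim_params(art_effect = -2), "positive")
  expect_error(sim_params(death_coefs = c(1, NA, 0, 0)), "non-finite")
})

test_that("baseline draws match the cohort's enrolment profile", {
  ## 12,000 children: the sample median of CD4% (quartile-implied SD 9.4)
  ## has SE ~0.13, so the 0.2-unit calibration band is a meaningful check
  raw <- generate_cohort(sim_params(n_children = 12000, seed = 12))
  b <- raw$baseline
  expect_lt(abs(median(b$cd4, na.rm = TRUE) - 592), 0.10 * 592)
  expect_lt(abs(median(b$cd4pct, na.rm = TRUE) - 16), 0.2)
  expect_lt(abs(median(b$waz, na.rm = TRUE) - (-1.4)), 0.2)
  expect_lt(abs(median(b$haz, na.rm = TRUE) - (-2.6)), 0.2)
  expect_true(all(b$age >= 2 & b$age <= 5))
  expect_true(all(b$cd4 >= 0, na.rm = TRUE))
  expect_true(all(b$cd4pct >= 0 & b$cd4pct <= 100, na.rm = TRUE))
})

test_that("no observation noise means no missing cells and no LTFU", {
  p <- clean_params(150, seed = 9)
  raw <- generate_cohort(p)
  expect_false(anyNA(raw$visits[, c("cd4", "cd4pct", "waz")]))
  expect_false(anyNA(raw$baseline[, c("cd4", "cd4pct", "waz", "haz")]))
  pan <- flag_ltfu(apply_locf(discretise(filter_eligible(raw)$cohort)))
  expect_identical(sum(pan$cens_reason == "ltfu"), 0L)
})

test_that("observation-process parameters never touch the ground truth", {
  base <- list(n_children = 80, seed = 31)
  a <- generate_cohort(do.call(sim_params, c(base, list(missing_rate = 0,
                                                        ltfu_hazard = 0))))
  b <- generate_cohort(do.call(sim_params, c(base, list(missing_rate = 0.4,
                                                        ltfu_hazard = 0.1))))
  expect_identical(attr(a, "truth"), attr(b, "truth"))
  ## but the observed tables do change
  expect_gt(sum(is.na(b$visits$cd4)), sum(is.na(a$visits$cd4)))
})

test_that("confounding by indication: crude on-ART death rate exceeds off-ART", {
  raw <- generate_cohort(sim_params(n_children = 4000, seed = 17))
  tr <- attr(raw, "truth")
  tr <- tr[order(tr$id, tr$t), ]
  same <- c(FALSE, tr$id[-1] == tr$id[-nrow(tr)])
  art_prev <- c(NA, tr$art[-nrow(tr)])[same]
  death <- tr$death[same]
  rate_on <- mean(death[art_prev == 1])
  rate_off <- mean(death[art_prev == 0])
  expect_gt(rate_on, rate_off)
})

test_that("null treatment effect forces identical oracle curves", {
  p <- sim_params(n_children = 0, art_effect = 1, seed = 3)
  imm <- true_regime_mortality(p, regime("immediate"), n_mc = 50000)
  nev <- true_regime_mortality(p, regime("never"), n_mc = 50000)
  ## common random numbers and no ART pathway: exactly equal
  mc_se <- sqrt(imm$mortality * (1 - imm$mortality) / 50000)
  expect_true(all(abs(imm$mortality - nev$mortality) <= 2 * mc_se + 1e-12))
})

test_that("constant-hazard oracle matches the geometric closed form", {
  p <- sim_params(n_children = 0, art_effect = 1,
                  death_coefs = c(intercept = qlogis(0.01), sqrt_cd4 = 0,
                                  cd4pct = 0, waz = 0), seed = 5)
  cur <- true_regime_mortality(p, regime("never"), n_mc = 50000)
  k <- seq_along(cur$time) - 1   # intervals elapsed by each grid time
  closed <- 1 - 0.99^k
  mc_se <- sqrt(pmax(closed * (1 - closed), 1e-6) / 50000)
  expect_true(all(abs(cur$mortality - closed) <= 3 * mc_se))
})

test_that("a protective effect lowers immediate-ART mortality below no-ART", {
  p <- sim_params(n_children = 0, art_effect = 0.3, seed = 11)
  imm <- true_regime_mortality(p, regime("immediate"), n_mc = 50000)
  nev <- true_regime_mortality(p, regime("never"), n_mc = 50000)
  expect_lt(tail(imm$mortality, 1), tail(nev$mortality, 1))
})

test_that("oracle curves are monotone, in [0,1], and regime-ordered", {
  p <- sim_params(n_children = 0, art_effect = 0.2, seed = 23)
  curves <- lapply(standard_regimes(), true_regime_mortality, params = p,
                   n_mc = 20000)
  for (cur in curves) {
    expect_true(all(diff(cur$mortality) >= 0))
    expect_true(all(cur$mortality >= 0 & cur$mortality <= 1))
  }
  m36 <- vapply(curves, function(cur) tail(cur$mortality, 1), numeric(1))
  expect_true(all(diff(m36[c("immediate", "t750", "t500", "t250",
                             "never")]) >= 0))
})

test_that("cohort tables round-trip through CSV", {
  raw <- generate_cohort(sim_params(n_children = 25, seed = 2))
  dir <- withr::local_tempdir()
  write_cohort(raw, dir)
  back <- read_cohort(dir)
  expect_equal(back$visits$cd4, raw$visits$cd4)
  expect_equal(back$events$art_start, raw$events$art_start)
  expect_equal(back$baseline$haz, raw$baseline$haz)
})

test_that("generator parameters round-trip through YAML", {
  p <- sim_params(n_children = 40, art_effect = 0.5, seed = 13)
  path <- withr::local_tempfile(fileext = ".yaml")
  sim_params_to_yaml(p, path)
  q <- sim_params_from_yaml(path)
  expect_equal(q$art_effect, 0.5)
  expect_equal(q$ar, p$ar, tolerance = 1e-6)
  expect_equal(q$baseline$region_probs, p$baseline$region_probs)
  expect_equal(q$death_coefs, p$death_coefs, tolerance = 1e-6)
  ## the reread parameters drive a valid, reproducible simulation
  expect_identical(generate_cohort(q)$visits, generate_cohort(q)$visits)
})
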