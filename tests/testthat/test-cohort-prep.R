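# Eligibility filtering, interval discretisation, LOCF and LTFU censoring.

test_that("eligibility: age window is inclusive at 24 and 60 months", {
  raw <- hand_cohort(
    rbind(brow(1, age = 23.9 / 12), brow(2, age = 24 / 12),
          brow(3, age = 60 / 12), brow(4, age = 60.1 / 12)),
    rbind(vrow(1, 0), vrow(1, 3), vrow(2, 0), vrow(2, 3),
          vrow(3, 0), vrow(3, 3), vrow(4, 0), vrow(4, 3)),
    rbind(erow(1), erow(2), erow(3), erow(4)))
  fe <- filter_eligible(raw)
  expect_setequal(fe$cohort$baseline$id, c(2, 3))
  expect_identical(unname(fe$exclusions["age_under"]), 1L)
  expect_identical(unname(fe$exclusions["age_over"]), 1L)
})

test_that("eligibility: prior ART and no-follow-up children are excluded", {
  raw <- hand_cohort(
    rbind(brow(1), brow(2), brow(3)),
    rbind(vrow(1, 0), vrow(1, 3), vrow(2, 0), vrow(2, 3), vrow(3, 0)),
    rbind(erow(1, art_start = -1), erow(2, art_start = 6), erow(3)))
  fe <- filter_eligible(raw)
  expect_equal(fe$cohort$baseline$id, 2)
  expect_identical(unname(fe$exclusions["prior_art"]), 1L)
  expect_identical(unname(fe$exclusions["no_followup"]), 1L)
  expect_identical(unname(fe$exclusions["retained"]), 1L)
})

test_that("discretisation selects the observation closest to the nominal time", {
  raw <- hand_cohort(
    brow(1),
    rbind(vrow(1, 0), vrow(1, 5.0, cd4 = 500), vrow(1, 6.8, cd4 = 710)),
    erow(1))
  pan <- discretise(raw)
  expect_equal(pan$cd4[pan$t == 6], 710)         # |6.8-6| < |5.0-6|
  raw2 <- hand_cohort(
    brow(1),
    rbind(vrow(1, 0), vrow(1, 5.2, cd4 = 520), vrow(1, 6.8, cd4 = 710)),
    erow(1))
  pan2 <- discretise(raw2)
  expect_equal(pan2$cd4[pan2$t == 6], 520)       # tie at 0.8: earlier wins
})

test_that("windows without observations yield missing cells", {
  raw <- hand_cohort(brow(1), rbind(vrow(1, 0), vrow(1, 3.1, cd4 = 400)),
                     erow(1))
  pan <- discretise(raw)
  expect_equal(pan$cd4[pan$t == 3], 400)
  expect_true(is.na(pan$cd4[pan$t == 6]))
  expect_false(pan$carried_cd4[pan$t == 6])      # carry flags set by LOCF only
})

test_that("death between grid times lands on the next grid time, absorbing", {
  raw <- hand_cohort(brow(1), rbind(vrow(1, 0), vrow(1, 3), vrow(1, 6)),
                     erow(1, death = 7.5, last_contact = 7.5))
  pan <- discretise(raw)
  expect_identical(pan$death[pan$t == 9], 1L)
  expect_true(all(pan$t <= 9))
  expect_identical(sum(pan$death), 1L)
})

test_that("ART start switches the indicator on from the next nominal time", {
  raw <- hand_cohort(brow(1), rbind(vrow(1, 0), vrow(1, 3), vrow(1, 6)),
                     erow(1, art_start = 4))
  pan <- discretise(raw)
  expect_identical(pan$art[pan$t <= 3], c(0L, 0L, 0L))
  expect_true(all(pan$art[pan$t >= 6] == 1L))
})

test_that("visits beyond the horizon window are ignored with a warning", {
  raw <- hand_cohort(brow(1), rbind(vrow(1, 0), vrow(1, 3), vrow(1, 40)),
                     erow(1))
  expect_warning(pan <- discretise(raw), "beyond the horizon")
  expect_true(all(pan$t <= 36))
})

test_that("LOCF fills forward up to 9 months and flags carried cells", {
  raw <- hand_cohort(
    brow(1),
    rbind(vrow(1, 0), vrow(1, 3, cd4 = 480),
          within(vrow(1, 6), cd4 <- NA), within(vrow(1, 9), cd4 <- NA),
          within(vrow(1, 12), cd4 <- NA), within(vrow(1, 15), cd4 <- NA)),
    erow(1))
  pan <- apply_locf(discretise(raw))
  got <- pan[pan$t %in% c(6, 9, 12, 15), c("t", "cd4", "carried_cd4")]
  expect_equal(got$cd4[got$t %in% c(6, 9, 12)], rep(480, 3))  # gaps 3, 6, 9
  expect_true(all(got$carried_cd4[got$t %in% c(6, 9, 12)]))
  expect_true(is.na(got$cd4[got$t == 15]))                    # gap 12 > 9
})

test_that("LOCF never carries backwards and leaves observed cells alone", {
  raw <- hand_cohort(
    within(brow(1), cd4 <- NA),
    rbind(within(vrow(1, 0), cd4 <- NA), vrow(1, 3, cd4 = 510)),
    erow(1))
  pan <- apply_locf(discretise(raw))
  expect_true(is.na(pan$cd4[pan$t == 0]))
  ## a child observed at every grid time: identity, no carried flags
  raw2 <- hand_cohort(brow(2),
                      do.call(rbind, lapply(visit_grid(), vrow, id = 2)),
                      erow(2))
  pan2 <- discretise(raw2)
  pan2f <- apply_locf(pan2)
  expect_equal(pan2f$cd4, pan2$cd4)
  expect_false(any(pan2f$carried_cd4 | pan2f$carried_cd4pct |
                     pan2f$carried_waz))
})

test_that("no cell is simultaneously observed and carried", {
  raw <- generate_cohort(sim_params(n_children = 120, seed = 41,
                                    missing_rate = 0.3))
  pan0 <- discretise(filter_eligible(raw)$cohort)
  pan <- apply_locf(pan0)
  was_obs <- !is.na(pan0$cd4)
  expect_false(any(was_obs & pan$carried_cd4))
})

test_that("LTFU flagged when contact stops >9 months before closure", {
  raw <- hand_cohort(
    rbind(brow(1), brow(2), brow(3)),
    rbind(vrow(1, 0), vrow(1, 26), vrow(2, 0), vrow(2, 28),
          vrow(3, 0), vrow(3, 3)),
    rbind(erow(1, last_contact = 26),                  # gap 10 -> LTFU
          erow(2, last_contact = 28),                  # gap 8  -> in care
          erow(3, death = 5, last_contact = 5)))       # dead -> never LTFU
  pan <- flag_ltfu(discretise(raw), closure = 36)
  expect_identical(unique(pan$cens_reason[pan$id == 1 & pan$cens == 1]),
                   "ltfu")
  expect_false(any(pan$cens_reason[pan$id == 2] == "ltfu"))
  expect_false(any(pan$cens[pan$id == 3] == 1))
  ## censoring row sits at the first grid time after last contact
  expect_identical(pan$t[pan$id == 1 & pan$cens == 1], 27L)
  expect_true(all(pan$t[pan$id == 1] <= 27))
})

test_that("a jitter-free noiseless cohort discretises to the generator truth", {
  raw <- generate_cohort(clean_params(80, seed = 19))
  pan <- discretise(filter_eligible(raw)$cohort)
  truth <- attr(raw, "truth")
  truth <- truth[truth$id %in% pan$id, ]
  key_p <- paste(pan$id, pan$t)
  key_t <- paste(truth$id, truth$t)
  expect_setequal(key_p, key_t)
  m <- match(key_t, key_p)
  expect_equal(pan$cd4[m], truth$cd4, tolerance = 1e-12)
  expect_equal(pan$cd4pct[m], truth$cd4pct, tolerance = 1e-12)
  expect_equal(pan$waz[m], truth$waz, tolerance = 1e-12)
  expect_identical(pan$art[m], truth$art)
  expect_identical(pan$death[m], truth$death)
})

test_that("panel invariants hold on generated data after full preparation", {
  raw <- generate_cohort(sim_params(n_children = 200, seed = 55))
  pan <- flag_ltfu(apply_locf(discretise(filter_eligible(raw)$cohort)))
  expect_true(artgcomp:::validate_panel(pan))
  expect_true(all(pan$t %in% visit_grid()))
})

test_that("panels round-trip through CSV", {
  raw <- generate_cohort(sim_params(n_children = 30, seed = 77))
  pan <- apply_locf(discretise(filter_eligible(raw)$cohort))
  path <- withr::local_tempfile(fileext = ".csv")
  write_panel(pan, path)
  back <- read_panel(path)
  expect_equal(back$cd4, pan$cd4)
  expect_identical(back$death, pan$death)
})
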