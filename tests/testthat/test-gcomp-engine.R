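# Regime decisions, forward simulation, mortality estimation, and the
# bootstrap/imputation engine.

test_that("regime_decision truth table", {
  r750 <- regime("threshold", 750, 25)
  expect_identical(regime_decision(r750, 800, 24, 0L), 1L)  # disjunction
  expect_identical(regime_decision(r750, 800, 26, 0L), 0L)
  expect_identical(regime_decision(r750, 740, 26, 0L), 1L)
  expect_identical(regime_decision(r750, 750, 25, 0L), 0L)  # strict
  expect_identical(regime_decision(r750, 2000, 40, 1L), 1L) # absorbing
  expect_identical(regime_decision(regime("never"), 10, 1, 0L), 0L)
  expect_identical(regime_decision(regime("immediate"), 2000, 40, 0L), 1L)
  expect_error(regime_decision(r750, NA, 20, 0L), "complete")
  expect_error(regime("threshold", -5, 25), "positive")
})

test_that("initiation bands are mutually exclusive and ordered", {
  expect_identical(classify_initiation_band(650, 19),
                   "<500 cells/mm3 or <20%")
  expect_identical(classify_initiation_band(200, 30),
                   "<250 cells/mm3 or <15%")
  expect_identical(classify_initiation_band(800, 26),
                   ">750 cells/mm3 and >25%")
  expect_identical(classify_initiation_band(NA, NA), "Unknown")
  expect_identical(classify_initiation_band(NA, 14),
                   "<250 cells/mm3 or <15%")
  expect_identical(classify_initiation_band(c(650, 800), c(19, 26)),
                   c("<500 cells/mm3 or <20%", ">750 cells/mm3 and >25%"))
})

test_that("a zero-hazard death model yields no simulated deaths", {
  cs <- cached_model_set()
  ms <- cs$models
  ms$death$pooled <- artgcomp:::const_model(0)
  ms$death$pooled_at[] <- TRUE
  sim <- simulate_forward(cs$panel, ms, regime("immediate"), seed = 1)
  expect_true(all(is.infinite(sim$death_time)))
  expect_true(all(estimate_mortality(sim)$mortality == 0))
})

test_that("constant-hazard forward simulation matches the geometric law", {
  cs <- cached_model_set()
  ms <- cs$models
  ms$death$pooled <- artgcomp:::const_model(0.01)
  ms$death$pooled_at[] <- TRUE
  sim <- simulate_forward(cs$panel, ms, regime("never"), seed = 3,
                          mc_factor = 40)   # ~23,000 trajectories
  est <- estimate_mortality(sim)
  k <- seq_along(est$time) - 1
  closed <- 1 - 0.99^k
  mc_se <- sqrt(pmax(closed * (1 - closed), 1e-6) / sim$n)
  expect_true(all(abs(est$mortality - closed) <= 3 * mc_se))
})

test_that("noiseless confounder models give deterministic trajectories", {
  cs <- cached_model_set()
  ms <- cs$models
  for (tg in c("sqrt_cd4", "cd4pct", "waz")) {
    for (k in seq_along(ms$times))
      if (!is.null(ms$models[[tg]]$per_time[[k]]))
        ms$models[[tg]]$per_time[[k]]$sigma <- 0
    if (!is.null(ms$models[[tg]]$pooled)) ms$models[[tg]]$pooled$sigma <- 0
  }
  ms$death$pooled <- artgcomp:::const_model(0)
  ms$death$pooled_at[] <- TRUE
  s1 <- simulate_forward(cs$panel, ms, regime("never"), seed = 1,
                         keep_states = TRUE)
  s2 <- simulate_forward(cs$panel, ms, regime("never"), seed = 999,
                         keep_states = TRUE)
  expect_equal(s1$states, s2$states, tolerance = 1e-12)
})

test_that("mortality estimation counts deaths cumulatively", {
  sim <- structure(list(times = c(0, 6, 12, 24), n = 4L,
                        death_time = c(12, 12, Inf, Inf), regime = "x",
                        states = NULL), class = "sim_panel")
  est <- estimate_mortality(sim)
  expect_equal(est$mortality, c(0, 0, 0.5, 0.5))
  sim$n <- 0L
  sim$death_time <- numeric(0)
  expect_error(estimate_mortality(sim), "empty")
})

test_that("bootstrap resampling keeps whole child trajectories", {
  cs <- cached_model_set()
  ids <- unique(cs$panel$id)
  pick <- c(ids[3], ids[3], ids[7])
  pb <- artgcomp:::resample_children(cs$panel, pick)
  expect_identical(sort(unique(pb$id)), 1:3)
  for (j in seq_along(pick)) {
    got <- pb[pb$id == j, c("t", "cd4", "death")]
    want <- cs$panel[cs$panel$id == pick[j], c("t", "cd4", "death")]
    rownames(got) <- rownames(want) <- NULL
    expect_equal(got, want)
  }
})

test_that("the engine is deterministic and its bounds are ordered", {
  cs <- cached_model_set()
  g1 <- run_gcomputation(cs$panel, regimes = standard_regimes()[c(1, 5)],
                         B = 6, seed = 13)
  g2 <- run_gcomputation(cs$panel, regimes = standard_regimes()[c(1, 5)],
                         B = 6, seed = 13)
  expect_identical(g1$point, g2$point)
  expect_identical(g1$lower, g2$lower)
  expect_true(all(g1$lower <= g1$upper + 1e-12))
  expect_true(all(apply(g1$point, 1, function(r) all(diff(r) >= -1e-12))))
  expect_true(all(g1$point >= 0 & g1$point <= 1))
  ## summary/coef/print surface
  s <- summary(g1, at = c(12, 36))
  expect_identical(nrow(s), 4L)
  expect_true(all(s$lower_pct <= s$upper_pct))
  expect_identical(dim(coef(g1)), dim(g1$point))
  expect_output(print(g1), "G-computation")
})

test_that("B = 1 with one imputation gives degenerate percentile bounds", {
  cs <- cached_model_set()
  g <- run_gcomputation(cs$panel, regimes = list(regime("never")), B = 1,
                        seed = 5)
  expect_equal(g$lower, g$upper)
  expect_equal(unname(g$lower[1, ]), g$draws[1, 1, ])
})

test_that("duplicated imputations leave the point estimate unchanged", {
  cs <- cached_model_set()
  g1 <- run_gcomputation(list(cs$panel), regimes = list(regime("never")),
                         B = 1, seed = 8)
  g2 <- run_gcomputation(list(cs$panel, cs$panel),
                         regimes = list(regime("never")), B = 1, seed = 8)
  expect_equal(g2$point, g1$point, tolerance = 1e-12)
})

test_that("an incomplete model set is rejected", {
  cs <- cached_model_set()
  ms <- cs$models
  ms$models$waz$per_time <- lapply(ms$models$waz$per_time,
                                   function(x) NULL)
  ms$models$waz$pooled <- NULL
  expect_error(simulate_forward(cs$panel, ms, regime("never"), seed = 1),
               "incomplete model set")
})

test_that("simulation requires complete baseline rows", {
  cs <- cached_model_set()
  pan <- cs$panel
  pan$cd4_0[1] <- NA
  expect_error(simulate_forward(pan, cs$models, regime("never"), seed = 1),
               "complete")
})
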