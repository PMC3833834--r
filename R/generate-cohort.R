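#' Simulate a raw longitudinal cohort
#'
#' Draws a synthetic cohort from the structural causal model described by a
#' [sim_params()] object. Children enrol at month 0 with correlated baseline
#' markers; between consecutive grid visits they may start ART (probability
#' given by the assignment model on the current markers, absorbing once
#' started), may die (logistic hazard on the markers at the interval start,
#' with the death odds multiplied by `art_effect` while on ART), and surviving
#' children's markers evolve by a first-order autoregression. The observation
#' process — visit-time jitter, missing-at-random recording gaps, loss to
#' follow-up, prior-ART and no-follow-up records — is applied *after* the
#' outcomes are drawn, so it never alters the underlying ground truth.
#'
#' Each child has its own reproducible random stream derived from the master
#' seed, so the first `k` children of a cohort of size `n` are identical to a
#' cohort of size `k` generated with the same parameters.
#'
#' @param params A [sim_params()] object.
#' @return An object of class `raw_cohort`: a list with data frames
#'   `baseline` (`id`, `age` in years, `sex`, `region`, `cd4`, `cd4pct`,
#'   `waz`, `haz`; marker cells may be `NA`), `visits` (`id`, `time` in months
#'   since first visit, `cd4`, `cd4pct`, `waz`) and `events` (`id`,
#'   `art_start`, `death`, `last_contact`, all in months; `art_start` is
#'   negative for children already on ART at entry, `NA` if ART was never
#'   started). The attribute `"truth"` holds the generator's internal
#'   discrete-time panel before any observation process was applied.
#' @examples
#' raw <- generate_cohort(sim_params(n_children = 50, seed = 3))
#' head(raw$visits)
#' @export
generate_cohort <- function(params) {
  stopifnot(inherits(params, "sim_params"))
  validate_sim_params(params)
  grid <- visit_grid(params$horizon_months)
  K <- length(grid)
  n <- as.integer(params$n_children)

  empty <- raw_cohort(
    baseline = data.frame(id = integer(), age = numeric(),
                          sex = character(), region = character(),
                          cd4 = numeric(), cd4pct = numeric(),
                          waz = numeric(), haz = numeric()),
    visits = data.frame(id = integer(), time = numeric(), cd4 = numeric(),
                        cd4pct = numeric(), waz = numeric()),
    events = data.frame(id = integer(), art_start = numeric(),
                        death = numeric(), last_contact = numeric()),
    truth = data.frame(id = integer(), t = numeric(), cd4 = numeric(),
                       cd4pct = numeric(), waz = numeric(), art = integer(),
                       death = integer()),
    grid = grid)
  if (n == 0L) return(empty)

  child_seeds <- with_seed(params$seed, sample.int(2147483646L, n))
  chol_corr <- chol(params$baseline$corr)
  sims <- vector("list", n)
  for (i in seq_len(n))
    sims[[i]] <- with_seed(child_seeds[i],
                           simulate_child(i, params, grid, K, chol_corr))

  ## assemble the three tables from the per-child vectors in one pass
  cat_field <- function(part, fld)
    unlist(lapply(sims, function(s) s[[part]][[fld]]), use.names = FALSE)
  baseline <- data.frame(
    id = seq_len(n),
    age = cat_field("baseline", "age"), sex = cat_field("baseline", "sex"),
    region = cat_field("baseline", "region"),
    cd4 = cat_field("baseline", "cd4"),
    cd4pct = cat_field("baseline", "cd4pct"),
    waz = cat_field("baseline", "waz"), haz = cat_field("baseline", "haz"))
  visits <- data.frame(
    id = cat_field("visits", "id"), time = cat_field("visits", "time"),
    cd4 = cat_field("visits", "cd4"), cd4pct = cat_field("visits", "cd4pct"),
    waz = cat_field("visits", "waz"))
  events <- data.frame(
    id = seq_len(n),
    art_start = cat_field("events", "art_start"),
    death = cat_field("events", "death"),
    last_contact = cat_field("events", "last_contact"))
  truth <- data.frame(
    id = cat_field("truth", "id"), t = cat_field("truth", "t"),
    cd4 = cat_field("truth", "cd4"), cd4pct = cat_field("truth", "cd4pct"),
    waz = cat_field("truth", "waz"), art = cat_field("truth", "art"),
    death = cat_field("truth", "death"))
  raw_cohort(baseline = baseline, visits = visits, events = events,
             truth = truth, grid = grid)
}

raw_cohort <- function(baseline, visits, events, truth, grid) {
  structure(list(baseline = baseline, visits = visits, events = events),
            truth = truth, grid = grid, class = "raw_cohort")
}

#' @export
print.raw_cohort <- function(x, ...) {
  cat(sprintf("Raw cohort: %d children, %d visit records\n",
              nrow(x$baseline), nrow(x$visits)))
  cat(sprintf("  deaths recorded: %d, ART starts recorded: %d\n",
              sum(!is.na(x$events$death)), sum(!is.na(x$events$art_start))))
  invisible(x)
}

## One child's full simulation; runs inside the child's own RNG stream.
## Draw order: baseline, trajectory (treatment / death / markers), then the
## observation process, so observation parameters never perturb outcomes.
simulate_child <- function(id, params, grid, K, chol_corr) {
  b <- params$baseline
  age <- b$age_range[1] + diff(b$age_range) *
    stats::rbeta(1, b$age_shape[1], b$age_shape[2])
  sex <- if (stats::runif(1) < b$male_prob) "male" else "female"
  region <- names(b$region_probs)[
    findInterval(stats::runif(1), cumsum(b$region_probs),
                 rightmost.closed = TRUE) + 1L]
  z <- as.vector(crossprod(chol_corr, stats::rnorm(4)))
  lat <- b$mean + b$sd * z
  sc <- max(lat[["sqrt_cd4"]], 0)          # sqrt CD4, truncated at 0
  pc <- clamp(lat[["cd4pct"]], 0, 100)
  wz <- lat[["waz"]]
  hz <- lat[["haz"]]

  ## trajectory
  L <- matrix(NA_real_, K, 3, dimnames = list(NULL, c("sc", "pc", "wz")))
  L[1, ] <- c(sc, pc, wz)
  art_on <- integer(K)                      # on ART by grid time k
  death_at <- NA_integer_                   # grid index of the death row
  death_month <- NA_real_
  art_start <- NA_real_
  ac <- params$assignment_coefs; dc <- params$death_coefs
  log_art <- log(params$art_effect)
  alive_k <- K                              # last grid index with a state row
  for (k in 2:K) {
    st <- L[k - 1L, ]
    on <- art_on[k - 1L]
    if (on == 0L) {
      p_start <- stats::plogis(ac[[1]] + ac[[2]] * st[["sc"]] +
                               ac[[3]] * st[["pc"]] + ac[[4]] * st[["wz"]])
      if (stats::runif(1) < p_start) {
        on <- 1L
        art_start <- grid[k - 1L]           # decided at the preceding visit
        art_on[k - 1L] <- 1L                # on ART from that visit onwards
      }
    }
    art_on[k] <- on
    p_death <- stats::plogis(dc[[1]] + dc[[2]] * st[["sc"]] +
                             dc[[3]] * st[["pc"]] + dc[[4]] * st[["wz"]] +
                             log_art * on)
    if (stats::runif(1) < p_death) {
      death_at <- k
      death_month <- grid[k - 1L] +
        stats::runif(1) * (grid[k] - grid[k - 1L])
      alive_k <- k - 1L
      break
    }
    ar <- params$ar
    eps <- stats::rnorm(3)
    L[k, "sc"] <- max(0, ar$sqrt_cd4[["intercept"]] +
                        ar$sqrt_cd4[["lag"]] * st[["sc"]] +
                        ar$sqrt_cd4[["art"]] * on + ar$sqrt_cd4[["sd"]] * eps[1])
    L[k, "pc"] <- clamp(ar$cd4pct[["intercept"]] +
                          ar$cd4pct[["lag"]] * st[["pc"]] +
                          ar$cd4pct[["art"]] * on + ar$cd4pct[["sd"]] * eps[2],
                        0, 100)
    L[k, "wz"] <- ar$waz[["intercept"]] + ar$waz[["lag"]] * st[["wz"]] +
      ar$waz[["art"]] * on + ar$waz[["sd"]] * eps[3]
    alive_k <- k
  }

  ## ground-truth panel (pre-observation-process)
  rows <- seq_len(if (is.na(death_at)) alive_k else death_at)
  truth <- list(
    id = rep(id, length(rows)), t = grid[rows],
    cd4 = L[rows, "sc"]^2, cd4pct = L[rows, "pc"], waz = L[rows, "wz"],
    art = art_on[rows],
    death = as.integer(!is.na(death_at) & rows == death_at))

  ## ---- observation process (outcomes fixed from here on) ----
  visit_k <- seq_len(alive_k)               # grid indices with a visit
  ## loss to follow-up: surviving children may drop out of care
  if (is.na(death_at) && params$ltfu_hazard > 0 && alive_k >= 2L) {
    u <- stats::runif(alive_k - 1L)
    drop <- which(u < params$ltfu_hazard)
    if (length(drop)) visit_k <- seq_len(drop[1L])  # last visit before drop-out
  }
  ## visit-time jitter
  vt <- grid[visit_k]
  if (params$jitter && length(visit_k) > 1L) {
    amp <- ifelse(grid[visit_k] == 1, 0.4, 1)
    jit <- stats::runif(length(visit_k), -1, 1) * amp
    jit[1L] <- 0
    vt <- grid[visit_k] + jit
  }
  ## missing-at-random recording gaps, depending on observed history (last
  ## observed WAZ, centred at the population location)
  mr <- params$missing_rate
  rate <- c(cd4 = mr, cd4pct = min(1, 1.3 * mr), waz = mr)
  base_rate <- c(cd4 = mr, cd4pct = min(1, 1.5 * mr), waz = mr,
                 haz = min(1, 2 * mr))
  obs <- matrix(TRUE, length(visit_k), 3,
                dimnames = list(NULL, c("cd4", "cd4pct", "waz")))
  haz_obs <- stats::runif(1) >= base_rate[["haz"]]
  ## MAR: the missingness shift uses only the last *previously observed* WAZ
  ## (centred at the population location); before any WAZ is observed the
  ## shift is zero, so enrolment recording gaps are completely at random.
  last_waz <- -1.4
  for (j in seq_along(visit_k)) {
    r <- if (j == 1L) base_rate[1:3] else rate
    shift <- params$mar_coef * (last_waz + 1.4)
    u3 <- stats::runif(3)
    obs[j, ] <- u3 >= stats::plogis(stats::qlogis(r) + shift)
    if (obs[j, "waz"]) last_waz <- L[visit_k[j], "wz"]
  }
  v_cd4 <- ifelse(obs[, "cd4"], L[visit_k, "sc"]^2, NA_real_)
  v_pct <- ifelse(obs[, "cd4pct"], L[visit_k, "pc"], NA_real_)
  v_waz <- ifelse(obs[, "waz"], L[visit_k, "wz"], NA_real_)

  ## prior-ART and no-follow-up records (such children fail eligibility)
  prior_art <- stats::runif(1) < params$prior_art_prob
  no_fup <- stats::runif(1) < params$no_followup_prob
  rec_art <- art_start
  rec_death <- death_month
  if (prior_art) rec_art <- -3
  if (no_fup) {
    vt <- vt[1L]; v_cd4 <- v_cd4[1L]; v_pct <- v_pct[1L]; v_waz <- v_waz[1L]
    rec_art <- NA_real_
    rec_death <- NA_real_
  }
  last_contact <- if (!no_fup && !is.na(rec_death)) rec_death else max(vt)

  list(
    baseline = list(age = age, sex = sex, region = region,
                    cd4 = v_cd4[1L], cd4pct = v_pct[1L], waz = v_waz[1L],
                    haz = if (haz_obs) hz else NA_real_),
    visits = list(id = rep(id, length(vt)), time = vt, cd4 = v_cd4,
                  cd4pct = v_pct, waz = v_waz),
    events = list(art_start = rec_art, death = rec_death,
                  last_contact = last_contact),
    truth = truth)
}

#' Exact counterfactual mortality under a treatment rule
#'
#' Brute-force Monte-Carlo evaluation of the generator's ground truth: `n_mc`
#' children are drawn from the baseline distribution and followed forward with
#' treatment *forced* by the regime (no assignment model, no missingness, no
#' loss to follow-up), giving the exact counterfactual cumulative mortality at
#' every grid time up to the horizon. All regimes evaluated with the same
#' `params` share the random draws, so curves for different rules are
#' compared on common random numbers.
#'
#' @param params A [sim_params()] object.
#' @param regime A [regime()] object.
#' @param n_mc Number of Monte-Carlo children (>= 1).
#' @param seed Optional seed; defaults to a stream derived from
#'   `params$seed`.
#' @return A `mortality_curve`: data frame with columns `time` (months) and
#'   `mortality` (cumulative probability of death by `time`), nondecreasing.
#' @examples
#' p <- sim_params(n_children = 0, seed = 1)
#' tr <- true_regime_mortality(p, regime("never"), n_mc = 2000)
#' tail(tr, 3)
#' @export
true_regime_mortality <- function(params, regime, n_mc, seed = NULL) {
  stopifnot(inherits(params, "sim_params"), inherits(regime, "art_regime"))
  if (!is.numeric(n_mc) || length(n_mc) != 1L || n_mc < 1)
    stop("`n_mc` must be at least 1", call. = FALSE)
  n_mc <- as.integer(n_mc)
  seed <- seed %||% derive_seed(params$seed, 999983L)
  grid <- visit_grid(params$horizon_months)
  K <- length(grid)
  b <- params$baseline
  ar <- params$ar; dc <- params$death_coefs
  log_art <- log(params$art_effect)

  with_seed(seed, {
    Z <- matrix(stats::rnorm(4L * n_mc), nrow = 4L)
    lat <- b$mean + b$sd * crossprod(chol(b$corr), Z)
    rownames(lat) <- names(b$mean)
    sc <- pmax(lat["sqrt_cd4", ], 0)
    pc <- clamp(lat["cd4pct", ], 0, 100)
    wz <- lat["waz", ]
    alive <- rep(TRUE, n_mc)
    art <- rep(0L, n_mc)
    dead_by <- matrix(FALSE, n_mc, K)
    for (k in 2:K) {
      art <- pmax(art, regime_decision(regime, cd4 = sc^2, cd4pct = pc,
                                       on_art = art))
      p_death <- stats::plogis(dc[[1]] + dc[[2]] * sc + dc[[3]] * pc +
                               dc[[4]] * wz + log_art * art)
      u <- stats::runif(n_mc)
      new_dead <- alive & (u < p_death)
      alive <- alive & !new_dead
      dead_by[, k] <- dead_by[, k - 1L] | new_dead
      eps1 <- stats::rnorm(n_mc); eps2 <- stats::rnorm(n_mc)
      eps3 <- stats::rnorm(n_mc)
      sc_new <- pmax(0, ar$sqrt_cd4[["intercept"]] +
                       ar$sqrt_cd4[["lag"]] * sc + ar$sqrt_cd4[["art"]] * art +
                       ar$sqrt_cd4[["sd"]] * eps1)
      pc_new <- clamp(ar$cd4pct[["intercept"]] + ar$cd4pct[["lag"]] * pc +
                        ar$cd4pct[["art"]] * art + ar$cd4pct[["sd"]] * eps2,
                      0, 100)
      wz_new <- ar$waz[["intercept"]] + ar$waz[["lag"]] * wz +
        ar$waz[["art"]] * art + ar$waz[["sd"]] * eps3
      sc <- ifelse(alive, sc_new, sc)
      pc <- ifelse(alive, pc_new, pc)
      wz <- ifelse(alive, wz_new, wz)
    }
    mortality_curve(grid, colMeans(dead_by), label = regime$label,
                    n = n_mc)
  })
}

mortality_curve <- function(time, mortality, label = NULL, n = NA_integer_) {
  structure(data.frame(time = time, mortality = mortality),
            label = label, n = n, class = c("mortality_curve", "data.frame"))
}

#' @export
plot.mortality_curve <- function(x, add = FALSE, col = 1, lty = 1, ...) {
  if (!add)
    plot(x$time, 100 * x$mortality, type = "s", col = col, lty = lty,
         xlab = "Months since first visit",
         ylab = "Cumulative mortality (%)", ...)
  else graphics::lines(x$time, 100 * x$mortality, type = "s", col = col,
                       lty = lty, ...)
  invisible(x)
}
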