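## Steps 2-6 of the g-computation algorithm: forward Monte-Carlo simulation
## of counterfactual panels under each dynamic regime, mortality estimation,
## child-level bootstrap confidence intervals, and combination across
## imputations.

## Baseline frame (one row per child) drawn from the panel's enrolment rows;
## requires complete post-imputation baselines.
baseline_frame <- function(panel) {
  b <- as.data.frame(panel[panel$t == 0, , drop = FALSE])
  data.frame(id = b$id, age = b$age, sex = b$sex, region = b$region,
             sqrt_cd4_0 = sqrt(pmax(b$cd4_0, 0)), cd4pct_0 = b$cd4pct_0,
             waz_0 = b$waz_0, haz_0 = b$haz_0,
             sqrt_cd4 = sqrt(pmax(b$cd4, 0)), cd4pct = b$cd4pct,
             waz = b$waz)
}

#' Simulate counterfactual follow-up under a treatment rule
#'
#' Step 2 of the algorithm: starting from every child's observed enrolment
#' state, at each grid time the treatment indicator is set by the regime
#' applied to the *simulated* state at the interval start (absorbing),
#' death over the interval is drawn from the fitted logistic model, and the
#' surviving children's confounders are drawn from normal distributions with
#' mean given by the fitted additive models and standard deviation equal to
#' the models' residual SD. Simulated sqrt-CD4 is truncated at 0 before
#' squaring and CD4% is clamped to \[0, 100\]. There is no censoring in the
#' simulated world; a child's follow-up ends only at simulated death.
#'
#' All draws are made for every child at every step (dead children's draws
#' are discarded), so two regimes simulated with the same seed share their
#' random numbers — regimes are compared on common random numbers.
#'
#' @param baselines Output of the internal baseline extractor (a data frame
#'   with enrolment state and baseline covariates), or an `interval_panel`
#'   from which it is taken.
#' @param models A complete [fit_model_set()] object.
#' @param regime A [regime()] object.
#' @param seed Seed for the simulation stream.
#' @param mc_factor Number of simulated trajectories per observed child
#'   (default 1).
#' @param keep_states Keep the simulated confounder trajectories (for
#'   diagnostics)?
#' @return An object of class `sim_panel`: grid times, per-trajectory death
#'   time (`Inf` if alive at the horizon), and optionally the state array.
#' @export
simulate_forward <- function(baselines, models, regime, seed = 1L,
                             mc_factor = 1L, keep_states = FALSE) {
  stopifnot(inherits(models, "model_set"), inherits(regime, "art_regime"))
  if (inherits(baselines, "interval_panel"))
    baselines <- baseline_frame(baselines)
  need <- c("age", "sex", "region", "sqrt_cd4_0", "cd4pct_0", "waz_0",
            "haz_0", "sqrt_cd4", "cd4pct", "waz")
  if (any(!stats::complete.cases(baselines[, need])))
    stop("baseline rows must be complete (impute first)", call. = FALSE)
  for (tg in c("sqrt_cd4", "cd4pct", "waz"))
    for (k in seq_along(models$times))
      if (is.null(model_at(models, tg, models$times[k])$fit))
        stop("incomplete model set", call. = FALSE)

  if (mc_factor > 1L)
    baselines <- baselines[rep(seq_len(nrow(baselines)), mc_factor), ,
                           drop = FALSE]
  n <- nrow(baselines)
  times <- models$times
  sc <- baselines$sqrt_cd4
  pc <- baselines$cd4pct
  wz <- baselines$waz
  art <- rep(0L, n)
  alive <- rep(TRUE, n)
  death_time <- rep(Inf, n)
  states <- if (keep_states)
    array(NA_real_, c(n, length(times) + 1L, 3L),
          dimnames = list(NULL, NULL, c("sqrt_cd4", "cd4pct", "waz")))
  if (keep_states) states[, 1L, ] <- cbind(sc, pc, wz)

  nd <- baselines
  ## design cache shared by the four models at each step: baseline-variable
  ## bases persist across steps, state-variable and treatment blocks are
  ## invalidated before every step
  cache <- new.env(parent = emptyenv())
  with_seed(seed, {
    for (k in seq_along(times)) {
      tt <- times[k]
      art <- pmax(art, regime_decision(regime, cd4 = sc^2, cd4pct = pc,
                                       on_art = art))
      nd$sqrt_cd4_prev <- sc; nd$cd4pct_prev <- pc; nd$waz_prev <- wz
      nd$art_prev <- art
      nd$t <- tt
      stale <- grep("^(sqrt_cd4_prev|cd4pct_prev|waz_prev|t|PAR)\\|",
                    ls(cache), value = TRUE)
      if (length(stale)) rm(list = stale, envir = cache)
      if (!is.null(models$cd4_breaks))
        nd$cd4_0_band <- cut(nd$sqrt_cd4_0^2, models$cd4_breaks,
                             include.lowest = TRUE)
      dm <- model_at(models, "death", tt)
      p_death <- predict(dm$fit, nd, type = "response", cache = cache)
      u <- stats::runif(n)
      new_dead <- alive & (u < p_death)
      death_time[new_dead] <- tt
      alive <- alive & !new_dead
      draw <- function(target) {
        m <- model_at(models, target, tt)
        mu <- predict(m$fit, nd, cache = cache)
        mu + m$fit$sigma * stats::rnorm(n)
      }
      sc_new <- pmax(draw("sqrt_cd4"), 0)
      pc_new <- clamp(draw("cd4pct"), 0, 100)
      wz_new <- draw("waz")
      sc <- ifelse(alive, sc_new, sc)
      pc <- ifelse(alive, pc_new, pc)
      wz <- ifelse(alive, wz_new, wz)
      if (keep_states) states[, k + 1L, ] <- cbind(sc, pc, wz)
    }
  })
  structure(list(times = c(0L, times), death_time = death_time, n = n,
                 regime = regime$label, states = states),
            class = "sim_panel")
}

#' Cumulative mortality of a simulated panel
#'
#' Step 3: the counterfactual cumulative mortality at each grid time is the
#' fraction of simulated trajectories dead by that time; nondecreasing by
#' construction.
#'
#' @param sim A `sim_panel` from [simulate_forward()].
#' @return A `mortality_curve` data frame (`time`, `mortality`).
#' @export
estimate_mortality <- function(sim) {
  stopifnot(inherits(sim, "sim_panel"))
  if (sim$n == 0L) stop("empty simulated panel", call. = FALSE)
  mortality_curve(sim$times,
                  vapply(sim$times, function(tt) mean(sim$death_time <= tt),
                         numeric(1)),
                  label = sim$regime, n = sim$n)
}

## Child-level resample of a panel: sampled children keep whole trajectories
## and receive fresh ids.
resample_children <- function(panel, ids, index = NULL) {
  index <- index %||% split(seq_len(nrow(panel)), panel$id)
  picked <- index[as.character(ids)]
  rows <- unlist(picked, use.names = FALSE)
  out <- as.data.frame(panel)[rows, , drop = FALSE]
  out$id <- rep(seq_along(ids), lengths(picked))
  rownames(out) <- NULL
  structure(out, grid = attr(panel, "grid"),
            horizon = attr(panel, "horizon"), events = NULL,
            class = class(panel))
}

#' Estimate counterfactual mortality under dynamic ART-initiation rules
#'
#' The core estimator: for each imputed panel it fits the full model set
#' (Step 1), simulates every child forward under each regime (Step 2),
#' estimates the counterfactual cumulative mortality curve (Steps 3-4),
#' repeats everything on `B` child-level bootstrap resamples per imputation
#' (Step 5), and combines across the `m` imputations (Step 6): the point
#' curve is the Rubin's-rules mean of the per-imputation full-data
#' estimates, and the 95% confidence bounds are the 2.5th and 97.5th
#' percentiles of all `B x m` bootstrap estimates pooled across
#' imputations. Bootstrap refits keep the model structure and smoothing
#' weights frozen at the full-data fit unless `refit_lambda = TRUE`.
#' The whole procedure is deterministic given `seed`.
#'
#' @param panels An `imputed_set` (see [impute_panel()]), a list of complete
#'   `interval_panel`s, or a single complete panel.
#' @param regimes A list of [regime()] objects (default the paper's five
#'   strategies, [standard_regimes()]).
#' @param B Number of bootstrap resamples per imputation (>= 1).
#' @param seed Master seed controlling all resampling and simulation.
#' @param mc_factor Simulated trajectories per child for the point-estimate
#'   simulations (>= 1). Bootstrap replicates always simulate one trajectory
#'   per resampled child: their Monte-Carlo noise is folded into the
#'   bootstrap distribution the percentile bounds summarise.
#' @param refit_lambda Re-run the GCV smoothing search in every bootstrap
#'   replicate instead of freezing the smoothing weights.
#' @param fit_args List of further arguments for [fit_model_set()].
#' @param verbose Print progress.
#' @return An object of class `gcomp` with the per-regime point curves,
#'   percentile bounds, bootstrap draws, and metadata; see
#'   [summary.gcomp()].
#' @export
run_gcomputation <- function(panels, regimes = standard_regimes(), B = 200L,
                             seed = 1L, mc_factor = 1L,
                             refit_lambda = FALSE, fit_args = list(),
                             verbose = FALSE) {
  if (inherits(panels, "imputed_set")) panels <- panels$panels
  if (inherits(panels, "interval_panel")) panels <- list(panels)
  if (!length(panels)) stop("`panels` must be nonempty", call. = FALSE)
  if (B < 1L) stop("`B` must be at least 1", call. = FALSE)
  if (is.null(names(regimes)))
    names(regimes) <- vapply(regimes, `[[`, character(1), "label")
  m <- length(panels)
  R <- length(regimes)
  grid <- attr(panels[[1L]], "grid")
  Tn <- length(grid)

  fits <- vector("list", m)
  point_j <- array(NA_real_, c(m, R, Tn))
  for (j in seq_len(m)) {
    if (verbose) message("fitting model set, imputation ", j)
    fits[[j]] <- do.call(fit_model_set, c(list(panels[[j]]), fit_args))
    bf <- baseline_frame(panels[[j]])
    for (r in seq_len(R)) {
      # one simulation stream shared by all imputations and regimes:
      # differences between curves then reflect the models, not the draws
      sim <- simulate_forward(bf, fits[[j]], regimes[[r]],
                              seed = derive_seed(seed, 0L),
                              mc_factor = mc_factor)
      point_j[j, r, ] <- estimate_mortality(sim)$mortality
    }
  }
  point <- apply(point_j, c(2, 3), mean)

  draws <- array(NA_real_, c(B * m, R, Tn))
  idx_cache <- lapply(panels, function(p) split(seq_len(nrow(p)), p$id))
  row_d <- 0L
  for (b in seq_len(B)) {
    for (j in seq_len(m)) {
      row_d <- row_d + 1L
      if (verbose && row_d %% 10L == 0L)
        message("bootstrap replicate ", row_d, " of ", B * m)
      ids_all <- unique(panels[[j]]$id)
      ok <- FALSE
      for (attempt in 0:5) {
        ids <- with_seed(derive_seed(seed, 1L, b, j, attempt),
                         sample(ids_all, length(ids_all), replace = TRUE))
        pb <- resample_children(panels[[j]], ids, idx_cache[[j]])
        ms_b <- tryCatch({
          if (refit_lambda)
            do.call(fit_model_set, c(list(pb), fit_args))
          else refit_model_set(fits[[j]], pb)
        }, error = function(e) NULL)
        if (!is.null(ms_b)) { ok <- TRUE; break }
      }
      if (!ok)
        stop(sprintf("bootstrap replicate (%d, %d) failed after 5 retries",
                     b, j), call. = FALSE)
      bf_b <- baseline_frame(pb)
      for (r in seq_len(R)) {
        sim <- simulate_forward(bf_b, ms_b, regimes[[r]],
                                seed = derive_seed(seed, 2L, b),
                                mc_factor = 1L)
        draws[row_d, r, ] <- estimate_mortality(sim)$mortality
      }
    }
  }
  lower <- apply(draws, c(2, 3), stats::quantile, probs = 0.025)
  upper <- apply(draws, c(2, 3), stats::quantile, probs = 0.975)
  dimnames(point) <- dimnames(lower) <- dimnames(upper) <-
    list(names(regimes), grid)
  structure(list(times = grid, regimes = regimes,
                 point = point, lower = lower, upper = upper,
                 draws = draws, per_imputation = point_j,
                 B = B, m = m, seed = seed, mc_factor = mc_factor,
                 n = length(unique(panels[[1L]]$id)),
                 call = match.call()),
            class = "gcomp")
}

#' @export
print.gcomp <- function(x, ...) {
  cat("G-computation estimate of counterfactual cumulative mortality\n")
  cat(sprintf("  %d children, %d imputation(s), %d bootstrap resamples each\n",
              x$n, x$m, x$B))
  print(round(100 * mortality_table(x), 2))
  invisible(x)
}

#' Mortality table at selected follow-up times
#'
#' @param x A `gcomp` fit.
#' @param at Follow-up times (months) at which to tabulate (default 12, 24,
#'   36).
#' @return Matrix of cumulative mortality (proportions), regimes by times.
#' @export
mortality_table <- function(x, at = c(12, 24, 36)) {
  stopifnot(inherits(x, "gcomp"))
  at <- at[at %in% x$times]
  x$point[, as.character(at), drop = FALSE]
}

#' Summarise a g-computation fit
#'
#' @param object A `gcomp` object.
#' @param at Follow-up times (months) to report.
#' @param ... Unused.
#' @return A data frame with one row per regime and time: estimate and 95%
#'   percentile-bootstrap bounds, in percent.
#' @export
summary.gcomp <- function(object, at = c(12, 24, 36), ...) {
  at <- at[at %in% object$times]
  out <- expand.grid(regime = rownames(object$point), months = at,
                     stringsAsFactors = FALSE)
  cols <- as.character(out$months)
  ix <- cbind(match(out$regime, rownames(object$point)),
              match(cols, colnames(object$point)))
  out$estimate_pct <- 100 * object$point[ix]
  out$lower_pct <- 100 * object$lower[ix]
  out$upper_pct <- 100 * object$upper[ix]
  class(out) <- c("summary.gcomp", "data.frame")
  out
}

#' @export
print.summary.gcomp <- function(x, ...) {
  df <- as.data.frame(x)
  df$estimate_pct <- sprintf("%.1f%%", df$estimate_pct)
  df$ci <- sprintf("(%.1f%%-%.1f%%)", df$lower_pct, df$upper_pct)
  print(df[, c("regime", "months", "estimate_pct", "ci")], row.names = FALSE)
  invisible(x)
}

#' @export
coef.gcomp <- function(object, ...) object$point

#' Plot counterfactual mortality curves
#'
#' Estimated cumulative mortality per regime over follow-up, with dashed
#' 95% percentile-bootstrap bounds.
#'
#' @param x A `gcomp` object.
#' @param which Regimes to draw (indices or names; default all).
#' @param col Colours, recycled over regimes.
#' @param ci Draw the bounds?
#' @param ... Passed to `plot()`.
#' @export
plot.gcomp <- function(x, which = seq_len(nrow(x$point)),
                       col = seq_along(which), ci = TRUE, ...) {
  ymax <- max(x$upper[which, , drop = FALSE]) * 100
  plot(NA, xlim = range(x$times), ylim = c(0, ymax * 1.05),
       xlab = "Months since first visit", ylab = "Cumulative mortality (%)",
       ...)
  for (i in seq_along(which)) {
    r <- which[i]
    graphics::lines(x$times, 100 * x$point[r, ], type = "s", col = col[i],
                    lwd = 2)
    if (ci) {
      graphics::lines(x$times, 100 * x$lower[r, ], type = "s", col = col[i],
                      lty = 2)
      graphics::lines(x$times, 100 * x$upper[r, ], type = "s", col = col[i],
                      lty = 2)
    }
  }
  graphics::legend("topleft", legend = rownames(x$point)[which], col = col,
                   lwd = 2, bty = "n")
  invisible(x)
}
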