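## Step-1 model fitting: per-grid-time additive models for the three
## time-dependent confounders (sqrt CD4, CD4%, WAZ) and a logistic additive
## model for death, each on the covariate recipe
##   state at the interval start (sqrt CD4, CD4%, WAZ, on-ART indicator),
##   baseline markers (sqrt CD4_0, CD4%_0, WAZ_0, HAZ_0),
##   demographics (age, sex, region).
## Sparse time points fall back to a pooled fit across time with a smooth
## time effect.

recipe_default <- function(pooled = FALSE) {
  list(linear = c("art_prev", "sex", "region"),
       smooth = c("sqrt_cd4_prev", "cd4pct_prev", "waz_prev",
                  "sqrt_cd4_0", "cd4pct_0", "waz_0", "haz_0", "age",
                  if (pooled) "t"))
}

#' Person-interval transition table
#'
#' Expands an interval panel into one row per child-interval: the response
#' columns at the interval's end (`sqrt_cd4`, `cd4pct`, `waz`, `death`,
#' `cens`) next to the covariates at the interval's start (`*_prev`,
#' `art_prev`) and the child's baseline covariates. This is the fitting table
#' for the confounder and death models.
#'
#' @param panel An `interval_panel`.
#' @return Data frame of transitions with attribute `"grid"`.
#' @export
build_transitions <- function(panel) {
  stopifnot(inherits(panel, "interval_panel"))
  df <- as.data.frame(panel)
  df <- df[order(df$id, df$t), , drop = FALSE]
  lag_same <- c(FALSE, df$id[-1L] == df$id[-nrow(df)])
  lg <- function(x) c(NA, x[-length(x)])
  out <- data.frame(
    id = df$id, t = df$t,
    sqrt_cd4 = sqrt(pmax(df$cd4, 0)), cd4pct = df$cd4pct, waz = df$waz,
    death = df$death, cens = df$cens,
    sqrt_cd4_prev = lg(sqrt(pmax(df$cd4, 0))), cd4pct_prev = lg(df$cd4pct),
    waz_prev = lg(df$waz), art_prev = lg(df$art),
    age = df$age, sex = df$sex, region = df$region,
    sqrt_cd4_0 = sqrt(pmax(df$cd4_0, 0)), cd4pct_0 = df$cd4pct_0,
    waz_0 = df$waz_0, haz_0 = df$haz_0)
  out <- out[lag_same, , drop = FALSE]
  rownames(out) <- NULL
  structure(out, grid = attr(panel, "grid"))
}

covar_cols <- function(pooled = FALSE) {
  rc <- recipe_default(pooled)
  unique(c(rc$linear, setdiff(rc$smooth, "t")))
}

#' Fit one time-dependent confounder model
#'
#' Additive linear model for a confounder at the end of an interval given the
#' state at its start, baselines and demographics, with ART under an
#' intention-to-treat coding. CD4 is handled on the square-root scale on both
#' sides. With `time = NULL` a pooled model across all intervals with a
#' smooth time effect is fitted.
#'
#' @param transitions Output of [build_transitions()] (complete cases are
#'   selected internally).
#' @param target One of `"sqrt_cd4"`, `"cd4pct"`, `"waz"`.
#' @param time Grid time of the interval end, or `NULL` for the pooled fit.
#' @param ... Passed to [fit_additive()].
#' @return A `padd` fit; its `sigma` is the residual SD used when simulating.
#' @export
fit_confounder_model <- function(transitions, target, time = NULL, ...) {
  target <- match.arg(target, c("sqrt_cd4", "cd4pct", "waz"))
  pooled <- is.null(time)
  rows <- transitions$death == 0L & transitions$cens == 0L &
    !is.na(transitions[[target]])
  if (!pooled) rows <- rows & transitions$t == time
  d <- transitions[rows, , drop = FALSE]
  cc <- stats::complete.cases(d[, c(covar_cols(), target)])
  d <- d[cc, , drop = FALSE]
  rc <- recipe_default(pooled)
  fit_additive(d[[target]], d, linear = rc$linear, smooth = rc$smooth, ...)
}

#' Fit the per-interval death model
#'
#' Logistic additive model for death in an interval given the state at the
#' interval's start, baselines and demographics, and the on-ART indicator.
#'
#' @inheritParams fit_confounder_model
#' @param firth Use Firth's bias-reduced scoring (default `TRUE`: deaths are
#'   rare, and the ordinary MLE of a rare-event logistic model is biased
#'   away from zero).
#' @return A `padd` fit (binomial family).
#' @export
fit_death_model <- function(transitions, time = NULL, firth = TRUE, ...) {
  pooled <- is.null(time)
  rows <- transitions$cens == 0L
  if (!pooled) rows <- rows & transitions$t == time
  d <- transitions[rows, , drop = FALSE]
  cc <- stats::complete.cases(d[, covar_cols()])
  d <- d[cc, , drop = FALSE]
  if (sum(d$death) < 1L || sum(1L - d$death) < 1L)
    stop("death model needs at least one death and one survivor",
         call. = FALSE)
  rc <- recipe_default(pooled)
  fit_additive(d$death, d, linear = rc$linear, smooth = rc$smooth,
               family = "binomial", firth = firth, ...)
}

#' Fit the full model set of the g-computation algorithm
#'
#' Fits, for every grid time `t >= 1`, additive linear models for the three
#' time-dependent confounders and a logistic additive model for death. A time
#' point whose fitting table falls below the row floor (confounder models) or
#' whose death count falls below the death floor uses a pooled fit across all
#' times with a smooth time effect instead; with the default death floor the
#' death model is in practice the pooled fit, which keeps the
#' events-per-coefficient ratio workable at realistic death counts.
#'
#' @param panel A complete (post-imputation) `interval_panel`.
#' @param floors Named vector: minimum `rows` per confounder fit and
#'   minimum `deaths` per death fit before the pooled fallback engages.
#' @param explore_interactions Logical: at the pooled level, consider
#'   interactions of each lagged-confounder smooth with baseline-CD4
#'   tertiles and with region, keeping one only if it strictly lowers the
#'   GCV score (default `FALSE`).
#' @param ... Passed to [fit_additive()] (e.g. `nbasis`, `lambda`,
#'   `sweeps`).
#' @return An object of class `model_set`.
#' @export
fit_model_set <- function(panel, floors = c(rows = 25, deaths = 25),
                          explore_interactions = FALSE, ...) {
  trans <- build_transitions(panel)
  grid <- attr(trans, "grid")
  times <- grid[-1L]
  targets <- c("sqrt_cd4", "cd4pct", "waz")

  cc_all <- stats::complete.cases(trans[, covar_cols()])
  ## shared smooth structures: one common basis (knots from the full
  ## fitting table) reused by every per-time and pooled fit, so simulation
  ## can evaluate each variable's basis once per step
  dots <- list(...)
  nb <- dots$nbasis %||% 8
  dg <- dots$degree %||% 3
  po <- dots$penalty_order %||% 2
  cc_tr <- trans[cc_all, , drop = FALSE]
  shared <- list()
  for (nm in c(recipe_default(pooled = TRUE)$smooth))
    shared[[nm]] <- smooth_structure(cc_tr[[nm]], nb, dg, po)
  n_rows <- table(factor(trans$t[cc_all & trans$cens == 0L &
                                   trans$death == 0L], levels = times))
  n_deaths <- tapply(trans$death[cc_all & trans$cens == 0L],
                     factor(trans$t[cc_all & trans$cens == 0L],
                            levels = times), sum)
  n_deaths[is.na(n_deaths)] <- 0

  conf_pooled_at <- as.vector(n_rows) < floors[["rows"]]
  death_pooled_at <- as.vector(n_deaths) < floors[["deaths"]]

  smooth_by <- NULL
  cd4_breaks <- NULL
  if (explore_interactions) {
    sel <- explore_pooled_interactions(trans, ...)
    smooth_by <- sel$smooth_by
    cd4_breaks <- sel$cd4_breaks
    if (!is.null(cd4_breaks))
      trans$cd4_0_band <- cut(trans$sqrt_cd4_0^2, cd4_breaks,
                              include.lowest = TRUE)
  }

  models <- list()
  for (tg in targets) {
    per_time <- stats::setNames(vector("list", length(times)),
                                as.character(times))
    for (k in seq_along(times)) {
      if (conf_pooled_at[k]) next
      per_time[k] <- list(tryCatch(
        fit_confounder_model(trans, tg, time = times[k],
                             smooth_by = smooth_by,
                             smooth_structures = shared, ...),
        error = function(e) NULL))
    }
    failed <- conf_pooled_at | vapply(per_time, is.null, logical(1))
    pooled <- if (any(failed))
      fit_confounder_model(trans, tg, time = NULL, smooth_by = smooth_by,
                           smooth_structures = shared, ...)
    models[[tg]] <- list(per_time = per_time, pooled = pooled,
                         pooled_at = failed)
  }

  death_per_time <- stats::setNames(vector("list", length(times)),
                                    as.character(times))
  for (k in seq_along(times)) {
    if (death_pooled_at[k]) next
    death_per_time[k] <- list(tryCatch(
      fit_death_model(trans, time = times[k], smooth_by = smooth_by,
                      smooth_structures = shared, ...),
      error = function(e) NULL))
  }
  dfailed <- death_pooled_at | vapply(death_per_time, is.null, logical(1))
  death_pooled <- if (any(dfailed)) {
    tryCatch(fit_death_model(trans, time = NULL, smooth_by = smooth_by,
                             smooth_structures = shared, ...),
             error = function(e) {
               # no deaths anywhere: flat empirical hazard
               const_model(mean(trans$death[trans$cens == 0L]))
             })
  }
  structure(list(times = times, grid = grid, models = models,
                 death = list(per_time = death_per_time,
                              pooled = death_pooled, pooled_at = dfailed),
                 smooth_by = smooth_by, cd4_breaks = cd4_breaks,
                 n = length(unique(panel$id))),
            class = "model_set")
}

## Pooled-level greedy interaction search: each lagged-confounder smooth may
## vary by baseline-CD4 tertile or by region; an interaction is kept only if
## it strictly lowers the pooled death-target GCV score.
explore_pooled_interactions <- function(trans, ...) {
  cc <- stats::complete.cases(trans[, covar_cols()])
  d <- trans[cc & trans$cens == 0L & trans$death == 0L, , drop = FALSE]
  qs <- stats::quantile(d$sqrt_cd4_0^2, c(0, 1/3, 2/3, 1), na.rm = TRUE)
  qs[1] <- -Inf; qs[length(qs)] <- Inf
  d$cd4_0_band <- cut(d$sqrt_cd4_0^2, qs, include.lowest = TRUE)
  rc <- recipe_default(pooled = TRUE)
  base <- list(linear = rc$linear, smooth = rc$smooth)
  cands <- list(base)
  for (sm in c("sqrt_cd4_prev", "cd4pct_prev", "waz_prev"))
    for (by in c("cd4_0_band", "region"))
      cands[[length(cands) + 1L]] <-
        utils::modifyList(base, list(smooth_by = stats::setNames(list(by), sm)))
  sel <- gcv_select(cands, d$sqrt_cd4, d, family = "gaussian", ...)
  chosen <- if (sel$index > 1L) cands[[sel$index]]$smooth_by else NULL
  list(smooth_by = chosen, cd4_breaks = if (!is.null(chosen)) qs)
}

#' Refit a model set on new data with frozen structure
#'
#' Re-estimates every coefficient of a fitted [fit_model_set()] object on a
#' new panel (typically a bootstrap resample) while keeping each model's
#' knots, constraints and smoothing weights fixed at the original fit.
#'
#' @param ms A `model_set`.
#' @param panel The new `interval_panel`.
#' @return A `model_set` of the same shape.
#' @export
refit_model_set <- function(ms, panel) {
  trans <- build_transitions(panel)
  if (!is.null(ms$cd4_breaks))
    trans$cd4_0_band <- cut(trans$sqrt_cd4_0^2, ms$cd4_breaks,
                            include.lowest = TRUE)
  ## shared row bookkeeping, computed once per refit
  cc <- stats::complete.cases(trans[, covar_cols()])
  alive <- trans$death == 0L & trans$cens == 0L
  uncens <- trans$cens == 0L
  by_time <- split(seq_len(nrow(trans)), trans$t)
  refit_conf <- function(old, target, time) {
    rows <- which(alive & cc & !is.na(trans[[target]]))
    if (!is.null(time)) rows <- intersect(rows, by_time[[as.character(time)]])
    d <- trans[rows, , drop = FALSE]
    fit_additive(d[[target]], d, structure = old)
  }
  refit_death <- function(old, time) {
    rows <- which(uncens & cc)
    if (!is.null(time)) rows <- intersect(rows, by_time[[as.character(time)]])
    if (inherits(old, "padd_const"))
      return(const_model(mean(trans$death[rows])))
    d <- trans[rows, , drop = FALSE]
    fit_additive(d$death, d, structure = old)
  }
  out <- ms
  for (tg in names(ms$models)) {
    mt <- ms$models[[tg]]
    for (k in seq_along(mt$per_time))
      if (!is.null(mt$per_time[[k]]))
        out$models[[tg]]$per_time[[k]] <-
          refit_conf(mt$per_time[[k]], tg, ms$times[k])
    if (!is.null(mt$pooled))
      out$models[[tg]]$pooled <- refit_conf(mt$pooled, tg, NULL)
  }
  for (k in seq_along(ms$death$per_time))
    if (!is.null(ms$death$per_time[[k]]))
      out$death$per_time[[k]] <- refit_death(ms$death$per_time[[k]],
                                             ms$times[k])
  if (!is.null(ms$death$pooled))
    out$death$pooled <- refit_death(ms$death$pooled, NULL)
  out$n <- length(unique(panel$id))
  out
}

## Resolve which fit serves target/time; returns list(fit, pooled flag).
## Exact [[-indexing: `pooled` may be absent and must not partial-match.
model_at <- function(ms, target, time) {
  k <- match(time, ms$times)
  if (target == "death") {
    if (!ms$death$pooled_at[k] && !is.null(ms$death$per_time[[k]]))
      return(list(fit = ms$death$per_time[[k]], pooled = FALSE))
    return(list(fit = ms$death[["pooled"]], pooled = TRUE))
  }
  mt <- ms$models[[target]]
  if (!mt$pooled_at[k] && !is.null(mt$per_time[[k]]))
    return(list(fit = mt$per_time[[k]], pooled = FALSE))
  list(fit = mt[["pooled"]], pooled = TRUE)
}

#' @export
print.model_set <- function(x, ...) {
  n_pool <- sum(vapply(x$models, function(m) sum(m$pooled_at), numeric(1)))
  cat(sprintf("g-computation model set: %d time points, %d children\n",
              length(x$times), x$n))
  cat(sprintf("  confounder fits using pooled fallback: %d of %d\n",
              n_pool, 3L * length(x$times)))
  cat(sprintf("  death model: %s\n",
              if (all(x$death$pooled_at)) "pooled across time"
              else "per time point (with pooled fallback)"))
  invisible(x)
}
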