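## Pre-ART time-to-threshold analyses: probability that a child presenting
## above the CD4 criteria falls below them during follow-up, by Kaplan-Meier
## (censoring ART start, death and LTFU) and by a competing-risk conditional
## cumulative-incidence estimator; plus the naive time-varying-treatment
## hazard comparison that illustrates confounding by indication.

## Per-child (time, type) of the first threshold crossing among pre-ART
## follow-up rows. type: 1 crossing, 2 competing event (ART start, death or
## LTFU), 0 administratively censored.
crossing_events <- function(panel, cd4_threshold, pct_threshold) {
  df <- as.data.frame(panel)
  df <- df[order(df$id, df$t), , drop = FALSE]
  elig <- df$t == 0 & !is.na(df$cd4) & !is.na(df$cd4pct) &
    df$cd4 >= cd4_threshold & df$cd4pct >= pct_threshold & df$art == 0L
  ids <- df$id[elig]
  if (!length(ids)) stop("no children start at or above both thresholds",
                         call. = FALSE)
  out <- data.frame(id = ids, time = NA_real_, type = NA_integer_)
  by_id <- split(df[df$id %in% ids, , drop = FALSE],
                 df$id[df$id %in% ids])
  for (i in seq_along(ids)) {
    ch <- by_id[[as.character(ids[i])]]
    tm <- NA_real_; ty <- 0L
    for (k in seq_len(nrow(ch))[-1L]) {
      if (ch$art[k] == 1L || ch$death[k] == 1L || ch$cens[k] == 1L) {
        tm <- ch$t[k]; ty <- 2L; break
      }
      crossed <- (!is.na(ch$cd4[k]) & ch$cd4[k] < cd4_threshold) |
        (!is.na(ch$cd4pct[k]) & ch$cd4pct[k] < pct_threshold)
      if (isTRUE(crossed)) { tm <- ch$t[k]; ty <- 1L; break }
    }
    if (is.na(tm)) { tm <- ch$t[nrow(ch)]; ty <- 0L }
    out$time[i] <- tm; out$type[i] <- ty
  }
  out
}

#' Kaplan-Meier probability of falling below a CD4 threshold
#'
#' Restricted to children presenting at or above *both* thresholds, the
#' event is the first grid time with CD4 below the count threshold or CD4%
#' below the percentage threshold, using pre-ART follow-up only; children
#' are censored at ART start, death or loss to follow-up. Returns the
#' crossing probability 1 - S(t) with Greenwood 95% confidence bounds.
#'
#' @param panel An `interval_panel`.
#' @param cd4_threshold,pct_threshold The CD4 criteria (defaults 750
#'   cells/mm3 and 25%).
#' @return A data frame of class `threshold_curve`: `time`, `estimate`
#'   (crossing probability), `lower`, `upper`, `n_risk`, `n_event`.
#' @export
km_threshold_crossing <- function(panel, cd4_threshold = 750,
                                  pct_threshold = 25) {
  ev <- crossing_events(panel, cd4_threshold, pct_threshold)
  sf <- survival::survfit(survival::Surv(ev$time, ev$type == 1L) ~ 1,
                          conf.type = "log")
  structure(data.frame(time = sf$time, estimate = 1 - sf$surv,
                       lower = 1 - sf$upper, upper = 1 - sf$lower,
                       n_risk = sf$n.risk, n_event = sf$n.event),
            n = nrow(ev), kind = "kaplan-meier",
            class = c("threshold_curve", "data.frame"))
}

#' Competing-risk conditional probability of falling below a CD4 threshold
#'
#' Treats ART initiation, death and loss to follow-up as competing events:
#' the estimate at each time is the Aalen-Johansen cumulative incidence of
#' crossing divided by one minus the cumulative incidence of a competing
#' event by that time, capped at 1; times where the denominator vanishes are
#' returned as missing with a warning. Confidence bounds are child-level
#' bootstrap percentiles.
#'
#' @inheritParams km_threshold_crossing
#' @param n_boot Number of bootstrap resamples for the 95% bounds
#'   (default 200).
#' @param seed Seed for the bootstrap.
#' @return A `threshold_curve` data frame (`time`, `estimate`, `lower`,
#'   `upper`).
#' @export
cif_threshold_crossing <- function(panel, cd4_threshold = 750,
                                   pct_threshold = 25, n_boot = 200L,
                                   seed = 1L) {
  ev <- crossing_events(panel, cd4_threshold, pct_threshold)
  times <- sort(unique(ev$time))
  est <- cif_conditional(ev, times)
  if (anyNA(est))
    warning("denominator reached 0; estimate undefined from that time on",
            call. = FALSE)
  bs <- matrix(NA_real_, n_boot, length(times))
  n <- nrow(ev)
  for (b in seq_len(n_boot)) {
    idx <- with_seed(derive_seed(seed, b), sample.int(n, n, replace = TRUE))
    bs[b, ] <- cif_conditional(ev[idx, , drop = FALSE], times)
  }
  lo <- apply(bs, 2, stats::quantile, probs = 0.025, na.rm = TRUE)
  hi <- apply(bs, 2, stats::quantile, probs = 0.975, na.rm = TRUE)
  structure(data.frame(time = times, estimate = est, lower = lo, upper = hi),
            n = n, kind = "competing-risk conditional",
            class = c("threshold_curve", "data.frame"))
}

## Aalen-Johansen state probabilities via survival::survfit on a multi-state
## factor, then the conditional estimate P(cross)/(1 - P(compete)). Event
## types absent from the data (possible in bootstrap resamples) contribute
## zero probability.
cif_conditional <- function(ev, times) {
  st <- factor(ev$type, levels = 0:2, labels = c("censor", "cross", "compete"))
  present <- unique(as.character(st))
  ev_states <- intersect(c("cross", "compete"), present)
  if (!length(ev_states)) return(rep(0, length(times)))
  st <- factor(as.character(st), levels = c("censor", ev_states))
  sf <- survival::survfit(survival::Surv(ev$time, st) ~ 1)
  p_cross <- summary_pstate(sf, times, "cross")
  p_comp <- summary_pstate(sf, times, "compete")
  denom <- 1 - p_comp
  ifelse(denom > 1e-12, pmin(p_cross / denom, 1), NA_real_)
}

## Step-function lookup of a survfit state probability at given times;
## zero for states the fit never visits.
summary_pstate <- function(sf, times, state) {
  col <- which(sf$states == state)
  if (!length(col)) return(rep(0, length(times)))
  p <- sf$pstate[, col]
  idx <- findInterval(times, sf$time)
  ifelse(idx == 0L, 0, p[pmax(idx, 1L)])
}

#' @export
print.threshold_curve <- function(x, ...) {
  cat(sprintf("Time to fall below the CD4 threshold (%s), %d children\n",
              attr(x, "kind"), attr(x, "n")))
  print(as.data.frame(round(x, 4)))
  invisible(x)
}

#' Naive time-varying-treatment hazard comparison
#'
#' The diagnostic regression that ignores time-dependent confounding: a
#' pooled discrete-time logistic hazard model of death on the time-varying
#' on-ART indicator, adjusting only for baseline disease severity and
#' demographics and a smooth time trend. Under confounding by indication
#' (sicker children start ART sooner) it overstates the hazard under ART;
#' contrasted with the g-computation estimates it demonstrates why the
#' causal machinery is needed. The exponentiated ART coefficient
#' approximates the hazard ratio at the low per-interval death rates in
#' scope.
#'
#' @param panel An `interval_panel` (complete baselines required; incomplete
#'   rows are dropped).
#' @return List with `hazard_ratio`, `conf_int` (Wald 95%), `log_hr`, `se`,
#'   `n_intervals`, `n_deaths`, and the fitted `glm` object.
#' @export
naive_art_association <- function(panel) {
  trans <- build_transitions(panel)
  d <- trans[trans$cens == 0L, , drop = FALSE]
  cols <- c("death", "art_prev", "sqrt_cd4_0", "cd4pct_0", "waz_0", "haz_0",
            "age", "sex", "region", "t")
  d <- d[stats::complete.cases(d[, cols]), cols, drop = FALSE]
  if (sum(d$death) < 1L) stop("no deaths in the panel", call. = FALSE)
  multi_region <- length(unique(d$region)) > 1L
  f <- stats::as.formula(paste(
    "death ~ art_prev + sqrt_cd4_0 + cd4pct_0 + waz_0 + haz_0 + age + sex +",
    if (multi_region) "region +" else "",
    "splines::ns(t, df = 3)"))
  fit <- stats::glm(f, family = stats::binomial(), data = d)
  co <- stats::coef(fit)["art_prev"]
  se <- sqrt(diag(stats::vcov(fit))["art_prev"])
  list(hazard_ratio = unname(exp(co)),
       conf_int = unname(exp(co + c(-1, 1) * stats::qnorm(0.975) * se)),
       log_hr = unname(co), se = unname(se),
       n_intervals = nrow(d), n_deaths = sum(d$death), fit = fit)
}
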