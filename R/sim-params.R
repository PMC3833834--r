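#' Structural parameters of the synthetic cohort generator
#'
#' Bundles every parameter of the structural causal model that
#' [generate_cohort()] simulates from and that [true_regime_mortality()]
#' evaluates exactly. The defaults emulate a Southern-African paediatric HIV
#' cohort of children enrolling into care between 2 and 5 years of age:
#' baseline marker distributions centred on a median CD4 count of 592
#' cells/mm3, CD4% of 16, weight-for-age z-score (WAZ) of -1.4 and
#' height-for-age z-score (HAZ) of -2.6; first-order autoregressive evolution
#' of sqrt-CD4, CD4% and WAZ between visits; treatment assignment that depends
#' on the current markers (confounding by indication: sicker children are more
#' likely to start ART); a per-interval logistic death hazard decreasing in
#' CD4, CD4% and WAZ; and observation-process parameters (visit-time jitter,
#' missing-at-random recording gaps, loss to follow-up).
#'
#' @param n_children Number of children to simulate (default 2934).
#' @param baseline List of baseline distribution settings; see Details.
#' @param ar List of autoregressive transition coefficients, one element per
#'   time-dependent confounder (`sqrt_cd4`, `cd4pct`, `waz`), each a numeric
#'   vector `c(intercept, lag, art, sd)`. The `art` entry is the additive
#'   effect of being on ART on the next value (0 by default, so `art_effect`
#'   alone carries the causal effect of treatment).
#' @param assignment_coefs Logistic coefficients
#'   `c(intercept, sqrt_cd4, cd4pct, waz)` of the per-interval probability of
#'   starting ART given the current (untreated) state. Negative marker
#'   coefficients encode confounding by indication.
#' @param death_coefs Logistic coefficients
#'   `c(intercept, sqrt_cd4, cd4pct, waz)` of the per-interval death
#'   probability given the state at the start of the interval.
#' @param art_effect Multiplicative effect of being on ART on the
#'   per-interval death odds; 1 is a null effect, values below 1 are
#'   protective (default 0.4).
#' @param missing_rate Per-visit probability that a follow-up confounder
#'   measurement goes unrecorded (scalar, applied to CD4/CD4%/WAZ with
#'   variable-specific multipliers; baseline recording gaps scale with it
#'   too). Set to 0 for fully observed data.
#' @param mar_coef Missing-at-random coefficient: logit shift of the
#'   missingness probability per unit of the child's last *observed* WAZ
#'   (centred at -1.4), so missingness depends on observed history only.
#' @param ltfu_hazard Per-interval probability that a surviving child drops
#'   out of care (loss to follow-up).
#' @param prior_art_prob Probability that a child's record shows an ART start
#'   predating the first visit (such children are excluded by
#'   [filter_eligible()]).
#' @param no_followup_prob Probability that a child has no recorded visit
#'   after enrolment (excluded by [filter_eligible()]).
#' @param jitter Logical: add uniform jitter to observed visit times (within
#'   +/- 1 month, +/- 0.4 month for the month-1 visit; the enrolment visit is
#'   always at 0). Disable to obtain visits exactly on the nominal grid.
#' @param horizon_months Follow-up horizon in months, a multiple of 3
#'   (default 36).
#' @param seed Master seed; identical parameters and seed give a
#'   bit-identical cohort.
#'
#' @details `baseline` accepts the elements `age_range` (years, default
#'   `c(2, 5)`), `age_shape` (Beta shape parameters for age within the range),
#'   `male_prob`, `region_probs` (named, 4 regions), `mean` and `sd` (named
#'   vectors over `sqrt_cd4`, `cd4pct`, `waz`, `haz` on the latent Gaussian
#'   scale) and `corr` (4x4 correlation matrix of the latent markers).
#'   Draws are truncated to the natural ranges (CD4 >= 0, CD4% in \[0, 100\]).
#'
#' @return An object of class `sim_params`.
#' @seealso [generate_cohort()], [true_regime_mortality()]
#' @examples
#' p <- sim_params(n_children = 100, seed = 7)
#' p$art_effect
#' @export
sim_params <- function(n_children = 2934,
                       baseline = list(),
                       ar = list(),
                       assignment_coefs = c(intercept = 1.1, sqrt_cd4 = -0.12,
                                            cd4pct = -0.06, waz = -0.45),
                       death_coefs = c(intercept = -1.8, sqrt_cd4 = -0.30,
                                       cd4pct = -0.09, waz = -0.90),
                       art_effect = 0.4,
                       missing_rate = 0.15,
                       mar_coef = 0.15,
                       ltfu_hazard = 0.02,
                       prior_art_prob = 0.03,
                       no_followup_prob = 0.05,
                       jitter = TRUE,
                       horizon_months = 36,
                       seed = 1L) {
  base_def <- list(
    age_range = c(2, 5),
    age_shape = c(1.4, 1.9),
    male_prob = 0.512,
    region_probs = c("SA-urban" = 0.76, "SA-rural" = 0.09,
                     "Malawi" = 0.10, "Zimbabwe" = 0.05),
    mean = c(sqrt_cd4 = sqrt(592), cd4pct = 16, waz = -1.4, haz = -2.6),
    sd = c(sqrt_cd4 = 8.19, cd4pct = 9.4, waz = 1.33, haz = 1.41),
    corr = matrix(c(1.0, 0.60, 0.25, 0.20,
                    0.60, 1.0, 0.25, 0.20,
                    0.25, 0.25, 1.0, 0.50,
                    0.20, 0.20, 0.50, 1.0), 4, 4)
  )
  baseline <- utils::modifyList(base_def, baseline)
  ## AR(1) residual SDs are stationarity-consistent with the baseline
  ## cross-sectional SDs at lag 0.85 (sd_baseline * sqrt(1 - 0.85^2)), so
  ## marker dispersion neither shrinks nor grows over follow-up.
  ar_def <- list(
    sqrt_cd4 = c(intercept = 3.649, lag = 0.85, art = 0, sd = 4.314),
    cd4pct   = c(intercept = 2.40, lag = 0.85, art = 0, sd = 4.952),
    waz      = c(intercept = -0.21, lag = 0.85, art = 0, sd = 0.701)
  )
  ar <- utils::modifyList(ar_def, ar)

  p <- list(n_children = n_children, baseline = baseline, ar = ar,
            assignment_coefs = assignment_coefs, death_coefs = death_coefs,
            art_effect = art_effect, missing_rate = missing_rate,
            mar_coef = mar_coef, ltfu_hazard = ltfu_hazard,
            prior_art_prob = prior_art_prob,
            no_followup_prob = no_followup_prob,
            jitter = isTRUE(jitter),
            horizon_months = horizon_months, seed = as.integer(seed))
  validate_sim_params(p)
  structure(p, class = "sim_params")
}

validate_sim_params <- function(p) {
  if (!is.numeric(p$n_children) || length(p$n_children) != 1L ||
      is.na(p$n_children) || p$n_children < 0 || p$n_children %% 1 != 0)
    stop("`n_children` must be a non-negative integer", call. = FALSE)
  num_fields <- c(unlist(p$ar), p$assignment_coefs, p$death_coefs,
                  p$art_effect, p$mar_coef, p$baseline$mean, p$baseline$sd)
  if (any(!is.finite(num_fields)))
    stop("non-finite generator parameter", call. = FALSE)
  if (p$art_effect <= 0)
    stop("`art_effect` must be a positive odds multiplier", call. = FALSE)
  for (nm in c("missing_rate", "ltfu_hazard", "prior_art_prob",
               "no_followup_prob"))
    stopifnot_scalar_prob(p[[nm]], nm)
  stopifnot_scalar_prob(p$baseline$male_prob, "baseline$male_prob")
  rp <- p$baseline$region_probs
  if (any(rp < 0) || abs(sum(rp) - 1) > 1e-8)
    stop("`baseline$region_probs` must be non-negative and sum to 1",
         call. = FALSE)
  grid <- tryCatch(visit_grid(p$horizon_months), error = function(e) NULL)
  if (is.null(grid) || !(p$horizon_months %in% grid))
    stop("`horizon_months` must lie on the visit grid", call. = FALSE)
  invisible(p)
}

#' @export
print.sim_params <- function(x, ...) {
  cat("Synthetic paediatric ART cohort parameters\n")
  cat(sprintf("  children: %d, horizon: %d months, seed: %d\n",
              x$n_children, x$horizon_months, x$seed))
  cat(sprintf("  ART effect on death odds: %.3g%s\n", x$art_effect,
              if (x$art_effect == 1) " (null)" else ""))
  cat(sprintf("  missing rate: %.3g, LTFU hazard/interval: %.3g\n",
              x$missing_rate, x$ltfu_hazard))
  invisible(x)
}

#' Read or write generator parameters as YAML
#'
#' Serialises a [sim_params()] object to a YAML file and back, so cohort
#' simulations can be configured from plain-text parameter files.
#'
#' @param path Path to a YAML file.
#' @param params A `sim_params` object.
#' @return `sim_params_from_yaml()` returns a validated `sim_params` object;
#'   `sim_params_to_yaml()` returns `path` invisibly.
#' @export
sim_params_from_yaml <- function(path) {
  raw <- yaml::read_yaml(path)
  raw$baseline$region_probs <- unlist(raw$baseline$region_probs)
  raw$baseline$mean <- unlist(raw$baseline$mean)
  raw$baseline$sd <- unlist(raw$baseline$sd)
  if (!is.null(raw$baseline$corr))
    raw$baseline$corr <- matrix(unlist(raw$baseline$corr), 4, 4)
  raw$ar <- lapply(raw$ar, unlist)
  raw$assignment_coefs <- unlist(raw$assignment_coefs)
  raw$death_coefs <- unlist(raw$death_coefs)
  do.call(sim_params, raw)
}

#' @rdname sim_params_from_yaml
#' @export
sim_params_to_yaml <- function(params, path) {
  stopifnot(inherits(params, "sim_params"))
  out <- unclass(params)
  ## named vectors become YAML maps (plain vectors lose their names)
  out$baseline$corr <- apply(out$baseline$corr, 1, as.list)
  for (nm in c("region_probs", "mean", "sd"))
    out$baseline[[nm]] <- as.list(out$baseline[[nm]])
  out$ar <- lapply(out$ar, as.list)
  out$assignment_coefs <- as.list(out$assignment_coefs)
  out$death_coefs <- as.list(out$death_coefs)
  yaml::write_yaml(out, path)
  invisible(path)
}
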