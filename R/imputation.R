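## Longitudinal multiple imputation in the EM-bootstrap style: the panel is
## reshaped to one row per child with time-indexed columns (so cross-time
## correlations are modelled directly and every variable's lag and lead are
## its neighbouring columns), a multivariate-normal model is estimated by EM
## on a child-level bootstrap resample, and the original data's missing
## cells are drawn from the estimated conditional normal given each child's
## observed cells. Repeated m times this gives m completed panels whose
## spread reflects parameter uncertainty.

#' Child-level wide matrix for the imputation model
#'
#' Reshapes an interval panel into the imputation model's layout: one row
#' per child with the baseline covariates (age, sex, region indicators,
#' HAZ), the time-indexed confounders (`cd4s_<t>` on the square-root scale,
#' `pct_<t>`, `waz_<t>` for every grid time), the mortality indicator,
#' follow-up time and the fraction of carried-forward cells. Cells after a
#' child's last panel row are structurally undefined and enter as missing
#' (they are modelled but never mapped back). Constant and all-missing
#' columns are dropped with a warning.
#'
#' @param panel An `interval_panel` (after [apply_locf()]).
#' @return A list with `data` (numeric matrix, one row per child), `ids`
#'   (child id per row), `columns` (data frame describing each column:
#'   name, variable, grid time, plus lag/lead column names for the
#'   time-indexed confounders), and `dropped` (names of dropped columns).
#' @export
build_imputation_matrix <- function(panel) {
  stopifnot(inherits(panel, "interval_panel"))
  grid <- attr(panel, "grid")
  df <- as.data.frame(panel)
  ids <- sort(unique(df$id))
  n <- length(ids)
  b <- df[df$t == 0, , drop = FALSE]
  b <- b[match(ids, b$id), , drop = FALSE]

  regions <- sort(unique(as.character(df$region)))
  X <- cbind(age = b$age,
             sex_male = as.numeric(b$sex == "male"))
  for (rg in regions[-1L]) {
    X <- cbind(X, as.numeric(as.character(b$region) == rg))
    colnames(X)[ncol(X)] <- paste0("region_", make.names(rg))
  }
  X <- cbind(X, haz_0 = b$haz_0)

  id_idx <- match(df$id, ids)
  t_idx <- match(df$t, grid)
  wide <- function(v, trans = identity) {
    M <- matrix(NA_real_, n, length(grid))
    ok <- !is.na(v)
    M[cbind(id_idx[ok], t_idx[ok])] <- trans(v[ok])
    M
  }
  Mcd4 <- wide(df$cd4, function(x) sqrt(pmax(x, 0)))
  Mpct <- wide(df$cd4pct)
  Mwaz <- wide(df$waz)
  colnames(Mcd4) <- paste0("cd4s_", grid)
  colnames(Mpct) <- paste0("pct_", grid)
  colnames(Mwaz) <- paste0("waz_", grid)

  died <- as.numeric(tapply(df$death, df$id, max)[as.character(ids)])
  futime <- as.numeric(tapply(df$t, df$id, max)[as.character(ids)])
  carried <- as.numeric(tapply(
    df$carried_cd4 + df$carried_cd4pct + df$carried_waz, df$id,
    mean)[as.character(ids)]) / 3

  X <- cbind(X, Mcd4, Mpct, Mwaz, died = died, futime = futime,
             carried = carried)

  all_na <- colSums(!is.na(X)) == 0L
  const <- apply(X, 2, function(x) {
    v <- x[!is.na(x)]
    length(v) > 0L && length(unique(v)) < 2L
  })
  drop <- all_na | const
  if (any(drop))
    warning(sprintf("dropping %d constant/all-missing column(s): %s",
                    sum(drop), paste(colnames(X)[drop], collapse = ", ")),
            call. = FALSE)
  kept <- colnames(X)[!drop]
  X <- X[, !drop, drop = FALSE]

  cols <- data.frame(name = kept, stringsAsFactors = FALSE)
  cols$var <- rep(NA_character_, nrow(cols))
  cols$t <- rep(NA_real_, nrow(cols))
  cols$lag <- rep(NA_character_, nrow(cols))
  cols$lead <- rep(NA_character_, nrow(cols))
  for (v in c("cd4s", "pct", "waz")) {
    hit <- grep(paste0("^", v, "_[0-9]+$"), cols$name)
    tt <- as.numeric(sub(paste0(v, "_"), "", cols$name[hit]))
    cols$var[hit] <- v
    cols$t[hit] <- tt
    ord <- order(tt)
    cols$lag[hit[ord][-1L]] <- cols$name[hit[ord][-length(ord)]]
    cols$lead[hit[ord][-length(ord)]] <- cols$name[hit[ord][-1L]]
  }
  list(data = X, ids = ids, columns = cols,
       dropped = colnames(panel)[FALSE], grid = grid)
}

## EM for the multivariate normal with missing data. Rows are grouped by
## missingness pattern; the observed-data log-likelihood is tracked. Two
## stabilisers guard the M-step: a diagonal shrinkage prior with `prior_df`
## pseudo-observations (default p + 2, enough to keep the MAP covariance
## positive definite when p is not small relative to n — the observed-data
## ML is otherwise unbounded) and a small additive ridge
## (ridge_frac * trace(Sigma)/p). Set both to 0 for the pure EM.
em_mvnorm <- function(X, ridge_frac = 1e-4, tol = 1e-4, max_iter = 500L,
                      prior_df = NULL) {
  n <- nrow(X); p <- ncol(X)
  M <- !is.na(X)
  key <- apply(M, 1L, function(r) paste(as.integer(r), collapse = ""))
  groups <- split(seq_len(n), key)

  mu <- colMeans(X, na.rm = TRUE)
  v <- apply(X, 2, stats::var, na.rm = TRUE)
  v[!is.finite(v) | v <= 0] <- 1
  Sigma <- diag(v, p)
  prior_df <- prior_df %||% (p + 2)
  S0 <- diag(v, p)
  loglik <- numeric(0)
  converged <- FALSE

  for (it in seq_len(max_iter)) {
    sum_x <- numeric(p)
    sum_xx <- matrix(0, p, p)
    ll <- 0
    for (g in groups) {
      o <- which(M[g[1L], ]); ms <- which(!M[g[1L], ])
      Xg <- X[g, , drop = FALSE]
      ng <- length(g)
      if (!length(o)) {
        # nothing observed: prior mean/cov
        Xg[, ] <- rep(mu, each = ng)
        sum_x <- sum_x + colSums(Xg)
        sum_xx <- sum_xx + crossprod(Xg) + ng * Sigma
        next
      }
      Soo <- Sigma[o, o, drop = FALSE]
      ch <- tryCatch(chol(Soo), error = function(e) {
        chol(Soo + diag(1e-8 * mean(diag(Soo)), length(o)))
      })
      Xo_c <- sweep(Xg[, o, drop = FALSE], 2, mu[o])
      # observed-data log-likelihood contribution
      q <- forwardsolve(t(ch), t(Xo_c))
      ll <- ll - 0.5 * (ng * (length(o) * log(2 * pi) +
                                2 * sum(log(diag(ch)))) + sum(q^2))
      if (length(ms)) {
        W <- backsolve(ch, forwardsolve(t(ch), Sigma[o, ms, drop = FALSE]))
        cm <- sweep(Xo_c %*% W, 2, mu[ms], `+`)
        Cc <- Sigma[ms, ms, drop = FALSE] -
          crossprod(Sigma[o, ms, drop = FALSE], W)
        Xg[, ms] <- cm
        add <- matrix(0, p, p)
        add[ms, ms] <- ng * Cc
        sum_xx <- sum_xx + crossprod(Xg) + add
      } else {
        sum_xx <- sum_xx + crossprod(Xg)
      }
      sum_x <- sum_x + colSums(Xg)
    }
    loglik <- c(loglik, ll)
    mu_new <- sum_x / n
    Sigma_new <- sum_xx / n - tcrossprod(mu_new)
    Sigma_new <- (Sigma_new + t(Sigma_new)) / 2
    if (prior_df > 0)
      Sigma_new <- (n * Sigma_new + prior_df * S0) / (n + prior_df)
    diag(Sigma_new) <- diag(Sigma_new) +
      ridge_frac * sum(diag(Sigma_new)) / p
    ## root-mean-square relative parameter change
    rel <- sqrt(mean(c((mu_new - mu)^2 / (abs(mu) + 1)^2,
                       (Sigma_new - Sigma)^2 / (abs(Sigma) + 1)^2)))
    mu <- mu_new; Sigma <- Sigma_new
    if (rel < tol) { converged <- TRUE; break }
  }
  list(mu = mu, Sigma = Sigma, iterations = length(loglik),
       loglik = loglik, converged = converged)
}

## Draw the missing cells of X from the conditional normal implied by
## (mu, Sigma), pattern by pattern.
conditional_draw <- function(X, mu, Sigma, mean_only = FALSE) {
  M <- !is.na(X)
  if (all(M)) return(X)
  key <- apply(M, 1L, function(r) paste(as.integer(r), collapse = ""))
  for (g in split(seq_len(nrow(X)), key)) {
    o <- which(M[g[1L], ]); ms <- which(!M[g[1L], ])
    if (!length(ms)) next
    ng <- length(g)
    if (!length(o)) {
      cm <- matrix(rep(mu, each = ng), ng)
      Cc <- Sigma
    } else {
      Soo <- Sigma[o, o, drop = FALSE]
      ch <- tryCatch(chol(Soo), error = function(e)
        chol(Soo + diag(1e-8 * mean(diag(Soo)), length(o))))
      W <- backsolve(ch, forwardsolve(t(ch), Sigma[o, ms, drop = FALSE]))
      cm <- sweep(sweep(X[g, o, drop = FALSE], 2, mu[o]) %*% W, 2,
                  mu[ms], `+`)
      Cc <- Sigma[ms, ms, drop = FALSE] -
        crossprod(Sigma[o, ms, drop = FALSE], W)
    }
    if (mean_only) {
      X[g, ms] <- cm
    } else {
      Cc <- (Cc + t(Cc)) / 2
      chC <- tryCatch(chol(Cc), error = function(e)
        chol(Cc + diag(1e-8 * mean(diag(Cc)) + 1e-12, nrow(Cc))))
      Z <- matrix(stats::rnorm(ng * length(ms)), ng)
      X[g, ms] <- cm + Z %*% chC
    }
  }
  X
}

#' EM-bootstrap multiple imputation of a wide matrix
#'
#' For each of `m` replicates: draw a child-level bootstrap resample of the
#' rows, estimate the multivariate-normal mean and covariance by EM to
#' tolerance, then fill the *original* matrix's missing cells with draws
#' from the estimated conditional normal given each row's observed cells.
#' Bootstrap re-estimation is what propagates parameter uncertainty into
#' the imputations.
#'
#' @param X Numeric matrix, one row per child; `NA` for missing cells.
#' @param m Number of imputed datasets (default 10).
#' @param seed Seed controlling resampling and draws.
#' @param ridge_frac Ridge added to the covariance diagonal each M-step, as
#'   a fraction of `trace(Sigma)/p` (default `1e-4`).
#' @param tol EM convergence tolerance on the root-mean-square relative
#'   parameter change (default `1e-4`).
#' @param max_iter Maximum EM iterations per replicate (default 500).
#' @param prior_df Pseudo-observations of the diagonal shrinkage prior that
#'   keeps the estimated covariance positive definite (default: number of
#'   columns + 2; set 0 for the pure maximum-likelihood EM).
#' @return An object of class `emb_imputation`: `imputations` (list of `m`
#'   completed matrices) and `diagnostics` (per-replicate EM iteration
#'   counts, final log-likelihood changes, convergence flags, and
#'   overimputation RMSE per column from the first replicate).
#' @export
em_bootstrap_impute <- function(X, m = 10L, seed = 1L, ridge_frac = 1e-4,
                                tol = 1e-4, max_iter = 500L,
                                prior_df = NULL) {
  if (!is.matrix(X) || !is.numeric(X)) stop("`X` must be a numeric matrix",
                                            call. = FALSE)
  if (m < 1L) stop("`m` must be at least 1", call. = FALSE)
  n_obs <- colSums(!is.na(X))
  if (any(n_obs < 2L))
    stop("every column needs at least 2 observed values", call. = FALSE)
  n <- nrow(X)
  imputations <- vector("list", m)
  iters <- integer(m); ll_delta <- numeric(m); conv <- logical(m)
  over_rmse <- NULL
  for (k in seq_len(m)) {
    res <- with_seed(derive_seed(seed, k), {
      idx <- sample.int(n, n, replace = TRUE)
      em <- em_mvnorm(X[idx, , drop = FALSE], ridge_frac, tol, max_iter,
                      prior_df = prior_df)
      if (!em$converged)
        stop(sprintf("EM did not converge within %d iterations (replicate %d)",
                     max_iter, k), call. = FALSE)
      imp <- conditional_draw(X, em$mu, em$Sigma)
      list(em = em, imp = imp)
    })
    imputations[[k]] <- res$imp
    iters[k] <- res$em$iterations
    nll <- length(res$em$loglik)
    ll_delta[k] <- if (nll > 1L) diff(utils::tail(res$em$loglik, 2L)) else 0
    conv[k] <- res$em$converged
    if (k == 1L)
      over_rmse <- with_seed(derive_seed(seed, 0L, 7L),
                             overimpute_rmse(X, res$em))
  }
  structure(list(imputations = imputations,
                 diagnostics = list(iterations = iters,
                                    loglik_change = ll_delta,
                                    converged = conv,
                                    overimputation_rmse = over_rmse)),
            class = "emb_imputation")
}

## Overimputation diagnostic: mask 10% of the observed cells, impute them
## from the fitted parameters, report the per-column RMSE.
overimpute_rmse <- function(X, em, frac = 0.1) {
  obs_idx <- which(!is.na(X))
  if (!length(obs_idx)) return(NULL)
  mask <- sample(obs_idx, max(1L, floor(frac * length(obs_idx))))
  Xm <- X
  Xm[mask] <- NA
  keep <- colSums(!is.na(Xm)) >= 2L
  if (!all(keep)) {
    bad <- which(!keep)
    mask <- mask[((mask - 1L) %/% nrow(X) + 1L) %in% which(keep)]
    Xm <- X; Xm[mask] <- NA
  }
  Xi <- conditional_draw(Xm, em$mu, em$Sigma, mean_only = TRUE)
  err <- Xi[mask] - X[mask]
  cols <- (mask - 1L) %/% nrow(X) + 1L
  rmse <- tapply(err^2, colnames(X)[cols], function(e) sqrt(mean(e)))
  rmse
}

#' Multiply impute an interval panel
#'
#' Runs [build_imputation_matrix()] and [em_bootstrap_impute()] and maps the
#' draws back into `m` completed panels: remaining missing follow-up CD4,
#' CD4% and WAZ cells (those the 9-month carry-forward could not fill) and
#' missing baseline values are replaced; observed cells are never altered.
#' Back-transformation restores the natural scales (imputed sqrt-CD4 is
#' truncated at 0 and squared; CD4% is clamped to \[0, 100\]).
#'
#' @param panel An `interval_panel` after [apply_locf()] and [flag_ltfu()].
#' @param m Number of imputations (default 10).
#' @param seed Seed.
#' @param ... Passed to [em_bootstrap_impute()].
#' @return An object of class `imputed_set`: `panels` (list of `m` complete
#'   panels), `diagnostics`, `m`.
#' @export
impute_panel <- function(panel, m = 10L, seed = 1L, ...) {
  stopifnot(inherits(panel, "interval_panel"))
  df <- as.data.frame(panel)
  target_cells <- is.na(df$cd4) | is.na(df$cd4pct) | is.na(df$waz) |
    is.na(df$cd4_0) | is.na(df$cd4pct_0) | is.na(df$waz_0) | is.na(df$haz_0)
  if (!any(target_cells)) {
    return(structure(list(panels = rep(list(panel), m),
                          diagnostics = list(note = "nothing to impute"),
                          m = m), class = "imputed_set"))
  }
  bm <- build_imputation_matrix(panel)
  emb <- em_bootstrap_impute(bm$data, m = m, seed = seed, ...)
  panels <- lapply(emb$imputations, function(Xi)
    matrix_to_panel(panel, Xi, bm))
  structure(list(panels = panels, diagnostics = emb$diagnostics, m = m),
            class = "imputed_set")
}

## Map a completed wide matrix back into the panel's missing cells.
matrix_to_panel <- function(panel, Xi, bm) {
  df <- as.data.frame(panel)
  grid <- bm$grid
  row_i <- match(df$id, bm$ids)
  cell <- function(prefix, tt, rows) {
    ci <- match(paste0(prefix, "_", tt), colnames(Xi))
    Xi[cbind(rows, ci)]                      # NA column index -> NA value
  }
  mi <- is.na(df$cd4)
  v <- cell("cd4s", df$t[mi], row_i[mi])
  df$cd4[mi][!is.na(v)] <- pmax(v[!is.na(v)], 0)^2
  mi <- is.na(df$cd4pct)
  v <- cell("pct", df$t[mi], row_i[mi])
  df$cd4pct[mi][!is.na(v)] <- clamp(v[!is.na(v)], 0, 100)
  mi <- is.na(df$waz)
  v <- cell("waz", df$t[mi], row_i[mi])
  df$waz[mi][!is.na(v)] <- v[!is.na(v)]
  ## baseline columns follow the imputed enrolment state / HAZ column
  for (spec in list(c("cd4_0", "cd4s"), c("cd4pct_0", "pct"),
                    c("waz_0", "waz"))) {
    mi <- is.na(df[[spec[1L]]])
    if (!any(mi)) next
    v <- cell(spec[2L], 0, row_i[mi])
    v <- if (spec[2L] == "cd4s") pmax(v, 0)^2
         else if (spec[2L] == "pct") clamp(v, 0, 100) else v
    df[[spec[1L]]][mi][!is.na(v)] <- v[!is.na(v)]
  }
  if ("haz_0" %in% colnames(Xi)) {
    hz <- Xi[cbind(row_i, match("haz_0", colnames(Xi)))]
    df$haz_0[is.na(df$haz_0)] <- hz[is.na(df$haz_0)]
  }
  structure(df, grid = grid, horizon = attr(panel, "horizon"),
            events = attr(panel, "events"), class = class(panel))
}

#' Combine estimates across imputations by Rubin's rules
#'
#' Pooled estimate is the mean of the per-imputation estimates; the between
#' variance `B` is their sample variance; the total variance is
#' `mean(within) + (1 + 1/m) * B`. With `m = 1` the single estimate is
#' returned with `B = 0`.
#'
#' @param estimates Numeric vector of per-imputation point estimates.
#' @param within Numeric vector of per-imputation (within) variances.
#' @return List with `estimate`, `between`, `within`, `total`, `m`, and the
#'   Rubin degrees of freedom `df` (Inf when `B = 0`).
#' @examples
#' rubin_combine(c(0.02, 0.04), c(0, 0))
#' @export
rubin_combine <- function(estimates, within) {
  if (!length(estimates)) stop("empty estimate vector", call. = FALSE)
  if (length(estimates) != length(within))
    stop("`estimates` and `within` must have equal length", call. = FALSE)
  m <- length(estimates)
  est <- mean(estimates)
  W <- mean(within)
  B <- if (m > 1L) stats::var(estimates) else 0
  total <- W + (1 + 1 / m) * B
  df <- if (B > 0) (m - 1) * (1 + W / ((1 + 1 / m) * B))^2 else Inf
  list(estimate = est, between = B, within = W, total = total, m = m,
       df = df)
}
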