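## Penalized B-spline (p-spline) additive models: B-spline bases on equally
## spaced knots with a difference penalty on adjacent coefficients, smoothing
## selected by generalized cross-validation. Gaussian response via penalized
## least squares, binomial via penalized IRLS with a performance-iteration
## GCV search. Everything is deterministic given the data.

#' P-spline basis and penalty
#'
#' Builds a B-spline design on equally spaced knots over the observed range
#' of `x`, together with the difference penalty `lambda * t(D) %*% D` (`D`
#' the order-`penalty_order` difference operator on the basis coefficients).
#' A sum-to-zero centring constraint is absorbed into the basis so the smooth
#' is identifiable next to an intercept; the penalty is transformed
#' accordingly. Evaluation outside the observed range extrapolates linearly
#' from the boundary.
#'
#' @param x Numeric vector with at least 2 distinct values.
#' @param nbasis Number of B-spline basis functions (default 8).
#' @param degree B-spline degree (default 3, cubic).
#' @param penalty_order Order of the difference penalty (default 2).
#' @param lambda Penalty weight (>= 0, default 1).
#' @return List with `basis` (n x (nbasis-1) constrained design), `penalty`
#'   (`lambda` times the constrained penalty matrix), and the knot/constraint
#'   information needed to evaluate the basis at new points.
#' @examples
#' d <- pspline_design(seq(0, 1, length.out = 50))
#' dim(d$basis)
#' @export
pspline_design <- function(x, nbasis = 8, degree = 3, penalty_order = 2,
                           lambda = 1) {
  if (nbasis <= penalty_order)
    stop("`nbasis` must exceed `penalty_order`", call. = FALSE)
  if (lambda < 0) stop("`lambda` must be non-negative", call. = FALSE)
  st <- smooth_structure(x, nbasis, degree, penalty_order)
  if (is.null(st))
    stop("degenerate basis: `x` has fewer than 2 distinct values",
         call. = FALSE)
  Z <- eval_smooth(st, x)
  list(basis = Z, penalty = lambda * st$Pz, knots = st$knots,
       degree = degree, range = c(st$lo, st$hi), Q2 = st$Q2)
}

## Internal smooth-term structure; NULL if x is degenerate.
smooth_structure <- function(x, nbasis, degree, penalty_order,
                             by = NULL, by_levels = NULL) {
  xf <- x[is.finite(x)]
  if (length(unique(xf)) < 2L) return(NULL)
  lo <- min(xf); hi <- max(xf)
  nseg <- nbasis - degree
  h <- (hi - lo) / nseg
  knots <- lo + h * ((-degree):(nseg + degree))
  B <- splines::splineDesign(knots, xf, ord = degree + 1L, outer.ok = TRUE)
  cm <- colMeans(B)
  Q <- qr.Q(qr(matrix(cm, ncol = 1L)), complete = TRUE)
  Q2 <- Q[, -1L, drop = FALSE]
  D <- diff(diag(nbasis), differences = penalty_order)
  Pz <- crossprod(D %*% Q2)
  list(knots = knots, degree = degree, lo = lo, hi = hi, Q2 = Q2, Pz = Pz,
       nbasis = nbasis, by = by, by_levels = by_levels)
}

## Constrained basis at arbitrary x, with linear extrapolation beyond the
## fitted range.
eval_smooth <- function(st, x) {
  ord <- st$degree + 1L
  xi <- clamp(x, st$lo, st$hi)
  B <- splines::splineDesign(st$knots, xi, ord = ord, outer.ok = TRUE)
  out_lo <- which(x < st$lo)
  out_hi <- which(x > st$hi)
  if (length(out_lo)) {
    d1 <- splines::splineDesign(st$knots, rep(st$lo, length(out_lo)),
                                ord = ord, derivs = rep(1L, length(out_lo)),
                                outer.ok = TRUE)
    B[out_lo, ] <- B[out_lo, , drop = FALSE] + d1 * (x[out_lo] - st$lo)
  }
  if (length(out_hi)) {
    d1 <- splines::splineDesign(st$knots, rep(st$hi, length(out_hi)),
                                ord = ord, derivs = rep(1L, length(out_hi)),
                                outer.ok = TRUE)
    B[out_hi, ] <- B[out_hi, , drop = FALSE] + d1 * (x[out_hi] - st$hi)
  }
  B %*% st$Q2
}

## Parse the model structure (parametric terms + smooth terms) from data.
## `smooth_by` is a named list: smooth name -> factor column whose levels get
## their own deviation smooth (a varying-coefficient interaction).
## `shared_smooths` supplies pre-built smooth structures (common knots across
## several fits of one model set), so bases can be shared and cached.
parse_structure <- function(data, linear, smooth, smooth_by, nbasis, degree,
                            penalty_order, shared_smooths = NULL) {
  f <- if (length(linear)) stats::reformulate(linear) else ~1
  mf <- stats::model.frame(f, data, na.action = stats::na.fail)
  tp <- attr(mf, "terms")
  xlev <- stats::.getXlevels(tp, mf)
  smooths <- list()
  dropped <- character()
  for (nm in smooth) {
    by <- smooth_by[[nm]]
    by_levels <- if (!is.null(by)) levels(factor(data[[by]]))
    st <- shared_smooths[[nm]] %||%
      smooth_structure(data[[nm]], nbasis, degree, penalty_order)
    if (is.null(st)) { dropped <- c(dropped, nm); next }
    st$by <- by
    st$by_levels <- by_levels
    st$name <- nm
    smooths[[nm]] <- st
  }
  if (length(dropped))
    warning(sprintf("smooth term(s) %s degenerate (constant); dropped",
                    paste(dropped, collapse = ", ")), call. = FALSE)
  list(terms_par = tp, xlevels = xlev, smooths = smooths)
}

## Full design matrix + penalty block bookkeeping for a parsed structure.
## Returns X, and `blocks`: list of (cols, Pz, term) per penalized block.
## `cache` (an environment) memoises parametric blocks and smooth bases
## across fits that share term structures and the same data rows; the
## caller owns invalidation when a column of `data` changes.
build_design <- function(st, data, cache = NULL) {
  par_key <- paste0("PAR|", paste(attr(st$terms_par, "term.labels"),
                                  collapse = "+"))
  X_par <- if (!is.null(cache) && !is.null(cache[[par_key]]) &&
               nrow(cache[[par_key]]) == nrow(data)) {
    cache[[par_key]]
  } else {
    mf <- stats::model.frame(st$terms_par, data, na.action = stats::na.pass,
                             xlev = st$xlevels)
    Xp <- stats::model.matrix(st$terms_par, mf)
    if (!is.null(cache)) cache[[par_key]] <- Xp
    Xp
  }
  parts <- list(X_par)
  blocks <- list()
  p0 <- ncol(X_par)
  for (sm in st$smooths) {
    key <- paste(sm$name, sm$lo, sm$hi, sm$nbasis, sep = "|")
    Z <- if (!is.null(cache) && !is.null(cache[[key]]) &&
             nrow(cache[[key]]) == nrow(data)) {
      cache[[key]]
    } else {
      Zi <- eval_smooth(sm, data[[sm$name]])
      if (!is.null(cache)) cache[[key]] <- Zi
      Zi
    }
    cols <- p0 + seq_len(ncol(Z))
    parts[[length(parts) + 1L]] <- Z
    blocks[[length(blocks) + 1L]] <- list(cols = cols, Pz = sm$Pz,
                                          term = sm$name)
    p0 <- p0 + ncol(Z)
    if (!is.null(sm$by)) {
      g <- factor(data[[sm$by]], levels = sm$by_levels)
      for (lev in sm$by_levels[-1L]) {
        Zl <- Z * (g == lev)
        cols <- p0 + seq_len(ncol(Zl))
        parts[[length(parts) + 1L]] <- Zl
        blocks[[length(blocks) + 1L]] <- list(cols = cols, Pz = sm$Pz,
                                              term = sm$name)
        p0 <- p0 + ncol(Zl)
      }
    }
  }
  X <- do.call(cbind, parts)
  list(X = X, blocks = blocks, n_par = ncol(X_par))
}

penalty_matrix <- function(p, blocks, lambda) {
  S <- matrix(0, p, p)
  for (bl in blocks)
    S[bl$cols, bl$cols] <- S[bl$cols, bl$cols] + lambda[[bl$term]] * bl$Pz
  S
}

## Penalized weighted least squares at fixed lambda, from precomputed
## sufficient statistics. Returns coef, edf, rss, gcv.
pls_fit <- function(XtX, Xty, yty, n, blocks, lambda, ridge = 0) {
  p <- ncol(XtX)
  S <- penalty_matrix(p, blocks, lambda)
  A <- XtX + S
  if (ridge > 0) diag(A) <- diag(A) + ridge
  ch <- tryCatch(chol(A), error = function(e) NULL)
  if (is.null(ch)) {
    diag(A) <- diag(A) + 1e-7 * mean(diag(XtX))
    ch <- chol(A)
  }
  beta <- backsolve(ch, forwardsolve(t(ch), Xty))
  Ainv_XtX <- backsolve(ch, forwardsolve(t(ch), XtX))
  edf <- sum(diag(Ainv_XtX))
  rss <- max(yty - 2 * sum(beta * Xty) + sum(beta * (XtX %*% beta)), 0)
  gcv <- n * rss / (n - min(edf, n - 1e-8))^2
  list(beta = beta, edf = edf, rss = rss, gcv = gcv)
}

## Deterministic golden-section minimisation on [lo, hi].
golden_min <- function(f, lo, hi, tol = 0.05) {
  gr <- (sqrt(5) - 1) / 2
  a <- lo; b <- hi
  x1 <- b - gr * (b - a); x2 <- a + gr * (b - a)
  f1 <- f(x1); f2 <- f(x2)
  while (b - a > tol) {
    if (f1 <= f2) { b <- x2; x2 <- x1; f2 <- f1
      x1 <- b - gr * (b - a); f1 <- f(x1)
    } else { a <- x1; x1 <- x2; f1 <- f2
      x2 <- a + gr * (b - a); f2 <- f(x2) }
  }
  if (f1 <= f2) x1 else x2
}

## Coordinate-wise per-term GCV search over log10(lambda).
select_lambda <- function(obj, term_names, sweeps = 2,
                          log_range = c(-3, 8), tol = 0.05) {
  lam <- stats::setNames(rep(1, length(term_names)), term_names)
  if (!length(term_names)) return(lam)
  for (s in seq_len(sweeps)) {
    for (nm in term_names) {
      g <- function(l) {
        lam2 <- lam; lam2[[nm]] <- 10^l
        obj(lam2)
      }
      lam[[nm]] <- 10^golden_min(g, log_range[1], log_range[2], tol)
    }
  }
  lam
}

#' Fit a penalized-spline additive model
#'
#' Gaussian or logistic additive model in which each `smooth` covariate
#' enters through a p-spline (see [pspline_design()]) and each `linear`
#' covariate (numeric or categorical) enters parametrically. Smoothing
#' weights are chosen per smooth term by a golden-section search on
#' `log10(lambda)` against the generalized cross-validation score
#' `n * RSS / (n - edf)^2` (deviance-based analogue for the logistic model);
#' the search is deterministic given the data. Passing `structure =` a
#' previous fit re-estimates the coefficients on new data while freezing the
#' knots, constraints and smoothing weights of that fit — the fast refit
#' used inside bootstrap replicates.
#'
#' @param y Response vector (0/1 for `family = "binomial"`).
#' @param data Data frame of covariates (complete cases).
#' @param linear Character vector of parametric covariate names.
#' @param smooth Character vector of smooth covariate names.
#' @param smooth_by Optional named list mapping a smooth name to a factor
#'   column, adding level-specific deviation smooths (an interaction of the
#'   smooth with a baseline category).
#' @param family `"gaussian"` or `"binomial"`.
#' @param nbasis,degree,penalty_order P-spline settings (defaults: 8 cubic
#'   basis functions, second-order difference penalty).
#' @param lambda Optional fixed smoothing weights: a single value or named
#'   vector over smooth terms; `NULL` (default) selects by GCV.
#' @param sweeps Coordinate-descent sweeps of the per-term GCV search
#'   (default 1; the centred smooths are close to orthogonal, so further
#'   sweeps rarely move the selected weights).
#' @param structure A previous `padd` fit whose structure (knots, penalty,
#'   lambda, parametric coding) should be reused.
#' @param firth Use Firth's bias-reduced modified-score iteration for the
#'   logistic fit (recommended for rare outcomes; default `FALSE`).
#' @param smooth_structures Optional named list of pre-built smooth-term
#'   structures (common knots shared across the fits of a model set).
#' @param design_cache Optional environment memoising design blocks across
#'   fits on the same rows (internal use).
#' @return An object of class `padd` with coefficients, effective degrees of
#'   freedom, residual standard deviation `sigma` (gaussian), the GCV score,
#'   and everything needed by `predict()`.
#' @export
fit_additive <- function(y, data, linear = character(), smooth = character(),
                         smooth_by = NULL,
                         family = c("gaussian", "binomial"),
                         nbasis = 8, degree = 3, penalty_order = 2,
                         lambda = NULL, sweeps = 1, structure = NULL,
                         firth = FALSE, smooth_structures = NULL,
                         design_cache = NULL) {
  family <- if (!is.null(structure)) structure$family else match.arg(family)
  if (!is.null(structure)) firth <- isTRUE(structure$firth)
  n <- length(y)
  if (!is.null(structure)) {
    st <- structure$structure
    lam <- structure$lambda
  } else {
    st <- parse_structure(data, linear, smooth, smooth_by, nbasis, degree,
                          penalty_order, shared_smooths = smooth_structures)
    lam <- NULL
    if (!is.null(lambda)) {
      nms <- names(st$smooths)
      lam <- if (length(lambda) == 1L && is.null(names(lambda)))
        stats::setNames(rep(lambda, length(nms)), nms)
      else stats::setNames(lambda[nms], nms)
    }
  }
  ds <- build_design(st, data, cache = design_cache)
  X <- ds$X
  if (nrow(X) != n) stop("design/response length mismatch", call. = FALSE)
  if (n <= ncol(X) && is.null(lam) && family == "binomial")
    stop("fewer rows than coefficients", call. = FALSE)

  if (family == "gaussian") {
    XtX <- crossprod(X); Xty <- crossprod(X, y)[, 1L]; yty <- sum(y^2)
    if (is.null(lam)) {
      obj <- function(l) pls_fit(XtX, Xty, yty, n, ds$blocks, as.list(l))$gcv
      lam <- select_lambda(obj, names(st$smooths), sweeps = sweeps)
    }
    fit <- pls_fit(XtX, Xty, yty, n, ds$blocks, as.list(lam))
    fitted <- as.vector(X %*% fit$beta)
    sigma <- sqrt(fit$rss / max(n - fit$edf, 1))
    out <- list(family = family, coef = fit$beta, structure = st,
                lambda = lam, edf = fit$edf, sigma = sigma, gcv = fit$gcv,
                fitted = fitted, n = n, deviance = fit$rss,
                converged = TRUE)
  } else {
    irls <- function(S_extra_lam, beta0 = NULL) {
      if (firth) irls_firth(X, y, ds$blocks, S_extra_lam, beta0 = beta0)
      else irls_fit(X, y, ds$blocks, S_extra_lam, beta0 = beta0)
    }
    if (is.null(lam)) {
      ## performance iteration: alternate a penalized IRLS fit with a GCV
      ## search on the frozen working model; the deviance-based score uses
      ## an inflated df charge (gamma = 1.4) against the well-known
      ## undersmoothing of GCV for binary responses.
      lam <- stats::setNames(rep(1, length(st$smooths)), names(st$smooths))
      f0 <- NULL
      for (pi_it in 1:2) {
        f0 <- irls(as.list(lam), beta0 = f0$beta)
        w <- f0$w; z <- f0$z
        sw <- sqrt(w)
        Xw <- X * sw; zw <- z * sw
        XtX <- crossprod(Xw); Xty <- crossprod(Xw, zw)[, 1L]
        yty <- sum(zw^2)
        ## known-scale (UBRE/AIC-type) score on the working model:
        ## working RSS + 2 * gamma * edf, with the standard gamma = 1.4
        ## inflation against undersmoothing of binary fits
        obj <- function(l) {
          fl <- pls_fit(XtX, Xty, yty, n, ds$blocks, as.list(l))
          fl$rss + 2 * 1.4 * fl$edf
        }
        lam <- select_lambda(obj, names(st$smooths), sweeps = sweeps)
      }
      fit <- irls(as.list(lam), beta0 = f0$beta)
    } else {
      # warm start from the structure fit's coefficients when refitting
      b0 <- if (!is.null(structure) &&
                length(structure$coef) == ncol(X)) structure$coef
      fit <- irls(as.list(lam), beta0 = b0)
    }
    gcv <- n * fit$deviance / (n - min(fit$edf, n - 1e-8))^2
    out <- list(family = family, coef = fit$beta, structure = st,
                lambda = lam, edf = fit$edf, sigma = NA_real_, gcv = gcv,
                fitted = fit$mu, n = n, deviance = fit$deviance,
                converged = fit$converged, firth = firth)
  }
  class(out) <- "padd"
  out
}

## Firth-type modified-score IRLS: the working response is adjusted by
## h_i (1/2 - mu_i), removing the leading-order small-sample bias of the
## rare-event logistic MLE (and taming separation). Used by the death model.
irls_firth <- function(X, y, blocks, lambda, beta0 = NULL, maxit = 100,
                       tol = 1e-6) {
  n <- nrow(X); p <- ncol(X)
  S <- penalty_matrix(p, blocks, lambda)
  beta <- beta0 %||% c(stats::qlogis(clamp(mean(y), 1e-4, 1 - 1e-4)),
                       rep(0, p - 1L))
  converged <- FALSE
  for (it in seq_len(maxit)) {
    eta <- clamp(as.vector(X %*% beta), -30, 30)
    mu <- stats::plogis(eta)
    w <- pmax(mu * (1 - mu), 1e-10)
    sw <- sqrt(w)
    Xw <- X * sw
    A <- crossprod(Xw) + S
    ch <- tryCatch(chol(A), error = function(e) {
      diag(A) <<- diag(A) + 1e-7 * mean(diag(A))
      chol(A)
    })
    Ainv <- chol2inv(ch)
    h <- pmin(w * rowSums((X %*% Ainv) * X), 1 - 1e-8)
    z <- eta + (y + h * (0.5 - mu) - mu) / w
    beta_new <- as.vector(Ainv %*% crossprod(Xw, z * sw)[, 1L])
    delta <- beta_new - beta
    # logistf-style step cap keeps the modified-score iteration stable
    cap <- max(abs(delta))
    if (cap > 1) delta <- delta / cap
    beta <- beta + delta
    if (max(abs(delta)) / (max(abs(beta)) + 0.1) < tol) {
      converged <- TRUE
      break
    }
  }
  eta <- clamp(as.vector(X %*% beta), -30, 30)
  mu <- stats::plogis(eta)
  w <- pmax(mu * (1 - mu), 1e-10)
  Xw <- X * sqrt(w)
  A <- crossprod(Xw) + S
  edf <- sum(diag(solve(A, crossprod(Xw))))
  list(beta = beta, mu = mu, w = w, z = eta + (y - mu) / w, edf = edf,
       deviance = -2 * sum(y * log(pmax(mu, 1e-12)) +
                             (1 - y) * log(pmax(1 - mu, 1e-12))),
       converged = converged)
}

## Penalized IRLS for the logistic model; falls back to a small ridge when
## the likelihood is unbounded (complete separation).
irls_fit <- function(X, y, blocks, lambda, beta0 = NULL, maxit = 60,
                     tol = 1e-8) {
  n <- nrow(X); p <- ncol(X)
  S <- penalty_matrix(p, blocks, lambda)
  beta <- beta0 %||% c(stats::qlogis(clamp(mean(y), 1e-4, 1 - 1e-4)),
                       rep(0, p - 1L))
  pen_dev <- function(b) {
    eta <- clamp(as.vector(X %*% b), -30, 30)
    mu <- stats::plogis(eta)
    -2 * sum(y * log(pmax(mu, 1e-12)) + (1 - y) * log(pmax(1 - mu, 1e-12))) +
      sum(b * (S %*% b))
  }
  dev_old <- pen_dev(beta)
  ridge <- 0
  converged <- FALSE
  for (it in seq_len(maxit)) {
    eta <- clamp(as.vector(X %*% beta), -30, 30)
    mu <- stats::plogis(eta)
    w <- pmax(mu * (1 - mu), 1e-8)
    z <- eta + (y - mu) / w
    sw <- sqrt(w)
    Xw <- X * sw
    A <- crossprod(Xw) + S
    if (ridge > 0) diag(A) <- diag(A) + ridge
    ch <- tryCatch(chol(A), error = function(e) NULL)
    if (is.null(ch)) {
      ridge <- 1e-3 * mean(diag(crossprod(Xw)))
      warning("near-singular logistic fit; adding a small ridge",
              call. = FALSE)
      diag(A) <- diag(A) + ridge
      ch <- chol(A)
    }
    beta_new <- backsolve(ch, forwardsolve(t(ch),
                                           crossprod(Xw, z * sw)[, 1L]))
    # step-halving keeps the penalized deviance monotone
    dev_new <- pen_dev(beta_new)
    half <- 0L
    while (dev_new > dev_old + 1e-10 && half < 20L) {
      beta_new <- (beta + beta_new) / 2
      dev_new <- pen_dev(beta_new)
      half <- half + 1L
    }
    beta <- beta_new
    if (abs(dev_old - dev_new) < tol * (abs(dev_new) + 0.1)) {
      converged <- TRUE
      dev_old <- dev_new
      break
    }
    dev_old <- dev_new
  }
  if (!converged && ridge == 0) {
    # unbounded likelihood (complete separation): penalized refit
    warning("logistic fit did not converge; refitting with a small ridge",
            call. = FALSE)
    ridge <- 1e-3 * mean(diag(crossprod(X)))
    return(irls_fit_ridged(X, y, S, ridge, maxit, tol))
  }
  eta <- clamp(as.vector(X %*% beta), -30, 30)
  mu <- stats::plogis(eta)
  w <- pmax(mu * (1 - mu), 1e-8)
  sw <- sqrt(w)
  Xw <- X * sw
  A <- crossprod(Xw) + S
  diag(A) <- diag(A) + ridge
  edf <- sum(diag(solve(A, crossprod(Xw))))
  list(beta = beta, mu = mu, w = w, z = eta + (y - mu) / w, edf = edf,
       deviance = -2 * sum(y * log(pmax(mu, 1e-12)) +
                             (1 - y) * log(pmax(1 - mu, 1e-12))),
       converged = TRUE)
}

irls_fit_ridged <- function(X, y, S, ridge, maxit, tol) {
  p <- ncol(X)
  beta <- c(stats::qlogis(clamp(mean(y), 1e-4, 1 - 1e-4)), rep(0, p - 1L))
  dev_old <- Inf
  for (it in seq_len(maxit)) {
    eta <- clamp(as.vector(X %*% beta), -30, 30)
    mu <- stats::plogis(eta)
    dev <- -2 * sum(y * log(pmax(mu, 1e-12)) +
                      (1 - y) * log(pmax(1 - mu, 1e-12)))
    if (abs(dev_old - dev) < tol * (abs(dev) + 0.1)) break
    dev_old <- dev
    w <- pmax(mu * (1 - mu), 1e-8)
    z <- eta + (y - mu) / w
    sw <- sqrt(w)
    Xw <- X * sw
    A <- crossprod(Xw) + S
    diag(A) <- diag(A) + ridge
    beta <- solve(A, crossprod(Xw, z * sw)[, 1L])
  }
  eta <- clamp(as.vector(X %*% beta), -30, 30)
  mu <- stats::plogis(eta)
  w <- pmax(mu * (1 - mu), 1e-8)
  Xw <- X * sqrt(w)
  A <- crossprod(Xw) + S
  diag(A) <- diag(A) + ridge
  list(beta = beta, mu = mu, w = w, z = eta + (y - mu) / w,
       edf = sum(diag(solve(A, crossprod(Xw)))),
       deviance = -2 * sum(y * log(pmax(mu, 1e-12)) +
                             (1 - y) * log(pmax(1 - mu, 1e-12))),
       converged = TRUE)
}

#' @export
predict.padd <- function(object, newdata, type = c("link", "response"),
                         cache = NULL, ...) {
  ds <- build_design(object$structure, newdata, cache = cache)
  type <- match.arg(type)
  eta <- as.vector(ds$X %*% object$coef)
  if (type == "response" && object$family == "binomial")
    stats::plogis(clamp(eta, -30, 30))
  else eta
}

#' @export
print.padd <- function(x, ...) {
  cat(sprintf("Penalized additive model (%s): %d coefficients, edf %.1f, GCV %.4g\n",
              x$family, length(x$coef), x$edf, x$gcv))
  if (x$family == "gaussian") cat(sprintf("  residual SD: %.4g\n", x$sigma))
  invisible(x)
}

## Constant-probability stand-in used where a degenerate outcome model is
## needed (e.g. a time point with no deaths, or controlled simulations).
const_model <- function(p) structure(list(p = p), class = "padd_const")

#' @export
predict.padd_const <- function(object, newdata, type = "response", ...) {
  rep(object$p, nrow(newdata))
}

#' Select among candidate additive models by GCV
#'
#' Fits every candidate term structure to the same response and returns the
#' one minimising the generalized cross-validation score; on ties the
#' earliest candidate wins, so interaction candidates listed after their
#' main-effect counterparts are selected only when they *strictly* lower the
#' score.
#'
#' @param candidates List of term structures, each a list with elements
#'   `linear`, `smooth` and optionally `smooth_by` (see [fit_additive()]).
#' @param y Response vector.
#' @param data Covariate data frame.
#' @param family `"gaussian"` or `"binomial"`.
#' @param ... Further arguments passed to [fit_additive()].
#' @return List with the chosen `fit`, its `index` among the candidates, and
#'   the vector of GCV `scores`.
#' @export
gcv_select <- function(candidates, y, data,
                       family = c("gaussian", "binomial"), ...) {
  family <- match.arg(family)
  fits <- vector("list", length(candidates))
  scores <- rep(Inf, length(candidates))
  for (i in seq_along(candidates)) {
    cand <- candidates[[i]]
    fits[[i]] <- tryCatch(
      fit_additive(y, data, linear = cand$linear %||% character(),
                   smooth = cand$smooth %||% character(),
                   smooth_by = cand$smooth_by, family = family, ...),
      error = function(e) NULL)
    if (!is.null(fits[[i]])) scores[i] <- fits[[i]]$gcv
  }
  if (all(!is.finite(scores)))
    stop("no candidate model could be fitted", call. = FALSE)
  best <- which.min(scores)
  list(fit = fits[[best]], index = best, scores = scores)
}
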