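#' Nominal visit grid
#'
#' The discrete follow-up grid used throughout the package: the first clinic
#' visit (month 0), an early review at month 1, and 3-monthly visits from
#' month 3 up to the follow-up horizon.
#'
#' @param horizon Follow-up horizon in months; must be a multiple of 3
#'   (default 36).
#' @return Integer vector of nominal visit times in months.
#' @examples
#' visit_grid()
#' @export
visit_grid <- function(horizon = 36) {
  if (!is.numeric(horizon) || length(horizon) != 1L || !is.finite(horizon) ||
      horizon < 3 || horizon %% 3 != 0)
    stop("`horizon` must be a positive multiple of 3 months", call. = FALSE)
  c(0L, 1L, seq.int(3L, as.integer(horizon), by = 3L))
}

## Evaluate `expr` under a temporary RNG state seeded with `seed`; the caller's
## .Random.seed is restored afterwards so package functions never perturb the
## user's RNG stream.
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

## Deterministic sub-stream seed derivation: combines a master seed with one or
## more small integer indices into a new seed < 2^31 (R's integer range).
derive_seed <- function(seed, ...) {
  idx <- c(...)
  m <- 2147483629  # large prime < 2^31
  s <- as.double(seed) %% m
  for (k in seq_along(idx))
    s <- (s * 48271 + as.double(idx[k]) * 16807 + 11) %% m
  as.integer(s %% 2147483587) + 1L
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

`%||%` <- function(a, b) if (is.null(a)) b else a

stopifnot_scalar_prob <- function(x, name) {
  if (!is.numeric(x) || any(!is.finite(x)) || any(x < 0) || any(x > 1))
    stop(sprintf("`%s` must be a probability in [0, 1]", name), call. = FALSE)
}
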