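#' Dynamic ART-initiation rules
#'
#' Constructs a dynamic treatment regime: a rule that maps a child's current
#' immunological state to a treat/defer decision. Three kinds are supported:
#' `"immediate"` (treat from the first visit irrespective of CD4 criteria),
#' `"threshold"` (defer until the CD4 count falls below `cd4_threshold` *or*
#' the CD4% falls below `pct_threshold`), and `"never"`. Decisions are
#' absorbing: once a child is on ART, the rule keeps them on ART.
#'
#' @param kind One of `"immediate"`, `"threshold"`, `"never"`.
#' @param cd4_threshold CD4-count threshold in cells/mm3 (threshold kind).
#' @param pct_threshold CD4% threshold in percent (threshold kind).
#' @param label Optional display label.
#' @return An object of class `art_regime`.
#' @examples
#' regime("threshold", 750, 25)
#' @export
regime <- function(kind = c("immediate", "threshold", "never"),
                   cd4_threshold = NULL, pct_threshold = NULL,
                   label = NULL) {
  kind <- match.arg(kind)
  if (kind == "threshold") {
    if (is.null(cd4_threshold) || is.null(pct_threshold) ||
        !is.finite(cd4_threshold) || !is.finite(pct_threshold) ||
        cd4_threshold <= 0 || pct_threshold <= 0)
      stop("threshold regimes need positive `cd4_threshold` and `pct_threshold`",
           call. = FALSE)
  } else {
    cd4_threshold <- pct_threshold <- NULL
  }
  label <- label %||% switch(kind,
    immediate = "immediate ART",
    never = "no ART",
    threshold = sprintf("ART at <%g cells/mm3 or <%g%%",
                        cd4_threshold, pct_threshold))
  structure(list(kind = kind, cd4_threshold = cd4_threshold,
                 pct_threshold = pct_threshold, label = label),
            class = "art_regime")
}

#' @export
print.art_regime <- function(x, ...) {
  cat("ART regime:", x$label, "\n")
  invisible(x)
}

#' The five initiation strategies of the primary analysis
#'
#' Immediate ART; deferral thresholds 750 cells/mm3 or 25%, 500 or 20%,
#' 250 or 15%; and no ART.
#'
#' @return A named list of [regime()] objects.
#' @export
standard_regimes <- function() {
  list(immediate = regime("immediate"),
       t750 = regime("threshold", 750, 25),
       t500 = regime("threshold", 500, 20),
       t250 = regime("threshold", 250, 15),
       never = regime("never"))
}

#' Treat/defer decision of a regime
#'
#' Vectorised over children. A threshold rule treats when the child is
#' already on ART (absorbing) or when the CD4 count falls strictly below the
#' count threshold *or* the CD4% strictly below the percentage threshold.
#'
#' @param regime An [regime()] object.
#' @param cd4 CD4 count(s), cells/mm3.
#' @param cd4pct CD4 percentage(s).
#' @param on_art Current on-ART indicator(s) (0/1).
#' @return Integer vector of 0/1 treatment indicators.
#' @examples
#' regime_decision(regime("threshold", 750, 25), cd4 = 800, cd4pct = 24,
#'                 on_art = 0)
#' @export
regime_decision <- function(regime, cd4, cd4pct, on_art = 0L) {
  stopifnot(inherits(regime, "art_regime"))
  n <- max(length(cd4), length(cd4pct), length(on_art))
  if (regime$kind == "immediate") return(rep(1L, n))
  if (regime$kind == "never") return(rep(0L, n))
  cd4 <- rep_len(cd4, n); cd4pct <- rep_len(cd4pct, n)
  on_art <- rep_len(on_art, n)
  need <- on_art == 0L
  if (any(need & (!is.finite(cd4) | !is.finite(cd4pct))))
    stop("threshold decision requires complete simulated CD4 and CD4% state",
         call. = FALSE)
  as.integer(on_art == 1L | cd4 < regime$cd4_threshold |
               cd4pct < regime$pct_threshold)
}

#' Classify the CD4 state at ART initiation into threshold bands
#'
#' Assigns the (CD4 count, CD4%) pair recorded at ART start to the first
#' matching mutually exclusive band: below 250 cells/mm3 or 15%, below 500 or
#' 20%, below 750 or 25%, else above 750 *and* above 25%. A child with a CD4
#' count of 650 cells/mm3 and a CD4% of 19% falls in the "<500 cells/mm3 or
#' <20%" band. If both values are missing the band is `"Unknown"`; if one is
#' missing the available value alone is classified.
#'
#' @param cd4 CD4 count(s) at ART start (cells/mm3), may be `NA`.
#' @param cd4pct CD4 percentage(s) at ART start, may be `NA`.
#' @return Character vector of band labels.
#' @examples
#' classify_initiation_band(650, 19)
#' @export
classify_initiation_band <- function(cd4, cd4pct) {
  n <- max(length(cd4), length(cd4pct))
  cd4 <- rep_len(as.numeric(cd4), n)
  cd4pct <- rep_len(as.numeric(cd4pct), n)
  bands <- cbind(c(250, 500, 750), c(15, 20, 25))
  labels <- c("<250 cells/mm3 or <15%", "<500 cells/mm3 or <20%",
              "<750 cells/mm3 or <25%", ">750 cells/mm3 and >25%")
  out <- character(n)
  for (i in seq_len(n)) {
    if (is.na(cd4[i]) && is.na(cd4pct[i])) { out[i] <- "Unknown"; next }
    hit <- which((!is.na(cd4[i]) & cd4[i] < bands[, 1]) |
                   (!is.na(cd4pct[i]) & cd4pct[i] < bands[, 2]))
    out[i] <- if (length(hit)) labels[min(hit)] else labels[4L]
  }
  out
}
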