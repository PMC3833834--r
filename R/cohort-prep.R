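#' Apply the eligibility criteria
#'
#' Retains children at least 24 and at most 60 months of age at enrolment,
#' ART-naive at entry (no ART start predating the first visit), and with
#' follow-up data: a visit after the enrolment visit, or a recorded
#' post-enrolment event (death or ART start, which are ascertained
#' independently of the visit record — dropping children who die before
#' their first review visit would truncate early mortality out of the
#' analysis population). Each excluded child is counted once under the
#' first criterion it fails (age, then prior ART, then no follow-up).
#'
#' @param raw A `raw_cohort` (see [generate_cohort()] / [read_cohort()]).
#' @return A list with elements `cohort` (the filtered `raw_cohort`) and
#'   `exclusions` (named integer vector of counts:
#'   `age_under`, `age_over`, `prior_art`, `no_followup`, `retained`).
#' @export
filter_eligible <- function(raw) {
  stopifnot(inherits(raw, "raw_cohort"))
  b <- raw$baseline
  ev <- raw$events[match(b$id, raw$events$id), , drop = FALSE]
  fup <- tapply(raw$visits$time > 0, raw$visits$id, any)
  has_fup <- as.logical(fup[as.character(b$id)])
  has_fup[is.na(has_fup)] <- FALSE
  has_fup <- has_fup | (!is.na(ev$death) & ev$death > 0) |
    (!is.na(ev$art_start) & ev$art_start > 0)

  age_m <- b$age * 12
  reason <- rep(NA_character_, nrow(b))
  reason[is.na(reason) & age_m < 24] <- "age_under"
  reason[is.na(reason) & age_m > 60] <- "age_over"
  reason[is.na(reason) & !is.na(ev$art_start) & ev$art_start < 0] <- "prior_art"
  reason[is.na(reason) & !has_fup] <- "no_followup"

  keep <- b$id[is.na(reason)]
  excl <- c(age_under = sum(reason == "age_under", na.rm = TRUE),
            age_over = sum(reason == "age_over", na.rm = TRUE),
            prior_art = sum(reason == "prior_art", na.rm = TRUE),
            no_followup = sum(reason == "no_followup", na.rm = TRUE),
            retained = length(keep))
  truth <- attr(raw, "truth")
  out <- raw_cohort(
    baseline = raw$baseline[raw$baseline$id %in% keep, , drop = FALSE],
    visits = raw$visits[raw$visits$id %in% keep, , drop = FALSE],
    events = raw$events[raw$events$id %in% keep, , drop = FALSE],
    truth = if (!is.null(truth)) truth[truth$id %in% keep, , drop = FALSE],
    grid = attr(raw, "grid") %||% visit_grid())
  list(cohort = out, exclusions = excl)
}

#' Discretise irregular visits onto the nominal grid
#'
#' Maps each child's irregularly timed visit records onto the nominal visit
#' grid. Each nominal time owns the half-open window between the midpoints
#' with its neighbouring nominal times (the enrolment window is exactly
#' \{0\}; the last window extends 1.5 months past the horizon); within a
#' window the observation closest to the nominal time is selected, the
#' earlier observation winning ties. Windows without an observation yield
#' missing cells. The on-ART indicator switches on at the first nominal time
#' at or after the recorded ART start; the death indicator is set at the
#' first nominal time at or after the death month, and no rows follow it.
#'
#' @param raw A `raw_cohort`, usually after [filter_eligible()].
#' @param horizon Follow-up horizon in months (default 36).
#' @return An `interval_panel`: one row per child and nominal time with
#'   columns `id`, `t`, the time-dependent confounders `cd4`, `cd4pct`,
#'   `waz`, per-confounder `carried_*` flags (all `FALSE` here; see
#'   [apply_locf()]), `art` (on ART by `t`), `death` (death in the interval
#'   ending at `t`), `cens`/`cens_reason` (set by [flag_ltfu()]), and the
#'   child's baseline covariates (`age`, `sex`, `region`, `cd4_0`,
#'   `cd4pct_0`, `waz_0`, `haz_0`). Events are carried in the `"events"`
#'   attribute.
#' @export
discretise <- function(raw, horizon = 36) {
  stopifnot(inherits(raw, "raw_cohort"))
  grid <- visit_grid(horizon)
  K <- length(grid)
  mid <- (grid[-K] + grid[-1L]) / 2
  lo <- c(-1e-9, mid)
  hi <- c(0, if (K > 2L) mid[-1L], grid[K] + 1.5)

  n_beyond <- sum(raw$visits$time > grid[K] + 1.5)
  if (n_beyond > 0)
    warning(sprintf("%d visit(s) beyond the horizon window were ignored",
                    n_beyond), call. = FALSE)

  b <- raw$baseline
  ev <- raw$events[match(b$id, raw$events$id), , drop = FALSE]
  vis_by_id <- split(raw$visits, raw$visits$id)

  nb <- nrow(b)
  acc <- list(id = vector("list", nb), t = vector("list", nb),
              L = vector("list", nb), art = vector("list", nb),
              death = vector("list", nb))
  n_rows_child <- integer(nb)
  for (i in seq_len(nb)) {
    id <- b$id[i]
    v <- vis_by_id[[as.character(id)]]
    death <- ev$death[i]
    death_k <- if (!is.na(death)) {
      kk <- which(grid >= death)
      if (length(kk)) kk[1L] else NA_integer_
    } else NA_integer_
    end_k <- if (!is.na(death_k)) death_k else K

    tt <- grid[seq_len(end_k)]
    L <- matrix(NA_real_, end_k, 3)
    if (!is.null(v) && nrow(v)) {
      ## coarse window by the right edges, then the exact (lo, hi] check
      win <- findInterval(v$time - 1e-12, c(lo[1L], hi))
      for (k in seq_len(end_k)) {
        in_win <- which(win == k & v$time > lo[k])
        if (!length(in_win)) next
        d <- abs(v$time[in_win] - grid[k])
        sel <- in_win[order(d, v$time[in_win])][1L]
        L[k, ] <- c(v$cd4[sel], v$cd4pct[sel], v$waz[sel])
      }
    }
    art_start <- ev$art_start[i]
    art <- if (is.na(art_start)) rep(0L, end_k)
           else as.integer(tt >= art_start)
    dth <- integer(end_k)
    if (!is.na(death_k)) dth[end_k] <- 1L
    acc$id[[i]] <- rep(id, end_k); acc$t[[i]] <- tt; acc$L[[i]] <- L
    acc$art[[i]] <- art; acc$death[[i]] <- dth
    n_rows_child[i] <- end_k
  }
  Lall <- do.call(rbind, acc$L)
  rep_b <- rep(seq_len(nb), n_rows_child)
  panel <- data.frame(
    id = unlist(acc$id), t = unlist(acc$t),
    cd4 = Lall[, 1L], cd4pct = Lall[, 2L], waz = Lall[, 3L],
    carried_cd4 = FALSE, carried_cd4pct = FALSE, carried_waz = FALSE,
    art = unlist(acc$art), death = unlist(acc$death), cens = 0L,
    cens_reason = "none",
    age = b$age[rep_b], sex = b$sex[rep_b], region = b$region[rep_b],
    cd4_0 = b$cd4[rep_b], cd4pct_0 = b$cd4pct[rep_b],
    waz_0 = b$waz[rep_b], haz_0 = b$haz[rep_b])
  structure(panel, grid = grid, horizon = grid[K], events = raw$events,
            class = c("interval_panel", "data.frame"))
}

#' Last observation carried forward (9-month limit)
#'
#' Fills each missing follow-up confounder cell with the child's most recent
#' observed value of that confounder, provided the nominal-time gap does not
#' exceed `max_gap` months. Filled cells are flagged `carried_*`; cells
#' beyond the gap (and cells with no prior observation — there is no backward
#' carry) remain missing for the imputation step.
#'
#' @param panel An `interval_panel` from [discretise()].
#' @param max_gap Maximum carry distance in months (default 9).
#' @return The panel with filled cells and carried flags set.
#' @export
apply_locf <- function(panel, max_gap = 9) {
  stopifnot(inherits(panel, "interval_panel"))
  vars <- c("cd4", "cd4pct", "waz")
  ord <- order(panel$id, panel$t)
  panel <- panel[ord, , drop = FALSE]
  idx_by_id <- split(seq_len(nrow(panel)), panel$id)
  for (var in vars) {
    flag <- paste0("carried_", var)
    x <- panel[[var]]
    fl <- panel[[flag]]
    tt <- panel$t
    for (ix in idx_by_id) {
      last_t <- -Inf; last_v <- NA_real_
      for (j in ix) {
        if (!is.na(x[j])) {
          last_t <- tt[j]; last_v <- x[j]
        } else if (tt[j] - last_t <= max_gap) {
          x[j] <- last_v; fl[j] <- TRUE
        }
      }
    }
    panel[[var]] <- x
    panel[[flag]] <- fl
  }
  rownames(panel) <- NULL
  panel
}

#' Flag loss to follow-up and censor the panel
#'
#' Children not recorded dead whose last clinic contact precedes database
#' closure by more than 9 months are lost to follow-up: they are censored at
#' the first grid time after their last contact (`cens_reason = "ltfu"`).
#' Other children without a death record are administratively censored at the
#' first grid time after their last contact when that precedes the horizon
#' (`cens_reason = "admin"`). Rows after a censoring row are removed;
#' recorded deaths are never censored.
#'
#' @param panel An `interval_panel`.
#' @param closure Database-closure time on the months-since-first-visit
#'   scale; must be at least every child's last contact. Defaults to the
#'   maximum last contact.
#' @return The censored panel.
#' @export
flag_ltfu <- function(panel, closure = NULL) {
  stopifnot(inherits(panel, "interval_panel"))
  ev <- attr(panel, "events")
  if (is.null(ev)) stop("panel lacks the events attribute", call. = FALSE)
  grid <- attr(panel, "grid")
  closure <- closure %||% max(ev$last_contact)
  if (closure < max(ev$last_contact))
    stop("`closure` must be at least every last-contact time", call. = FALSE)
  keep <- rep(TRUE, nrow(panel))
  for (i in seq_len(nrow(ev))) {
    if (!is.na(ev$death[i])) next
    lc <- ev$last_contact[i]
    k_after <- which(grid > lc)
    if (!length(k_after)) next                    # in care through the horizon
    cens_t <- grid[k_after[1L]]
    reason <- if (closure - lc > 9) "ltfu" else "admin"
    ix <- which(panel$id == ev$id[i])
    row_c <- ix[panel$t[ix] == cens_t]
    if (length(row_c)) {
      panel$cens[row_c] <- 1L
      panel$cens_reason[row_c] <- reason
      keep[ix[panel$t[ix] > cens_t]] <- FALSE
    }
  }
  out <- panel[keep, , drop = FALSE]
  rownames(out) <- NULL
  structure(out, grid = grid, horizon = attr(panel, "horizon"),
            events = ev, class = class(panel))
}

## Structural checks on an interval panel: absorbing death/censoring,
## nondecreasing treatment, grid-only times. Used by tests and internally
## before model fitting.
validate_panel <- function(panel) {
  grid <- attr(panel, "grid")
  if (!all(panel$t %in% grid)) stop("panel times off the grid")
  by_id <- split(seq_len(nrow(panel)), panel$id)
  for (ix in by_id) {
    ix <- ix[order(panel$t[ix])]
    a <- panel$art[ix]
    if (any(diff(a) < 0)) stop("treatment not nondecreasing")
    y <- panel$death[ix]; cc <- panel$cens[ix]
    if (any(y == 1L) && max(which(y == 1L)) != length(ix))
      stop("rows after death")
    if (any(cc == 1L) && max(which(cc == 1L)) != length(ix))
      stop("rows after censoring")
    if (sum(y) + sum(cc) > 1L) stop("death and censoring both present")
  }
  invisible(TRUE)
}

#' Cohort and panel CSV input/output
#'
#' Writes the three raw-cohort tables (`baseline.csv`, `visits.csv`,
#' `events.csv`) to a directory with empty strings for missing cells, and
#' reads them back; `write_panel()`/`read_panel()` do the same for a tidy
#' interval panel.
#'
#' @param x A `raw_cohort` or `interval_panel`.
#' @param dir,path Target directory / CSV file path.
#' @return The read functions return the reconstructed object; the write
#'   functions return the target path invisibly.
#' @export
write_cohort <- function(x, dir) {
  stopifnot(inherits(x, "raw_cohort"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  for (nm in c("baseline", "visits", "events"))
    utils::write.csv(x[[nm]], file.path(dir, paste0(nm, ".csv")),
                     row.names = FALSE, na = "")
  invisible(dir)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(dir) {
  rd <- function(nm) utils::read.csv(file.path(dir, paste0(nm, ".csv")),
                                     na.strings = "",
                                     stringsAsFactors = FALSE)
  raw_cohort(baseline = rd("baseline"), visits = rd("visits"),
             events = rd("events"), truth = NULL, grid = visit_grid())
}

#' @rdname write_cohort
#' @export
write_panel <- function(x, path) {
  stopifnot(inherits(x, "interval_panel"))
  utils::write.csv(as.data.frame(x), path, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_panel <- function(path, horizon = 36) {
  df <- utils::read.csv(path, na.strings = "", stringsAsFactors = FALSE)
  structure(df, grid = visit_grid(horizon), horizon = horizon,
            events = NULL, class = c("interval_panel", "data.frame"))
}
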