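#' Intermediate-event clock
#'
#' An event clock holds the (possibly absent) intermediate-event time
#' \eqn{\rho} of a subject and answers the two time-indexing questions every
#' submodel needs: has the intermediate event occurred by time \eqn{t}
#' (\eqn{R(t) = I(t \ge \rho)}), and how long ago
#' (\eqn{t^+ = \max(0, t - \rho)}). The boundary is closed at \eqn{\rho}:
#' \eqn{R(\rho) = 1}.
#'
#' @param rho Intermediate-event time (a single nonnegative number), or `NA`
#'   if the subject never experiences the intermediate event.
#' @return An object of class `event_clock`.
#' @examples
#' cl <- event_clock(4)
#' event_indicator(cl, c(3, 4, 10))
#' relative_time(cl, c(3, 4, 10))
#' @export
event_clock <- function(rho = NA_real_) {
  if (length(rho) != 1L) stop("'rho' must be a single value or NA")
  rho <- as.numeric(rho)
  if (!is.na(rho) && rho < 0) stop("'rho' must be nonnegative")
  structure(list(rho = rho), class = "event_clock")
}

#' @export
print.event_clock <- function(x, ...) {
  if (is.na(x$rho)) {
    cat("Event clock: no intermediate event\n")
  } else {
    cat("Event clock: intermediate event at rho =", format(x$rho), "\n")
  }
  invisible(x)
}

has_event <- function(clock) !is.na(clock$rho)

#' Intermediate-event indicator R(t)
#'
#' @param clock An [event_clock()].
#' @param t Vector of nonnegative times.
#' @return Integer vector, `I(t >= rho)`; all zeros when the clock carries no
#'   intermediate event.
#' @export
event_indicator <- function(clock, t) {
  stopifnot(inherits(clock, "event_clock"))
  if (any(t < 0)) stop("'t' must be nonnegative")
  if (!has_event(clock)) return(integer(length(t)))
  as.integer(t >= clock$rho)
}

#' Time since the intermediate event t+
#'
#' @inheritParams event_indicator
#' @return Numeric vector `max(0, t - rho)`; zeros when the clock carries no
#'   intermediate event.
#' @export
relative_time <- function(clock, t) {
  stopifnot(inherits(clock, "event_clock"))
  if (any(t < 0)) stop("'t' must be nonnegative")
  if (!has_event(clock)) return(numeric(length(t)))
  pmax(0, t - clock$rho)
}

#' Per-subject follow-up record
#'
#' Bundles the repeated biomarker measurements and the survival triple of one
#' subject: visit times and values, baseline covariates for the two
#' submodels, observed event/censoring time `T_obs`, event indicator `delta`,
#' and the intermediate-event time `rho` (`NA` if none).
#'
#' @param id Subject identifier.
#' @param obs_times Strictly increasing visit times, all `<= T_obs`.
#' @param y Biomarker values aligned with `obs_times`.
#' @param T_obs Observed event or censoring time (positive).
#' @param delta Event indicator, 0 (censored) or 1 (event).
#' @param rho Intermediate-event time or `NA`.
#' @param x_baseline Named numeric vector of longitudinal-submodel baseline
#'   covariates (may be empty).
#' @param w_baseline Named numeric vector of survival-submodel baseline
#'   covariates (may be empty).
#' @return An object of class `subject_data`.
#' @export
subject_data <- function(id, obs_times, y, T_obs, delta, rho = NA_real_,
                         x_baseline = numeric(), w_baseline = numeric()) {
  keep <- !is.na(y)
  if (!all(keep)) {
    warning(sprintf("subject %s: dropping %d visit(s) with missing biomarker",
                    as.character(id), sum(!keep)))
    obs_times <- obs_times[keep]
    y <- y[keep]
  }
  structure(list(id = id,
                 obs_times = as.numeric(obs_times),
                 y = as.numeric(y),
                 T_obs = as.numeric(T_obs),
                 delta = as.integer(delta),
                 rho = as.numeric(rho),
                 x_baseline = x_baseline,
                 w_baseline = w_baseline),
            class = "subject_data")
}

subject_clock <- function(subj) event_clock(subj$rho)

#' Study container
#'
#' @param subjects List of [subject_data()] records with unique ids.
#' @param meta Optional list of column names / units.
#' @return An object of class `study_data`.
#' @export
study_data <- function(subjects, meta = list()) {
  structure(list(subjects = subjects, meta = meta), class = "study_data")
}

#' @export
print.study_data <- function(x, ...) {
  n <- length(x$subjects)
  nie <- sum(vapply(x$subjects, function(s) !is.na(s$rho), logical(1)))
  nev <- sum(vapply(x$subjects, function(s) s$delta, integer(1)))
  nobs <- sum(vapply(x$subjects, function(s) length(s$y), integer(1)))
  cat(sprintf(paste0("Study with %d subjects, %d longitudinal measurements\n",
                     "  events: %d (%.1f%%), intermediate events: %d (%.1f%%)\n"),
              n, nobs, nev, 100 * nev / max(n, 1), nie, 100 * nie / max(n, 1)))
  invisible(x)
}

#' Validate a study against the container invariants
#'
#' Checks every subject for ordered visit times within follow-up, positive
#' observed time, aligned biomarker vector, a valid event indicator and a
#' nonnegative intermediate-event time, plus study-level uniqueness of ids.
#' Violations are reported, not thrown, so a partially dirty import can be
#' inspected.
#'
#' @param data A [study_data()] object.
#' @return A list with elements `ok` (logical) and `violations` (character
#'   vector, empty when the study is clean).
#' @export
validate_study <- function(data) {
  stopifnot(inherits(data, "study_data"))
  v <- character()
  if (length(data$subjects) == 0L) {
    v <- c(v, "study contains no subjects")
  }
  ids <- vapply(data$subjects, function(s) as.character(s$id), character(1))
  if (anyDuplicated(ids)) {
    v <- c(v, sprintf("duplicated subject ids: %s",
                      paste(unique(ids[duplicated(ids)]), collapse = ", ")))
  }
  for (s in data$subjects) {
    tag <- sprintf("subject %s", as.character(s$id))
    if (length(s$obs_times) != length(s$y))
      v <- c(v, sprintf("%s: obs_times and y differ in length", tag))
    if (length(s$obs_times) > 1 && any(diff(s$obs_times) <= 0))
      v <- c(v, sprintf("%s: obs_times not strictly increasing", tag))
    if (!is.finite(s$T_obs) || s$T_obs <= 0)
      v <- c(v, sprintf("%s: T_obs must be positive", tag))
    if (length(s$obs_times) && any(s$obs_times > s$T_obs))
      v <- c(v, sprintf("%s: visit time beyond observed time T_obs", tag))
    if (length(s$obs_times) && any(s$obs_times < 0))
      v <- c(v, sprintf("%s: negative visit time", tag))
    if (!s$delta %in% c(0L, 1L))
      v <- c(v, sprintf("%s: delta must be 0 or 1", tag))
    if (!is.na(s$rho) && s$rho < 0)
      v <- c(v, sprintf("%s: negative intermediate-event time", tag))
  }
  list(ok = length(v) == 0L, violations = v)
}

# ---- long/survival CSV interface --------------------------------------------

#' Read a study from the long-format CSV pair
#'
#' The longitudinal file has columns `id, time, y` followed by any baseline
#' covariates; the survival file has `id, time_obs, status, rho` (empty
#' `rho` = no intermediate event) followed by baseline covariates. Covariate
#' columns present in the longitudinal file feed the longitudinal submodel
#' (`x_baseline`); those in the survival file feed the survival submodel
#' (`w_baseline`).
#'
#' @param long_file Path to the longitudinal CSV.
#' @param surv_file Path to the survival CSV.
#' @return A [study_data()] object.
#' @export
read_study <- function(long_file, surv_file) {
  lng <- read.csv(long_file, stringsAsFactors = FALSE)
  srv <- read.csv(surv_file, stringsAsFactors = FALSE)
  need_l <- c("id", "time", "y")
  need_s <- c("id", "time_obs", "status", "rho")
  if (!all(need_l %in% names(lng)))
    stop("longitudinal CSV must contain columns: ", paste(need_l, collapse = ", "))
  if (!all(need_s %in% names(srv)))
    stop("survival CSV must contain columns: ", paste(need_s, collapse = ", "))
  xcov <- setdiff(names(lng), need_l)
  wcov <- setdiff(names(srv), need_s)
  subjects <- lapply(seq_len(nrow(srv)), function(k) {
    id <- srv$id[k]
    rows <- lng[lng$id == id, , drop = FALSE]
    rows <- rows[order(rows$time), , drop = FALSE]
    xb <- if (length(xcov)) {
      if (nrow(rows)) unlist(rows[1, xcov, drop = TRUE])
      else setNames(rep(NA_real_, length(xcov)), xcov)
    } else numeric()
    subject_data(id = id,
                 obs_times = rows$time, y = rows$y,
                 T_obs = srv$time_obs[k], delta = srv$status[k],
                 rho = if (is.na(srv$rho[k])) NA_real_ else srv$rho[k],
                 x_baseline = xb,
                 w_baseline = if (length(wcov)) unlist(srv[k, wcov, drop = TRUE]) else numeric())
  })
  study_data(subjects,
             meta = list(long_covariates = xcov, surv_covariates = wcov))
}

#' Convert a study to the long-format data frame pair
#'
#' @param data A [study_data()] object.
#' @return A list with data frames `longitudinal` and `survival`, the inverse
#'   of [read_study()].
#' @export
as_study_frames <- function(data) {
  stopifnot(inherits(data, "study_data"))
  lng <- do.call(rbind, lapply(data$subjects, function(s) {
    if (!length(s$obs_times)) return(NULL)
    df <- data.frame(id = s$id, time = s$obs_times, y = s$y)
    for (nm in names(s$x_baseline)) df[[nm]] <- s$x_baseline[[nm]]
    df
  }))
  srv <- do.call(rbind, lapply(data$subjects, function(s) {
    df <- data.frame(id = s$id, time_obs = s$T_obs, status = s$delta,
                     rho = s$rho)
    for (nm in names(s$w_baseline)) df[[nm]] <- s$w_baseline[[nm]]
    df
  }))
  if (is.null(lng)) lng <- data.frame(id = character(), time = numeric(), y = numeric())
  list(longitudinal = lng, survival = srv)
}

#' Write a study to the CSV pair read by [read_study()]
#'
#' @inheritParams as_study_frames
#' @param long_file,surv_file Output paths.
#' @return Invisibly, the list of data frames written.
#' @export
write_study <- function(data, long_file, surv_file) {
  fr <- as_study_frames(data)
  write.csv(fr$longitudinal, long_file, row.names = FALSE, na = "")
  write.csv(fr$survival, surv_file, row.names = FALSE, na = "")
  invisible(fr)
}
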