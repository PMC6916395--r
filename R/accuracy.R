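# Subjects at risk at the landmark, with their intermediate-event stratum:
# A = intermediate event not yet occurred at t, B = occurred at or before t.
risk_set_frame <- function(data, t) {
  subs <- data$subjects
  df <- data.frame(
    id = vapply(subs, function(s) as.character(s$id), character(1)),
    T_obs = vapply(subs, function(s) s$T_obs, numeric(1)),
    delta = vapply(subs, function(s) s$delta, integer(1)),
    rho = vapply(subs, function(s) s$rho, numeric(1)),
    stringsAsFactors = FALSE)
  df <- df[df$T_obs > t, , drop = FALSE]
  df$stratum <- ifelse(!is.na(df$rho) & df$rho <= t, "B", "A")
  df
}

merge_predictions <- function(rs, predictions, need_cens = TRUE) {
  if (!all(c("id", "pi_u_t") %in% names(predictions)))
    stop("'predictions' must have columns id, pi_u_t (and pi_u_Ti for censored-in-window subjects)")
  predictions$id <- as.character(predictions$id)
  m <- match(rs$id, predictions$id)
  if (anyNA(m))
    stop("subjects missing predictions: ", paste(rs$id[is.na(m)], collapse = ", "))
  rs$pi_u_t <- predictions$pi_u_t[m]
  rs$pi_u_Ti <- if ("pi_u_Ti" %in% names(predictions)) predictions$pi_u_Ti[m] else NA_real_
  rs
}

#' Comparable and censoring-limited pairs for the time-dependent AUC
#'
#' Enumerates the ordered subject pairs entering the stratified AUC
#' decomposition at landmark `t` and horizon `dt`. Pairs are formed only
#' within an intermediate-event stratum (both subjects pre-event, or both
#' post-event, at `t`). The four sets are: (1) case with an observed event
#' in the window vs a survivor beyond it; (2) subject censored in the
#' window vs a survivor; (3) observed case vs a subject censored later in
#' the window; (4) censored subject vs a later-censored subject. Sets 2-4
#' carry the probability weights \eqn{\hat\nu} that the pair would have
#' been comparable.
#'
#' @param data A [study_data()].
#' @param predictions Data frame with columns `id`, `pi_u_t`
#'   (\eqn{\hat\pi(t+\Delta t \mid t)}) and `pi_u_Ti`
#'   (\eqn{\hat\pi(t+\Delta t \mid T_i)}, needed for subjects censored
#'   inside the window).
#' @param t Landmark time.
#' @param dt Horizon.
#' @return Data frame with one row per contributing ordered pair: ids,
#'   stratum, set (`omega`), weight, and the concordance indicator.
#' @export
classify_pairs <- function(data, predictions, t, dt) {
  rs <- merge_predictions(risk_set_frame(data, t), predictions)
  u <- t + dt
  out <- list()
  for (st in c("A", "B")) {
    d <- rs[rs$stratum == st, , drop = FALSE]
    if (!nrow(d)) next
    win1 <- which(d$T_obs > t & d$T_obs <= u & d$delta == 1L)
    win0 <- which(d$T_obs > t & d$T_obs <= u & d$delta == 0L)
    surv <- which(d$T_obs > u)
    cens_pi <- function(i) {
      v <- d$pi_u_Ti[i]
      if (anyNA(v))
        stop("missing pi_u_Ti for censored-in-window subjects: ",
             paste(d$id[i][is.na(v)], collapse = ", "))
      v
    }
    pair_rows <- function(ii, jj, omega, w_fun) {
      if (!length(ii) || !length(jj)) return(NULL)
      g <- expand.grid(i = ii, j = jj)
      g <- g[d$T_obs[g$i] < d$T_obs[g$j] | omega %in% 1:2, , drop = FALSE]
      if (!nrow(g)) return(NULL)
      data.frame(id_i = d$id[g$i], id_j = d$id[g$j], stratum = st,
                 omega = omega, weight = w_fun(g$i, g$j),
                 concordant = as.integer(d$pi_u_t[g$i] < d$pi_u_t[g$j]),
                 tie = as.integer(d$pi_u_t[g$i] == d$pi_u_t[g$j]))
    }
    out <- c(out, list(
      pair_rows(win1, surv, 1L, function(i, j) rep(1, length(i))),
      pair_rows(win0, surv, 2L, function(i, j) 1 - cens_pi(i)),
      pair_rows(win1, win0, 3L, function(i, j) cens_pi(j)),
      pair_rows(win0, win0, 4L, function(i, j) (1 - cens_pi(i)) * cens_pi(j))))
  }
  out <- out[!vapply(out, is.null, logical(1))]
  if (!length(out))
    return(data.frame(id_i = character(), id_j = character(), stratum = character(),
                      omega = integer(), weight = numeric(), concordant = integer(),
                      tie = integer()))
  do.call(rbind, out)
}

#' Intermediate-event-stratified time-dependent AUC
#'
#' Estimates AUC(`t`, `dt`) from the pair decomposition of
#' [classify_pairs()]: directly comparable pairs count with weight one, and
#' pairs limited by censoring are weighted by the probability that they
#' would have been comparable. The headline value pools the weighted
#' concordant and comparable masses over both intermediate-event strata
#' (and so is bounded by 1); the per-stratum ratios and per-component
#' values are reported alongside.
#'
#' @inheritParams classify_pairs
#' @return An object of class `jmie_accuracy` with elements `auc`
#'   (pooled), `auc_components` (pooled per set), `strata` (per-stratum
#'   table), `pair_counts`, and `n_ties`.
#' @export
auc_dynamic <- function(data, predictions, t, dt) {
  pairs <- classify_pairs(data, predictions, t, dt)
  comp <- function(d) {
    num <- sum(d$weight * d$concordant)
    den <- sum(d$weight)
    c(num = num, den = den)
  }
  per <- expand.grid(stratum = c("A", "B"), omega = 1:4, stringsAsFactors = FALSE)
  per$num <- per$den <- 0
  for (k in seq_len(nrow(per))) {
    d <- pairs[pairs$stratum == per$stratum[k] & pairs$omega == per$omega[k], , drop = FALSE]
    cc <- comp(d)
    per$num[k] <- cc["num"]; per$den[k] <- cc["den"]
  }
  total_num <- sum(per$num); total_den <- sum(per$den)
  auc <- if (total_den > 0) total_num / total_den else NA_real_
  comps <- vapply(1:4, function(m) {
    nm <- sum(per$num[per$omega == m]); dn <- sum(per$den[per$omega == m])
    if (dn > 0) nm / dn else NA_real_
  }, numeric(1))
  strata <- do.call(rbind, lapply(c("A", "B"), function(st) {
    nm <- sum(per$num[per$stratum == st]); dn <- sum(per$den[per$stratum == st])
    data.frame(stratum = st, num = nm, den = dn,
               auc = if (dn > 0) nm / dn else NA_real_)
  }))
  counts <- with(pairs, table(factor(stratum, c("A", "B")), factor(omega, 1:4)))
  structure(list(t = t, dt = dt, auc = auc, auc_components = comps,
                 strata = strata, pair_counts = counts,
                 n_ties = sum(pairs$tie),
                 defined = is.finite(auc) && total_den > 0,
                 measure = "auc"),
            class = "jmie_accuracy")
}

#' Expected prediction error with intermediate events
#'
#' Square-loss expected prediction error of \eqn{\hat\pi(u \mid t)} at
#' horizon `u`, estimated over the at-risk subjects: survivors beyond `u`
#' contribute \eqn{(1 - \hat\pi)^2}, observed events before `u` contribute
#' \eqn{\hat\pi^2}, and subjects censored at \eqn{T_i \in (t, u)} enter
#' through both branches weighted by \eqn{\hat\pi(u \mid T_i)}. The
#' estimator is computed within each intermediate-event stratum and pooled
#' with weights proportional to the stratum risk-set sizes.
#'
#' @inheritParams classify_pairs
#' @param u Horizon time, `u > t`; `predictions$pi_u_t` must be
#'   \eqn{\hat\pi(u \mid t)} and `pi_u_Ti` \eqn{\hat\pi(u \mid T_i)} for
#'   subjects censored in `(t, u)`.
#' @return A `jmie_accuracy` object with elements `pe` (pooled), `strata`.
#' @export
pe_dynamic <- function(data, predictions, t, u) {
  stopifnot(u > t)
  rs <- merge_predictions(risk_set_frame(data, t), predictions)
  if (!nrow(rs))
    return(structure(list(t = t, u = u, pe = NA_real_, strata = NULL,
                          defined = FALSE, measure = "pe"),
                     class = "jmie_accuracy"))
  strata <- do.call(rbind, lapply(c("A", "B"), function(st) {
    d <- rs[rs$stratum == st, , drop = FALSE]
    if (!nrow(d)) return(data.frame(stratum = st, n = 0L, pe = NA_real_))
    surv <- d$T_obs >= u
    evt <- !surv & d$delta == 1L
    cen <- !surv & d$delta == 0L
    if (any(cen & is.na(d$pi_u_Ti)))
      stop("missing pi_u_Ti for censored-in-window subjects: ",
           paste(d$id[cen & is.na(d$pi_u_Ti)], collapse = ", "))
    terms <- numeric(nrow(d))
    terms[surv] <- (1 - d$pi_u_t[surv])^2
    terms[evt] <- (0 - d$pi_u_t[evt])^2
    terms[cen] <- d$pi_u_Ti[cen] * (1 - d$pi_u_t[cen])^2 +
      (1 - d$pi_u_Ti[cen]) * (0 - d$pi_u_t[cen])^2
    data.frame(stratum = st, n = nrow(d), pe = mean(terms))
  }))
  ntot <- sum(strata$n)
  pe <- sum(strata$pe[strata$n > 0] * strata$n[strata$n > 0]) / ntot
  structure(list(t = t, u = u, pe = pe, strata = strata,
                 defined = ntot > 0, measure = "pe"),
            class = "jmie_accuracy")
}

#' @export
print.jmie_accuracy <- function(x, ...) {
  if (x$measure == "auc") {
    cat(sprintf("Time-dependent AUC(t = %g, dt = %g): %s\n", x$t, x$dt,
                if (x$defined) sprintf("%.4f", x$auc) else "undefined (no comparable mass)"))
    cat("  components (pooled):",
        paste(sprintf("AUC%d = %s", 1:4,
                      ifelse(is.na(x$auc_components), "-",
                             sprintf("%.4f", x$auc_components))), collapse = ", "), "\n")
    if (x$n_ties > 0) cat("  tied predictions in", x$n_ties, "pair(s)\n")
  } else {
    cat(sprintf("Expected prediction error PE(u = %g | t = %g): %s\n", x$u, x$t,
                if (x$defined) sprintf("%.4f", x$pe) else "undefined (empty risk set)"))
  }
  invisible(x)
}

#' Model-based predictions for accuracy evaluation
#'
#' Computes the prediction columns needed by [auc_dynamic()] and
#' [pe_dynamic()] for every subject at risk at `t`: \eqn{\hat\pi(t +
#' \Delta t \mid t)} under the subject's observed intermediate-event status
#' at `t` (pre-event subjects are predicted under the
#' no-intermediate-event-through-horizon scenario, post-event subjects
#' under their observed \eqn{\rho}), and, for subjects censored inside the
#' window, \eqn{\hat\pi(t + \Delta t \mid T_i)} re-run at landmark
#' \eqn{T_i} under the status observed at \eqn{T_i}.
#'
#' @param object A `jmie_fit` or `jmie_cox` model.
#' @param data Test [study_data()].
#' @param t Landmark time.
#' @param dt Horizon.
#' @param M Monte Carlo draws per prediction (joint model fits).
#' @param seed Integer seed.
#' @return Data frame with columns `id`, `pi_u_t`, `pi_u_Ti`.
#' @export
accuracy_predictions <- function(object, data, t, dt, M = 300, seed = 1L) {
  u <- t + dt
  rs <- risk_set_frame(data, t)
  subs <- data$subjects
  names(subs) <- vapply(subs, function(s) as.character(s$id), character(1))
  one <- function(id, landmark) {
    s <- subs[[id]]
    keep <- s$obs_times <= landmark
    post <- !is.na(s$rho) && s$rho <= landmark
    snew <- subject_data(id = s$id, obs_times = s$obs_times[keep], y = s$y[keep],
                         T_obs = s$T_obs, delta = s$delta,
                         rho = if (post) s$rho else NA_real_,
                         x_baseline = s$x_baseline, w_baseline = s$w_baseline)
    sc <- if (post) scenario_observed() else scenario_none()
    if (inherits(object, "jmie_cox")) {
      cox_predict_surv(object, snew, landmark, u)
    } else {
      predict_survival(object, snew, landmark, u_grid = u, scenario = sc,
                       M = M, seed = seed)$median
    }
  }
  pi_u_t <- vapply(rs$id, function(id) one(id, t), numeric(1))
  cens <- rs$T_obs > t & rs$T_obs < u & rs$delta == 0L
  pi_u_Ti <- rep(NA_real_, nrow(rs))
  pi_u_Ti[cens] <- vapply(rs$id[cens], function(id)
    one(id, subs[[id]]$T_obs), numeric(1))
  data.frame(id = rs$id, pi_u_t = pi_u_t, pi_u_Ti = pi_u_Ti,
             stringsAsFactors = FALSE)
}
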