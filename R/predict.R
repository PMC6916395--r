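#' Intermediate-event scenarios for dynamic prediction
#'
#' Individualized survival predictions are computed under a stated
#' assumption about the intermediate event: it never occurs through the
#' prediction horizon, it occurs immediately at the landmark `t`, it is
#' scheduled at a later time `s` inside the horizon, or it has already
#' occurred (at the subject's observed \eqn{\rho \le t}).
#'
#' @param s Scheduled intermediate-event time (for [scenario_at()] only).
#' @return An object of class `jmie_scenario`.
#' @name scenarios
NULL

#' @rdname scenarios
#' @export
scenario_none <- function() structure(list(kind = "none_through_u", s = NA_real_),
                                      class = "jmie_scenario")
#' @rdname scenarios
#' @export
scenario_immediate <- function() structure(list(kind = "immediate", s = NA_real_),
                                           class = "jmie_scenario")
#' @rdname scenarios
#' @export
scenario_at <- function(s) structure(list(kind = "at_time", s = as.numeric(s)),
                                     class = "jmie_scenario")
#' @rdname scenarios
#' @export
scenario_observed <- function() structure(list(kind = "already_occurred", s = NA_real_),
                                          class = "jmie_scenario")

# Effective intermediate-event time implied by a scenario at landmark t.
scenario_rho <- function(scenario, subject, t, u_max) {
  sc <- scenario$kind
  rho_obs <- subject$rho
  if (sc == "already_occurred") {
    if (is.na(rho_obs) || rho_obs > t)
      stop("scenario 'already_occurred' requires an observed intermediate event at or before t")
    return(rho_obs)
  }
  if (!is.na(rho_obs) && rho_obs <= t)
    stop("subject already experienced the intermediate event before t; use scenario_observed()")
  switch(sc,
         none_through_u = NA_real_,
         immediate = t,
         at_time = {
           if (!(scenario$s > t && scenario$s <= u_max))
             stop("scenario_at() requires t < s <= max(u_grid)")
           scenario$s
         })
}

# Precompute scenario-dependent pieces for one subject: longitudinal design
# at observed times, survival quadrature nodes on (0, t] (conditioning) and
# the (t, u] grid segments.
predict_pieces <- function(fit, subject, t, u_grid, scenario) {
  lsp <- fit$spec$longitudinal
  assoc <- fit$spec$association
  bl <- fit$fd_baseline
  if (length(subject$obs_times) && any(subject$obs_times > t))
    stop("newdata contains measurements after the landmark t")
  u_max <- max(u_grid, t)
  rho_eff <- scenario_rho(scenario, subject, t, u_max)
  clock <- event_clock(rho_eff)

  d_obs <- if (length(subject$obs_times))
    ld_design(lsp, clock, subject$obs_times, subject$x_baseline)
  else list(X = matrix(0, 0, ld_dims(lsp)["p"]), Z = matrix(0, 0, ld_dims(lsp)["q"]))

  use_intercept <- bl$kind == "weibull"
  wvec <- c(if (use_intercept) 1, unlist(subject$w_baseline[fit$wnames[fit$wnames != "(Intercept)"]]))

  quad_nodes <- function(t0, t1) {
    if (t1 <= t0) return(list(s = numeric(), w = numeric(), seg_end = numeric()))
    brk <- c(t0, if (!is.na(rho_eff) && rho_eff > t0 && rho_eff < t1) rho_eff, t1)
    s <- NULL; w <- NULL
    for (k in seq_len(length(brk) - 1L)) {
      m <- max(1L, ceiling((brk[k + 1L] - brk[k]) / 5))
      edges <- seq(brk[k], brk[k + 1L], length.out = m + 1L)
      for (j in seq_len(m)) {
        g <- gk15(edges[j], edges[j + 1L])
        s <- c(s, g$nodes); w <- c(w, g$weights)
      }
    }
    list(s = s, w = w)
  }

  feat_mats <- function(times) {
    feats <- assoc_features(assoc)
    lapply(setNames(feats, feats), function(f) {
      base <- if (f == "slope_int") "slope" else f
      d <- switch(base,
                  value = ld_design(lsp, clock, times, subject$x_baseline),
                  slope = ld_design(lsp, clock, times, subject$x_baseline, deriv = 1L),
                  area = ld_design_area(lsp, clock, times, subject$x_baseline))
      R <- event_indicator(clock, times)
      sc <- assoc$scales[[if (f == "slope_int") "slope" else f]]
      a <- if (f == "slope_int") as.numeric(R == 1L) else
        as.numeric((R == 0L & f %in% assoc$pre) | (R == 1L & f %in% assoc$post))
      list(X = d$X, Z = d$Z, a = sc * a)
    })
  }

  q_cond <- quad_nodes(0, t)
  # horizon segments between consecutive grid points (so the curve is
  # monotone by construction); split additionally at rho_eff
  ug <- sort(unique(pmax(u_grid, t)))
  edges <- sort(unique(c(t, ug, if (!is.na(rho_eff) && rho_eff > t && rho_eff < max(ug)) rho_eff)))
  segs <- cbind(edges[-length(edges)], edges[-1L])
  seg_list <- lapply(seq_len(nrow(segs)), function(k) {
    qn <- quad_nodes(segs[k, 1], segs[k, 2])
    c(qn, list(end = segs[k, 2]))
  })

  node_pack <- function(s) {
    R <- event_indicator(clock, pmax(s, 0))
    list(log_s = log(pmax(s, 1e-300)), R = R,
         B = if (bl$kind == "bspline_log") baseline_basis(bl, s) else NULL,
         feats = feat_mats(s))
  }
  list(rho_eff = rho_eff, clock = clock, d_obs = d_obs, wvec = wvec,
       q_cond = c(q_cond, list(pack = node_pack(q_cond$s))),
       segs = seg_list,
       seg_pack = lapply(seg_list, function(sg) node_pack(sg$s)),
       seg_ends = vapply(seg_list, `[[`, numeric(1), "end"),
       u_grid = ug, bl = bl)
}

node_log_hazard <- function(pack, th, wvec, assoc_names, bl) {
  lh <- if (bl$kind == "weibull") {
    xi <- exp(th$basepar[1])
    log(xi) + (xi - 1) * pack$log_s
  } else {
    drop(pack$B %*% th$basepar)
  }
  if (length(wvec)) lh <- lh + sum(th$gamma * wvec)
  lh <- lh + pack$R * th$zeta
  lh
}

node_assoc <- function(pack, th, beta, b) {
  out <- 0
  for (k in seq_along(pack$feats)) {
    ft <- pack$feats[[k]]
    out <- out + th$alpha[k] * ft$a * (drop(ft$X %*% beta) + drop(ft$Z %*% b))
  }
  out
}

#' Scenario-adaptive dynamic survival prediction
#'
#' Monte Carlo estimate of \eqn{\pi_j(u \mid t, \rho_j)}: for each retained
#' posterior draw, the subject's random effects are drawn from their full
#' conditional (given survival to `t`, the biomarker history up to `t` and
#' the scenario) by Metropolis-Hastings with the exact
#' mixed-model conditional Gaussian as proposal, then the conditional
#' survival \eqn{\exp\{-\int_t^u h_j(s) ds\}} is evaluated on the grid with
#' the integration split at the scenario's intermediate-event time. The
#' pointwise median across draws is the point estimate; the 2.5% and 97.5%
#' percentiles give a 95% credible band.
#'
#' @param fit A `jmie_fit`.
#' @param newdata A [subject_data()] with measurements up to `t`.
#' @param t Landmark time (subject known event-free at `t`).
#' @param u_grid Prediction times, all `>= t`.
#' @param scenario A scenario object, see [scenarios].
#' @param M Number of Monte Carlo draws (posterior draws are recycled by
#'   thinned cycling if `M` exceeds the number available). A warning is
#'   recorded in the result when `M < 200`.
#' @param mh_steps Metropolis-Hastings refreshes of the random effects per
#'   retained draw.
#' @param seed Integer seed for the Monte Carlo scheme.
#' @param keep_draws Keep the full draw-by-grid matrix.
#' @return An object of class `jmie_prediction` with the grid, the median
#'   curve and the 95% band.
#' @export
predict_survival <- function(fit, newdata, t, u_grid,
                             scenario = scenario_none(), M = 2000,
                             mh_steps = 2, seed = 1L, keep_draws = FALSE) {
  stopifnot(inherits(fit, "jmie_fit"), inherits(newdata, "subject_data"),
            inherits(scenario, "jmie_scenario"))
  if (any(u_grid < t)) stop("all prediction times must be >= t")
  set.seed(seed)
  warnings <- character()
  if (M < 200) warnings <- c(warnings, sprintf("M = %d Monte Carlo draws is small (< 200)", M))
  pp <- predict_pieces(fit, newdata, t, u_grid, scenario)
  nd <- nrow(fit$draws)
  idx <- if (M <= nd) round(seq(1L, nd, length.out = M)) else
    rep_len(seq_len(nd), M)
  q <- fit$dims$q
  b <- rep(0, q)
  curves <- matrix(NA_real_, M, length(pp$u_grid))
  Xo <- pp$d_obs$X; Zo <- pp$d_obs$Z; yo <- newdata$y[seq_len(nrow(Xo))]

  cond_H <- function(th, bvec) {
    if (!length(pp$q_cond$s)) return(0)
    lh <- node_log_hazard(pp$q_cond$pack, th, pp$wvec, NULL, pp$bl) +
      node_assoc(pp$q_cond$pack, th, th$beta, bvec)
    sum(pp$q_cond$w * exp(lh))
  }

  for (m in seq_len(M)) {
    th <- theta_draw(fit, idx[m])
    Dinv <- chol2inv(chol(th$D))
    Vinv <- if (nrow(Xo)) crossprod(Zo) / th$sigma^2 + Dinv else Dinv
    cV <- chol(Vinv)
    mu <- if (nrow(Xo))
      backsolve(cV, backsolve(cV, crossprod(Zo, yo - drop(Xo %*% th$beta)) / th$sigma^2,
                              transpose = TRUE))
    else rep(0, q)
    Hcur <- cond_H(th, b)
    for (step in seq_len(mh_steps)) {
      bp <- drop(mu + backsolve(cV, rnorm(q)))
      Hp <- cond_H(th, bp)
      if (log(runif(1)) < Hcur - Hp) { b <- bp; Hcur <- Hp }
    }
    # survival curve over the horizon segments
    Hseg <- vapply(seq_along(pp$segs), function(k) {
      sg <- pp$segs[[k]]
      if (!length(sg$s)) return(0)
      lh <- node_log_hazard(pp$seg_pack[[k]], th, pp$wvec, NULL, pp$bl) +
        node_assoc(pp$seg_pack[[k]], th, th$beta, b)
      sum(sg$w * exp(lh))
    }, numeric(1))
    Hcum <- cumsum(Hseg)
    surv_at <- exp(-Hcum[match(pp$u_grid, pp$seg_ends)])
    surv_at[pp$u_grid == t] <- 1
    curves[m, ] <- surv_at
  }
  out <- list(t = t, u = pp$u_grid, scenario = scenario,
              median = apply(curves, 2, median),
              lower = apply(curves, 2, quantile, 0.025),
              upper = apply(curves, 2, quantile, 0.975),
              M = M, warnings = warnings,
              draws = if (keep_draws) curves else NULL)
  class(out) <- "jmie_prediction"
  out
}

#' @export
print.jmie_prediction <- function(x, ...) {
  cat(sprintf("Dynamic survival prediction from t = %g (scenario: %s, M = %d)\n",
              x$t, x$scenario$kind, x$M))
  print(as.data.frame(x)[, c("u", "median", "lower", "upper")],
        digits = 3, row.names = FALSE)
  for (w in x$warnings) cat("warning:", w, "\n")
  invisible(x)
}

#' @export
as.data.frame.jmie_prediction <- function(x, ...) {
  data.frame(scenario = x$scenario$kind, t = x$t, u = x$u,
             median = x$median, lower = x$lower, upper = x$upper)
}

#' Tabulate predictions under several scenarios
#'
#' @inheritParams predict_survival
#' @param scenarios List of scenario objects.
#' @param ... Passed to [predict_survival()].
#' @return Data frame with one row per (scenario, u): median and 95% band.
#' @export
predict_table <- function(fit, newdata, t, u_grid, scenarios = list(scenario_none()),
                          ...) {
  if (!length(u_grid))
    return(data.frame(scenario = character(), t = numeric(), u = numeric(),
                      median = numeric(), lower = numeric(), upper = numeric()))
  do.call(rbind, lapply(scenarios, function(sc)
    as.data.frame(predict_survival(fit, newdata, t, u_grid, scenario = sc, ...))))
}

#' Draw conditional random effects for a new subject
#'
#' One Metropolis-Hastings draw from
#' \eqn{p(b_j \mid T_j^* > t, Y_j(t), \theta)} for each supplied posterior
#' draw index: the proposal is the exact conditional Gaussian given the
#' longitudinal data alone, corrected by the survival-to-`t` factor under
#' the scenario.
#'
#' @inheritParams predict_survival
#' @param draw_idx Row indices into the posterior draw matrix.
#' @return Matrix of random-effect draws (one row per index).
#' @export
sample_conditional_random_effects <- function(fit, newdata, t,
                                              scenario = scenario_none(),
                                              draw_idx = seq_len(nrow(fit$draws)),
                                              mh_steps = 5, seed = 1L) {
  set.seed(seed)
  pp <- predict_pieces(fit, newdata, t, u_grid = t, scenario = scenario)
  q <- fit$dims$q
  Xo <- pp$d_obs$X; Zo <- pp$d_obs$Z; yo <- newdata$y[seq_len(nrow(Xo))]
  out <- matrix(NA_real_, length(draw_idx), q)
  b <- rep(0, q)
  cond_H <- function(th, bvec) {
    if (!length(pp$q_cond$s)) return(0)
    lh <- node_log_hazard(pp$q_cond$pack, th, pp$wvec, NULL, pp$bl) +
      node_assoc(pp$q_cond$pack, th, th$beta, bvec)
    sum(pp$q_cond$w * exp(lh))
  }
  for (m in seq_along(draw_idx)) {
    th <- theta_draw(fit, draw_idx[m])
    Dinv <- chol2inv(chol(th$D))
    Vinv <- if (nrow(Xo)) crossprod(Zo) / th$sigma^2 + Dinv else Dinv
    cV <- chol(Vinv)
    mu <- if (nrow(Xo))
      backsolve(cV, backsolve(cV, crossprod(Zo, yo - drop(Xo %*% th$beta)) / th$sigma^2,
                              transpose = TRUE))
    else rep(0, q)
    Hcur <- cond_H(th, b)
    for (step in seq_len(mh_steps)) {
      bp <- drop(mu + backsolve(cV, rnorm(q)))
      Hp <- cond_H(th, bp)
      if (log(runif(1)) < Hcur - Hp) { b <- bp; Hcur <- Hp }
    }
    out[m, ] <- b
  }
  out
}

#' Build a fit object from fixed parameter values
#'
#' Wraps one fixed parameter set in the container returned by
#' [fit_joint_model()], so the prediction and accuracy machinery can be run
#' with known (e.g. simulation-truth) parameters. The "posterior" is a
#' point mass at the supplied values.
#'
#' @param spec A [model_spec()].
#' @param beta,sigma,D,gamma,zeta,alpha,basepar Parameter values
#'   (`basepar` is `log(shape)` for a Weibull baseline or the B-spline
#'   coefficient vector).
#' @param baseline Resolved baseline recipe (as in [hazard_params()]).
#' @param n_draws Number of (identical) rows in the draw matrix.
#' @return A `jmie_fit`.
#' @export
manual_fit <- function(spec, beta, sigma, D, gamma = numeric(), zeta = 0,
                       alpha, basepar,
                       baseline = list(kind = "weibull"), n_draws = 50L) {
  dims <- ld_dims(spec$longitudinal)
  q <- unname(dims["q"])
  stopifnot(length(beta) == dims["p"], nrow(D) == q)
  nf <- length(assoc_features(spec$association))
  stopifnot(length(alpha) == nf)
  use_intercept <- baseline$kind == "weibull"
  if (use_intercept) {
    # the Weibull baseline carries a free intercept: gamma[1] is log-scale
    if (!length(gamma)) gamma <- c("(Intercept)" = 0)
    if (is.null(names(gamma)) || names(gamma)[1] != "(Intercept)")
      names(gamma) <- c("(Intercept)", names(gamma)[-1])
  }
  wnames <- names(gamma)
  row <- c(beta, sigma, D[lower.tri(D, diag = TRUE)], gamma, zeta, alpha, basepar)
  draws <- matrix(rep(row, each = n_draws), n_draws)
  fd_names <- list(p = unname(dims["p"]), q = q, pw = length(wnames),
                   nf = nf, nbase = length(basepar), n = 0L)
  structure(list(kind = "manual", spec = spec, fd_baseline = baseline,
                 draws = draws, b_draws = NULL, chain = rep(1L, n_draws),
                 summary = NULL, converged = TRUE, accept = list(),
                 dims = fd_names, wnames = wnames, drop_post_obs = FALSE),
            class = "jmie_fit")
}
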