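#' Association structure of the relative-risk submodel
#'
#' Which functionals of the biomarker trajectory enter the log hazard, with
#' the functional form allowed to differ before and after the intermediate
#' event. Supported features: `"value"` (current level \eqn{\eta(t)}),
#' `"slope"` (current rate of change), `"area"` (cumulative level
#' \eqn{\int_0^t \eta(s) ds}). `slope_interaction = TRUE` additionally adds
#' an \eqn{R(t) \times} slope term after the event, so the slope effect can
#' change at the intermediate event.
#'
#' @param pre Character subset of `c("value", "slope", "area")` active
#'   before the intermediate event.
#' @param post Features active from the intermediate event onwards
#'   (defaults to `pre`).
#' @param slope_interaction Add a post-event `R(t) * slope` term.
#' @param scales Named multipliers applied to the features before the
#'   association coefficients (e.g. to express an effect per 20 units);
#'   default 1 for every feature.
#' @return An object of class `association_spec`.
#' @export
association_spec <- function(pre = "value", post = pre,
                             slope_interaction = FALSE,
                             scales = c(value = 1, slope = 1, area = 1)) {
  feats <- c("value", "slope", "area")
  if (!all(pre %in% feats) || !all(post %in% feats))
    stop("features must be among: ", paste(feats, collapse = ", "))
  if (length(pre) == 0L && length(post) == 0L && !slope_interaction)
    stop("association must use at least one feature")
  sc <- c(value = 1, slope = 1, area = 1)
  sc[names(scales)] <- scales
  structure(list(pre = pre, post = post,
                 slope_interaction = isTRUE(slope_interaction),
                 scales = sc),
            class = "association_spec")
}

# Ordered coefficient labels for alpha.
assoc_features <- function(assoc) {
  f <- intersect(c("value", "slope", "area"), union(assoc$pre, assoc$post))
  if (assoc$slope_interaction) f <- c(f, "slope_int")
  f
}

#' Survival submodel parameters
#'
#' @param gamma Baseline-covariate log hazard ratios (may be empty).
#' @param zeta Intermediate-event log hazard ratio \eqn{\zeta}.
#' @param alpha Association coefficients, aligned with the ordered feature
#'   union of the [association_spec()] (`value`, `slope`, `area`,
#'   then `slope_int`).
#' @param baseline Baseline hazard recipe: either
#'   `list(kind = "weibull", shape = xi)` with \eqn{h_0(t) = \xi
#'   t^{\xi - 1}}, or `list(kind = "bspline_log", coef = , knots = ,
#'   boundary = )` for a cubic B-spline expansion of \eqn{\log h_0(t)}.
#' @return An object of class `hazard_params`.
#' @export
hazard_params <- function(gamma = numeric(), zeta = 0, alpha = numeric(),
                          baseline = list(kind = "weibull", shape = 1)) {
  if (!baseline$kind %in% c("weibull", "bspline_log"))
    stop("baseline kind must be 'weibull' or 'bspline_log'")
  if (baseline$kind == "weibull" && baseline$shape <= 0)
    stop("Weibull shape must be positive")
  structure(list(gamma = as.numeric(gamma), zeta = as.numeric(zeta),
                 alpha = as.numeric(alpha), baseline = baseline),
            class = "hazard_params")
}

#' Log baseline hazard
#'
#' @param params A [hazard_params()].
#' @param t Positive times.
#' @return `log h0(t)`: `log(xi) + (xi - 1) log(t)` for the Weibull recipe,
#'   or the B-spline expansion for `bspline_log` (clamped at its boundary
#'   knots).
#' @export
baseline_log_hazard <- function(params, t) {
  if (any(t <= 0)) stop("baseline hazard requires t > 0")
  bl <- params$baseline
  if (bl$kind == "weibull") {
    log(bl$shape) + (bl$shape - 1) * log(t)
  } else {
    drop(baseline_basis(bl, t) %*% bl$coef)
  }
}

baseline_basis <- function(bl, t) {
  kn <- sort(c(rep(bl$boundary, 4L), bl$knots))
  tt <- pmin(pmax(t, bl$boundary[1]), bl$boundary[2])
  splines::splineDesign(kn, tt, ord = 4L)
}

n_baseline_coefs <- function(bl) {
  if (bl$kind == "weibull") 1L else length(bl$knots) + 4L
}

# Trajectory features (value/slope/area) for one subject at times t, each a
# linear functional of (beta, b): returns the numeric feature values.
traj_feature <- function(feature, spec, traj, clock, t, x_baseline) {
  b <- check_dims(spec, traj)
  d <- switch(feature,
              value = ld_design(spec, clock, t, x_baseline),
              slope = ld_design(spec, clock, t, x_baseline, deriv = 1L),
              area = ld_design_area(spec, clock, t, x_baseline))
  drop(d$X %*% traj$beta + d$Z %*% b)
}

#' Subject-specific log hazard
#'
#' \eqn{\log h_i(t) = \log h_0(t) + \gamma^\top w + R(t) \zeta + \alpha^\top
#' f(t)}, where the feature vector \eqn{f} uses the pre-event features for
#' `t < rho` and the post-event features (plus the optional
#' `R(t) * slope` interaction) from the intermediate event onwards. At
#' `t == rho` the post-event side is used, consistent with
#' \eqn{R(\rho) = 1}.
#'
#' @param params A [hazard_params()].
#' @param assoc An [association_spec()].
#' @param spec A [longitudinal_spec()].
#' @param traj A [trajectory_params()].
#' @param clock An [event_clock()].
#' @param t Positive times.
#' @param w_baseline,x_baseline Named baseline covariates for the survival
#'   and longitudinal submodels.
#' @return Numeric vector of log hazards.
#' @export
log_hazard <- function(params, assoc, spec, traj, clock, t,
                       w_baseline = numeric(), x_baseline = numeric()) {
  feats <- assoc_features(assoc)
  if (length(params$alpha) != length(feats))
    stop(sprintf("alpha has length %d but the association uses %d feature(s): %s",
                 length(params$alpha), length(feats), paste(feats, collapse = ", ")))
  if (length(params$gamma) != length(w_baseline))
    stop("gamma and w_baseline differ in length")
  R <- event_indicator(clock, t)
  lh <- baseline_log_hazard(params, t) + R * params$zeta
  if (length(params$gamma))
    lh <- lh + sum(params$gamma * unlist(w_baseline))
  al <- setNames(params$alpha, feats)
  base_feats <- setdiff(feats, "slope_int")
  for (f in base_feats) {
    active <- (R == 0L & f %in% assoc$pre) | (R == 1L & f %in% assoc$post)
    if (!any(active)) next
    vals <- traj_feature(f, spec, traj, clock, t[active], x_baseline)
    lh[active] <- lh[active] + al[[f]] * assoc$scales[[f]] * vals
  }
  if (assoc$slope_interaction && any(R == 1L)) {
    on <- R == 1L
    vals <- traj_feature("slope", spec, traj, clock, t[on], x_baseline)
    lh[on] <- lh[on] + al[["slope_int"]] * assoc$scales[["slope"]] * vals
  }
  lh
}

#' Cumulative hazard by adaptive Gauss-Kronrod quadrature
#'
#' \eqn{\int_{t_0}^{t_1} h_i(s) ds}, with the interval split at the
#' intermediate-event time whenever it falls inside (the integrand has a
#' kink or jump there, and quadrature across it would lose accuracy).
#'
#' @inheritParams log_hazard
#' @param t0,t1 Integration limits, `0 <= t0 <= t1`.
#' @param tol Relative tolerance of the adaptive scheme.
#' @return The cumulative hazard (a single number).
#' @export
cumulative_hazard <- function(params, assoc, spec, traj, clock, t0, t1,
                              w_baseline = numeric(), x_baseline = numeric(),
                              tol = 1e-8) {
  stopifnot(t0 >= 0, t1 >= t0)
  if (t1 == t0) return(0)
  f <- function(s) {
    s <- pmax(s, 1e-300)  # guard t = 0 for Weibull shapes < 1
    exp(log_hazard(params, assoc, spec, traj, clock, s, w_baseline, x_baseline))
  }
  breaks <- if (has_event(clock)) clock$rho else numeric()
  integrate_adaptive(f, t0, t1, breaks = breaks, tol = tol)
}

#' Conditional survival over an interval
#'
#' \eqn{\Pr(T^* \ge u \mid T^* > t) = \exp\{-\int_t^u h_i(s) ds\}} for fixed
#' parameters and random effects.
#'
#' @inheritParams cumulative_hazard
#' @param t Conditioning time.
#' @param u Horizon, `u >= t`.
#' @return Survival probability in `(0, 1]`; exactly 1 at `u == t`.
#' @export
survival_interval <- function(params, assoc, spec, traj, clock, t, u,
                              w_baseline = numeric(), x_baseline = numeric(),
                              tol = 1e-8) {
  if (u < t) stop("'u' must be >= 't'")
  exp(-cumulative_hazard(params, assoc, spec, traj, clock, t, u,
                         w_baseline, x_baseline, tol = tol))
}
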