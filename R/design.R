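#' Longitudinal submodel specification
#'
#' Describes the mixed-effects design for the biomarker trajectory
#' \eqn{\eta_i(t)}: the pre-event part (intercept, time -- linear or a
#' natural cubic spline -- and baseline covariates) and the post-event part
#' \eqn{g\{R(t), t^+\}} that switches on at the intermediate event. Two
#' post-event forms are supported: `"drop_and_slope"` adds the columns
#' \eqn{R(t)} (level drop) and \eqn{t^+} (slope change), `"post_spline"`
#' adds a B-spline basis in \eqn{t^+} (no separate \eqn{R(t)} column), and
#' `"none"` drops the post-event part altogether (the extrapolation
#' comparator).
#'
#' @param covariates Character vector of baseline covariate names entering
#'   the fixed effects.
#' @param time_knots Interior knots for a natural cubic spline in time;
#'   `NULL` (default) keeps time linear.
#' @param time_boundary Boundary knots for the time spline (length 2).
#' @param post_form One of `"drop_and_slope"`, `"post_spline"`, `"none"`.
#' @param post_knots Interior knots of the post-event B-spline, on the
#'   \eqn{t^+} scale (post_spline only).
#' @param post_boundary Upper boundary knot of the post-event B-spline; the
#'   basis is defined on \eqn{[0, }`post_boundary`\eqn{]} and evaluation
#'   beyond it is an error, never a silent extrapolation.
#' @param random_post Do the post-event columns carry random effects?
#' @return An object of class `longitudinal_spec`.
#' @export
longitudinal_spec <- function(covariates = character(),
                              time_knots = NULL, time_boundary = NULL,
                              post_form = c("drop_and_slope", "post_spline", "none"),
                              post_knots = NULL, post_boundary = NULL,
                              random_post = TRUE) {
  post_form <- match.arg(post_form)
  if (!is.null(time_knots)) {
    if (is.null(time_boundary) || length(time_boundary) != 2L)
      stop("'time_boundary' (length 2) is required with 'time_knots'")
    if (is.unsorted(time_knots, strictly = TRUE)) stop("'time_knots' must be strictly increasing")
  }
  if (post_form == "post_spline") {
    if (is.null(post_boundary)) stop("'post_boundary' is required for post_spline")
    if (!is.null(post_knots) && is.unsorted(post_knots, strictly = TRUE))
      stop("'post_knots' must be strictly increasing")
  }
  structure(list(covariates = covariates,
                 time_knots = time_knots, time_boundary = time_boundary,
                 post_form = post_form,
                 post_knots = post_knots, post_boundary = post_boundary,
                 random_post = random_post),
            class = "longitudinal_spec")
}

# Natural cubic spline basis with fixed knots, with analytic derivatives
# (same construction as stats::ns, which does not expose derivatives).
ns_basis <- function(x, knots, boundary, deriv = 0L) {
  if (any(x < boundary[1] - 1e-10 | x > boundary[2] + 1e-10))
    stop("time outside the natural-spline boundary knots")
  x <- pmin(pmax(x, boundary[1]), boundary[2])
  Aknots <- sort(c(rep(boundary, 4L), knots))
  basis <- splines::splineDesign(Aknots, x, ord = 4L,
                                 derivs = rep(deriv, length(x)))
  const <- splines::splineDesign(Aknots, boundary, ord = 4L, derivs = c(2L, 2L))
  basis <- basis[, -1L, drop = FALSE]    # drop intercept direction
  const <- const[, -1L, drop = FALSE]
  qr.const <- qr(t(const))
  t(qr.qty(qr.const, t(basis)))[, -(1:2), drop = FALSE]
}

# Column labels of the fixed design.
ld_fixed_names <- function(spec) {
  tn <- if (is.null(spec$time_knots)) "time"
        else paste0("time_ns", seq_len(length(spec$time_knots) + 1L))
  post <- switch(spec$post_form,
                 drop_and_slope = c("R(t)", "t_plus"),
                 post_spline = paste0("post_bs", seq_len(n_post_cols(spec))),
                 none = character())
  c("(Intercept)", tn, spec$covariates, post)
}

n_time_cols <- function(spec) {
  if (is.null(spec$time_knots)) 1L else length(spec$time_knots) + 1L
}

n_post_cols <- function(spec) {
  switch(spec$post_form,
         drop_and_slope = 2L,
         post_spline = length(spec$post_knots) + 4L - 1L,  # cubic, no intercept col dropped
         none = 0L)
}

#' Design dimensions
#'
#' @param spec A [longitudinal_spec()].
#' @return Named vector `c(p = fixed columns, q = random columns)`.
#' @export
ld_dims <- function(spec) {
  p <- 1L + n_time_cols(spec) + length(spec$covariates) + n_post_cols(spec)
  q <- 1L + n_time_cols(spec) + if (spec$random_post) n_post_cols(spec) else 0L
  c(p = p, q = q)
}

# Post-event B-spline basis in t_plus on [0, post_boundary]; cubic, with the
# first column dropped so that the basis vanishes at t_plus = 0 and the
# trajectory stays continuous at rho.
post_bs <- function(spec, tplus, deriv = 0L) {
  if (any(tplus > spec$post_boundary + 1e-10))
    stop("t_plus beyond the post-event spline boundary knot; refusing to extrapolate")
  kn <- sort(c(rep(c(0, spec$post_boundary), 4L), spec$post_knots))
  B <- splines::splineDesign(kn, pmin(tplus, spec$post_boundary), ord = 4L,
                             derivs = rep(deriv, length(tplus)))
  B[, -1L, drop = FALSE]
}

#' Longitudinal design rows for one subject
#'
#' Builds the fixed- and random-effects design matrices at the requested
#' times: the post-event columns are exactly zero before the intermediate
#' event, and switch on (closed boundary) at it. `deriv = 1` gives the
#' analytic time-derivative design used for slope features.
#'
#' @param spec A [longitudinal_spec()].
#' @param clock An [event_clock()].
#' @param t Evaluation times (nonnegative).
#' @param x_baseline Named baseline covariates, if the spec uses any.
#' @param deriv 0 for the level design, 1 for its time derivative.
#' @return List with matrices `X` (fixed, labelled columns) and `Z`
#'   (random).
#' @export
ld_design <- function(spec, clock, t, x_baseline = numeric(), deriv = 0L) {
  stopifnot(inherits(spec, "longitudinal_spec"), inherits(clock, "event_clock"))
  if (any(t < 0)) stop("'t' must be nonnegative")
  n <- length(t)
  if (n == 0L) {
    dims <- ld_dims(spec)
    X <- matrix(0, 0L, dims["p"], dimnames = list(NULL, ld_fixed_names(spec)))
    return(list(X = X, Z = matrix(0, 0L, dims["q"])))
  }
  R <- event_indicator(clock, t)
  tp <- relative_time(clock, t)

  icol <- if (deriv == 0L) rep(1, n) else rep(0, n)
  tcols <- if (is.null(spec$time_knots)) {
    matrix(if (deriv == 0L) t else rep(1, n), ncol = 1L)
  } else {
    ns_basis(t, spec$time_knots, spec$time_boundary, deriv = deriv)
  }
  ccols <- if (length(spec$covariates)) {
    miss <- setdiff(spec$covariates, names(x_baseline))
    if (length(miss)) stop("missing baseline covariates: ", paste(miss, collapse = ", "))
    vals <- if (deriv == 0L) unlist(x_baseline[spec$covariates]) else rep(0, length(spec$covariates))
    matrix(rep(vals, each = n), nrow = n)
  } else NULL

  pcols <- switch(spec$post_form,
    drop_and_slope = {
      if (deriv == 0L) cbind(R, tp) else cbind(0 * R, R)
    },
    post_spline = {
      B <- matrix(0, n, n_post_cols(spec))
      on <- R == 1L
      if (any(on)) B[on, ] <- post_bs(spec, tp[on], deriv = deriv)
      B
    },
    none = NULL)

  X <- cbind(icol, tcols, ccols, pcols)
  colnames(X) <- ld_fixed_names(spec)
  zidx <- c(seq_len(1L + n_time_cols(spec)),
            if (spec$random_post && n_post_cols(spec))
              1L + n_time_cols(spec) + length(spec$covariates) + seq_len(n_post_cols(spec)))
  Z <- X[, zidx, drop = FALSE]
  list(X = X, Z = Z)
}

#' Integrated longitudinal design rows
#'
#' Rows are the column-wise integrals of the design over `[0, t]`, split
#' at the intermediate event; exact for polynomial-in-time designs
#' (Gauss-Kronrod on each smooth piece).
#'
#' @inheritParams ld_design
#' @return List with matrices `X` and `Z` of integrated columns.
#' @export
ld_design_area <- function(spec, clock, t, x_baseline = numeric()) {
  dims <- ld_dims(spec)
  one <- function(tt) {
    segs <- if (has_event(clock) && clock$rho < tt) {
      rbind(c(0, clock$rho), c(clock$rho, tt))
    } else matrix(c(0, tt), 1L)
    Xa <- matrix(0, 1L, dims["p"])
    Za <- matrix(0, 1L, dims["q"])
    for (k in seq_len(nrow(segs))) {
      if (segs[k, 2] <= segs[k, 1]) next
      g <- gk15(segs[k, 1], segs[k, 2])
      d <- ld_design(spec, clock, g$nodes, x_baseline)
      Xa <- Xa + g$weights %*% d$X
      Za <- Za + g$weights %*% d$Z
    }
    list(X = Xa, Z = Za)
  }
  parts <- lapply(t, one)
  X <- do.call(rbind, lapply(parts, `[[`, "X"))
  Z <- do.call(rbind, lapply(parts, `[[`, "Z"))
  colnames(X) <- ld_fixed_names(spec)
  list(X = X, Z = Z)
}

#' Trajectory parameters
#'
#' @param beta Fixed-effect vector (pre- and post-event parts concatenated,
#'   in the column order of the design).
#' @param b Subject random-effect vector; defaults to zero.
#' @param sigma Residual standard deviation (positive).
#' @return An object of class `trajectory_params`.
#' @export
trajectory_params <- function(beta, b = NULL, sigma = 1) {
  if (sigma <= 0) stop("'sigma' must be positive")
  structure(list(beta = as.numeric(beta),
                 b = if (is.null(b)) NULL else as.numeric(b),
                 sigma = sigma),
            class = "trajectory_params")
}

check_dims <- function(spec, params) {
  dims <- ld_dims(spec)
  if (length(params$beta) != dims["p"])
    stop(sprintf("beta has length %d but the design has %d fixed columns",
                 length(params$beta), dims["p"]))
  b <- params$b
  if (is.null(b)) b <- numeric(dims["q"])
  if (length(b) != dims["q"])
    stop(sprintf("b has length %d but the design has %d random columns",
                 length(b), dims["q"]))
  b
}

#' Evaluate the biomarker trajectory eta(t)
#'
#' The subject-specific mean trajectory: pre-event design for `t < rho`,
#' with the post-event terms switching on at the intermediate event
#' (discontinuously under the drop-and-slope form).
#'
#' @param spec A [longitudinal_spec()].
#' @param params A [trajectory_params()].
#' @param clock An [event_clock()].
#' @param t Vector of evaluation times.
#' @param x_baseline Named baseline covariate values, if the spec uses any.
#' @return Numeric vector of trajectory values.
#' @export
eta <- function(spec, params, clock, t, x_baseline = numeric()) {
  b <- check_dims(spec, params)
  d <- ld_design(spec, clock, t, x_baseline)
  drop(d$X %*% params$beta + d$Z %*% b)
}

#' Trajectory slope d/dt eta(t)
#'
#' Analytic time-derivative of the design. Under the drop-and-slope form the
#' trajectory jumps at `rho`, so the derivative there is one-sided: request
#' it explicitly via `side`.
#'
#' @inheritParams eta
#' @param side `"auto"` (error at `t == rho` under a discontinuous form),
#'   `"left"` or `"right"` one-sided evaluation at the jump.
#' @return Numeric vector of slopes.
#' @export
eta_slope <- function(spec, params, clock, t, x_baseline = numeric(),
                      side = c("auto", "left", "right")) {
  side <- match.arg(side)
  b <- check_dims(spec, params)
  at_jump <- has_event(clock) && spec$post_form == "drop_and_slope" &&
    any(t == clock$rho)
  if (at_jump && side == "auto")
    stop("slope undefined at t = rho (trajectory jump); evaluate one-sided via side = \"left\" or \"right\"")
  cl <- clock
  if (side == "left" && has_event(clock)) {
    # shift the jump just past t so the pre-event branch is used at t == rho
    cl <- event_clock(clock$rho + 1e-9 * max(1, clock$rho))
  }
  d <- ld_design(spec, cl, t, x_baseline, deriv = 1L)
  drop(d$X %*% params$beta + d$Z %*% b)
}

#' Cumulative trajectory area
#'
#' \eqn{\int_0^t \eta(s) ds}, split at the intermediate event; exact for
#' polynomial-in-time designs, Gauss-Kronrod quadrature for spline designs.
#'
#' @inheritParams eta
#' @return Numeric vector of cumulative areas.
#' @export
eta_area <- function(spec, params, clock, t, x_baseline = numeric()) {
  b <- check_dims(spec, params)
  d <- ld_design_area(spec, clock, t, x_baseline)
  drop(d$X %*% params$beta + d$Z %*% b)
}
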