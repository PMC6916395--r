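#' Simulation configuration
#'
#' Study conditions for the synthetic-data generator: subject-specific
#' linear biomarker trajectories with a level drop and slope change at a
#' biomarker-triggered intermediate event, a Weibull baseline hazard
#' modulated by the current trajectory value, and exponential censoring.
#' Visits are scheduled uniformly on a window and truncated at the observed
#' time.
#'
#' The three shipped scenarios share intercept 20.7 and slope 1.6 and
#' differ in the intermediate-event effects: scenario 1 has drop -15.5 and
#' slope change -0.76; scenario 2 sets the slope change to 0; scenario 3
#' sets the drop to 0.
#'
#' @param n_subjects Number of subjects.
#' @param scenario 1, 2 or 3, selecting the fixed-effect sets above;
#'   ignored when `fixed` is given.
#' @param fixed Optional custom fixed effects
#'   `c(intercept, slope, drop, slope_change)`.
#' @param n_visits Scheduled visits per subject (default 20).
#' @param visit_window Visit-time window, default `c(0, 30)`.
#' @param D Random-effects covariance (4 x 4) for
#'   `(intercept, slope, drop, slope_change)`.
#' @param sigma Residual standard deviation of the biomarker.
#' @param gamma Log baseline risk (intercept of the log hazard).
#' @param zeta Intermediate-event log hazard ratio.
#' @param alpha_value Association of the current biomarker value with the
#'   log hazard.
#' @param xi Weibull baseline shape, \eqn{h_0(t) = \xi t^{\xi - 1}}.
#' @param censor_mean Mean of the exponential censoring time (default 22.6).
#' @param c_trig Biomarker threshold triggering the intermediate event at
#'   the next visit; `Inf` disables intermediate events.
#' @param trigger_on Evaluate the trigger on the observed noisy measurement
#'   (`"y"`, default) or on the noise-free trajectory (`"eta"`). With
#'   `"y"` the intermediate-event time is a deterministic function of the
#'   observed data, so conditioning on it in the fitted likelihood is
#'   exact; with `"eta"` the trigger leaks unobserved random-effect
#'   information and attenuates the post-event coefficients of any model
#'   that treats the intermediate event as exogenous.
#' @param seed Integer seed; every random draw of the generator flows
#'   through it.
#' @return An object of class `simulation_config`.
#' @export
simulation_config <- function(n_subjects = 2000, scenario = 1, fixed = NULL,
                              n_visits = 20, visit_window = c(0, 30),
                              D = default_sim_D(), sigma = 4,
                              gamma = -6.5, zeta = -0.7, alpha_value = 0.05,
                              xi = 1.5, censor_mean = 22.6,
                              c_trig = 40, trigger_on = c("y", "eta"),
                              seed = 1L) {
  trigger_on <- match.arg(trigger_on)
  if (is.null(fixed)) {
    fixed <- switch(as.character(scenario),
                    "1" = c(20.7, 1.6, -15.5, -0.76),
                    "2" = c(20.7, 1.6, -15.5, 0),
                    "3" = c(20.7, 1.6, 0, -0.76),
                    stop("'scenario' must be 1, 2 or 3"))
  } else {
    stopifnot(length(fixed) == 4L)
    scenario <- NA_integer_
  }
  stopifnot(n_visits >= 1, n_subjects >= 1, xi > 0, censor_mean > 0,
            all(visit_window >= 0), diff(visit_window) >= 0,
            nrow(D) == 4L, ncol(D) == 4L, sigma > 0)
  names(fixed) <- c("intercept", "slope", "drop", "slope_change")
  structure(list(n_subjects = as.integer(n_subjects), scenario = scenario,
                 fixed = fixed, n_visits = as.integer(n_visits),
                 visit_window = visit_window, D = D, sigma = sigma,
                 gamma = gamma, zeta = zeta, alpha_value = alpha_value,
                 xi = xi, censor_mean = censor_mean, c_trig = c_trig,
                 trigger_on = trigger_on, seed = as.integer(seed)),
            class = "simulation_config")
}

#' @rdname simulation_config
#' @export
default_sim_D <- function() {
  diag(c(4, 0.4, 2, 0.2)^2)
}

#' Scheduled visit times
#'
#' Draws `n_visits` independent uniform times on the visit window per
#' subject and sorts them; truncation at the observed time happens later in
#' [simulate_study()].
#'
#' @param config A [simulation_config()].
#' @return List of sorted visit-time vectors, one per subject.
#' @export
simulate_visits <- function(config) {
  lapply(seq_len(config$n_subjects), function(i)
    sort(runif(config$n_visits, config$visit_window[1], config$visit_window[2])))
}

#' Biomarker-triggered intermediate event time
#'
#' Walks the visit schedule: at each visit the (still pre-event) trajectory
#' is evaluated, and the first visit at which the biomarker exceeds the
#' trigger threshold schedules the intermediate event at the *next* visit.
#' If the threshold is never exceeded, or is first exceeded at the last
#' visit, the subject never experiences the intermediate event.
#'
#' @param config A [simulation_config()].
#' @param b Subject random effects `(intercept, slope, drop, slope_change)`.
#' @param visits Sorted visit times.
#' @param eps Optional measurement errors aligned with `visits`, used when
#'   `trigger_on = "y"`.
#' @return The intermediate-event time, or `NA` if none.
#' @export
simulate_intermediate_event <- function(config, b, visits, eps = NULL) {
  if (!is.finite(config$c_trig) && config$c_trig > 0) return(NA_real_)
  pre <- (config$fixed[1] + b[1]) + (config$fixed[2] + b[2]) * visits
  marker <- if (config$trigger_on == "y") {
    if (is.null(eps)) stop("'eps' required when triggering on the noisy biomarker")
    pre + eps
  } else pre
  hit <- which(marker > config$c_trig)
  if (!length(hit) || hit[1] >= length(visits)) return(NA_real_)
  visits[hit[1] + 1L]
}

# Truth -> model objects used by the generator and by oracle computations.
sim_model_pieces <- function(config) {
  list(spec = longitudinal_spec(),
       assoc = association_spec("value"),
       hazard = hazard_params(gamma = numeric(), zeta = config$zeta,
                              alpha = config$alpha_value,
                              baseline = list(kind = "weibull", shape = config$xi)))
}

# Cumulative hazard of the generating model, evaluated by piecewise 15-point
# Gauss-Kronrod (segments split at rho and capped at length 2, which is exact
# to rounding for this smooth exp-linear x Weibull integrand). gamma enters
# as a plain intercept on the log hazard.
sim_cum_hazard <- function(config, b, rho, t1) {
  if (t1 <= 0) return(0)
  a0 <- config$fixed[1] + b[1]; a1 <- config$fixed[2] + b[2]
  d0 <- config$fixed[3] + b[3]; d1 <- config$fixed[4] + b[4]
  brk <- c(0, if (!is.na(rho) && rho < t1) rho, t1)
  pts <- sort(unique(unlist(lapply(seq_len(length(brk) - 1L), function(k)
    seq(brk[k], brk[k + 1L], length.out = max(2L, ceiling((brk[k + 1L] - brk[k]) / 2) + 1L))))))
  H <- 0
  for (k in seq_len(length(pts) - 1L)) {
    g <- gk15(pts[k], pts[k + 1L])
    s <- pmax(g$nodes, 1e-300)
    R <- if (is.na(rho)) 0 else as.numeric(s >= rho)
    etas <- a0 + a1 * s + R * (d0 + d1 * (s - ifelse(is.na(rho), 0, rho)))
    lh <- log(config$xi) + (config$xi - 1) * log(s) + config$gamma +
      R * config$zeta + config$alpha_value * etas
    H <- H + sum(g$weights * exp(lh))
  }
  unname(H)
}

#' True event time by hazard inversion
#'
#' Solves \eqn{H_i(T^*) = E} with \eqn{E \sim Exp(1)} by bracketed
#' root-finding on the quadrature-evaluated cumulative hazard (split at the
#' intermediate event). Returns `Inf` when the total hazard on the search
#' support never reaches `E`.
#'
#' @param config A [simulation_config()].
#' @param b Subject random effects.
#' @param rho Intermediate-event time or `NA`.
#' @param E Standard-exponential draw (supply to reuse; drawn if missing).
#' @param t_max Upper end of the root search support.
#' @return The true event time `T*` (possibly `Inf`).
#' @export
simulate_event_time <- function(config, b, rho, E = rexp(1), t_max = 150) {
  H <- function(t) sim_cum_hazard(config, b, rho, t)
  if (H(t_max) < E) return(Inf)
  lo <- 0; hi <- t_max
  # expand precision via uniroot on H(t) - E
  r <- uniroot(function(t) H(t) - E, lower = lo, upper = hi, tol = 1e-12)
  r$root
}

#' Simulate a complete study
#'
#' Per subject: random effects from `N(0, D)`, a uniform visit schedule, the
#' biomarker-triggered intermediate event, the true event time by hazard
#' inversion, exponential censoring, truncation of visits (and of the
#' intermediate event) at the observed time, and noisy biomarker values.
#' The generating truth (parameters, per-subject random effects, latent
#' event times) and a half/half train/test split are attached.
#'
#' @param config A [simulation_config()].
#' @return A list of class `simulated_study` with elements `data`
#'   (a [study_data()]), `truth`, and `split` (factor of `"train"`/`"test"`
#'   labels indexed by subject id).
#' @export
simulate_study <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(config$seed)
  n <- config$n_subjects
  L <- chol(config$D)
  bmat <- matrix(rnorm(n * 4), n, 4) %*% L
  visits <- simulate_visits(config)
  eps <- lapply(visits, function(v) rnorm(length(v), 0, config$sigma))
  E <- rexp(n)
  C <- rexp(n, rate = 1 / config$censor_mean)

  subjects <- vector("list", n)
  Tstar <- numeric(n); rho_all <- numeric(n)
  for (i in seq_len(n)) {
    b <- bmat[i, ]
    rho <- simulate_intermediate_event(config, b, visits[[i]], eps[[i]])
    Ts <- simulate_event_time(config, b, rho, E = E[i])
    Tobs <- min(Ts, C[i])
    delta <- as.integer(Ts <= C[i])
    keep <- visits[[i]] <= Tobs
    rho_obs <- if (!is.na(rho) && rho <= Tobs) rho else NA_real_
    clock <- event_clock(rho_obs)
    tv <- visits[[i]][keep]
    yv <- if (length(tv)) {
      traj <- trajectory_params(config$fixed, b = b)
      eta(longitudinal_spec(), traj, clock, tv) + eps[[i]][keep]
    } else numeric()
    Tstar[i] <- Ts; rho_all[i] <- rho
    subjects[[i]] <- subject_data(id = i, obs_times = tv, y = yv,
                                  T_obs = Tobs, delta = delta, rho = rho_obs)
  }
  split <- factor(rep(c("train", "test"), length.out = n))
  truth <- list(config = config, b = bmat, E = E, censor = C,
                T_star = Tstar, rho_latent = rho_all)
  structure(list(data = study_data(subjects,
                                   meta = list(long_covariates = character(),
                                               surv_covariates = character())),
                 truth = truth, split = split),
            class = "simulated_study")
}

#' Train/test halves of a simulated study
#'
#' @param sim A `simulated_study`.
#' @return List with `train` and `test` [study_data()] objects.
#' @export
split_study <- function(sim) {
  stopifnot(inherits(sim, "simulated_study"))
  subs <- sim$data$subjects
  list(train = study_data(subs[sim$split == "train"], meta = sim$data$meta),
       test = study_data(subs[sim$split == "test"], meta = sim$data$meta))
}
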