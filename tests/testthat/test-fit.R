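mvtnorm_logd <- function(x, S) {
  -length(x) / 2 * log(2 * pi) - 0.5 * as.numeric(determinant(S)$modulus) -
    0.5 * drop(x %*% solve(S) %*% x)
}

toy_theta <- function(q = 4) {
  list(beta = c(20, 1.5, -10, -0.5), sigma = 2,
       D = diag(c(4, 0.2, 2, 0.1)),
       gamma = -3, zeta = 0.3, alpha = 0.02, basepar = log(1.2))
}

toy_study <- function() {
  study_data(list(
    subject_data(1, obs_times = c(1, 3, 6), y = c(21, 24.5, 18),
                 T_obs = 8, delta = 1L, rho = 5),
    subject_data(2, obs_times = c(2, 4), y = c(22, 26),
                 T_obs = 7, delta = 0L, rho = NA)))
}

test_that("log joint posterior equals an independent term-by-term computation", {
  spec <- model_spec()
  data <- toy_study()
  th <- toy_theta()
  b <- rbind(c(0.5, -0.1, 0.8, 0.05), c(-1, 0.2, 0, 0))
  lp <- log_joint_posterior(spec, data, th, b)

  # independent reconstruction from the exported building blocks
  lsp <- longitudinal_spec()
  ll <- 0
  for (i in 1:2) {
    s <- data$subjects[[i]]
    cl <- event_clock(s$rho)
    traj <- trajectory_params(th$beta, b = b[i, ], sigma = th$sigma)
    mu <- eta(lsp, traj, cl, s$obs_times)
    ll <- ll + sum(dnorm(s$y, mu, th$sigma, log = TRUE))
    hp <- hazard_params(gamma = th$gamma, zeta = th$zeta, alpha = th$alpha,
                        baseline = list(kind = "weibull", shape = exp(th$basepar)))
    H <- cumulative_hazard(hp, association_spec("value"), lsp, traj, cl, 0, s$T_obs,
                           w_baseline = c("(Intercept)" = 1))
    if (s$delta == 1)
      ll <- ll + log_hazard(hp, association_spec("value"), lsp, traj, cl, s$T_obs,
                            w_baseline = c("(Intercept)" = 1))
    ll <- ll - H
    ll <- ll + mvtnorm_logd(b[i, ], th$D)
  }
  pr <- spec$priors
  ll <- ll + sum(dnorm(th$beta, 0, pr$beta_sd, log = TRUE)) +
    sum(dnorm(c(th$gamma, th$zeta, th$alpha, th$basepar), 0, pr$surv_sd, log = TRUE)) +
    (-(pr$sigma2_a + 1) * log(th$sigma^2) - pr$sigma2_b / th$sigma^2)
  nu0 <- 4 + pr$D_df_add
  Dinv <- solve(th$D)
  ll <- ll - (nu0 + 4 + 1) / 2 * as.numeric(determinant(th$D)$modulus) -
    0.5 * sum(diag(diag(rep(pr$D_scale, 4)) %*% Dinv))
  # the fitted likelihood uses fixed Gauss-Kronrod abscissae; the oracle's
  # adaptive route agrees to quadrature accuracy
  expect_equal(lp, ll, tolerance = 1e-5)
})

test_that("residual-free data give the pure normalizing Gaussian term", {
  spec <- model_spec()
  data <- toy_study()
  th <- toy_theta()
  b <- matrix(0, 2, 4)
  # overwrite y with the exact trajectory values
  lsp <- longitudinal_spec()
  for (i in 1:2) {
    s <- data$subjects[[i]]
    data$subjects[[i]]$y <- eta(lsp, trajectory_params(th$beta, b = b[i, ]),
                                event_clock(s$rho), s$obs_times)
  }
  N <- 5
  lp_fit <- log_joint_posterior(spec, data, th, b)
  th2 <- th; th2$sigma <- 3
  lp_fit2 <- log_joint_posterior(spec, data, th2, b)
  pr <- spec$priors
  gauss <- function(sg) -N / 2 * log(2 * pi * sg^2) -
    (pr$sigma2_a + 1) * log(sg^2) - pr$sigma2_b / sg^2
  # difference isolates the Gaussian + sigma-prior terms exactly
  expect_equal(lp_fit - lp_fit2, gauss(2) - gauss(3), tolerance = 1e-8)
})

test_that("doubling the post-event hazard shifts the survival term as predicted", {
  spec <- model_spec()
  data <- toy_study()
  th <- toy_theta()
  b <- matrix(0, 2, 4)
  th2 <- th; th2$zeta <- th$zeta + log(2)
  diff_lp <- log_joint_posterior(spec, data, th2, b) -
    log_joint_posterior(spec, data, th, b)
  # subject 1's event at T = 8 >= rho = 5 gains log 2; both subjects swap
  # their cumulative hazards, recomputed via the generic quadrature route
  lsp <- longitudinal_spec()
  Hz <- function(zeta_val, i) {
    s <- data$subjects[[i]]
    hp <- hazard_params(gamma = th$gamma, zeta = zeta_val, alpha = th$alpha,
                        baseline = list(kind = "weibull", shape = exp(th$basepar)))
    cumulative_hazard(hp, association_spec("value"), lsp,
                      trajectory_params(th$beta, b = b[i, ]),
                      event_clock(s$rho), 0, s$T_obs,
                      w_baseline = c("(Intercept)" = 1))
  }
  dH <- sum(vapply(1:2, function(i) Hz(th$zeta, i) - Hz(th2$zeta, i), numeric(1)))
  pr_shift <- dnorm(th2$zeta, 0, spec$priors$surv_sd, log = TRUE) -
    dnorm(th$zeta, 0, spec$priors$surv_sd, log = TRUE)
  expect_equal(diff_lp, log(2) + dH + pr_shift, tolerance = 1e-6)
})

test_that("degenerate variance parameters are rejected, not infinite", {
  spec <- model_spec()
  data <- toy_study()
  th <- toy_theta()
  b <- matrix(0, 2, 4)
  th_bad <- th; th_bad$sigma <- -1
  expect_identical(log_joint_posterior(spec, data, th_bad, b), -Inf)
  th_deg <- th; th_deg$D <- diag(c(1, 1, 1, 0))
  expect_identical(log_joint_posterior(spec, data, th_deg, b), -Inf)
  # sigma -> 0+ decreases the posterior for non-degenerate residuals
  th_small <- th; th_small$sigma <- 1e-4
  expect_lt(log_joint_posterior(spec, data, th_small, b),
            log_joint_posterior(spec, data, th, b))
})

test_that("fits are reproducible under a fixed seed and reject invalid data", {
  data <- tiny_study(n = 30, seed = 4)
  ms <- model_spec(mcmc = list(chains = 1, warmup = 60, sampling = 40, seed = 9))
  f1 <- suppressWarnings(fit_joint_model(ms, data))
  f2 <- suppressWarnings(fit_joint_model(ms, data))
  expect_identical(f1$draws, f2$draws)
  bad <- study_data(list(suppressWarnings(
    subject_data(1, obs_times = 5, y = 1, T_obs = 2, delta = 1))))
  expect_error(fit_joint_model(ms, bad), "invalid study")
})

test_that("survival parameters agree with an independent parametric PH fit", {
  skip_if_not_installed("flexsurv")
  # no association, no intermediate events: Weibull PH with intercept only
  cfg <- simulation_config(n_subjects = 400, alpha_value = 0, c_trig = Inf,
                           gamma = -4.2, xi = 1.4, seed = 31)
  sim <- simulate_study(cfg)
  ms <- model_spec(mcmc = list(chains = 1, warmup = 250, sampling = 350, seed = 2))
  fit <- suppressWarnings(fit_joint_model(ms, sim$data))
  s <- fit$summary
  Tn <- vapply(sim$data$subjects, function(x) x$T_obs, numeric(1))
  dl <- vapply(sim$data$subjects, function(x) x$delta, integer(1))
  ml <- flexsurv::flexsurvreg(survival::Surv(Tn, dl) ~ 1, dist = "weibullPH")
  co <- ml$res
  # flexsurv weibullPH: h0(t) = scale * shape * t^(shape - 1)
  xi_ml <- co["shape", "est"]; logsc_ml <- log(co["scale", "est"])
  xi_pm <- exp(s$mean[s$parameter == "log_shape"])
  g_pm <- s$mean[s$parameter == "gamma[(Intercept)]"]
  # the joint model's baseline is xi t^(xi-1) with a free intercept gamma:
  # log scale = gamma + log(xi) - log(xi_fit) cancels into comparable pieces
  expect_lt(abs(xi_pm - xi_ml), 3 * (co["shape", "se"] + s$sd[s$parameter == "log_shape"] * xi_pm))
  expect_lt(abs(g_pm - logsc_ml), 3 * (co["scale", "se"] / co["scale", "est"] +
                                         s$sd[s$parameter == "gamma[(Intercept)]"]))
  # null association recovered
  a_lo <- s$q2.5[s$parameter == "alpha[value]"]
  a_hi <- s$q97.5[s$parameter == "alpha[value]"]
  expect_true(a_lo < 0 && a_hi > 0)
})

test_that("the spline log-baseline variant fits and matches the Weibull fit broadly", {
  data <- tiny_study(n = 80, seed = 9)
  mcmc <- list(chains = 1, warmup = 200, sampling = 200, seed = 3)
  fw <- suppressWarnings(fit_joint_model(model_spec(mcmc = mcmc), data))
  fb <- suppressWarnings(fit_joint_model(
    model_spec(baseline = list(kind = "bspline_log", df = 7), mcmc = mcmc), data))
  expect_equal(sum(grepl("^basecoef", colnames(fb$draws))), 7L)
  expect_true(all(is.finite(fb$draws)))
  # the two baseline parameterizations agree on the longitudinal submodel
  for (par in c("beta[(Intercept)]", "beta[R(t)]", "sigma")) {
    expect_lt(abs(mean(fw$draws[, par]) - mean(fb$draws[, par])),
              4 * sqrt(var(fw$draws[, par]) + var(fb$draws[, par])))
  }
})

test_that("with essentially no data the posterior reproduces the prior", {
  # a single subject censored immediately, no measurements: the fixed
  # effects are informed only by their N(0, beta_sd^2) prior
  data <- study_data(list(subject_data(1, obs_times = numeric(), y = numeric(),
                                       T_obs = 0.01, delta = 0L)))
  ms <- model_spec(mcmc = list(chains = 1, warmup = 100, sampling = 400, seed = 17))
  fit <- suppressWarnings(fit_joint_model(ms, data))
  bdraws <- fit$draws[, grepl("^beta", colnames(fit$draws))]
  expect_lt(max(abs(colMeans(bdraws))), 25)          # mean 0 within MC error
  expect_true(all(apply(bdraws, 2, sd) > 60))        # sd ~ 100
  expect_true(all(apply(bdraws, 2, sd) < 150))
})

test_that("the extrapolation comparator strips the post-event longitudinal part", {
  data <- tiny_study(n = 60, seed = 12)
  ms <- model_spec(mcmc = list(chains = 1, warmup = 80, sampling = 60, seed = 5))
  fe <- suppressWarnings(fit_extrapolation_model(ms, data))
  expect_equal(fe$dims$p, 2L)  # intercept + time only
  expect_equal(fe$dims$q, 2L)
  expect_false(any(grepl("R\\(t\\)|t_plus", colnames(fe$draws))))
  # survival submodel unchanged: zeta still present
  expect_true("zeta" %in% colnames(fe$draws))
})

test_that("on intermediate-event-free data extrapolation and whole-trajectory agree", {
  data <- tiny_study(n = 120, seed = 6, c_trig = Inf)
  ms <- model_spec(mcmc = list(chains = 1, warmup = 150, sampling = 200, seed = 5))
  fw <- suppressWarnings(fit_joint_model(ms, data))
  fe <- suppressWarnings(fit_extrapolation_model(ms, data))
  for (par in c("beta[(Intercept)]", "beta[time]", "sigma")) {
    mw <- mean(fw$draws[, par]); me <- mean(fe$draws[, par])
    sw <- sd(fw$draws[, par]); se <- sd(fe$draws[, par])
    expect_lt(abs(mw - me), 3 * sqrt(sw^2 + se^2))
  }
})

test_that("start-stop episode construction splits exactly at rho", {
  data <- study_data(list(
    subject_data(1, obs_times = 1, y = 1, T_obs = 10, delta = 1L, rho = 4),
    subject_data(2, obs_times = 1, y = 1, T_obs = 6, delta = 0L, rho = NA)))
  ep <- cox_episodes(data)
  e1 <- ep[ep$id == 1, ]
  expect_equal(e1$start, c(0, 4))
  expect_equal(e1$stop, c(4, 10))
  expect_equal(e1$R, c(0L, 1L))
  expect_equal(e1$event, c(0L, 1L))
  expect_equal(ep[ep$id == 2, ]$R, 0L)
})

test_that("the Cox comparator recovers a known intermediate-event effect", {
  cfg <- simulation_config(n_subjects = 700, alpha_value = 0, zeta = -0.8,
                           gamma = -3.4, xi = 1, seed = 44)
  sim <- simulate_study(cfg)
  cx <- fit_timedep_cox(sim$data)
  se <- sqrt(cx$fit$var[1, 1])
  expect_lt(abs(cx$zeta - (-0.8)), 2.5 * se)
  # no intermediate events at all: zeta flagged unidentified
  sim0 <- simulate_study(simulation_config(n_subjects = 60, c_trig = Inf, seed = 3))
  cx0 <- fit_timedep_cox(sim0$data)
  expect_false(cx0$zeta_identified)
  expect_true(is.na(cx0$zeta))
})
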