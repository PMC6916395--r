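fixed_fit <- function(zeta = log(0.5), alpha = 0, h = 0.3, D = diag(rep(1e-12, 4))) {
  manual_fit(model_spec(), beta = c(20, 1, -10, -0.5), sigma = 1, D = D,
             gamma = c("(Intercept)" = log(h)), zeta = zeta, alpha = alpha,
             basepar = 0, n_draws = 25)
}

new_subj <- function() subject_data("new", obs_times = c(1, 3), y = c(21.2, 22.8),
                                    T_obs = 5, delta = 0L, rho = NA)

test_that("prediction curves start at one, stay in [0,1] and decrease", {
  fit <- fixed_fit(alpha = 0.05, D = diag(c(4, 0.2, 2, 0.1)))
  p <- predict_survival(fit, new_subj(), t = 5, u_grid = seq(5, 12, by = 0.5),
                        M = 120, seed = 2, keep_draws = TRUE)
  expect_equal(p$median[1], 1)
  expect_true(all(p$draws >= 0 & p$draws <= 1))
  expect_true(all(apply(p$draws, 1, function(v) all(diff(v) <= 1e-12))))
  expect_true(all(p$lower <= p$median + 1e-12 & p$median <= p$upper + 1e-12))
  expect_match(p$warnings, "small", all = FALSE)  # M < 200 recorded
})

test_that("an immediate beneficial intervention square-roots the no-event curve", {
  fit <- fixed_fit(zeta = log(0.5))
  ug <- seq(5, 12, by = 1)
  pn <- predict_survival(fit, new_subj(), 5, ug, scenario_none(), M = 10, seed = 1)
  pi <- predict_survival(fit, new_subj(), 5, ug, scenario_immediate(), M = 10, seed = 1)
  expect_lt(max(abs(pi$median - pn$median^0.5)), 1e-10)
  # closed form for the constant hazard
  expect_lt(max(abs(pn$median - exp(-0.3 * (ug - 5)))), 1e-10)
})

test_that("scheduled-event curves overlap the no-event curves before s and split after", {
  fit <- fixed_fit(zeta = log(0.5), D = diag(c(1, 0.05, 0.5, 0.02)))
  ug <- seq(5, 12, by = 0.5)
  pn <- predict_survival(fit, new_subj(), 5, ug, scenario_none(), M = 50, seed = 4)
  pa <- predict_survival(fit, new_subj(), 5, ug, scenario_at(8), M = 50, seed = 4)
  expect_equal(pa$median[ug <= 8], pn$median[ug <= 8], tolerance = 1e-12)
  expect_true(all(pa$median[ug > 8.5] > pn$median[ug > 8.5]))
})

test_that("scenario ordering follows the sign of the intermediate-event effect", {
  ug <- seq(5, 12, by = 1)
  fit_ben <- fixed_fit(zeta = -0.8)
  pn <- predict_survival(fit_ben, new_subj(), 5, ug, scenario_none(), M = 10, seed = 1)
  pi <- predict_survival(fit_ben, new_subj(), 5, ug, scenario_immediate(), M = 10, seed = 1)
  expect_true(all(pi$median[-1] >= pn$median[-1]))
  fit_harm <- fixed_fit(zeta = 0.8)
  pn2 <- predict_survival(fit_harm, new_subj(), 5, ug, scenario_none(), M = 10, seed = 1)
  pi2 <- predict_survival(fit_harm, new_subj(), 5, ug, scenario_immediate(), M = 10, seed = 1)
  expect_true(all(pi2$median[-1] <= pn2$median[-1]))
})

test_that("scenario preconditions are enforced", {
  fit <- fixed_fit()
  s_post <- subject_data("p", obs_times = 1, y = 21, T_obs = 5, delta = 0L, rho = 2)
  expect_error(predict_survival(fit, s_post, 5, 5:8, scenario_none()),
               "scenario_observed")
  expect_error(predict_survival(fit, new_subj(), 5, 5:8, scenario_observed()),
               "requires an observed intermediate event")
  expect_error(predict_survival(fit, new_subj(), 5, 5:8, scenario_at(20)),
               "s <= max")
  expect_error(predict_survival(fit, new_subj(), 2, 2:4), "after the landmark")
})

test_that("with no information the conditional random effects are the prior", {
  D <- matrix(c(4, 0.3, 0.5, 0.1,
                0.3, 0.2, 0.05, 0.02,
                0.5, 0.05, 2, 0.15,
                0.1, 0.02, 0.15, 0.1), 4, 4)
  fit <- manual_fit(model_spec(), beta = c(20, 1, -10, -0.5), sigma = 1, D = D,
                    gamma = c("(Intercept)" = -30), zeta = 0, alpha = 0,
                    basepar = 0, n_draws = 4000)
  empty <- subject_data("e", obs_times = numeric(), y = numeric(),
                        T_obs = 1, delta = 0L, rho = NA)
  bs <- sample_conditional_random_effects(fit, empty, t = 0, mh_steps = 1, seed = 8)
  expect_lt(max(abs(colMeans(bs))), 4 * sqrt(max(diag(D)) / nrow(bs)) + 0.05)
  expect_equal(unname(cov(bs)), unname(D), tolerance = 0.15)
})

test_that("with survival switched off the draws match the conjugate closed form", {
  D <- matrix(c(4, 0.3, 0.5, 0.1,
                0.3, 0.2, 0.05, 0.02,
                0.5, 0.05, 2, 0.15,
                0.1, 0.02, 0.15, 0.1), 4, 4)
  beta <- c(20, 1, -10, -0.5); sigma <- 1.5
  fit <- manual_fit(model_spec(), beta = beta, sigma = sigma, D = D,
                    gamma = c("(Intercept)" = -30),  # hazard ~ 0: no survival info
                    zeta = 0, alpha = 0, basepar = 0, n_draws = 4000)
  subj <- new_subj()
  bs <- sample_conditional_random_effects(fit, subj, t = 5, mh_steps = 1, seed = 9)
  # closed-form mixed-model conditional: all observations are pre-event, so
  # the post-event effects follow their Schur conditional prior
  Z <- cbind(1, subj$obs_times, 0, 0)
  X <- cbind(1, subj$obs_times, 0, 0)
  V <- solve(crossprod(Z) / sigma^2 + solve(D))
  m <- drop(V %*% crossprod(Z, subj$y - X %*% beta) / sigma^2)
  expect_lt(max(abs(colMeans(bs) - m)), 0.15)
  expect_equal(unname(cov(bs)), unname(V), tolerance = 0.2)
  # Schur-complement regression of post on pre components
  pre <- 1:2; post <- 3:4
  Breg <- D[post, pre] %*% solve(D[pre, pre])
  emp <- t(coef(lm(bs[, post] ~ bs[, pre]))[-1, ])
  expect_lt(max(abs(unname(emp) - unname(Breg))), 0.12)
})

test_that("prediction tables enumerate scenarios by grid and round-trip to CSV", {
  fit <- fixed_fit(D = diag(c(1, 0.05, 0.5, 0.02)))
  ug <- seq(5.5, 10, length.out = 10)
  tab <- predict_table(fit, new_subj(), 5, ug,
                       scenarios = list(scenario_none(), scenario_immediate()),
                       M = 30, seed = 1)
  expect_equal(nrow(tab), 20)
  expect_setequal(unique(tab$scenario), c("none_through_u", "immediate"))
  f <- withr::local_tempfile(fileext = ".csv")
  write.csv(tab, f, row.names = FALSE)
  back <- read.csv(f)
  expect_equal(back$median, tab$median)
  expect_equal(back$lower, tab$lower)
  # empty grid: empty table, no failure
  expect_equal(nrow(predict_table(fit, new_subj(), 5, numeric())), 0)
})

test_that("the Monte Carlo error of the median shrinks like one over root M", {
  fit <- fixed_fit(alpha = 0.05, D = diag(c(9, 0.4, 4, 0.1)))
  subj <- new_subj()
  Ms <- c(60, 240, 960)
  ses <- vapply(Ms, function(M) {
    meds <- vapply(1:24, function(r)
      predict_survival(fit, subj, 5, u_grid = 9, M = M, seed = 1000 + r)$median,
      numeric(1))
    sd(meds)
  }, numeric(1))
  slope <- coef(lm(log(ses) ~ log(Ms)))[2]
  expect_lt(abs(slope + 0.5), 0.2)
})
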