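mk_study <- function(df) {
  study_data(lapply(seq_len(nrow(df)), function(i)
    subject_data(id = df$id[i], obs_times = numeric(), y = numeric(),
                 T_obs = df$T_obs[i], delta = df$delta[i], rho = df$rho[i])))
}

test_that("pair classification matches the printed comparability sets", {
  # one event in the window, one survivor, one censored inside the window
  df <- data.frame(id = c("e", "s", "c"), T_obs = c(3, 9, 3.5),
                   delta = c(1L, 0L, 0L), rho = NA_real_,
                   pi_u_t = c(0.2, 0.9, 0.5), pi_u_Ti = c(NA, NA, 0.4))
  pairs <- classify_pairs(mk_study(df), df, t = 2, dt = 2)
  expect_equal(sum(pairs$omega == 1), 1)  # (e, s)
  expect_equal(sum(pairs$omega == 2), 1)  # (c, s)
  expect_equal(sum(pairs$omega == 3), 1)  # (e, c): T_e < T_c <= u
  expect_equal(sum(pairs$omega == 4), 0)
  expect_equal(pairs$weight[pairs$omega == 2], 1 - 0.4)
  expect_equal(pairs$weight[pairs$omega == 3], 0.4)

  # all subjects gone before t -> no pairs at all
  df2 <- transform(df, T_obs = c(1, 1.5, 0.5))
  expect_equal(nrow(classify_pairs(mk_study(df2), df2, t = 2, dt = 2)), 0)
})

test_that("pairs are never formed across intermediate-event strata", {
  df <- data.frame(id = c("a", "b"), T_obs = c(3, 9), delta = c(1L, 0L),
                   rho = c(NA, 1), pi_u_t = c(0.2, 0.9), pi_u_Ti = NA_real_)
  expect_equal(nrow(classify_pairs(mk_study(df), df, t = 2, dt = 2)), 0)
})

test_that("AUC components match hand-computed values", {
  # event pi 0.2 vs survivors pi 0.9 and 0.1: one concordant pair of two
  df <- data.frame(id = c("e", "s1", "s2"), T_obs = c(3, 9, 8),
                   delta = c(1L, 0L, 0L), rho = NA_real_,
                   pi_u_t = c(0.2, 0.9, 0.1), pi_u_Ti = NA_real_)
  a <- auc_dynamic(mk_study(df), df, t = 2, dt = 2)
  expect_equal(a$auc_components[1], 0.5)
  expect_equal(a$auc, 0.5)

  # perfect ranking without censoring
  df2 <- data.frame(id = letters[1:4], T_obs = c(3, 3.5, 9, 10),
                    delta = c(1L, 1L, 0L, 0L), rho = NA_real_,
                    pi_u_t = c(0.1, 0.2, 0.8, 0.9), pi_u_Ti = NA_real_)
  expect_equal(auc_dynamic(mk_study(df2), df2, t = 2, dt = 2)$auc, 1)

  # a single censored-vs-survivor pair is a weighted ratio
  df3 <- data.frame(id = c("c", "s"), T_obs = c(3, 9), delta = c(0L, 0L),
                    rho = NA_real_, pi_u_t = c(0.3, 0.8), pi_u_Ti = c(0.6, NA))
  a3 <- auc_dynamic(mk_study(df3), df3, t = 2, dt = 2)
  expect_equal(a3$auc_components[2], 1)        # 0.4 * 1 / 0.4
  expect_equal(a3$strata$num[1], 0.4)
  expect_equal(a3$strata$den[1], 0.4)
})

test_that("AUC is undefined, not zero, without comparable mass", {
  df <- data.frame(id = c("s1", "s2"), T_obs = c(9, 10), delta = 0L,
                   rho = NA_real_, pi_u_t = c(0.5, 0.6), pi_u_Ti = NA_real_)
  a <- auc_dynamic(mk_study(df), df, t = 2, dt = 2)
  expect_true(is.na(a$auc))
  expect_false(a$defined)
})

test_that("AUC is a rank statistic: monotone-transform invariant, swap symmetric", {
  inst <- random_accuracy_instance(404)
  a0 <- auc_dynamic(inst$study, inst$preds, inst$t, inst$dt)
  tr <- inst$preds
  tr$pi_u_t <- plogis(3 * tr$pi_u_t - 1)   # strictly increasing transform
  a1 <- auc_dynamic(inst$study, tr, inst$t, inst$dt)
  expect_equal(a1$auc, a0$auc)
  expect_equal(a1$auc_components, a0$auc_components)

  # censoring-free label swap: AUC1 -> 1 - AUC1 when the ranking is negated
  df <- data.frame(id = letters[1:5], T_obs = c(3, 3.5, 9, 10, 11),
                   delta = c(1L, 1L, 0L, 0L, 0L), rho = NA_real_,
                   pi_u_t = c(0.3, 0.8, 0.5, 0.9, 0.1), pi_u_Ti = NA_real_)
  st <- mk_study(df)
  a <- auc_dynamic(st, df, 2, 2)
  neg <- transform(df, pi_u_t = 1 - pi_u_t)
  an <- auc_dynamic(st, neg, 2, 2)
  expect_equal(an$auc_components[1], 1 - a$auc_components[1])
})

test_that("without censoring the weighted terms vanish and the total is AUC1", {
  df <- data.frame(id = letters[1:6], T_obs = c(2.5, 3, 9, 10, 2.7, 12),
                   delta = c(1L, 1L, 0L, 0L, 1L, 0L),
                   rho = c(NA, 1, NA, 1.5, NA, NA),
                   pi_u_t = c(0.4, 0.1, 0.7, 0.8, 0.2, 0.9), pi_u_Ti = NA_real_)
  a <- auc_dynamic(mk_study(df), df, 2, 2)
  expect_true(all(is.na(a$auc_components[2:4])))
  num <- sum(a$strata$num); den <- sum(a$strata$den)
  expect_equal(a$auc, num / den)
  expect_equal(sum(a$pair_counts[, 2:4]), 0)
})

test_that("prediction error matches its three hand-evaluated branches", {
  # perfect predictions, no censoring
  df <- data.frame(id = c("s", "e"), T_obs = c(9, 3), delta = c(0L, 1L),
                   rho = NA_real_, pi_u_t = c(1, 0), pi_u_Ti = NA_real_)
  expect_equal(pe_dynamic(mk_study(df), df, 2, 4)$pe, 0)

  # constant 0.5 prediction, everyone survives
  df2 <- data.frame(id = letters[1:3], T_obs = 9, delta = 0L, rho = NA_real_,
                    pi_u_t = 0.5, pi_u_Ti = NA_real_)
  expect_equal(pe_dynamic(mk_study(df2), df2, 2, 4)$pe, 0.25)

  # survivor 0.8, event 0.4, censored-in-window with pi(u|T) = 0.5, pi(u|t) = 0.6
  df3 <- data.frame(id = c("s", "e", "c"), T_obs = c(9, 3, 3.5),
                    delta = c(0L, 1L, 0L), rho = NA_real_,
                    pi_u_t = c(0.8, 0.4, 0.6), pi_u_Ti = c(NA, NA, 0.5))
  expect_equal(pe_dynamic(mk_study(df3), df3, 2, 4)$pe,
               (0.04 + 0.16 + (0.5 * 0.16 + 0.5 * 0.36)) / 3)
})

test_that("PE is undefined on an empty risk set and errors on missing pi(u|T)", {
  df <- data.frame(id = "a", T_obs = 1, delta = 1L, rho = NA_real_,
                   pi_u_t = 0.5, pi_u_Ti = NA_real_)
  expect_false(pe_dynamic(mk_study(df), df, 2, 4)$defined)
  df2 <- data.frame(id = c("a", "c"), T_obs = c(9, 3), delta = 0L, rho = NA_real_,
                    pi_u_t = 0.5, pi_u_Ti = NA_real_)
  expect_error(pe_dynamic(mk_study(df2), df2, 2, 4), "missing pi_u_Ti")
  expect_error(auc_dynamic(mk_study(df2), df2[1, ], 2, 2), "missing predictions")
})

test_that("estimators equal the brute-force enumeration on random instances", {
  for (seed in 1:25) {
    inst <- random_accuracy_instance(seed)
    a <- auc_dynamic(inst$study, inst$preds, inst$t, inst$dt)
    bf <- brute_force_auc(inst$preds, inst$t, inst$dt)
    if (is.na(bf$auc)) expect_true(is.na(a$auc)) else
      expect_equal(a$auc, bf$auc, tolerance = 1e-12)
    expect_equal(unname(a$auc_components), unname(bf$components), tolerance = 1e-12)
    p <- pe_dynamic(inst$study, inst$preds, inst$t, inst$t + inst$dt)
    bp <- brute_force_pe(inst$preds, inst$t, inst$t + inst$dt)
    expect_equal(p$pe, bp$pe, tolerance = 1e-12)
  }
})
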