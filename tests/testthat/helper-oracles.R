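# Independent brute-force implementations used as oracles, written directly
# from the printed estimator definitions: every ordered pair is enumerated
# with explicit loops, no code shared with the package internals.

brute_force_auc <- function(df, t, dt) {
  # df: data.frame(id, T_obs, delta, rho, pi_u_t, pi_u_Ti)
  u <- t + dt
  d <- df[df$T_obs > t, , drop = FALSE]
  d$stratum <- ifelse(!is.na(d$rho) & d$rho <= t, "B", "A")
  num <- den <- matrix(0, 2, 4, dimnames = list(c("A", "B"), NULL))
  for (i in seq_len(nrow(d))) for (j in seq_len(nrow(d))) {
    if (i == j) next
    if (d$stratum[i] != d$stratum[j]) next
    st <- d$stratum[i]
    conc <- as.numeric(d$pi_u_t[i] < d$pi_u_t[j])
    in_win_i <- d$T_obs[i] > t && d$T_obs[i] <= u
    surv_j <- d$T_obs[j] > u
    cens_in_win_j <- d$T_obs[j] > t && d$T_obs[j] <= u && d$delta[j] == 0 &&
      d$T_obs[i] < d$T_obs[j]
    if (in_win_i && d$delta[i] == 1 && surv_j) {
      num[st, 1] <- num[st, 1] + conc; den[st, 1] <- den[st, 1] + 1
    }
    if (in_win_i && d$delta[i] == 0 && surv_j) {
      w <- 1 - d$pi_u_Ti[i]
      num[st, 2] <- num[st, 2] + conc * w; den[st, 2] <- den[st, 2] + w
    }
    if (in_win_i && d$delta[i] == 1 && cens_in_win_j) {
      w <- d$pi_u_Ti[j]
      num[st, 3] <- num[st, 3] + conc * w; den[st, 3] <- den[st, 3] + w
    }
    if (in_win_i && d$delta[i] == 0 && cens_in_win_j) {
      w <- (1 - d$pi_u_Ti[i]) * d$pi_u_Ti[j]
      num[st, 4] <- num[st, 4] + conc * w; den[st, 4] <- den[st, 4] + w
    }
  }
  list(auc = if (sum(den) > 0) sum(num) / sum(den) else NA_real_,
       components = ifelse(colSums(den) > 0, colSums(num) / colSums(den), NA_real_),
       num = num, den = den)
}

brute_force_pe <- function(df, t, u) {
  d <- df[df$T_obs > t, , drop = FALSE]
  d$stratum <- ifelse(!is.na(d$rho) & d$rho <= t, "B", "A")
  pes <- ns <- c(A = 0, B = 0)
  for (st in c("A", "B")) {
    dd <- d[d$stratum == st, , drop = FALSE]
    ns[st] <- nrow(dd)
    if (!nrow(dd)) { pes[st] <- NA; next }
    tot <- 0
    for (i in seq_len(nrow(dd))) {
      pi_t <- dd$pi_u_t[i]
      if (dd$T_obs[i] >= u) {
        tot <- tot + (1 - pi_t)^2
      } else if (dd$delta[i] == 1) {
        tot <- tot + pi_t^2
      } else {
        pi_T <- dd$pi_u_Ti[i]
        tot <- tot + pi_T * (1 - pi_t)^2 + (1 - pi_T) * pi_t^2
      }
    }
    pes[st] <- tot / nrow(dd)
  }
  ok <- !is.na(pes)
  list(pe = sum(pes[ok] * ns[ok]) / sum(ns[ok]), strata = pes)
}

# Random small accuracy instance: subjects with events/censoring around the
# landmark, random intermediate events, random predicted probabilities.
random_accuracy_instance <- function(seed, n_max = 12) {
  set.seed(seed)
  n <- sample(3:n_max, 1)
  t <- 2; dt <- 2
  T_obs <- round(runif(n, 0.5, 8), 2)
  delta <- rbinom(n, 1, 0.6)
  rho <- ifelse(runif(n) < 0.45, round(runif(n, 0, 6), 2), NA)
  rho <- ifelse(!is.na(rho) & rho > T_obs, NA, rho)
  df <- data.frame(id = as.character(seq_len(n)), T_obs = T_obs, delta = delta,
                   rho = rho,
                   pi_u_t = round(runif(n), 3),
                   pi_u_Ti = round(runif(n), 3), stringsAsFactors = FALSE)
  subjects <- lapply(seq_len(n), function(i)
    subject_data(id = df$id[i], obs_times = numeric(), y = numeric(),
                 T_obs = df$T_obs[i], delta = df$delta[i], rho = df$rho[i]))
  list(study = study_data(subjects), preds = df, t = t, dt = dt)
}

# Tiny fixed-size study for fit-level tests.
tiny_study <- function(n = 40, seed = 1, ...) {
  cfg <- simulation_config(n_subjects = n, seed = seed, ...)
  simulate_study(cfg)$data
}
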