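#' Simulation benchmark of predictive accuracy
#'
#' For each replicate: simulate a study, split it in half into training and
#' test parts, fit the whole-trajectory joint model, the extrapolation
#' comparator and the time-dependent Cox model on the training half, and
#' evaluate the intermediate-event-stratified AUC(`t`, `dt`) and
#' PE(`t + dt` | `t`) of each on the test half at every landmark.
#'
#' @param config A [simulation_config()]; replicate `r` uses seed
#'   `config$seed + r - 1`.
#' @param replicates Number of simulation replicates.
#' @param landmarks Landmark times `t`.
#' @param dt Horizon (default 2, a clinically relevant prediction window).
#' @param spec [model_spec()] used for the two joint-model fits.
#' @param M Monte Carlo draws per test-subject prediction.
#' @param models Subset of `c("whole_trajectory", "extrapolation", "cox")`.
#' @return A `data.frame` with one row per (replicate, model, landmark,
#'   measure): columns `replicate, model, t, dt, measure, value, n` (size
#'   of the landmark risk set). Replicates where a fit fails are logged and
#'   excluded (attribute `n_failed`).
#' @export
run_benchmark <- function(config, replicates = 10, landmarks = c(20, 22, 24),
                          dt = 2, spec = model_spec(), M = 300,
                          models = c("whole_trajectory", "extrapolation", "cox")) {
  stopifnot(replicates >= 1)
  rows <- list()
  n_failed <- 0L
  for (r in seq_len(replicates)) {
    cfg <- config
    cfg$seed <- config$seed + r - 1L
    res <- tryCatch({
      sim <- simulate_study(cfg)
      halves <- split_study(sim)
      fits <- list()
      if ("whole_trajectory" %in% models)
        fits$whole_trajectory <- suppressWarnings(fit_joint_model(spec, halves$train))
      if ("extrapolation" %in% models)
        fits$extrapolation <- suppressWarnings(fit_extrapolation_model(spec, halves$train))
      if ("cox" %in% models)
        fits$cox <- fit_timedep_cox(halves$train)
      out <- list()
      for (mod in names(fits)) {
        for (t in landmarks) {
          preds <- accuracy_predictions(fits[[mod]], halves$test, t, dt,
                                        M = M, seed = cfg$seed)
          n_at_risk <- nrow(preds)
          auc <- auc_dynamic(halves$test, preds, t, dt)
          pe <- pe_dynamic(halves$test, preds, t, t + dt)
          out <- c(out, list(data.frame(
            replicate = r, model = mod, t = t, dt = dt,
            measure = c("auc", "pe"),
            value = c(auc$auc, pe$pe), n = n_at_risk)))
        }
      }
      do.call(rbind, out)
    }, error = function(e) {
      message(sprintf("replicate %d failed: %s", r, conditionMessage(e)))
      NULL
    })
    if (is.null(res)) n_failed <- n_failed + 1L else rows <- c(rows, list(res))
  }
  out <- do.call(rbind, rows)
  attr(out, "n_failed") <- n_failed
  out
}

#' Mean accuracy by model from a benchmark table
#'
#' @param bench Output of [run_benchmark()].
#' @return Data frame of mean AUC and PE per (model, t), NA-aware.
#' @export
summarize_benchmark <- function(bench) {
  ag <- stats::aggregate(value ~ model + t + measure, data = bench,
                         FUN = function(v) mean(v, na.rm = TRUE))
  ag[order(ag$measure, ag$t, ag$model), ]
}
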