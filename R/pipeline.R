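#' Run the full decoding pipeline on simulated sessions
#'
#' End-to-end orchestration: simulate one or more sessions, bin firing
#' rates, decode stimulus identity (150 ms window, 50 ms step) and
#' match/nonmatch choice (10 ms step over the test epoch) on correct trials,
#' spline-interpolate the choice curve and estimate its chance-crossing
#' latency, run the correct-to-error cross-condition test at `t_cross_ms`,
#' and fit the stimulus/decision subspace model at `t_ref_ms`. All outputs
#' (session CSVs, decoding-curve CSVs, condition-averaged trajectories, a
#' summary JSON stamped with the configuration hash, seed and package
#' version) are written under `out_dir`; rerunning with the same
#' configuration reproduces them byte for byte.
#'
#' @param config a [simulation_config()]; session `k` uses seed
#'   `config$seed + k - 1`.
#' @param out_dir output directory.
#' @param n_sessions number of sessions to simulate (default 1; t-tests
#'   against chance require >= 2).
#' @param n_folds cross-validation folds (default 20).
#' @param t_cross_ms time of the cross-condition test (default 2900 ms).
#' @param t_ref_ms subspace reference time (default 2700 ms).
#' @param interp_ms spline grid for the choice curve (default 2 ms).
#' @return invisibly, the summary list written to `summary.json`.
#' @export
run_pipeline <- function(config, out_dir, n_sessions = 1L, n_folds = 20L,
                         t_cross_ms = 2900, t_ref_ms = 2700, interp_ms = 2) {
  stopifnot(inherits(config, "sim_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  t_on <- config$test_onset_ms
  t_end <- t_on + config$test_max_ms

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stopf(paste0("pipeline stage '%s' failed: %s\n  reproduce with ",
                   "run_pipeline(simulation_config(seed = %d), ...)"),
            name, conditionMessage(e), config$seed))
  }

  stim_curves <- choice_curves <- vector("list", n_sessions)
  cross <- vector("list", n_sessions)
  sessions <- vector("list", n_sessions)
  for (k in seq_len(n_sessions)) {
    cfg_k <- config
    cfg_k$seed <- config$seed + k - 1L
    ses <- stage("simulate", generate_session(cfg_k))
    sessions[[k]] <- ses
    bundle <- session_bundle(ses$events, ses$trials,
                             session_id = sprintf("session%02d", k),
                             n_channels = cfg_k$n_channels,
                             provenance = unclass(cfg_k)["seed"])
    stage("write_session",
          write_session(bundle, file.path(out_dir, bundle$session_id)))
    corr <- ses$trials$correct

    stim_tensor <- stage("bin_stimulus",
      bin_firing_rates(ses$events, ses$trials, window_ms = 150, step_ms = 50,
                       t_range_ms = c(0, t_end), n_channels = cfg_k$n_channels))
    stim_curves[[k]] <- stage("decode_stimulus",
      time_resolved_decode(subset_tensor(stim_tensor, corr),
                           ses$trials$test_stim[corr],
                           n_folds = n_folds, seed = cfg_k$seed + 1000L))

    choice_tensor <- stage("bin_choice",
      bin_firing_rates(ses$events, ses$trials, window_ms = 150, step_ms = 10,
                       t_range_ms = c(t_on - 200, t_end),
                       n_channels = cfg_k$n_channels))
    choice_curves[[k]] <- stage("decode_choice",
      time_resolved_decode(subset_tensor(choice_tensor, corr),
                           ses$trials$trial_type[corr],
                           n_folds = n_folds, seed = cfg_k$seed + 2000L))

    cross[[k]] <- stage("cross_condition",
      cross_condition_test(choice_tensor, ses$trials, t_ms = t_cross_ms,
                           n_folds = n_folds, seed = cfg_k$seed + 3000L))
  }

  stim_curve <- combine_curves(stim_curves)
  choice_curve <- combine_curves(choice_curves)
  choice_fine <- stage("interpolate", interpolate_curve(choice_curve, interp_ms))
  latency <- latency_of_chance_crossing(choice_fine, test_onset_ms = t_on)

  stim_test <- if (n_sessions >= 2L)
    curve_vs_chance_test(stim_curve, t_ref_ms) else NULL

  # subspaces and trajectories from the first session
  ses1 <- sessions[[1L]]
  stim_tensor1 <- bin_firing_rates(ses1$events, ses1$trials, window_ms = 150,
                                   step_ms = 50, t_range_ms = c(0, t_end),
                                   n_channels = config$n_channels)
  model <- stage("subspace",
                 build_subspace_model(stim_tensor1, ses1$trials,
                                      t_ref_ms = t_ref_ms))
  at <- rates_at(stim_tensor1, t_ref_ms, warn = FALSE)
  corr1 <- ses1$trials$correct
  stim_pts <- at$x[corr1, , drop = FALSE] %*% model$stim_projection
  sil_stim <- class_separation_score(stim_pts, ses1$trials$test_stim[corr1])
  sil_dec <- class_separation_score(stim_pts, ses1$trials$trial_type[corr1])
  angles <- subspace_principal_angles(model$decision_projection,
                                      model$stim_projection)
  traj <- project_trajectories(stim_tensor1, model)
  traj_avg <- average_trajectories(traj, ses1$trials)

  write_curve_csv(stim_curve, file.path(out_dir, "stimulus_curve.csv"))
  write_curve_csv(choice_curve, file.path(out_dir, "choice_curve.csv"))
  write_traj_csv(traj_avg, file.path(out_dir, "trajectories.csv"))

  summary <- list(
    parameters = list(config_hash = obj_hash(unclass(config)),
                      seed = config$seed, n_sessions = n_sessions,
                      n_trials = config$n_trials, n_folds = n_folds,
                      t_cross_ms = t_cross_ms, t_ref_ms = t_ref_ms,
                      interp_ms = interp_ms,
                      package_version = as.character(utils::packageVersion("dmsdecode"))),
    stimulus = c(list(peak_accuracy = max(stim_curve$mean_accuracy),
                      peak_time_ms = stim_curve$times_ms[which.max(stim_curve$mean_accuracy)],
                      chance_level = stim_curve$chance_level),
                 if (!is.null(stim_test))
                   list(t_vs_chance = stim_test$t, p_vs_chance = stim_test$p,
                        t_test_time_ms = stim_test$t_used_ms)),
    choice = list(latency_ms_after_test_onset = latency,
                  peak_accuracy = max(choice_curve$mean_accuracy),
                  chance_level = choice_curve$chance_level),
    cross_condition = list(
      accuracy_correct = mean(vapply(cross, `[[`, 0, "accuracy_correct")),
      accuracy_error = mean(vapply(cross, `[[`, 0, "accuracy_error")),
      t_used_ms = cross[[1L]]$t_used_ms),
    subspace = list(t_ref_ms = model$t_ref_ms,
                    principal_angles_deg = angles,
                    silhouette_by_stimulus = sil_stim,
                    silhouette_by_decision = sil_dec))
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA,
                       null = "null")
  invisible(summary)
}

# restrict a rate tensor to a logical/integer trial subset
subset_tensor <- function(tensor, which_trials) {
  tensor$values <- tensor$values[which_trials, , , drop = FALSE]
  tensor$trial_ids <- tensor$trial_ids[which_trials]
  tensor
}

write_curve_csv <- function(curve, path) {
  df <- data.frame(time_ms = curve$times_ms,
                   mean_accuracy = curve$mean_accuracy,
                   ci95_halfwidth = curve$dispersion,
                   chance_level = curve$chance_level)
  acc <- t(curve$per_session_accuracy)
  colnames(acc) <- paste0("session", seq_len(ncol(acc)))
  utils::write.csv(cbind(df, acc), path, row.names = FALSE)
}

write_traj_csv <- function(traj_avg, path) {
  dn <- dimnames(traj_avg)
  long <- expand.grid(condition = dn[[1L]], time_ms = as.numeric(dn[[2L]]),
                      stringsAsFactors = FALSE)
  for (ax in dn[[3L]]) long[[ax]] <- as.vector(traj_avg[, , ax])
  utils::write.csv(long, path, row.names = FALSE)
}
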