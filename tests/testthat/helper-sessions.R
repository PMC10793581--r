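# shared simulated sessions, built once per test run
session_cache <- new.env(parent = emptyenv())

cached_session <- function(key, ...) {
  if (is.null(session_cache[[key]]))
    session_cache[[key]] <- generate_session(simulation_config(...))
  session_cache[[key]]
}

# default study conditions, medium size: used by several test files
default_session <- function() cached_session("default300", n_trials = 300, seed = 11)

# rates integrated over each trial's choice-signal epoch, for geometry tests
signal_epoch_rates <- function(ses, t_start = 2700, rt_min = 300) {
  keep <- ses$trials$rt_ms >= rt_min
  tr <- ses$trials[keep, , drop = FALSE]
  ev <- ses$events[ses$events$trial_id %in% tr$trial_id, , drop = FALSE]
  t_end <- ses$config$test_onset_ms +
    pmin(tr$rt_ms, ses$config$test_max_ms) + ses$config$visual_latency_ms
  list(x = epoch_firing_rates(ev, tr, t_start, t_end,
                              n_channels = ses$config$n_channels),
       trials = tr)
}
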