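#' Configuration for a simulated delayed match-to-sample session
#'
#' Builds and validates the parameter set for [generate_session()]. The
#' defaults describe a session of the kind recorded in awake-monkey V1
#' experiments: 32 multi-unit channels, 3 stimuli per session, trials
#' consisting of 500 ms fixation, 500 ms sample, 1500 ms delay and a test
#' stimulus shown for at most 500 ms (so the test comes on 2500 ms after
#' fixation onset). Channels carry stimulus-tuned Poisson firing plus an
#' additive choice signal that switches on a fixed latency after test onset
#' along a population direction with a controllable principal angle to the
#' stimulus-coding span.
#'
#' @param n_trials number of trials to simulate.
#' @param n_channels number of recording channels.
#' @param n_stimuli number of distinct stimulus images per session.
#' @param p_match probability that a trial is a match trial.
#' @param error_rate probability that the simulated animal answers wrongly.
#' @param fixation_ms,sample_ms,delay_ms,test_max_ms epoch durations in ms.
#'   Trial time 0 is fixation onset; test onset is at
#'   `fixation_ms + sample_ms + delay_ms`.
#' @param baseline_rate baseline firing rate, spikes/s per channel.
#' @param stim_gain `n_channels x n_stimuli` matrix of additive rate
#'   modulation (spikes/s) applied while the corresponding stimulus drives
#'   the channel. Default: round-robin preferred-stimulus tuning with
#'   `stim_gain_max` for the preferred image and 0 otherwise.
#' @param stim_gain_max peak tuning gain used to build the default `stim_gain`.
#' @param visual_latency_ms delay from stimulus onset/offset to the rate change.
#' @param decision_gain amplitude (spikes/s) of the choice signal along
#'   `decision_direction`.
#' @param decision_latency_ms delay from test onset to choice-signal onset.
#' @param decision_ramp_ms linear rise time of the choice signal.
#' @param decision_angle_deg target principal angle (degrees) between the
#'   decision direction and the span of stimulus tuning contrasts; used to
#'   construct `decision_direction` when that is `NULL`.
#' @param decision_direction optional unit vector over channels; overrides
#'   `decision_angle_deg`.
#' @param decision_signal `"choice"` (default): the signal follows the
#'   animal's choice, so it is inverted relative to trial type on error
#'   trials. `"trial_type"`: the signal follows match/nonmatch regardless of
#'   the choice (a control condition in which a decoder trained on correct
#'   trials generalizes to error trials).
#' @param rt_mean_ms,rt_sd_ms reaction-time distribution (normal truncated at
#'   zero), measured from test onset.
#' @param seed integer seed; the whole session is reproducible given the
#'   configuration.
#'
#' @return an object of class `sim_config` (a validated list). The realized
#'   decision direction is stored in `$decision_direction`.
#' @seealso [generate_session()], [expected_rate()]
#' @export
simulation_config <- function(n_trials = 600L,
                              n_channels = 32L,
                              n_stimuli = 3L,
                              p_match = 0.5,
                              error_rate = 0.22,
                              fixation_ms = 500,
                              sample_ms = 500,
                              delay_ms = 1500,
                              test_max_ms = 500,
                              baseline_rate = 10,
                              stim_gain = NULL,
                              stim_gain_max = 15,
                              visual_latency_ms = 50,
                              decision_gain = 10,
                              decision_latency_ms = 150,
                              decision_ramp_ms = 100,
                              decision_angle_deg = 90,
                              decision_direction = NULL,
                              decision_signal = c("choice", "trial_type"),
                              rt_mean_ms = 632,
                              rt_sd_ms = 174.7,
                              seed = 1L) {
  decision_signal <- match.arg(decision_signal)
  if (n_trials < 1 || n_channels < 1 || n_stimuli < 2)
    stopf("need n_trials >= 1, n_channels >= 1, n_stimuli >= 2")
  if (p_match < 0 || p_match > 1 || error_rate < 0 || error_rate > 1)
    stopf("p_match and error_rate must lie in [0, 1]")
  if (any(c(fixation_ms, sample_ms, delay_ms, test_max_ms) <= 0))
    stopf("all epoch durations must be > 0")
  if (baseline_rate < 0 || decision_gain < 0)
    stopf("baseline_rate and decision_gain must be >= 0")
  if (rt_sd_ms < 0 || rt_mean_ms <= 0)
    stopf("reaction-time parameters must be positive")

  if (is.null(stim_gain)) {
    stim_gain <- matrix(0, n_channels, n_stimuli)
    pref <- (seq_len(n_channels) - 1L) %% n_stimuli + 1L
    stim_gain[cbind(seq_len(n_channels), pref)] <- stim_gain_max
  }
  stim_gain <- as.matrix(stim_gain)
  if (!all(dim(stim_gain) == c(n_channels, n_stimuli)))
    stopf("stim_gain must be %d x %d", n_channels, n_stimuli)
  if (any(stim_gain < 0))
    stopf("stim_gain must be nonnegative (tuning is additive)")

  if (is.null(decision_direction)) {
    decision_direction <- make_decision_direction(stim_gain, decision_angle_deg)
  } else {
    nrm <- sqrt(sum(decision_direction^2))
    if (nrm == 0) stopf("decision_direction must be nonzero")
    decision_direction <- decision_direction / nrm
    if (length(decision_direction) != n_channels)
      stopf("decision_direction must have one entry per channel")
  }

  cfg <- structure(list(
    n_trials = as.integer(n_trials), n_channels = as.integer(n_channels),
    n_stimuli = as.integer(n_stimuli), p_match = p_match,
    error_rate = error_rate, fixation_ms = fixation_ms,
    sample_ms = sample_ms, delay_ms = delay_ms, test_max_ms = test_max_ms,
    baseline_rate = baseline_rate, stim_gain = stim_gain,
    visual_latency_ms = visual_latency_ms, decision_gain = decision_gain,
    decision_latency_ms = decision_latency_ms,
    decision_ramp_ms = decision_ramp_ms,
    decision_angle_deg = decision_angle_deg,
    decision_direction = decision_direction,
    decision_signal = decision_signal,
    rt_mean_ms = rt_mean_ms, rt_sd_ms = rt_sd_ms,
    test_onset_ms = fixation_ms + sample_ms + delay_ms,
    seed = as.integer(seed)), class = "sim_config")

  check_rate_nonnegativity(cfg)
  cfg
}

# Construct a unit decision direction at a given principal angle to the span
# of stimulus tuning contrasts (columns of stim_gain centered across stimuli).
# Deterministic: in-span component along the leading contrast axis, out-of-span
# component along a fixed alternating pattern orthogonalized against the span.
make_decision_direction <- function(stim_gain, angle_deg) {
  if (angle_deg < 0 || angle_deg > 90)
    stopf("decision_angle_deg must lie in [0, 90]")
  nch <- nrow(stim_gain)
  contrasts <- stim_gain - rowMeans(stim_gain)
  basis <- orth_basis(contrasts)
  if (ncol(basis) == 0L) {
    # no stimulus tuning: angle undefined, fall back to the fixed pattern
    w <- rep_len(c(1, -1), nch)
    return(w / sqrt(sum(w^2)))
  }
  u <- basis[, 1L]
  w <- rep_len(c(1, -1), nch)
  w <- w - basis %*% crossprod(basis, w)
  nw <- sqrt(sum(w^2))
  if (nw < 1e-8) stopf("cannot build an out-of-span direction; supply decision_direction")
  w <- as.vector(w) / nw
  th <- angle_deg * pi / 180
  d <- cos(th) * u + sin(th) * w
  d / sqrt(sum(d^2))
}

# Reject configurations whose summed rate would be clipped at zero for more
# than 1% of channel-time on a representative trial (rt = rt_mean_ms).
check_rate_nonnegativity <- function(cfg) {
  rt <- cfg$rt_mean_ms
  t_on <- cfg$test_onset_ms
  end <- t_on + max(cfg$test_max_ms, rt)
  grid <- seq(0, end, by = 5)
  clipped <- 0
  for (ch in seq_len(cfg$n_channels)) {
    amp <- -cfg$decision_gain * abs(cfg$decision_direction[ch])  # worst sign
    ramp <- pmin(1, pmax(0, (grid - (t_on + cfg$decision_latency_ms)) /
                              max(cfg$decision_ramp_ms, 1e-9)))
    ramp[grid < t_on + cfg$decision_latency_ms | grid >= t_on + rt] <- 0
    r <- cfg$baseline_rate + amp * ramp  # no tuning: conservative lower bound
    clipped <- clipped + sum(r < 0)
  }
  frac <- clipped / (cfg$n_channels * length(grid))
  if (frac >= 0.01)
    stopf(paste0("configuration implies negative instantaneous rates over ",
                 "%.1f%% of channel-time (limit 1%%); reduce decision_gain ",
                 "or raise baseline_rate"), 100 * frac)
  invisible(frac)
}

#' Lever choice implied by trial type and correctness
#'
#' In the task the lever moves forward on match trials and backward on
#' nonmatch trials; an incorrect response is the opposite lever direction.
#'
#' @param trial_type character vector, `"match"` or `"nonmatch"`.
#' @param correct logical vector.
#' @return character vector, `"forward"` or `"backward"`.
#' @export
assign_choice <- function(trial_type, correct) {
  if (!all(trial_type %in% c("match", "nonmatch")))
    stopf("trial_type must be 'match' or 'nonmatch'")
  correct_choice <- ifelse(trial_type == "match", "forward", "backward")
  wrong_choice <- ifelse(trial_type == "match", "backward", "forward")
  ifelse(correct, correct_choice, wrong_choice)
}

#' Ground-truth firing rate of the generator
#'
#' Evaluates the instantaneous rate (spikes/s) that [generate_session()] uses
#' for one channel on one trial, after clipping at zero. Useful as an oracle
#' when validating binning and decoding on simulated sessions.
#'
#' @param config a [simulation_config()].
#' @param trial one row of the trial table returned by [generate_session()]
#'   (needs `sample_stim`, `test_stim`, `trial_type`, `choice`, `rt_ms`).
#' @param channel channel id (0-based, as in the spike table).
#' @param t numeric vector of times in ms from fixation onset.
#' @return numeric vector of rates, same length as `t`.
#' @export
expected_rate <- function(config, trial, channel, t) {
  ch <- channel + 1L
  vl <- config$visual_latency_ms
  t_on <- config$test_onset_ms
  s_on <- config$fixation_ms + vl
  s_off <- config$fixation_ms + config$sample_ms + vl
  rt <- trial$rt_ms
  test_off <- t_on + min(rt, config$test_max_ms) + vl
  c_on <- t_on + config$decision_latency_ms
  c_off <- t_on + rt
  sgn <- choice_sign(config, trial)
  g_s <- config$stim_gain[ch, trial$sample_stim + 1L]
  g_t <- config$stim_gain[ch, trial$test_stim + 1L]
  amp <- sgn * config$decision_gain * config$decision_direction[ch]
  ramp <- pmin(1, pmax(0, (t - c_on) / max(config$decision_ramp_ms, 1e-9)))
  ramp[t < c_on | t >= c_off] <- 0
  r <- config$baseline_rate +
    g_s * (t >= s_on & t < s_off) +
    g_t * (t >= t_on + vl & t < test_off) +
    amp * ramp
  pmax(r, 0)
}

choice_sign <- function(config, trial) {
  if (config$decision_signal == "choice") {
    ifelse(trial$choice == "forward", 1, -1)
  } else {
    ifelse(trial$trial_type == "match", 1, -1)
  }
}

#' Simulate one delayed match-to-sample session
#'
#' Draws trial labels (sample and test stimulus, match/nonmatch, choice,
#' correctness, reaction time) and generates inhomogeneous-Poisson spike
#' trains for every channel by thinning against the ground-truth rate of
#' [expected_rate()]: baseline + stimulus tuning during sample and test
#' epochs (after a short visual latency) + an additive choice signal that
#' ramps on `decision_latency_ms` after test onset and stays on until the
#' response. On error trials the choice signal is inverted relative to trial
#' type (unless `decision_signal = "trial_type"`).
#'
#' Spike times are in ms from fixation onset, rounded to 1 microsecond, and
#' sorted by (trial, channel, time). The trial recording ends at
#' `test_onset + max(test_max_ms, rt_ms)`.
#'
#' @param config a [simulation_config()].
#' @return a list with elements
#'   \describe{
#'     \item{events}{data.frame `trial_id`, `channel` (0-based),
#'       `spike_time_ms` — the spike-event table.}
#'     \item{trials}{data.frame `trial_id`, `sample_stim`, `test_stim`
#'       (0-based ids), `trial_type`, `choice`, `correct`, `rt_ms`.}
#'     \item{config}{the configuration used.}
#'   }
#' @export
generate_session <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  n <- config$n_trials
  ns <- config$n_stimuli

  sample_stim <- sample.int(ns, n, replace = TRUE) - 1L
  is_match <- stats::runif(n) < config$p_match
  offset <- sample.int(ns - 1L, n, replace = TRUE)
  test_stim <- ifelse(is_match, sample_stim, (sample_stim + offset) %% ns)
  trial_type <- ifelse(is_match, "match", "nonmatch")
  correct <- stats::runif(n) >= config$error_rate
  choice <- assign_choice(trial_type, correct)
  rt_ms <- round(rtrunc_norm(n, config$rt_mean_ms, config$rt_sd_ms), 3)

  trials <- data.frame(trial_id = seq_len(n), sample_stim = as.integer(sample_stim),
                       test_stim = as.integer(test_stim), trial_type = trial_type,
                       choice = choice, correct = correct, rt_ms = rt_ms,
                       stringsAsFactors = FALSE)

  nch <- config$n_channels
  t_on <- config$test_onset_ms
  ev_trial <- vector("list", n)
  ev_chan <- vector("list", n)
  ev_time <- vector("list", n)
  for (i in seq_len(n)) {
    tr <- trials[i, ]
    t_end <- t_on + max(config$test_max_ms, tr$rt_ms)
    sgn <- choice_sign(config, tr)
    times_per_ch <- vector("list", nch)
    for (ch in seq_len(nch)) {
      g_max <- max(config$stim_gain[ch, tr$sample_stim + 1L],
                   config$stim_gain[ch, tr$test_stim + 1L])
      amp <- sgn * config$decision_gain * config$decision_direction[ch]
      r_max <- config$baseline_rate + g_max + max(amp, 0)
      if (r_max <= 0) { times_per_ch[[ch]] <- numeric(0); next }
      n_cand <- stats::rpois(1L, r_max * t_end / 1000)
      if (n_cand == 0L) { times_per_ch[[ch]] <- numeric(0); next }
      tt <- stats::runif(n_cand, 0, t_end)
      keep <- stats::runif(n_cand) * r_max < expected_rate(config, tr, ch - 1L, tt)
      times_per_ch[[ch]] <- tt[keep]
    }
    counts <- lengths(times_per_ch)
    ev_trial[[i]] <- rep.int(i, sum(counts))
    ev_chan[[i]] <- rep.int(0:(nch - 1L), counts)
    ev_time[[i]] <- unlist(times_per_ch, use.names = FALSE)
  }
  events <- data.frame(trial_id = unlist(ev_trial, use.names = FALSE),
                       channel = unlist(ev_chan, use.names = FALSE),
                       spike_time_ms = round(unlist(ev_time, use.names = FALSE), 3))
  events <- events[order(events$trial_id, events$channel, events$spike_time_ms), ,
                   drop = FALSE]
  rownames(events) <- NULL
  list(events = events, trials = trials, config = config)
}

# normal truncated at zero (rejection; rt_mean_ms several sd above 0 in
# practice, so acceptance is near 1)
rtrunc_norm <- function(n, mean, sd) {
  out <- stats::rnorm(n, mean, sd)
  bad <- which(out <= 0)
  while (length(bad)) {
    out[bad] <- stats::rnorm(length(bad), mean, sd)
    bad <- bad[out[bad] <= 0]
  }
  out
}
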