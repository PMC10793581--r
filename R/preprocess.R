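#' Detect threshold-crossing spike events in a filtered trace
#'
#' Multi-unit activity is taken as the times at which the band-passed
#' voltage trace first crosses +/- `threshold_multiplier` times the standard
#' deviation of the whole trace, with one event per crossing enforced by a
#' dead time. The input is assumed to be already band-pass filtered (e.g.
#' 300-4000 Hz); filtering itself is a standard signal-processing step and
#' is not performed here.
#'
#' @param signal numeric vector, one channel's filtered trace.
#' @param fs_hz sampling rate in Hz.
#' @param threshold_multiplier threshold in units of the trace SD (default 4).
#' @param dead_time_ms minimum separation between successive events, ms.
#' @return numeric vector of event times in ms from the start of the trace.
#' @export
detect_spikes <- function(signal, fs_hz, threshold_multiplier = 4,
                          dead_time_ms = 1) {
  if (dead_time_ms <= 0) stopf("dead_time_ms must be > 0")
  s <- stats::sd(signal)
  if (!is.finite(s) || s == 0) stopf("signal has zero variance; no threshold defined")
  thr <- threshold_multiplier * s
  above <- abs(signal) >= thr
  onset <- above & !c(FALSE, above[-length(above)])
  times <- (which(onset) - 1L) / fs_hz * 1000
  if (length(times) <= 1L) return(times)
  keep <- logical(length(times))
  keep[1L] <- TRUE
  last <- times[1L]
  for (i in 2:length(times)) {
    if (times[i] - last >= dead_time_ms) {
      keep[i] <- TRUE
      last <- times[i]
    }
  }
  times[keep]
}

#' Shift spike times so that 0 marks the behavioral response
#'
#' Subtracts `test_onset_ms + rt_ms` from every spike of each trial, so that
#' downstream binning is indexed by time-to-response (negative before the
#' lever movement). Rate tensors are not shifted in place — they live on a
#' shared session clock — so response-aligned tensors are produced by
#' re-binning the shifted events with [bin_firing_rates()].
#'
#' @param events spike-event data.frame (`trial_id`, `channel`,
#'   `spike_time_ms`).
#' @param trials trial table with `trial_id` and `rt_ms`.
#' @param test_onset_ms test-stimulus onset on the session clock (2500 ms for
#'   the standard epoch structure).
#' @return the events data.frame with `spike_time_ms` re-expressed as time to
#'   response.
#' @export
align_to_response <- function(events, trials, test_onset_ms = 2500) {
  idx <- match(events$trial_id, trials$trial_id)
  if (anyNA(idx)) stopf("events reference trial ids missing from the trial table")
  rt <- trials$rt_ms[idx]
  if (anyNA(rt)) {
    bad <- unique(events$trial_id[is.na(rt)])
    stopf("missing reaction time for trial(s) %s", paste(bad, collapse = ", "))
  }
  events$spike_time_ms <- events$spike_time_ms - (test_onset_ms + rt)
  events
}

#' Bin spikes into a trials x channels x time firing-rate tensor
#'
#' Counts spikes in causal moving windows: the bin labeled `t` covers the
#' half-open interval `(t - window_ms, t]`, so a spike exactly at the label
#' time counts and nothing after `t` can influence the bin. Counts are
#' converted to rates in spikes/s. Bin labels sit on the grid
#' `t_range_ms[1] + k * step_ms`; windows that would extend before
#' `t_range_ms[1]` are dropped (with a warning when that removes requested
#' grid points before trial start).
#'
#' @param events spike-event data.frame (`trial_id`, `channel` 0-based,
#'   `spike_time_ms`).
#' @param trials trial table; defines trial order and, for response
#'   alignment, reaction times.
#' @param window_ms causal window width, ms (default 150).
#' @param step_ms grid step, ms (default 50; use 10 for finer choice-decoding
#'   grids).
#' @param alignment `"stimulus_onset"`: times on the session clock with 0 at
#'   fixation onset; `"response_onset"`: events are first shifted with
#'   [align_to_response()] so 0 is the response.
#' @param t_range_ms length-2 numeric, the time span to cover (bin labels
#'   inclusive of both ends where a full window fits).
#' @param n_channels number of channels; default `max(channel) + 1`.
#' @param test_onset_ms passed to [align_to_response()] when needed.
#' @return a `rate_tensor`: list with `values` (trials x channels x bins
#'   array, spikes/s), `bin_times_ms` (right edges), `window_ms`, `step_ms`,
#'   `alignment`, `trial_ids`.
#' @export
bin_firing_rates <- function(events, trials, window_ms = 150, step_ms = 50,
                             alignment = c("stimulus_onset", "response_onset"),
                             t_range_ms, n_channels = NULL,
                             test_onset_ms = 2500) {
  alignment <- match.arg(alignment)
  if (window_ms <= 0 || step_ms <= 0) stopf("window_ms and step_ms must be > 0")
  if (length(t_range_ms) != 2L || diff(t_range_ms) <= 0)
    stopf("t_range_ms must be (start, end) with end > start")
  if (alignment == "response_onset")
    events <- align_to_response(events, trials, test_onset_ms)
  n_channels <- n_channels %||%
    (if (nrow(events)) max(events$channel) + 1L else stopf("n_channels required for empty event tables"))

  t0 <- t_range_ms[1]
  grid <- seq(t0, t_range_ms[2], by = step_ms)
  full <- grid - window_ms >= t0 - 1e-9
  if (!any(full)) stopf("no full window fits inside t_range_ms")
  bin_times <- grid[full]
  k_off <- which(full)[1L] - 1L  # grid index offset of the first kept bin

  n_tr <- nrow(trials)
  n_bins <- length(bin_times)
  tr_pos <- match(events$trial_id, trials$trial_id)
  if (anyNA(tr_pos)) stopf("events reference trial ids missing from the trial table")
  if (nrow(events) && (min(events$channel) < 0 || max(events$channel) >= n_channels))
    stopf("channel ids must lie in 0..%d", n_channels - 1L)

  counts <- integer(n_tr * n_channels * n_bins)
  if (nrow(events)) {
    s <- events$spike_time_ms
    kmin <- ceiling((s - t0) / step_ms - 1e-7) - k_off
    kmax <- ceiling((s + window_ms - t0) / step_ms - 1e-7) - 1L - k_off
    kmin <- pmax(kmin, 0L)
    kmax <- pmin(kmax, n_bins - 1L)
    nk <- pmax(kmax - kmin + 1L, 0L)
    sel <- nk > 0L
    if (any(sel)) {
      reps <- nk[sel]
      bins <- sequence(reps) - 1L + rep.int(kmin[sel], reps)
      tr_rep <- rep.int(tr_pos[sel], reps)
      ch_rep <- rep.int(events$channel[sel] + 1L, reps)
      idx <- ((tr_rep - 1L) * n_channels + (ch_rep - 1L)) * n_bins + bins + 1L
      counts <- tabulate(idx, nbins = n_tr * n_channels * n_bins)
    }
  }
  vals <- aperm(array(counts, dim = c(n_bins, n_channels, n_tr)), c(3L, 2L, 1L)) /
    (window_ms / 1000)
  dimnames(vals) <- list(as.character(trials$trial_id),
                         paste0("ch", 0:(n_channels - 1L)),
                         as.character(bin_times))
  structure(list(values = vals, bin_times_ms = bin_times, window_ms = window_ms,
                 step_ms = step_ms, alignment = alignment,
                 trial_ids = trials$trial_id),
            class = "rate_tensor")
}

#' @export
print.rate_tensor <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("rate_tensor: %d trials x %d channels x %d bins\n", d[1], d[2], d[3]))
  cat(sprintf("  window %g ms, step %g ms, alignment %s, t in [%g, %g] ms\n",
              x$window_ms, x$step_ms, x$alignment,
              min(x$bin_times_ms), max(x$bin_times_ms)))
  invisible(x)
}

#' Per-trial firing rates over a single (possibly trial-specific) epoch
#'
#' Counts spikes in the half-open window `(t_start_ms, t_end_ms]` of each
#' trial and converts to spikes/s. `t_end_ms` may be one value per trial
#' (e.g. the response time), which integrates each trial exactly over the
#' span during which a signal of interest is present.
#'
#' @param events spike-event data.frame.
#' @param trials trial table defining trial order.
#' @param t_start_ms scalar epoch start.
#' @param t_end_ms scalar or per-trial vector of epoch ends (> `t_start_ms`).
#' @param n_channels number of channels; default `max(channel) + 1`.
#' @return trials x channels matrix of rates (spikes/s).
#' @export
epoch_firing_rates <- function(events, trials, t_start_ms, t_end_ms,
                               n_channels = NULL) {
  n_channels <- n_channels %||%
    (if (nrow(events)) max(events$channel) + 1L else stopf("n_channels required"))
  t_end_ms <- rep_len(t_end_ms, nrow(trials))
  if (any(t_end_ms <= t_start_ms)) stopf("t_end_ms must exceed t_start_ms")
  tr_pos <- match(events$trial_id, trials$trial_id)
  if (anyNA(tr_pos)) stopf("events reference trial ids missing from the trial table")
  keep <- events$spike_time_ms > t_start_ms &
    events$spike_time_ms <= t_end_ms[tr_pos]
  idx <- (tr_pos[keep] - 1L) * n_channels + events$channel[keep] + 1L
  cnt <- matrix(tabulate(idx, nbins = nrow(trials) * n_channels),
                nrow = nrow(trials), byrow = TRUE)
  dimnames(cnt) <- list(as.character(trials$trial_id),
                        paste0("ch", 0:(n_channels - 1L)))
  cnt / ((t_end_ms - t_start_ms) / 1000)
}

# rate vectors (trials x channels) at the bin nearest to t_ms
rates_at <- function(tensor, t_ms, warn = TRUE) {
  i <- which.min(abs(tensor$bin_times_ms - t_ms))
  if (warn && abs(tensor$bin_times_ms[i] - t_ms) > 1e-9)
    warnf("t = %g ms is not on the bin grid; using nearest bin at %g ms",
          t_ms, tensor$bin_times_ms[i])
  list(x = tensor$values[, , i, drop = TRUE], t_ms = tensor$bin_times_ms[i])
}
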