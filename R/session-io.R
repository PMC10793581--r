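#' Bundle a session's events, trials and metadata
#'
#' Validates and packages one session: every event must reference a known
#' trial, channel ids must lie in `0..n_channels-1`, and events are stored
#' sorted by (trial, channel, time) so that on-disk output is deterministic.
#'
#' @param events spike-event data.frame (`trial_id`, `channel`,
#'   `spike_time_ms`).
#' @param trials trial table (`trial_id`, `sample_stim`, `test_stim`,
#'   `trial_type`, `choice`, `correct`, `rt_ms`).
#' @param session_id character identifier.
#' @param n_channels channel count; default `max(channel) + 1`.
#' @param provenance optional list recorded verbatim in the metadata (e.g.
#'   the generator configuration).
#' @return a `session_bundle`.
#' @export
session_bundle <- function(events, trials, session_id = "session1",
                           n_channels = NULL, provenance = NULL) {
  req_ev <- c("trial_id", "channel", "spike_time_ms")
  req_tr <- c("trial_id", "sample_stim", "test_stim", "trial_type", "choice",
              "correct", "rt_ms")
  miss <- setdiff(req_ev, names(events))
  if (length(miss)) stopf("events table lacks column(s): %s", paste(miss, collapse = ", "))
  miss <- setdiff(req_tr, names(trials))
  if (length(miss)) stopf("trial table lacks column(s): %s", paste(miss, collapse = ", "))
  orphans <- setdiff(unique(events$trial_id), trials$trial_id)
  if (length(orphans))
    stopf("events reference trial id(s) absent from the trial table: %s",
          paste(utils::head(orphans, 5L), collapse = ", "))
  n_channels <- n_channels %||% (if (nrow(events)) max(events$channel) + 1L else 1L)
  if (nrow(events) && (min(events$channel) < 0 || max(events$channel) >= n_channels))
    stopf("channel ids must lie in 0..%d", n_channels - 1L)
  if (nrow(events) && min(events$spike_time_ms) < 0)
    stopf("spike times must be >= 0 (ms from fixation onset)")
  if (any(trials$rt_ms <= 0)) stopf("reaction times must be > 0")
  events <- events[order(events$trial_id, events$channel, events$spike_time_ms),
                   req_ev, drop = FALSE]
  rownames(events) <- NULL
  trials <- trials[order(trials$trial_id), req_tr, drop = FALSE]
  rownames(trials) <- NULL
  structure(list(session_id = session_id, events = events, trials = trials,
                 n_channels = as.integer(n_channels),
                 provenance = provenance),
            class = "session_bundle")
}

#' Write a session bundle to disk
#'
#' Writes `events.csv`, `trials.csv` and `session.json` (metadata: id,
#' channel count, provenance, a provenance hash, package version) into a
#' directory. Rows are ordered (trial, channel, time), so repeated writes of
#' the same bundle are byte-identical.
#'
#' @param bundle a `session_bundle`.
#' @param path output directory (created if absent).
#' @param format only `"csv"` is supported.
#' @return `path`, invisibly.
#' @export
write_session <- function(bundle, path, format = "csv") {
  stopifnot(inherits(bundle, "session_bundle"))
  format <- match.arg(format, "csv")
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(bundle$events, file.path(path, "events.csv"), row.names = FALSE)
  utils::write.csv(bundle$trials, file.path(path, "trials.csv"), row.names = FALSE)
  meta <- list(session_id = bundle$session_id, n_channels = bundle$n_channels,
               n_trials = nrow(bundle$trials), n_events = nrow(bundle$events),
               provenance = bundle$provenance,
               provenance_hash = obj_hash(bundle$provenance),
               package_version = as.character(utils::packageVersion("dmsdecode")))
  jsonlite::write_json(meta, file.path(path, "session.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' Read a session bundle from disk
#'
#' Inverse of [write_session()]; all bundle invariants are re-validated on
#' load, and schema violations name the offending file and column.
#'
#' @param path directory containing `events.csv`, `trials.csv`,
#'   `session.json`.
#' @param format only `"csv"`.
#' @return a `session_bundle`.
#' @export
read_session <- function(path, format = "csv") {
  format <- match.arg(format, "csv")
  ev_file <- file.path(path, "events.csv")
  tr_file <- file.path(path, "trials.csv")
  meta_file <- file.path(path, "session.json")
  for (f in c(ev_file, tr_file, meta_file))
    if (!file.exists(f)) stopf("missing session file: %s", f)
  events <- tryCatch(
    utils::read.csv(ev_file, colClasses = c(trial_id = "integer",
                                            channel = "integer",
                                            spike_time_ms = "numeric")),
    error = function(e) stopf("%s: malformed events table (%s)", ev_file,
                              conditionMessage(e)))
  trials <- tryCatch(
    utils::read.csv(tr_file, colClasses = c(trial_id = "integer",
                                            sample_stim = "integer",
                                            test_stim = "integer",
                                            trial_type = "character",
                                            choice = "character",
                                            correct = "logical",
                                            rt_ms = "numeric")),
    error = function(e) stopf("%s: malformed trial table (%s)", tr_file,
                              conditionMessage(e)))
  if (!all(trials$trial_type %in% c("match", "nonmatch")))
    stopf("%s: column trial_type has values outside {match, nonmatch}", tr_file)
  if (!all(trials$choice %in% c("forward", "backward")))
    stopf("%s: column choice has values outside {forward, backward}", tr_file)
  meta <- jsonlite::read_json(meta_file, simplifyVector = TRUE)
  session_bundle(events, trials, session_id = meta$session_id,
                 n_channels = meta$n_channels, provenance = meta$provenance)
}

#' @export
print.session_bundle <- function(x, ...) {
  cat(sprintf("session_bundle '%s': %d trials, %d channels, %d spikes\n",
              x$session_id, nrow(x$trials), x$n_channels, nrow(x$events)))
  invisible(x)
}
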