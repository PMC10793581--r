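#' Fit a shrinkage-regularized linear discriminant classifier
#'
#' Gaussian classes with a shared covariance: class means are per-class
#' sample means and the pooled within-class covariance is shrunk toward its
#' diagonal, `(1 - shrinkage) * S + shrinkage * diag(diag(S))`, which keeps
#' the fit well-conditioned when the number of channels approaches the
#' per-class sample count in a cross-validation fold.
#'
#' @param x numeric matrix, samples x channels (firing rates).
#' @param y class labels (coerced to factor; classes ordered by level).
#' @param shrinkage coefficient in `[0, 1]` (default 0.1).
#' @param priors class prior probabilities; default empirical frequencies.
#' @return an `lda_model`: class means, regularized pooled covariance (and
#'   its Cholesky factor), priors, labels.
#' @export
fit_lda <- function(x, y, shrinkage = 0.1, priors = NULL) {
  x <- as.matrix(x)
  y <- factor(y)
  if (nlevels(y) < 2L) stopf("need at least 2 classes")
  if (shrinkage < 0 || shrinkage > 1) stopf("shrinkage must lie in [0, 1]")
  counts <- table(y)
  if (any(counts < 2L))
    stopf("every class needs >= 2 samples (got %s)",
          paste(names(counts)[counts < 2], collapse = ", "))
  if (nrow(x) != length(y)) stopf("x and y lengths differ")
  k <- nlevels(y)
  p <- ncol(x)
  means <- matrix(0, k, p, dimnames = list(levels(y), colnames(x)))
  sw <- matrix(0, p, p)
  for (j in seq_len(k)) {
    xi <- x[y == levels(y)[j], , drop = FALSE]
    means[j, ] <- colMeans(xi)
    xc <- sweep(xi, 2L, means[j, ])
    sw <- sw + crossprod(xc)
  }
  sw <- sw / (nrow(x) - k)
  sigma <- (1 - shrinkage) * sw + shrinkage * diag(diag(sw), p)
  ch <- tryCatch(chol(sigma), error = function(e) NULL)
  if (is.null(ch) && shrinkage > 0) {
    # zero-variance features survive diagonal shrinkage; a minimal ridge keeps
    # the model defined (priors then decide among identical class means)
    ridge <- 1e-8 * max(mean(diag(sigma)), 1)
    sigma2 <- sigma + diag(ridge, p)
    ch <- tryCatch(chol(sigma2), error = function(e) NULL)
    if (!is.null(ch)) sigma <- sigma2
  }
  if (is.null(ch))
    stopf("pooled covariance is singular; increase shrinkage (got %g)", shrinkage)
  priors <- priors %||% as.vector(counts / sum(counts))
  if (length(priors) != k || any(priors < 0) || abs(sum(priors) - 1) > 1e-8)
    stopf("priors must be %d nonnegative values summing to 1", k)
  structure(list(class_labels = levels(y), class_means = means,
                 covariance = sigma, chol_cov = ch, priors = priors,
                 shrinkage = shrinkage),
            class = "lda_model")
}

#' Predict classes or discriminant scores from a fitted LDA model
#'
#' The discriminant score of class k at point x is the shared-covariance
#' Gaussian log posterior up to a constant:
#' `x' S^-1 m_k - m_k' S^-1 m_k / 2 + log prior_k`. Ties are broken toward
#' the lowest class label.
#'
#' @param model an `lda_model` from [fit_lda()].
#' @param x samples x channels matrix (or a single vector).
#' @param type `"class"` (default), `"score"` or `"posterior"`.
#' @return factor of predicted labels, or a samples x classes matrix.
#' @export
predict_lda <- function(model, x, type = c("class", "score", "posterior")) {
  type <- match.arg(type)
  if (is.vector(x)) x <- matrix(x, nrow = 1L)
  x <- as.matrix(x)
  p <- ncol(model$class_means)
  if (ncol(x) != p)
    stopf("x has %d columns but the model expects %d channels", ncol(x), p)
  # S^-1 M' via the Cholesky factor
  sim <- backsolve(model$chol_cov,
                   forwardsolve(t(model$chol_cov), t(model$class_means)))
  scores <- x %*% sim
  scores <- sweep(scores, 2L, 0.5 * colSums(t(model$class_means) * sim)) # - m'S^-1 m / 2
  scores <- sweep(scores, 2L, log(model$priors), `+`)
  colnames(scores) <- model$class_labels
  if (type == "score") return(scores)
  if (type == "posterior") {
    e <- exp(scores - apply(scores, 1L, max))
    return(e / rowSums(e))
  }
  factor(model$class_labels[max.col(scores, ties.method = "first")],
         levels = model$class_labels)
}

# stratified fold assignment: within each class, shuffled round-robin
stratified_folds <- function(y, n_folds) {
  fold <- integer(length(y))
  for (lev in levels(y)) {
    idx <- which(y == lev)
    fold[idx] <- sample(rep_len(seq_len(n_folds), length(idx)))
  }
  fold
}

#' Cross-validated classification accuracy
#'
#' Repeated stratified k-fold cross-validation of the shrinkage LDA
#' classifier: each repeat partitions the data into `n_folds` folds
#' preserving class proportions, trains on k-1 folds and scores the held-out
#' fold; the reported accuracy is the mean over all held-out evaluations.
#'
#' @param x samples x channels matrix.
#' @param y class labels.
#' @param n_folds number of folds (default 20). If the rarest class has
#'   fewer samples than `n_folds`, the fold count is reduced to that size
#'   with a warning.
#' @param n_repeats number of independent fold draws (default 1).
#' @param stratified preserve class proportions across folds (default TRUE).
#' @param shrinkage passed to [fit_lda()].
#' @param seed optional integer; set for reproducible fold draws.
#' @return list with `mean_accuracy`, `fold_accuracy` (vector of
#'   `n_folds * n_repeats`), and `n_folds` actually used.
#' @export
crossval_accuracy <- function(x, y, n_folds = 20L, n_repeats = 1L,
                              stratified = TRUE, shrinkage = 0.1,
                              seed = NULL) {
  x <- as.matrix(x)
  y <- factor(y)
  if (!is.null(seed)) set.seed(seed)
  min_class <- min(table(y))
  if (min_class < 2L) stopf("every class needs >= 2 samples for cross-validation")
  if (min_class < n_folds) {
    warnf("rarest class has %d samples; reducing folds from %d to %d",
          min_class, n_folds, min_class)
    n_folds <- min_class
  }
  accs <- numeric(0)
  for (r in seq_len(n_repeats)) {
    fold <- if (stratified) stratified_folds(y, n_folds)
            else sample(rep_len(seq_len(n_folds), length(y)))
    for (f in seq_len(n_folds)) {
      tr <- fold != f
      if (nlevels(droplevels(y[tr])) < nlevels(y))
        stopf("a class is absent from a training split; use stratified folds")
      model <- fit_lda(x[tr, , drop = FALSE], y[tr], shrinkage = shrinkage)
      pred <- predict_lda(model, x[!tr, , drop = FALSE])
      accs <- c(accs, mean(pred == y[!tr]))
    }
  }
  list(mean_accuracy = mean(accs), fold_accuracy = accs, n_folds = n_folds)
}

#' Time-resolved decoding curve for one session
#'
#' Trains an independent cross-validated classifier at every time bin of a
#' rate tensor and collects the accuracies into a decoding curve. Bins are
#' decoded independently; no information is shared across time.
#'
#' @param tensor a `rate_tensor` from [bin_firing_rates()].
#' @param labels one label per trial of the tensor.
#' @param n_folds,n_repeats,shrinkage,seed passed to [crossval_accuracy()]
#'   (the seed is set once, so fold draws differ across bins but the whole
#'   curve is reproducible).
#' @return a `decoding_curve` with one session row; combine sessions with
#'   [combine_curves()].
#' @export
time_resolved_decode <- function(tensor, labels, n_folds = 20L, n_repeats = 1L,
                                 shrinkage = 0.1, seed = NULL) {
  stopifnot(inherits(tensor, "rate_tensor"))
  labels <- factor(labels)
  if (length(labels) != dim(tensor$values)[1L])
    stopf("need one label per trial (%d labels, %d trials)",
          length(labels), dim(tensor$values)[1L])
  if (!is.null(seed)) set.seed(seed)
  n_bins <- length(tensor$bin_times_ms)
  acc <- numeric(n_bins)
  for (b in seq_len(n_bins)) {
    cv <- tryCatch(
      crossval_accuracy(tensor$values[, , b, drop = TRUE], labels,
                        n_folds = n_folds, n_repeats = n_repeats,
                        stratified = TRUE, shrinkage = shrinkage, seed = NULL),
      error = function(e)
        stopf("decoding failed at bin t = %g ms: %s",
              tensor$bin_times_ms[b], conditionMessage(e)))
    acc[b] <- cv$mean_accuracy
  }
  decoding_curve(tensor$bin_times_ms, matrix(acc, nrow = 1L),
                 chance_level = 1 / nlevels(labels),
                 window_ms = tensor$window_ms, step_ms = tensor$step_ms)
}

#' Construct a decoding curve
#'
#' @param times_ms bin label times.
#' @param per_session_accuracy sessions x times matrix of accuracies.
#' @param chance_level accuracy of an uninformed classifier (1 / classes).
#' @param window_ms,step_ms binning parameters carried for bookkeeping.
#' @param interpolated whether the grid is a spline-interpolated refinement.
#' @return a `decoding_curve` with the session mean and, for >= 2 sessions,
#'   the 95% confidence half-width at each time.
#' @export
decoding_curve <- function(times_ms, per_session_accuracy, chance_level,
                           window_ms = NA, step_ms = NA, interpolated = FALSE) {
  acc <- as.matrix(per_session_accuracy)
  if (ncol(acc) != length(times_ms)) stopf("accuracy columns must match times")
  if (any(acc < -1e-9 | acc > 1 + 1e-9)) stopf("accuracies must lie in [0, 1]")
  if (chance_level <= 0 || chance_level >= 1) stopf("chance_level must be in (0, 1)")
  if (is.unsorted(times_ms, strictly = TRUE)) stopf("times must be strictly increasing")
  n_ses <- nrow(acc)
  disp <- if (n_ses >= 2L) {
    se <- apply(acc, 2L, stats::sd) / sqrt(n_ses)
    stats::qt(0.975, df = n_ses - 1L) * se
  } else rep(NA_real_, length(times_ms))
  structure(list(times_ms = as.numeric(times_ms), per_session_accuracy = acc,
                 mean_accuracy = colMeans(acc), dispersion = disp,
                 chance_level = chance_level, window_ms = window_ms,
                 step_ms = step_ms, interpolated = interpolated),
            class = "decoding_curve")
}

#' Stack per-session decoding curves onto a shared time grid
#'
#' @param curves list of `decoding_curve` objects with identical time grids
#'   and chance levels.
#' @return a single `decoding_curve` whose rows are sessions.
#' @export
combine_curves <- function(curves) {
  stopifnot(length(curves) >= 1L, all(vapply(curves, inherits, TRUE, "decoding_curve")))
  t0 <- curves[[1L]]$times_ms
  for (cv in curves[-1L])
    if (!isTRUE(all.equal(cv$times_ms, t0)) ||
        cv$chance_level != curves[[1L]]$chance_level)
      stopf("curves must share time grid and chance level")
  decoding_curve(t0, do.call(rbind, lapply(curves, `[[`, "per_session_accuracy")),
                 chance_level = curves[[1L]]$chance_level,
                 window_ms = curves[[1L]]$window_ms,
                 step_ms = curves[[1L]]$step_ms,
                 interpolated = curves[[1L]]$interpolated)
}

#' Refine a decoding curve with natural cubic splines
#'
#' Each session's accuracy trace is interpolated with a natural cubic spline
#' onto a grid of `target_resolution_ms` (default 2 ms, i.e. finer than
#' 5 ms); original knot values are reproduced exactly. Interpolation is
#' applied per session before any averaging, and the session mean is then
#' recomputed on the fine grid.
#'
#' @param curve a `decoding_curve`.
#' @param target_resolution_ms spacing of the refined grid (< 5 ms).
#' @return an interpolated `decoding_curve`.
#' @export
interpolate_curve <- function(curve, target_resolution_ms = 2) {
  stopifnot(inherits(curve, "decoding_curve"))
  if (length(curve$times_ms) < 4L)
    stopf("need at least 4 time points for cubic-spline interpolation")
  if (target_resolution_ms >= 5)
    warnf("target resolution %g ms is not finer than 5 ms", target_resolution_ms)
  grid <- sort(unique(c(seq(min(curve$times_ms), max(curve$times_ms),
                            by = target_resolution_ms), curve$times_ms)))
  fine <- t(apply(curve$per_session_accuracy, 1L, function(row)
    stats::spline(curve$times_ms, row, xout = grid, method = "natural")$y))
  fine <- pmin(pmax(fine, 0), 1)  # splines can overshoot the [0, 1] range
  decoding_curve(grid, fine, chance_level = curve$chance_level,
                 window_ms = curve$window_ms, step_ms = curve$step_ms,
                 interpolated = TRUE)
}

#' One-sample t-test of decoding accuracy against chance
#'
#' Tests the per-session accuracies at one time point against the chance
#' level with a two-sided one-sample t-test.
#'
#' @param curve a multi-session `decoding_curve`.
#' @param t_ms time at which to test; the nearest grid point is used (and
#'   reported) if `t_ms` is off-grid.
#' @return list with `t`, `p`, `n_sessions`, `mean_accuracy`, `t_used_ms`.
#' @export
curve_vs_chance_test <- function(curve, t_ms) {
  stopifnot(inherits(curve, "decoding_curve"))
  n_ses <- nrow(curve$per_session_accuracy)
  if (n_ses < 2L) stopf("need >= 2 sessions for a one-sample t-test")
  i <- which.min(abs(curve$times_ms - t_ms))
  if (abs(curve$times_ms[i] - t_ms) > 1e-9)
    warnf("t = %g ms is off the grid; testing at nearest point %g ms",
          t_ms, curve$times_ms[i])
  vals <- curve$per_session_accuracy[, i]
  if (stats::sd(vals) == 0) {
    # degenerate: identical sessions; t is 0/0 at chance, +/-Inf otherwise
    delta <- vals[1L] - curve$chance_level
    tt <- list(statistic = c(t = ifelse(delta == 0, 0, sign(delta) * Inf)),
               p.value = ifelse(delta == 0, 1, 0))
  } else {
    tt <- stats::t.test(vals, mu = curve$chance_level)
  }
  list(t = unname(tt$statistic), p = tt$p.value, n_sessions = n_ses,
       mean_accuracy = mean(vals), t_used_ms = curve$times_ms[i])
}

#' First persistent chance crossing after test onset
#'
#' Scans the session-mean accuracy for the first time after `test_onset_ms`
#' at which it exceeds chance and stays above chance for at least
#' `persistence_ms`. The persistence requirement suppresses spurious
#' crossings of a noisy interpolated curve. The returned latency is relative
#' to test onset; `NA` means no crossing was detected.
#'
#' @param curve a `decoding_curve` (typically interpolated, covering the
#'   test epoch).
#' @param test_onset_ms test onset on the curve's clock (default 2500).
#' @param persistence_ms minimum time the curve must remain above chance.
#' @return latency in ms after test onset, or `NA_real_` if not detected.
#' @export
latency_of_chance_crossing <- function(curve, test_onset_ms = 2500,
                                       persistence_ms = 50) {
  stopifnot(inherits(curve, "decoding_curve"))
  sel <- curve$times_ms >= test_onset_ms
  if (!any(sel)) stopf("curve does not cover times after test onset")
  tt <- curve$times_ms[sel]
  above <- curve$mean_accuracy[sel] > curve$chance_level
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  for (j in seq_along(r$values)) {
    if (!r$values[j]) next
    dur <- tt[ends[j]] - tt[starts[j]]
    if (dur >= persistence_ms) return(tt[starts[j]] - test_onset_ms)
  }
  NA_real_
}

#' Correct-to-error cross-condition generalization of a choice decoder
#'
#' Trains match/nonmatch decoders on correct trials at one time point
#' (cross-validated) and, within every cross-validation step, applies the
#' same decoder to all error trials. If the decoded signal tracks the
#' animal's choice — which is inverted relative to trial type on error
#' trials — the transfer accuracy falls below chance (0.5), mirroring the
#' held-out correct-trial accuracy about 0.5. If instead the signal reflects
#' the physical match/nonmatch stimulus relation, the decoder generalizes
#' and the transfer accuracy stays above chance.
#'
#' Trials with reaction times shorter than `rt_exclude_ms` are excluded so
#' that the response has not yet occurred at the decoded time point.
#'
#' @param tensor a `rate_tensor` on the stimulus-aligned session clock.
#' @param trials trial table (needs `trial_type`, `correct`, `rt_ms`).
#' @param t_ms time of the decoded rate vector (default 2900 ms, i.e. 400 ms
#'   after test onset).
#' @param rt_exclude_ms drop trials with `rt_ms` below this (default 400 ms,
#'   responses occurring before `t_ms` for the standard epochs).
#' @param n_folds,shrinkage,seed cross-validation settings.
#' @return list with `accuracy_correct` (held-out CV accuracy on correct
#'   trials), `accuracy_error` (mean transfer accuracy on error trials),
#'   per-fold vectors, and counts of trials used.
#' @export
cross_condition_test <- function(tensor, trials, t_ms = 2900,
                                 rt_exclude_ms = 400, n_folds = 20L,
                                 shrinkage = 0.1, seed = NULL) {
  stopifnot(inherits(tensor, "rate_tensor"))
  at <- rates_at(tensor, t_ms)
  keep <- trials$rt_ms >= rt_exclude_ms
  x <- at$x[keep, , drop = FALSE]
  tr <- trials[keep, , drop = FALSE]
  y <- factor(tr$trial_type, levels = c("match", "nonmatch"))
  is_corr <- tr$correct
  if (sum(!is_corr) == 0L)
    stopf("no error trials remain after excluding rt < %g ms", rt_exclude_ms)
  xc <- x[is_corr, , drop = FALSE]; yc <- droplevels(y[is_corr])
  xe <- x[!is_corr, , drop = FALSE]; ye <- y[!is_corr]
  if (nlevels(yc) < 2L) stopf("correct trials must contain both trial types")
  if (!is.null(seed)) set.seed(seed)
  min_class <- min(table(yc))
  if (min_class < n_folds) {
    warnf("rarest class has %d correct trials; reducing folds from %d to %d",
          min_class, n_folds, min_class)
    n_folds <- min_class
  }
  imb <- max(table(yc)) / min_class
  if (imb > 3) warnf("match/nonmatch imbalance %.1f:1 among correct trials", imb)
  fold <- stratified_folds(yc, n_folds)
  acc_c <- acc_e <- numeric(n_folds)
  for (f in seq_len(n_folds)) {
    trn <- fold != f
    model <- fit_lda(xc[trn, , drop = FALSE], yc[trn], shrinkage = shrinkage)
    acc_c[f] <- mean(predict_lda(model, xc[!trn, , drop = FALSE]) == yc[!trn])
    acc_e[f] <- mean(predict_lda(model, xe) == ye)
  }
  list(accuracy_correct = mean(acc_c), accuracy_error = mean(acc_e),
       fold_accuracy_correct = acc_c, fold_accuracy_error = acc_e,
       n_correct = sum(is_corr), n_error = sum(!is_corr),
       t_used_ms = at$t_ms, n_folds = n_folds)
}

#' @export
print.decoding_curve <- function(x, ...) {
  cat(sprintf("decoding_curve: %d session(s), %d time points in [%g, %g] ms%s\n",
              nrow(x$per_session_accuracy), length(x$times_ms),
              min(x$times_ms), max(x$times_ms),
              if (x$interpolated) " (interpolated)" else ""))
  cat(sprintf("  chance %.3f, peak mean accuracy %.3f at %g ms\n",
              x$chance_level, max(x$mean_accuracy),
              x$times_ms[which.max(x$mean_accuracy)]))
  invisible(x)
}

#' Plot a decoding curve
#'
#' Session mean with 95% confidence band (when several sessions are present)
#' and the chance level as a dotted line.
#'
#' @param x a `decoding_curve`.
#' @param ... passed to [graphics::plot()].
#' @export
plot.decoding_curve <- function(x, ...) {
  graphics::plot(x$times_ms, x$mean_accuracy, type = "l", lwd = 2,
                 xlab = "time (ms)", ylab = "decoding accuracy",
                 ylim = c(0, 1), ...)
  if (!anyNA(x$dispersion))
    graphics::polygon(c(x$times_ms, rev(x$times_ms)),
                      c(x$mean_accuracy + x$dispersion,
                        rev(x$mean_accuracy - x$dispersion)),
                      border = NA, col = grDevices::adjustcolor("steelblue", 0.3))
  graphics::abline(h = x$chance_level, lty = 3)
  invisible(x)
}
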