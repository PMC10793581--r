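#' Supervised discriminant subspace of a labeled point cloud
#'
#' Finds the (classes - 1)-dimensional linear projection that maximizes
#' separation between classes relative to dispersion within classes: the
#' columns are the leading generalized eigenvectors of the between-class
#' scatter against the (shrinkage-regularized) within-class scatter, ordered
#' by eigenvalue. Columns are unit-norm and sign-fixed so that the
#' largest-magnitude entry of each column is positive, making fitted axes
#' reproducible.
#'
#' When another task variable drives large rate variance (for example,
#' stimulus identity varying within the match and nonmatch classes), that
#' variance enters the within-class scatter and rotates the discriminant
#' axis away from the true coding direction. Passing the nuisance variable
#' as `within` computes the within-scatter inside `y x within` cells, so
#' only genuine trial-to-trial noise is whitened; class means (and hence the
#' between-class scatter) are unchanged.
#'
#' @param x samples x channels matrix.
#' @param y class labels.
#' @param shrinkage within-scatter shrinkage toward its diagonal (default
#'   0.1, shared with the decoding module).
#' @param within optional factor of a nuisance variable; the within-class
#'   scatter is pooled over `y x within` cells.
#' @return channels x (classes - 1) projection matrix with attribute
#'   `eigenvalues` (between/within separation along each axis).
#' @export
fit_discriminant_subspace <- function(x, y, shrinkage = 0.1, within = NULL) {
  x <- as.matrix(x)
  y <- factor(y)
  k <- nlevels(y)
  if (k < 2L) stopf("need at least 2 classes")
  p <- ncol(x)
  mu <- colMeans(x)
  sb <- matrix(0, p, p)
  for (lev in levels(y)) {
    xi <- x[y == lev, , drop = FALSE]
    mk <- colMeans(xi)
    sb <- sb + nrow(xi) * tcrossprod(mk - mu)
  }
  cells <- if (is.null(within)) y else interaction(y, factor(within), drop = TRUE)
  if (any(table(cells) < 2L))
    stopf("every %s cell needs >= 2 samples for the within-class scatter",
          if (is.null(within)) "class" else "class x nuisance")
  sw <- matrix(0, p, p)
  for (lev in levels(cells)) {
    xi <- x[cells == lev, , drop = FALSE]
    xc <- sweep(xi, 2L, colMeans(xi))
    sw <- sw + crossprod(xc)
  }
  sw <- sw / (nrow(x) - nlevels(cells))
  sb <- sb / (nrow(x) - 1L)
  sw <- (1 - shrinkage) * sw + shrinkage * diag(diag(sw), p)
  r <- tryCatch(chol(sw), error = function(e) NULL)
  if (is.null(r))
    stopf("within-class scatter is degenerate; increase shrinkage (got %g)",
          shrinkage)
  ri <- backsolve(r, diag(p))
  sym <- crossprod(ri, sb %*% ri)
  eig <- eigen((sym + t(sym)) / 2, symmetric = TRUE)
  proj <- ri %*% eig$vectors[, seq_len(k - 1L), drop = FALSE]
  proj <- apply(proj, 2L, function(v) {
    v <- v / sqrt(sum(v^2))
    if (v[which.max(abs(v))] < 0) -v else v
  })
  proj <- matrix(proj, nrow = p)
  rownames(proj) <- colnames(x)
  attr(proj, "eigenvalues") <- eig$values[seq_len(k - 1L)]
  proj
}

#' Fit stimulus and decision subspaces at a reference time
#'
#' At a single reference bin (default 2700 ms, i.e. 200 ms after test onset,
#' when both stimulus identity and the upcoming choice are decodable), fits
#' a 2-D stimulus subspace from test-stimulus identity labels and a 1-D
#' decision axis from match/nonmatch labels, both on the same correct-trial
#' rate vectors.
#'
#' @param tensor a `rate_tensor` on the stimulus-aligned clock.
#' @param trials trial table aligned with the tensor.
#' @param t_ref_ms reference time; the nearest bin is used with a warning if
#'   off-grid.
#' @param shrinkage scatter regularization (default 0.1).
#' @param correct_only restrict the fit to correct trials (default TRUE).
#' @param condition_decision_on_stimulus compute the decision fit's
#'   within-scatter inside stimulus x decision cells (default TRUE), so the
#'   stimulus-driven rate variance — which lies in the stimulus span and
#'   would otherwise push the whitened decision axis away from it — is not
#'   treated as noise. Set FALSE for the plain single-factor fit.
#' @return a `subspace_model`: `stim_projection` (channels x
#'   `n_stimuli - 1`), `decision_projection` (channels x 1), `t_ref_ms`
#'   (the bin actually used), `fit_labels`, `shrinkage`.
#' @export
build_subspace_model <- function(tensor, trials, t_ref_ms = 2700,
                                 shrinkage = 0.1, correct_only = TRUE,
                                 condition_decision_on_stimulus = TRUE) {
  stopifnot(inherits(tensor, "rate_tensor"))
  at <- rates_at(tensor, t_ref_ms)
  keep <- if (correct_only) trials$correct else rep(TRUE, nrow(trials))
  x <- at$x[keep, , drop = FALSE]
  tr <- trials[keep, , drop = FALSE]
  stim_y <- factor(tr$test_stim)
  dec_y <- factor(tr$trial_type, levels = c("match", "nonmatch"))
  stim_proj <- fit_discriminant_subspace(x, stim_y, shrinkage = shrinkage)
  dec_proj <- fit_discriminant_subspace(
    x, dec_y, shrinkage = shrinkage,
    within = if (condition_decision_on_stimulus) stim_y else NULL)
  # guard against fitting a "decision axis" to pure noise
  cv <- crossval_accuracy(x, dec_y, n_folds = min(10L, min(table(dec_y))),
                          shrinkage = shrinkage, seed = 0L)
  if (cv$mean_accuracy < 0.55)
    warnf(paste0("match/nonmatch separability at t_ref is near chance ",
                 "(CV accuracy %.2f); the decision axis may be noise"),
          cv$mean_accuracy)
  structure(list(stim_projection = stim_proj, decision_projection = dec_proj,
                 t_ref_ms = at$t_ms,
                 fit_labels = list(stimulus = levels(stim_y),
                                   decision = levels(dec_y)),
                 shrinkage = shrinkage, correct_only = correct_only,
                 decision_separability = cv$mean_accuracy),
            class = "subspace_model")
}

#' Project rate trajectories into the joint stimulus-decision space
#'
#' Projects every trial's rate vector at every bin onto the axes
#' `[stimulus 1, stimulus 2, ..., decision]` of a fitted subspace model,
#' giving low-dimensional population trajectories whose separation along the
#' stimulus axes and deflection along the decision axis can be read out over
#' time.
#'
#' @param tensor a `rate_tensor` with the same channels as the model.
#' @param model a `subspace_model`.
#' @return trials x bins x axes numeric array; axis dimnames are
#'   `stim1, stim2, ..., decision`.
#' @seealso [average_trajectories()] for condition means.
#' @export
project_trajectories <- function(tensor, model) {
  stopifnot(inherits(tensor, "rate_tensor"), inherits(model, "subspace_model"))
  pmat <- cbind(model$stim_projection, model$decision_projection)
  if (dim(tensor$values)[2L] != nrow(pmat))
    stopf("tensor has %d channels but the model expects %d",
          dim(tensor$values)[2L], nrow(pmat))
  d <- dim(tensor$values)
  flat <- matrix(aperm(tensor$values, c(1L, 3L, 2L)), ncol = d[2L])
  proj <- flat %*% pmat
  out <- array(proj, dim = c(d[1L], d[3L], ncol(pmat)))
  dimnames(out) <- list(dimnames(tensor$values)[[1L]],
                        as.character(tensor$bin_times_ms),
                        c(paste0("stim", seq_len(ncol(model$stim_projection))),
                          "decision"))
  out
}

#' Condition-averaged trajectories
#'
#' Averages projected trajectories over trials within each combination of
#' the grouping columns (typically test stimulus x choice, giving the six
#' traces of a 3-stimulus session).
#'
#' @param traj trials x bins x axes array from [project_trajectories()].
#' @param trials trial table aligned with the first dimension.
#' @param by character vector of grouping columns (default
#'   `c("test_stim", "choice")`).
#' @return conditions x bins x axes array; condition dimnames are the
#'   joined group labels.
#' @export
average_trajectories <- function(traj, trials, by = c("test_stim", "choice")) {
  g <- interaction(trials[by], drop = TRUE, sep = "/")
  out <- array(NA_real_, dim = c(nlevels(g), dim(traj)[2L], dim(traj)[3L]),
               dimnames = c(list(levels(g)), dimnames(traj)[2:3]))
  for (lev in levels(g)) {
    sel <- g == lev
    out[lev, , ] <- apply(traj[sel, , , drop = FALSE], c(2L, 3L), mean)
  }
  out
}

#' Principal angles between two subspaces
#'
#' Canonical angles between the column spans of `a` and `b`, computed from
#' the singular values of the product of their orthonormal bases. Angles are
#' returned in degrees, ascending; `min(angles) = 0` means the spans share a
#' direction and all angles at 90 means the subspaces are orthogonal.
#'
#' @param a,b channels x p and channels x q matrices of full column rank.
#' @return numeric vector of `min(p, q)` angles in `[0, 90]` degrees.
#' @export
subspace_principal_angles <- function(a, b) {
  a <- as.matrix(a); b <- as.matrix(b)
  if (nrow(a) != nrow(b)) stopf("subspaces must live in the same channel space")
  qa <- orth_basis(a); qb <- orth_basis(b)
  if (ncol(qa) < ncol(a) || ncol(qb) < ncol(b))
    stopf("rank-deficient input: columns do not span the stated dimension")
  d <- svd(crossprod(qa, qb))$d
  sort(acos(pmin(1, pmax(-1, d))) * 180 / pi)
}

#' Split-half debiased angle between a coding axis and a coding subspace
#'
#' Estimates the principal angle between the population direction of a
#' binary contrast (e.g. the choice signal) and the subspace spanned by the
#' class-mean contrasts of a second variable (e.g. stimulus identity),
#' correcting two noise artifacts that bias the naive fitted angle:
#'
#' * trial-to-trial noise in the estimated axis inflates small angles
#'   toward 90 degrees (in high dimensions, noise is mostly orthogonal to
#'   any low-dimensional span). The squared in-span and total components of
#'   the contrast are therefore estimated from cross-products of two
#'   independent trial halves, whose noises have zero expected product;
#' * variance driven by the span variable itself (stimulus-evoked rate
#'   differences) projects coherently onto the span, so the axis contrast
#'   is computed within each level of `span_labels` and then averaged.
#'
#' The returned value is `acos(sqrt(in_span / total))` in degrees, averaged
#' over `n_splits` random stratified half-splits; estimates are clamped to
#' `[0, 90]`.
#'
#' @param x samples x channels rate matrix (raw rate space; the angle is a
#'   statement about rate-space geometry, so no whitening is applied).
#' @param axis_labels two-level factor defining the coding axis contrast.
#' @param span_labels factor (>= 2 levels) defining the subspace.
#' @param n_splits number of random half-splits to average (default 20).
#' @param seed optional seed for the splits.
#' @return angle in degrees.
#' @export
debiased_axis_angle <- function(x, axis_labels, span_labels, n_splits = 20L,
                                seed = NULL) {
  x <- as.matrix(x)
  axis_labels <- factor(axis_labels)
  span_labels <- factor(span_labels)
  if (nlevels(axis_labels) != 2L) stopf("axis_labels must have exactly 2 levels")
  if (nlevels(span_labels) < 2L) stopf("span_labels must have >= 2 levels")
  if (!is.null(seed)) set.seed(seed)
  cells <- interaction(axis_labels, span_labels, drop = TRUE)
  if (any(table(cells) < 2L))
    stopf("every axis x span cell needs >= 2 samples")
  mu <- vapply(levels(span_labels),
               function(s) colMeans(x[span_labels == s, , drop = FALSE]),
               numeric(ncol(x)))
  span_basis <- orth_basis(mu - rowMeans(mu))
  contrast <- function(idx) {
    cs <- vapply(levels(span_labels), function(s) {
      i <- idx[span_labels[idx] == s]
      colMeans(x[i[axis_labels[i] == levels(axis_labels)[1L]], , drop = FALSE]) -
        colMeans(x[i[axis_labels[i] == levels(axis_labels)[2L]], , drop = FALSE])
    }, numeric(ncol(x)))
    rowMeans(cs)
  }
  num <- den <- 0
  for (k in seq_len(n_splits)) {
    h <- unlist(lapply(split(seq_len(nrow(x)), cells),
                       function(i) sample(i, length(i) %/% 2L)),
                use.names = FALSE)
    o <- setdiff(seq_len(nrow(x)), h)
    d1 <- contrast(h)
    d2 <- contrast(o)
    num <- num + sum(crossprod(span_basis, d1) * crossprod(span_basis, d2))
    den <- den + sum(d1 * d2)
  }
  if (den <= 0) return(90)  # contrast indistinguishable from noise
  acos(sqrt(min(1, max(0, num / den)))) * 180 / pi
}

#' Silhouette-based class-separation score
#'
#' Mean silhouette width of the labeled points in a projected space
#' (Euclidean distance): near 1 for tight, well-separated classes, near 0
#' for overlapping classes. Points in singleton classes are scored 0 with a
#' warning.
#'
#' @param x points x dims matrix of projected coordinates.
#' @param labels class labels (>= 2 classes).
#' @return mean silhouette width in `[-1, 1]`.
#' @export
class_separation_score <- function(x, labels) {
  x <- as.matrix(x)
  labels <- factor(labels)
  if (nlevels(labels) < 2L) stopf("need at least 2 classes")
  if (any(table(labels) == 1L))
    warnf("singleton class(es) present; their points are scored 0")
  sil <- cluster::silhouette(as.integer(labels), stats::dist(x))
  mean(sil[, "sil_width"])
}

#' @export
print.subspace_model <- function(x, ...) {
  cat(sprintf("subspace_model fit at t = %g ms: stimulus %dD + decision 1D\n",
              x$t_ref_ms, ncol(x$stim_projection)))
  ang <- subspace_principal_angles(x$decision_projection, x$stim_projection)
  cat(sprintf("  decision axis vs stimulus span: smallest principal angle %.1f deg\n",
              min(ang)))
  cat(sprintf("  match/nonmatch CV separability at t_ref: %.3f\n",
              x$decision_separability))
  invisible(x)
}
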