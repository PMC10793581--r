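# brute-force silhouette, straight from the definition
naive_silhouette <- function(x, labels) {
  d <- as.matrix(dist(x))
  mean(vapply(seq_len(nrow(x)), function(i) {
    own <- labels == labels[i]
    if (sum(own) == 1L) return(0)
    a <- mean(d[i, own & seq_len(nrow(x)) != i])
    b <- min(vapply(unique(labels[!own]),
                    function(l) mean(d[i, labels == l]), 0))
    (b - a) / max(a, b)
  }, 0))
}

test_that("two classes with isotropic scatter give the mean-difference axis", {
  # symmetric point sets make the pooled within-class scatter proportional
  # to the identity, so the discriminant axis is the mean difference
  spread <- rbind(diag(3), -diag(3))
  x <- rbind(sweep(spread, 2, c(0, 0, 0), `+`),
             sweep(spread, 2, c(2, 1, 0), `+`))
  y <- rep(c("a", "b"), each = 6)
  w <- fit_discriminant_subspace(x, y, shrinkage = 0)
  target <- c(2, 1, 0) / sqrt(5)
  expect_equal(abs(sum(w * target)), 1, tolerance = 1e-8)
})

test_that("the projection has exactly classes-minus-one columns", {
  set.seed(4)
  for (k in 2:4) {
    x <- matrix(rnorm(40 * k * 5), 40 * k, 5)
    y <- rep(seq_len(k), each = 40)
    x[, 1] <- x[, 1] + y
    w <- fit_discriminant_subspace(x, y)
    expect_equal(dim(w), c(5L, k - 1L))
    expect_equal(colSums(w^2), rep(1, k - 1L), tolerance = 1e-12)
    # sign convention: largest-magnitude entry positive
    expect_true(all(apply(w, 2, function(v) v[which.max(abs(v))] > 0)))
  }
})

test_that("no random direction beats the leading discriminant axis", {
  set.seed(9)
  x <- matrix(rnorm(90 * 4), 90, 4)
  y <- rep(c("a", "b", "c"), each = 30)
  x[y == "b", 1] <- x[y == "b", 1] + 2
  x[y == "c", 2] <- x[y == "c", 2] + 2
  ratio <- function(v) {
    mu <- colMeans(x)
    sb <- sw <- 0
    for (l in unique(y)) {
      xi <- x[y == l, , drop = FALSE]
      sb <- sb + nrow(xi) * sum((colMeans(xi) - mu) * v)^2
      sw <- sw + sum((sweep(xi, 2, colMeans(xi)) %*% v)^2)
    }
    sb / sw
  }
  w <- fit_discriminant_subspace(x, y, shrinkage = 0)
  best <- ratio(w[, 1])
  rand <- matrix(rnorm(4 * 10000), 10000, 4)
  rand <- rand / sqrt(rowSums(rand^2))
  expect_true(all(apply(rand, 1, ratio) <= best + 1e-9))
})

test_that("principal angles reproduce closed-form cases", {
  e <- diag(3)
  expect_equal(subspace_principal_angles(e[, 1], e[, 1]), 0)
  expect_equal(subspace_principal_angles(e[, 1], e[, 2]), 90)
  v45 <- c(1, 1, 0) / sqrt(2)
  expect_equal(subspace_principal_angles(e[, 1], v45), 45, tolerance = 1e-9)
  expect_equal(subspace_principal_angles(e[, 1:2], e[, 2:3]), c(0, 90),
               tolerance = 1e-9)
  expect_error(subspace_principal_angles(cbind(e[, 1], e[, 1]), e[, 2]),
               "rank")
})

test_that("angles and silhouettes are invariant under channel-space rotation", {
  set.seed(12)
  n <- 240
  x <- matrix(rnorm(n * 6), n, 6)
  stim <- rep(0:2, each = n / 3)
  dec <- rep(c("m", "n"), n / 2)
  x[, 1] <- x[, 1] + 2 * (stim == 1)
  x[, 2] <- x[, 2] + 2 * (stim == 2)
  x[, 3] <- x[, 3] + (dec == "m")
  q <- qr.Q(qr(matrix(rnorm(36), 6)))
  fit <- function(xx) {
    s <- fit_discriminant_subspace(xx, stim, shrinkage = 0)
    d <- fit_discriminant_subspace(xx, dec, shrinkage = 0)
    list(angle = min(subspace_principal_angles(d, s)),
         sil = class_separation_score(xx %*% s, stim))
  }
  f1 <- fit(x)
  f2 <- fit(x %*% q)
  expect_equal(f1$angle, f2$angle, tolerance = 1e-6)
  expect_equal(f1$sil, f2$sil, tolerance = 1e-6)
})

test_that("silhouette scoring matches the definition and edge cases", {
  set.seed(6)
  x20 <- matrix(rnorm(40), 20, 2)
  lab <- rep(c("a", "b"), 10)
  expect_equal(class_separation_score(x20, lab), naive_silhouette(x20, lab),
               tolerance = 1e-12)
  far <- rbind(matrix(rnorm(30, sd = 0.05), 15, 2),
               matrix(rnorm(30, 50, sd = 0.05), 15, 2))
  expect_gt(class_separation_score(far, rep(c("a", "b"), each = 15)), 0.95)
  blob <- matrix(rnorm(60), 30, 2)
  expect_lt(abs(class_separation_score(blob, rep(c("a", "b"), 15))), 0.15)
  expect_warning(class_separation_score(blob, c("z", rep(c("a", "b"), len = 29))),
                 "singleton")
})

test_that("trajectory projection is linear, consistent and zero-preserving", {
  ses <- default_session()
  tens <- bin_firing_rates(ses$events, ses$trials, t_range_ms = c(0, 3000),
                           n_channels = 32)
  model <- suppressWarnings(build_subspace_model(tens, ses$trials,
                                                 t_ref_ms = 2900))
  traj <- project_trajectories(tens, model)
  expect_equal(dim(traj), c(300, length(tens$bin_times_ms), 3))
  # projecting the t_ref vectors reproduces the fitted-point coordinates
  b <- which(tens$bin_times_ms == model$t_ref_ms)
  pts <- tens$values[, , b] %*% cbind(model$stim_projection,
                                      model$decision_projection)
  expect_equal(traj[, b, ], pts, ignore_attr = TRUE)
  # zero rates project to the origin
  z <- tens
  z$values[] <- 0
  expect_true(all(project_trajectories(z, model) == 0))
  # condition averages have one row per stimulus x choice combination
  avg <- average_trajectories(traj, ses$trials)
  expect_equal(dim(avg)[1], length(unique(interaction(ses$trials$test_stim,
                                                      ses$trials$choice))))
})

test_that("a zero-gain decision axis is flagged as chance-level", {
  ses <- cached_session("nodec", n_trials = 240, decision_gain = 0, seed = 17)
  tens <- bin_firing_rates(ses$events, ses$trials, t_range_ms = c(0, 3000),
                           n_channels = 32)
  expect_warning(build_subspace_model(tens, ses$trials, t_ref_ms = 2900),
                 "near chance")
})

test_that("stimulus conditioning keeps the decision axis near the true direction", {
  ses <- cached_session("angle60", n_trials = 400, decision_angle_deg = 60,
                        seed = 23)
  tens <- bin_firing_rates(ses$events, ses$trials, t_range_ms = c(0, 3000),
                           n_channels = 32)
  m <- suppressWarnings(build_subspace_model(tens, ses$trials, t_ref_ms = 2900))
  d_true <- matrix(ses$config$decision_direction)
  ang_cond <- min(subspace_principal_angles(m$decision_projection, d_true))
  m0 <- suppressWarnings(build_subspace_model(tens, ses$trials, t_ref_ms = 2900,
                                              condition_decision_on_stimulus = FALSE))
  ang_plain <- min(subspace_principal_angles(m0$decision_projection, d_true))
  expect_lt(ang_cond, ang_plain + 1e-9)
  expect_lt(ang_cond, 45)
})

test_that("debiased axis-angle recovery is monotone in the injected angle", {
  est <- vapply(c(30, 60, 90), function(a) {
    ses <- cached_session(paste0("mono", a), n_trials = 400,
                          decision_angle_deg = a, seed = 700 + a)
    se <- signal_epoch_rates(ses)
    debiased_axis_angle(se$x, se$trials$choice, se$trials$test_stim, seed = 1)
  }, 0)
  expect_true(all(diff(est) > 0))
})
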