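# direct Gaussian shared-covariance posterior, written independently of the
# package's discriminant-score implementation
direct_posterior_predict <- function(means, sigma, priors, x) {
  dens <- apply(x, 1, function(v)
    vapply(seq_len(nrow(means)), function(k) {
      d <- v - means[k, ]
      priors[k] * exp(-0.5 * drop(t(d) %*% solve(sigma, d)))
    }, 0))
  rownames(means)[apply(dens, 2, which.max)]
}

test_that("two symmetric 1-D classes put the decision boundary midway", {
  x <- matrix(c(-1, 1, 9, 11), ncol = 1)
  y <- c("a", "a", "b", "b")
  m <- fit_lda(x, y, shrinkage = 0)
  expect_equal(as.character(predict_lda(m, matrix(4.999))), "a")
  expect_equal(as.character(predict_lda(m, matrix(5.001))), "b")
  # exact tie resolved toward the lowest class label
  expect_equal(as.character(predict_lda(m, matrix(5))), "a")
})

test_that("LDA predictions match a direct Gaussian-posterior computation", {
  set.seed(7)
  x <- rbind(matrix(rnorm(40, 0), 20), matrix(rnorm(40, 1.2), 20),
             matrix(rnorm(40, c(0, 3)), 20, byrow = TRUE))
  y <- rep(c("a", "b", "c"), each = 20)
  m <- fit_lda(x, y, shrinkage = 0)
  grid <- as.matrix(expand.grid(seq(-2, 4, 0.5), seq(-2, 4, 0.5)))
  expect_equal(as.character(predict_lda(m, grid)),
               direct_posterior_predict(m$class_means, m$covariance,
                                        m$priors, grid))
  # and the posterior probabilities agree with the closed-form densities
  post <- predict_lda(m, grid, type = "posterior")
  expect_equal(rowSums(post), rep(1, nrow(grid)))
})

test_that("LDA agrees with an independent reference implementation", {
  skip_if_not_installed("MASS")
  set.seed(21)
  x <- matrix(rnorm(300), 100, 3)
  y <- rep(c("a", "b"), 50)
  x[y == "b", ] <- x[y == "b", ] + 0.8
  m <- fit_lda(x, y, shrinkage = 0)
  ref <- MASS::lda(x, grouping = y)
  expect_equal(as.character(predict_lda(m, x)),
               as.character(predict(ref, x)$class))
})

test_that("full shrinkage reduces to the diagonal-whitened nearest-mean rule", {
  set.seed(3)
  x <- matrix(rnorm(80, sd = rep(c(1, 4), each = 40)), 40, 2)
  y <- rep(c("a", "b"), 20)
  x[y == "b", ] <- x[y == "b", ] + 3
  m <- fit_lda(x, y, shrinkage = 1)
  v <- diag(m$covariance)
  nearest <- apply(x, 1, function(p) {
    d <- apply(m$class_means, 1, function(mu) sum((p - mu)^2 / v))
    names(which.min(d))
  })
  expect_equal(as.character(predict_lda(m, x)), unname(nearest))
})

test_that("degenerate fits fail with actionable errors", {
  x <- cbind(1:8, 1:8)  # perfectly collinear channels
  y <- rep(c("a", "b"), 4)
  expect_error(fit_lda(x, y, shrinkage = 0), "shrinkage")
  expect_error(fit_lda(matrix(1:4, ncol = 1), c("a", "a", "a", "b")), "2 samples")
  m <- fit_lda(matrix(rnorm(20), 10, 2), rep(c("a", "b"), 5))
  expect_error(predict_lda(m, matrix(1, 1, 3)), "channels")
})

test_that("cross-validation is exact on separable and uninformative data", {
  set.seed(5)
  x <- matrix(rnorm(60), 60, 1)
  x[31:60, ] <- x[31:60, ] + 40  # 20 SDs apart: always separable
  y <- rep(c("a", "b"), each = 30)
  cv <- crossval_accuracy(x, y, n_folds = 10, seed = 1)
  expect_equal(cv$fold_accuracy, rep(1, 10))
  # identical features: prediction falls back to the training majority class
  x0 <- matrix(1, 50, 2)
  y0 <- rep(c("a", "b"), c(30, 20))
  cv0 <- suppressWarnings(crossval_accuracy(x0, y0, n_folds = 10, seed = 1))
  expect_equal(cv0$mean_accuracy, 0.6, tolerance = 1e-12)
})

test_that("fold reduction warns and reproducibility holds under a seed", {
  set.seed(2)
  x <- matrix(rnorm(24), 12, 2)
  y <- rep(c("a", "b"), 6)
  expect_warning(cv <- crossval_accuracy(x, y, n_folds = 20, seed = 4),
                 "reducing folds")
  expect_equal(cv$n_folds, 6)
  cv2 <- suppressWarnings(crossval_accuracy(x, y, n_folds = 20, seed = 4))
  expect_identical(cv$fold_accuracy, cv2$fold_accuracy)
})

test_that("10- and 20-fold accuracies agree on a well-powered session", {
  set.seed(8)
  n <- 600
  x <- matrix(rnorm(n * 8), n, 8)
  y <- rep(c("a", "b", "c"), each = n / 3)
  x[y == "b", 1] <- x[y == "b", 1] + 1.2
  x[y == "c", 2] <- x[y == "c", 2] + 1.2
  a10 <- crossval_accuracy(x, y, n_folds = 10, seed = 1)$mean_accuracy
  a20 <- crossval_accuracy(x, y, n_folds = 20, seed = 1)$mean_accuracy
  expect_lt(abs(a10 - a20), 0.03)
})

test_that("time-resolved decoding tracks the epochs carrying stimulus signal", {
  ses <- default_session()
  corr <- ses$trials$correct
  tens <- bin_firing_rates(ses$events, ses$trials, t_range_ms = c(0, 3000),
                           n_channels = 32)
  tens <- dmsdecode:::subset_tensor(tens, corr)
  curve <- time_resolved_decode(tens, ses$trials$test_stim[corr],
                                n_folds = 10, seed = 2)
  expect_s3_class(curve, "decoding_curve")
  expect_equal(curve$chance_level, 1 / 3)
  # fixation epoch: no stimulus on screen, accuracy at chance
  fix <- curve$times_ms <= 500
  expect_lt(abs(mean(curve$mean_accuracy[fix]) - 1 / 3), 0.06)
  # test epoch (after visual latency): strongly decodable
  test_bins <- curve$times_ms >= 2700 & curve$times_ms <= 3000
  expect_gt(mean(curve$mean_accuracy[test_bins]), 0.8)
})

test_that("spline refinement preserves knots and linearity", {
  times <- seq(2500, 2950, by = 50)
  acc <- matrix(seq(0.3, 0.75, length.out = 10), 1)
  curve <- decoding_curve(times, acc, chance_level = 0.5)
  fine <- interpolate_curve(curve, 2)
  # knots exact
  expect_equal(fine$per_session_accuracy[1, match(times, fine$times_ms)],
               acc[1, ], tolerance = 1e-12)
  # natural spline of collinear points is linear everywhere
  lin <- approx(times, acc[1, ], xout = fine$times_ms)$y
  expect_equal(fine$per_session_accuracy[1, ], lin, tolerance = 1e-9)
  # constant curve stays constant
  cc <- decoding_curve(times, matrix(0.5, 1, 10), 1 / 3)
  expect_true(all(interpolate_curve(cc, 2)$per_session_accuracy == 0.5))
  expect_error(interpolate_curve(decoding_curve(1:3, matrix(0.4, 1, 3), 0.5), 2),
               "4 time points")
})

test_that("the t-test against chance matches a hand computation", {
  accs <- c(0.9, 0.92, 0.94, 0.93, 0.95, 0.91)
  curve <- decoding_curve(c(2700, 2750, 2800, 2850),
                          matrix(rep(accs, 4), 6, 4), chance_level = 1 / 3)
  res <- curve_vs_chance_test(curve, 2700)
  t_hand <- (mean(accs) - 1 / 3) / (sd(accs) / sqrt(6))
  expect_equal(res$t, t_hand, tolerance = 1e-12)
  expect_equal(res$p, 2 * pt(-abs(t_hand), 5), tolerance = 1e-12)
  expect_equal(res$n_sessions, 6)
  # all sessions exactly at chance
  c0 <- decoding_curve(c(1, 2, 3), matrix(1 / 3, 4, 3), 1 / 3)
  r0 <- curve_vs_chance_test(c0, 2)
  expect_equal(r0$t, 0)
  expect_equal(r0$p, 1)
  c1 <- decoding_curve(c(1, 2), matrix(0.5, 1, 2), 1 / 3)
  expect_error(curve_vs_chance_test(c1, 1), "2 sessions")
})

test_that("chance-crossing latency follows its definition", {
  times <- seq(2500, 3000, by = 10)
  # flat at chance: never detected
  flat <- decoding_curve(times, matrix(0.5, 1, length(times)), 0.5)
  expect_true(is.na(latency_of_chance_crossing(flat)))
  # single permanent crossing at 2650 -> latency 150
  acc <- ifelse(times >= 2650, 0.8, 0.5)
  up <- decoding_curve(times, matrix(acc, 1), 0.5)
  expect_equal(latency_of_chance_crossing(up), 150)
  # a 30 ms blip does not satisfy a 50 ms persistence requirement
  blip <- rep(0.5, length(times))
  blip[times >= 2600 & times <= 2630] <- 0.7
  bc <- decoding_curve(times, matrix(blip, 1), 0.5)
  expect_true(is.na(latency_of_chance_crossing(bc, persistence_ms = 50)))
})

test_that("permuted labels drive the curve to chance", {
  set.seed(31)
  x <- matrix(rnorm(90 * 6), 90, 6)
  y <- rep(0:2, each = 30)
  accs <- replicate(30, {
    crossval_accuracy(x, sample(y), n_folds = 10)$mean_accuracy
  })
  se <- sd(accs) / sqrt(length(accs))
  expect_lt(abs(mean(accs) - 1 / 3), 3 * se + 0.01)
})
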