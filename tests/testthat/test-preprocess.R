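test_that("linear smoothing preserves constants, linear trends and length", {
  expect_equal(smooth_linear(rep(5, 8), 7L), rep(5, 8))
  expect_equal(smooth_linear(0:9, 3L)[5L], 4)  # interior of a linear series
  set.seed(1)
  v <- stats::rnorm(100)
  for (k in c(3L, 7L, 11L)) {
    sm <- smooth_linear(v, k)
    expect_length(sm, 100L)
    # brute-force shrunken-window oracle
    h <- (k - 1L) %/% 2L
    oracle <- vapply(seq_along(v), function(i) {
      hi <- min(h, i - 1L, length(v) - i)
      mean(v[(i - hi):(i + hi)])
    }, numeric(1L))
    expect_equal(sm, oracle, tolerance = 1e-10)
    expect_true(all(sm >= min(v) & sm <= max(v)))
  }
})

test_that("smoothing rejects invalid window sizes", {
  expect_error(smooth_linear(1:20, 4L), "odd")
  expect_error(smooth_linear(1:20, 13L), "odd window size")
  expect_error(smooth_linear(1:3, 5L), ">= k")
})

test_that("pair-consistency rule uses a strict threshold over the window", {
  cfg <- tiny_config()
  rec <- generate_record("fresh", "s1", generator_config(
    n_per_class = 1L, noise_sd = 0, outlier_fraction = 0))
  rule <- pair_anomaly_rule()
  expect_false(flag_pair_anomaly(rec, rule))  # identical channels
  shifted <- rec
  shifted$curves[[5L]]$values <- rec$curves[[1L]]$values + 1.5
  expect_true(flag_pair_anomaly(shifted, rule))
  # exact boundary: "greater than" is strict (integer-valued curves keep the
  # difference exactly at the threshold)
  times <- seq(0, 350)
  flat <- function(level, ch) response_curve(ch, times, rep(level, 351))
  boundary <- sample_record("b1", "fresh", list(
    flat(2, 1L), flat(0, 2L), flat(0, 3L), flat(1, 4L),
    flat(3.25, 5L), flat(0, 6L), flat(0, 7L), flat(1, 8L)))
  expect_false(flag_pair_anomaly(boundary, pair_anomaly_rule(threshold = 1.25)))
  expect_true(flag_pair_anomaly(boundary, pair_anomaly_rule(threshold = 1.2)))
  # monotone in the threshold: raising it can only turn true into false
  relaxed <- pair_anomaly_rule(threshold = 2)
  expect_false(flag_pair_anomaly(shifted, relaxed))
  expect_error(flag_pair_anomaly(rec, pair_anomaly_rule(channel_b = 12L)),
               "channel 12")
})

test_that("dead-channel exclusion drops exactly the silent sensors", {
  ds <- generate_dataset(tiny_config())
  dd <- drop_dead_channels(ds)
  expect_identical(dd$dropped, c(3L, 7L))
  expect_length(dd$dataset[[1L]]$curves, 6L)
  # strict epsilon rule: a single tiny value keeps the channel
  ds2 <- dd$dataset
  ds2[[1L]]$curves[[2L]]$values <- rep(0, 311)
  ds2[[1L]]$curves[[2L]]$values[5L] <- 1e-9
  dd2 <- drop_dead_channels(ds2, epsilon = 0)
  expect_false(2L %in% dd2$dropped)
  # no dead channels: nothing dropped, dataset unchanged
  dd3 <- drop_dead_channels(dd$dataset)
  expect_identical(dd3$dropped, integer())
  expect_identical(dd3$dataset, dd$dataset)
  # all channels dead
  zero_ds <- lapply(ds[1:2], function(r) {
    r$curves <- lapply(r$curves, function(cu) {
      cu$values[] <- 0; cu
    })
    r
  })
  expect_error(drop_dead_channels(structure(zero_ds, class = "enose_dataset")),
               "all channels")
})

test_that("Mahalanobis distances match hand-computed and brute-force values", {
  # identity covariance by construction: distance of (3,4) from origin is 5
  base <- rbind(c(1, 0), c(-1, 0), c(0, 1), c(0, -1)) * sqrt(3 / 2)
  X <- rbind(base, c(3, 4), -c(3, 4))  # symmetric pair keeps mean at 0
  S <- stats::cov(X)
  # whiten so the sample covariance is the identity, then check (3,4)
  W <- solve(chol(S))
  Xw <- X %*% W
  dw <- mahalanobis_distances(Xw)
  expect_equal(dw, sqrt(rowSums(sweep(Xw, 2, colMeans(Xw))^2)),
               tolerance = 1e-10)
  # hand-computed 2x2 case: data {(1,0),(-1,0),(0,2),(0,-2)}
  Xh <- rbind(c(1, 0), c(-1, 0), c(0, 2), c(0, -2))
  dh <- mahalanobis_distances(Xh)
  expect_equal(dh[1L], sqrt(3 / 2), tolerance = 1e-12)
  # brute-force oracle with explicit matrix algebra
  mu <- colMeans(Xh); Sinv <- solve(stats::cov(Xh))
  oracle <- apply(Xh, 1L, function(x) sqrt((x - mu) %*% Sinv %*% (x - mu)))
  expect_equal(dh, oracle, tolerance = 1e-12)
})

test_that("Mahalanobis distances are affine-invariant and satisfy the sum identity", {
  set.seed(4)
  X <- matrix(stats::rnorm(200), 40L, 5L)
  d0 <- mahalanobis_distances(X)
  A <- matrix(stats::rnorm(25), 5L, 5L) + diag(5) * 2
  b <- stats::rnorm(5)
  d1 <- mahalanobis_distances(sweep(X %*% A, 2L, b, "+"))
  expect_equal(d0, d1, tolerance = 1e-8)
  # with unbiased S, squared distances sum to d(n-1)
  expect_equal(sum(d0^2), 5 * (40 - 1), tolerance = 1e-8)
})

test_that("singular covariance errors without regularization", {
  X <- cbind(1:10, (1:10) * 2)  # rank 1
  expect_error(mahalanobis_distances(X, regularize = FALSE), "regulariz")
  expect_silent(mahalanobis_distances(X))
})

test_that("outlier removal respects alpha limits and is deterministic", {
  set.seed(9)
  X <- matrix(stats::rnorm(200), 50L, 4L)
  labels <- rep(c("a", "b"), each = 25L)
  # alpha -> 0: cutoff so large nothing is removed
  res <- remove_outliers(X, labels, alpha = 1e-12)
  expect_length(res$report$removed_indices, 0L)
  res1 <- remove_outliers(X, labels, alpha = 0.025)
  res2 <- remove_outliers(X, labels, alpha = 0.025)
  expect_identical(res1$report$removed_indices, res2$report$removed_indices)
  expect_true(all(res1$report$distances >= 0))
  # removed set is exactly the beyond-cutoff set
  expect_identical(res1$report$removed_indices,
                   which(res1$report$distances > res1$report$cutoff))
})

test_that("repeated outlier removal removes no more points the second time", {
  set.seed(10)
  X <- rbind(matrix(stats::rnorm(120), 30L, 4L),
             matrix(stats::rnorm(40, mean = 8), 10L, 4L))
  labels <- rep("a", 40L)
  r1 <- remove_outliers(X, labels, alpha = 0.025)
  r2 <- remove_outliers(r1$X, r1$labels, alpha = 0.025)
  expect_lte(length(r2$report$removed_indices),
             length(r1$report$removed_indices))
})

test_that("classical (unshrunk) removal requires enough samples per class", {
  set.seed(11)
  X <- matrix(stats::rnorm(9 * 8), 9L, 8L)
  expect_error(remove_outliers(X, rep("a", 9L), shrinkage = 0), "pooled")
})

test_that("injected whole-record outliers are recovered from the feature space", {
  cfg <- generator_config(seed = 3L, outlier_fraction = 0.1, outlier_scale = 5)
  ds <- generate_dataset(cfg)
  ft <- extract_features(drop_dead_channels(ds)$dataset)
  truth <- dataset_outlier_flags(ds)
  res <- remove_outliers(ft$X, ft$labels, alpha = 0.025)
  removed <- seq_len(nrow(ft$X)) %in% res$report$removed_indices
  expect_gte(mean(removed[truth]), 0.8)
  expect_lte(mean(removed[!truth]), 0.1)
})
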