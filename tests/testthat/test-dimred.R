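test_that("PCA captures collinear data with one component", {
  set.seed(31)
  t <- stats::rnorm(50)
  X <- cbind(t, 2 * t)
  m <- fit_pca(X, k = 1L)
  expect_equal(m$explained[1L], 1, tolerance = 1e-12)
  expect_equal(abs(sum(m$components[, 1L] * c(1, 2) / sqrt(5))), 1,
               tolerance = 1e-8)
})

test_that("PCA satisfies the discarded-eigenvalue reconstruction identity", {
  set.seed(32)
  X <- matrix(stats::rnorm(300), 50L, 6L) %*% diag(c(3, 2, 1.5, 1, 0.5, 0.2))
  for (k in c(2L, 4L)) {
    m <- fit_pca(X, k)
    Z <- predict(m, X)
    R <- pca_reconstruct(m, Z)
    mse <- sum((X - R)^2) / (nrow(X) - 1L)
    expect_equal(mse, sum(m$all_eigenvalues[-seq_len(k)]), tolerance = 1e-8)
  }
  m <- fit_pca(X)
  expect_true(all(diff(m$explained) <= 1e-12))
  expect_lte(sum(m$explained), 1 + 1e-12)
  expect_gte(sum(m$explained), 0.95)  # default k targets 95% variance
  # deterministic sign convention
  expect_identical(fit_pca(X, 3L)$components, fit_pca(X, 3L)$components)
  expect_true(all(apply(m$components, 2L, function(v) v[which.max(abs(v))]) > 0))
  # unit-norm columns
  expect_equal(colSums(m$components^2), rep(1, m$k), tolerance = 1e-12)
})

test_that("PCA agrees with a reference implementation", {
  set.seed(33)
  X <- matrix(stats::rnorm(200), 40L, 5L)
  m <- fit_pca(X, 3L)
  ref <- stats::prcomp(X, center = TRUE, scale. = FALSE)
  for (j in 1:3) {
    expect_equal(abs(sum(m$components[, j] * ref$rotation[, j])), 1,
                 tolerance = 1e-8)
  }
  expect_equal(m$explained, (ref$sdev^2 / sum(ref$sdev^2))[1:3],
               tolerance = 1e-10)
})

test_that("LDA respects the class-count bound and finds the separating axis", {
  set.seed(34)
  X4 <- matrix(stats::rnorm(160), 40L, 4L)
  y4 <- rep(letters[1:4], each = 10L)
  expect_error(fit_lda(X4, y4, k = 4L), "n_classes - 1")
  expect_identical(fit_lda(X4, y4)$k, 3L)
  # two clouds separated along axis 1
  X <- rbind(cbind(stats::rnorm(30, 0, 0.3), stats::rnorm(30)),
             cbind(stats::rnorm(30, 10, 0.3), stats::rnorm(30)))
  y <- rep(c("a", "b"), each = 30L)
  m <- fit_lda(X, y, 1L)
  expect_gt(abs(m$components[1L, 1L]), 0.99)
})

test_that("LDA matches a brute-force Fisher-ratio search in 2-D", {
  set.seed(35)
  X <- rbind(matrix(stats::rnorm(60, 0, 1), ncol = 2L),
             sweep(matrix(stats::rnorm(60, 0, 1), ncol = 2L), 2L, c(4, 2), "+"),
             sweep(matrix(stats::rnorm(60, 0, 1), ncol = 2L), 2L, c(-1, 5), "+"))
  y <- rep(c("a", "b", "c"), each = 30L)
  fisher <- function(w) {
    w <- w / sqrt(sum(w^2))
    z <- X %*% w
    mu <- mean(z)
    sb <- 0; sw <- 0
    for (cls in unique(y)) {
      zc <- z[y == cls]
      sb <- sb + length(zc) * (mean(zc) - mu)^2
      sw <- sw + sum((zc - mean(zc))^2)
    }
    sb / sw
  }
  theta <- seq(0, pi, length.out = 20001L)
  best <- max(vapply(theta, function(a) fisher(c(cos(a), sin(a))), numeric(1L)))
  m <- fit_lda(X, y, 1L)
  expect_equal(fisher(m$components[, 1L]), best, tolerance = 1e-3)
})

test_that("LDA projections are invariant under class relabeling (up to sign)", {
  set.seed(36)
  X <- matrix(stats::rnorm(200), 50L, 4L)
  y <- rep(letters[1:5], each = 10L)
  relabel <- c(a = "v", b = "w", c = "x", d = "y", e = "z")
  m1 <- fit_lda(X, y, 2L)
  m2 <- fit_lda(X, unname(relabel[y]), 2L)
  for (j in 1:2) {
    expect_equal(abs(sum(m1$components[, j] * m2$components[, j])), 1,
                 tolerance = 1e-6)
  }
})

test_that("factor analysis recovers a planted one-factor structure", {
  set.seed(37)
  n <- 500L
  f <- stats::rnorm(n)
  lam <- c(0.9, 0.4, 0.7, 0.3, 0.85, 0.55)
  sigma <- 0.1
  X <- outer(f, lam) + matrix(stats::rnorm(n * 6L, 0, sigma), n, 6L)
  m <- fit_fa(X, k = 1L)
  # the model is fit on the correlation matrix, so compare against the
  # generating loadings on the standardised scale
  lam_std <- lam / sqrt(lam^2 + sigma^2)
  expect_gt(abs(stats::cor(m$loadings[, 1L], lam_std)), 0.95)
  expect_true(all(m$communalities <= 1))
  # deterministic: same input, same output
  expect_identical(fit_fa(X, 1L)$loadings, fit_fa(X, 1L)$loadings)
  # k = d keeps communalities bounded
  mfull <- fit_fa(X, k = 6L)
  expect_true(all(mfull$communalities <= 1))
  expect_error(fit_fa(X, k = 1L, max_iter = 1L), "converge")
})

test_that("projection contract: centring, dimensions, round trip", {
  set.seed(38)
  X <- matrix(stats::rnorm(120), 30L, 4L)
  m <- fit_pca(X, 2L)
  expect_equal(as.numeric(predict(m, matrix(m$mean, 1L))), c(0, 0),
               tolerance = 1e-12)
  expect_error(predict(m, X[, 1:3]), "columns")
  expect_identical(dim(predict(m, X)), c(30L, 2L))
  expect_identical(project_features(m, X), predict(m, X))
  # serialization round trip
  prefix <- tempfile()
  save_projection(m, prefix)
  m2 <- load_projection(prefix)
  expect_equal(predict(m2, X), predict(m, X), tolerance = 1e-12)
})
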