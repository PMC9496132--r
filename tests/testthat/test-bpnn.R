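test_that("initialisation is deterministic with chained layer shapes", {
  cfg <- bpnn_config(input_dim = 3L, hidden_sizes = c(10L, 8L), n_classes = 4L,
                     seed = 5L)
  m1 <- init_bpnn(cfg); m2 <- init_bpnn(cfg)
  expect_identical(m1$weights, m2$weights)
  expect_identical(vapply(m1$weights, dim, integer(2L)),
                   matrix(c(3L, 10L, 10L, 8L, 8L, 4L), 2L))
  expect_true(all(vapply(m1$biases, function(b) all(b == 0), logical(1L))))
  expect_error(bpnn_config(input_dim = 3L, hidden_sizes = integer()),
               "hidden layer")
  expect_error(bpnn_config(input_dim = 3L, hidden_sizes = 0L), "node")
})

test_that("forward pass produces calibrated softmax probabilities", {
  cfg <- bpnn_config(input_dim = 2L, hidden_sizes = 3L, n_classes = 4L,
                     standardize = FALSE)
  m <- init_bpnn(cfg)
  # all-zero weights: perfectly uniform output
  m$weights <- lapply(m$weights, function(w) w * 0)
  P <- bpnn_forward(m, c(0.3, -0.2))
  expect_equal(as.numeric(P), rep(0.25, 4L), tolerance = 1e-12)
  set.seed(6)
  m2 <- init_bpnn(cfg)
  X <- matrix(stats::rnorm(20), 10L, 2L)
  P2 <- bpnn_forward(m2, X)
  expect_equal(rowSums(P2), rep(1, 10L), tolerance = 1e-12)
  expect_true(all(P2 >= 0))
  # softmax shift invariance: adding a constant to output biases changes nothing
  m3 <- m2
  m3$biases[[2L]] <- m3$biases[[2L]] + 7
  expect_equal(bpnn_forward(m3, X), P2, tolerance = 1e-12)
  expect_error(bpnn_forward(m2, matrix(0, 2L, 3L)), "expects")
})

test_that("analytic gradients match central finite differences", {
  cfg <- bpnn_config(input_dim = 3L, hidden_sizes = c(4L, 3L), n_classes = 3L,
                     seed = 2L, standardize = FALSE)
  m <- init_bpnn(cfg)
  set.seed(3)
  X <- matrix(stats::rnorm(15), 5L, 3L)
  Y <- diag(3)[sample.int(3L, 5L, replace = TRUE), ]
  g <- enose:::bpnn_loss_grad(m, X, Y)
  eps <- 1e-6
  worst <- 0
  for (l in seq_along(m$weights)) {
    for (i in seq_along(m$weights[[l]])) {
      mp <- m; mp$weights[[l]][i] <- mp$weights[[l]][i] + eps
      mm <- m; mm$weights[[l]][i] <- mm$weights[[l]][i] - eps
      num <- (enose:::bpnn_loss_grad(mp, X, Y)$loss -
              enose:::bpnn_loss_grad(mm, X, Y)$loss) / (2 * eps)
      ana <- g$gW[[l]][i]
      worst <- max(worst, abs(num - ana) / max(abs(num) + abs(ana), 1e-8))
    }
    for (i in seq_along(m$biases[[l]])) {
      mp <- m; mp$biases[[l]][i] <- mp$biases[[l]][i] + eps
      mm <- m; mm$biases[[l]][i] <- mm$biases[[l]][i] - eps
      num <- (enose:::bpnn_loss_grad(mp, X, Y)$loss -
              enose:::bpnn_loss_grad(mm, X, Y)$loss) / (2 * eps)
      worst <- max(worst, abs(num - g$gb[[l]][i]) /
                            max(abs(num) + abs(g$gb[[l]][i]), 1e-8))
    }
  }
  expect_lt(worst, 1e-5)
})

test_that("training separates Gaussian blobs and learns XOR", {
  blobs <- make_blobs()
  cfg <- bpnn_config(input_dim = 2L, hidden_sizes = c(8L, 8L), n_classes = 2L,
                     epochs = 500L, seed = 1L)
  m <- train_bpnn(cfg, blobs$X, blobs$y)
  expect_equal(bpnn_accuracy(m, blobs$X, blobs$y), 1.0)
  expect_length(m$loss_history, 500L)
  expect_true(all(is.finite(m$loss_history)))
  # median loss decreases over successive 50-epoch spans
  spans <- split(m$loss_history, rep(1:10, each = 50L))
  meds <- vapply(spans, stats::median, numeric(1L))
  expect_true(all(diff(meds) < 0))
  # XOR with a single 4-node hidden layer (median over 5 seeds)
  xor_acc <- vapply(1:5, function(s) {
    set.seed(100 + s)
    base <- rbind(c(0, 0), c(0, 1), c(1, 0), c(1, 1))
    X <- base[rep(1:4, each = 10L), ] + matrix(stats::rnorm(80, 0, 0.05), 40L, 2L)
    y <- rep(c("p", "q", "q", "p"), each = 10L)
    cfg <- bpnn_config(input_dim = 2L, hidden_sizes = 4L, n_classes = 2L,
                       learning_rate = 0.5, epochs = 2000L, seed = s)
    bpnn_accuracy(train_bpnn(cfg, X, y), X, y)
  }, numeric(1L))
  expect_equal(stats::median(xor_acc), 1.0)
})

test_that("degenerate training settings behave as specified", {
  blobs <- make_blobs(n_per = 10L)
  cfg <- bpnn_config(input_dim = 2L, hidden_sizes = 4L, n_classes = 2L,
                     learning_rate = 1e-12, epochs = 5L, seed = 3L)
  m0 <- init_bpnn(cfg)
  m <- train_bpnn(cfg, blobs$X, blobs$y)
  # a vanishing learning rate leaves the weights essentially unchanged
  expect_equal(m$weights, m0$weights, tolerance = 1e-9)
  expect_lt(max(abs(diff(m$loss_history))), 1e-9)
  # non-finite loss raises an actionable error
  cfg_relu <- bpnn_config(input_dim = 2L, hidden_sizes = 4L, n_classes = 2L,
                          activation = "relu", learning_rate = 1e4,
                          epochs = 50L, seed = 1L, standardize = FALSE)
  expect_error(train_bpnn(cfg_relu, blobs$X * 1e150, blobs$y),
               "learning rate")
})

test_that("prediction and accuracy follow the classification contract", {
  blobs <- make_blobs(n_per = 15L)
  cfg <- bpnn_config(input_dim = 2L, hidden_sizes = 4L, n_classes = 2L,
                     epochs = 300L, seed = 2L)
  m <- train_bpnn(cfg, blobs$X, blobs$y)
  expect_identical(predict(m, blobs$X[1L, , drop = FALSE]), blobs$y[1L])
  expect_equal(bpnn_accuracy(m, blobs$X, blobs$y), 1.0)
  # constant predictor on balanced 4-class data scores 0.25
  conf <- matrix(0L, 4L, 4L, dimnames = list(letters[1:4], letters[1:4]))
  conf[, 1L] <- 10L
  expect_equal(macro_tpr(conf), 0.25)
  # labels outside the class set are rejected
  expect_error(train_bpnn(m, matrix(0, 1L, 2L), "zebra"), "zebra")
})

test_that("model serialization round-trips predictions", {
  blobs <- make_blobs(n_per = 12L, seed = 5L)
  cfg <- bpnn_config(input_dim = 2L, hidden_sizes = c(5L, 3L), n_classes = 2L,
                     epochs = 200L, seed = 4L)
  m <- train_bpnn(cfg, blobs$X, blobs$y)
  path <- tempfile(fileext = ".txt")
  save_bpnn(m, path)
  m2 <- load_bpnn(path)
  expect_equal(bpnn_forward(m2, blobs$X), bpnn_forward(m, blobs$X),
               tolerance = 1e-12)
  expect_identical(predict(m2, blobs$X), predict(m, blobs$X))
})
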