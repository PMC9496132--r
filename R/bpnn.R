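#' Configuration of a back-propagation neural network classifier
#'
#' A feedforward multilayer perceptron with sigmoid (or ReLU) hidden layers
#' and a softmax output head, trained by full-batch gradient descent on the
#' mean cross-entropy. Inputs are standardised with training-set mean and
#' standard deviation; the statistics are stored in the model and reused at
#' prediction time.
#'
#' @param input_dim number of input features.
#' @param hidden_sizes nodes per hidden layer (default \code{c(8, 8)}: two
#'   hidden layers, the quantity the swarm optimizers search over).
#' @param n_classes number of output classes (default 4).
#' @param activation hidden activation, "sigmoid" (default) or "relu".
#' @param learning_rate gradient-descent step size (default 0.3; full-batch
#'   descent on standardised inputs needs a much larger step than stochastic
#'   variants).
#' @param epochs number of full-batch passes (default 500).
#' @param batch_size rows per update; NULL (default) means full batch.
#' @param standardize standardise inputs with training statistics (default TRUE).
#' @param seed integer seed for weight initialisation and batch shuffling.
#' @return object of class \code{bpnn_config}.
#' @export
bpnn_config <- function(input_dim, hidden_sizes = c(8L, 8L), n_classes = 4L,
                        activation = c("sigmoid", "relu"),
                        learning_rate = 0.3, epochs = 500L,
                        batch_size = NULL, standardize = TRUE, seed = 1L) {
  activation <- match.arg(activation)
  hidden_sizes <- as.integer(hidden_sizes)
  if (length(hidden_sizes) < 1L) stop("at least one hidden layer is required")
  if (any(hidden_sizes < 1L)) stop("every hidden layer needs >= 1 node")
  if (learning_rate <= 0) stop("learning_rate must be > 0")
  if (input_dim < 1L || n_classes < 2L) stop("invalid input_dim or n_classes")
  structure(list(input_dim = as.integer(input_dim),
                 hidden_sizes = hidden_sizes,
                 n_classes = as.integer(n_classes),
                 activation = activation,
                 learning_rate = learning_rate,
                 epochs = as.integer(epochs),
                 batch_size = if (is.null(batch_size)) NULL else as.integer(batch_size),
                 standardize = isTRUE(standardize),
                 seed = as.integer(seed)),
            class = "bpnn_config")
}

#' Initialise a network from its configuration
#'
#' Weights are drawn uniformly from \eqn{[-1/\sqrt{f}, 1/\sqrt{f}]} with f the
#' layer fan-in (the classical scaling keeping sigmoid pre-activations in
#' their responsive range); biases start at zero. Deterministic given
#' \code{config$seed}.
#'
#' @param config a \code{\link{bpnn_config}}.
#' @return object of class \code{bpnn_model} with untrained weights.
#' @export
init_bpnn <- function(config) {
  stopifnot(inherits(config, "bpnn_config"))
  sizes <- c(config$input_dim, config$hidden_sizes, config$n_classes)
  set.seed(config$seed)
  weights <- vector("list", length(sizes) - 1L)
  biases <- vector("list", length(sizes) - 1L)
  for (l in seq_along(weights)) {
    fan_in <- sizes[l]
    a <- 1 / sqrt(fan_in)
    weights[[l]] <- matrix(stats::runif(fan_in * sizes[l + 1L], -a, a),
                           fan_in, sizes[l + 1L])
    biases[[l]] <- rep(0, sizes[l + 1L])
  }
  structure(list(config = config, weights = weights, biases = biases,
                 loss_history = numeric(), center = NULL, scale = NULL,
                 levels = NULL),
            class = "bpnn_model")
}

act_fun <- function(z, activation) {
  if (activation == "sigmoid") 1 / (1 + exp(-z)) else pmax(z, 0)
}

act_grad <- function(a, z, activation) {
  if (activation == "sigmoid") a * (1 - a) else (z > 0) + 0
}

softmax_rows <- function(Z) {
  Z <- Z - apply(Z, 1L, max)
  E <- exp(Z)
  E / rowSums(E)
}

standardize_rows <- function(model, X) {
  if (is.null(model$center)) return(X)
  sweep(sweep(X, 2L, model$center), 2L, model$scale, "/")
}

# Forward pass over a (pre-standardised) matrix; returns activations per layer.
bpnn_forward_pass <- function(model, X) {
  L <- length(model$weights)
  A <- vector("list", L + 1L)
  Z <- vector("list", L)
  A[[1L]] <- X
  for (l in seq_len(L)) {
    Z[[l]] <- sweep(A[[l]] %*% model$weights[[l]], 2L, model$biases[[l]], "+")
    A[[l + 1L]] <- if (l < L) act_fun(Z[[l]], model$config$activation)
                   else softmax_rows(Z[[l]])
  }
  list(A = A, Z = Z)
}

#' Class probabilities for input rows
#'
#' @param model a \code{bpnn_model}.
#' @param X numeric matrix (or vector for one sample) with
#'   \code{config$input_dim} columns.
#' @return n x n_classes matrix of probabilities; each row is non-negative and
#'   sums to 1.
#' @export
bpnn_forward <- function(model, X) {
  if (is.null(dim(X))) X <- matrix(X, nrow = 1L)
  X <- as.matrix(X)
  if (ncol(X) != model$config$input_dim) {
    stop("input has ", ncol(X), " columns; network expects ",
         model$config$input_dim)
  }
  P <- bpnn_forward_pass(model, standardize_rows(model, X))$A[[length(model$weights) + 1L]]
  if (!is.null(model$levels)) colnames(P) <- model$levels
  P
}

# Mean cross-entropy loss and analytic gradients for (already standardised)
# X and one-hot Y; shared by training and the finite-difference check.
bpnn_loss_grad <- function(model, X, Y) {
  fp <- bpnn_forward_pass(model, X)
  L <- length(model$weights)
  n <- nrow(X)
  P <- fp$A[[L + 1L]]
  loss <- -mean(log(pmax(rowSums(P * Y), 1e-300)))
  gW <- vector("list", L)
  gb <- vector("list", L)
  delta <- (P - Y) / n
  for (l in rev(seq_len(L))) {
    gW[[l]] <- crossprod(fp$A[[l]], delta)
    gb[[l]] <- colSums(delta)
    if (l > 1L) {
      delta <- (delta %*% t(model$weights[[l]])) *
        act_grad(fp$A[[l]], fp$Z[[l - 1L]], model$config$activation)
    }
  }
  list(loss = loss, gW = gW, gb = gb)
}

#' Train a network by back-propagation
#'
#' Gradient descent on the mean cross-entropy, full batch by default.
#' Standardisation statistics, class levels and the per-epoch loss history are
#' stored on the returned model. Deterministic given \code{config$seed}.
#'
#' @param config a \code{\link{bpnn_config}} (or an initialised
#'   \code{bpnn_model} to continue training).
#' @param X numeric training matrix.
#' @param labels per-row class labels; distinct values must number at most
#'   \code{n_classes}.
#' @return a trained \code{bpnn_model}.
#' @export
train_bpnn <- function(config, X, labels) {
  model <- if (inherits(config, "bpnn_model")) config else init_bpnn(config)
  cfg <- model$config
  X <- as.matrix(X)
  labels <- as.character(labels)
  if (nrow(X) != length(labels)) stop("labels must match rows of X")
  lev <- if (!is.null(model$levels)) model$levels else sort(unique(labels))
  if (length(lev) > cfg$n_classes) {
    stop("data has ", length(lev), " classes; network outputs ", cfg$n_classes)
  }
  yi <- match(labels, lev)
  if (anyNA(yi)) stop("labels outside the class set: ",
                      paste(unique(labels[is.na(yi)]), collapse = ", "))
  if (cfg$standardize && is.null(model$center)) {
    model$center <- colMeans(X)
    sc <- apply(X, 2L, stats::sd)
    model$scale <- ifelse(sc > 0, sc, 1)
  }
  Xs <- standardize_rows(model, X)
  Y <- matrix(0, nrow(X), cfg$n_classes)
  Y[cbind(seq_len(nrow(X)), yi)] <- 1
  model$levels <- lev
  bs <- if (is.null(cfg$batch_size)) nrow(X) else min(cfg$batch_size, nrow(X))
  set.seed(cfg$seed + 1L)
  for (ep in seq_len(cfg$epochs)) {
    ord <- if (bs < nrow(X)) sample.int(nrow(X)) else seq_len(nrow(X))
    ep_loss <- 0
    nb <- 0L
    for (start in seq(1L, nrow(X), by = bs)) {
      rows <- ord[start:min(start + bs - 1L, nrow(X))]
      g <- bpnn_loss_grad(model, Xs[rows, , drop = FALSE],
                          Y[rows, , drop = FALSE])
      if (!is.finite(g$loss)) {
        stop("training loss became non-finite at epoch ", ep,
             "; try a smaller learning rate")
      }
      for (l in seq_along(model$weights)) {
        model$weights[[l]] <- model$weights[[l]] - cfg$learning_rate * g$gW[[l]]
        model$biases[[l]] <- model$biases[[l]] - cfg$learning_rate * g$gb[[l]]
      }
      ep_loss <- ep_loss + g$loss * length(rows)
      nb <- nb + length(rows)
    }
    model$loss_history <- c(model$loss_history, ep_loss / nb)
  }
  model
}

#' Predict class labels
#'
#' @param object a trained \code{bpnn_model}.
#' @param newdata numeric matrix.
#' @param ... unused.
#' @return character vector of predicted labels (argmax of the class
#'   probabilities).
#' @export
predict.bpnn_model <- function(object, newdata, ...) {
  P <- bpnn_forward(object, newdata)
  object$levels[max.col(P, ties.method = "first")]
}

#' Classification accuracy of a model on labelled data
#'
#' @param model a trained \code{bpnn_model}.
#' @param X numeric matrix.
#' @param labels true labels.
#' @return proportion of correct predictions in [0, 1].
#' @export
bpnn_accuracy <- function(model, X, labels) {
  mean(predict(model, X) == as.character(labels))
}

#' @export
print.bpnn_model <- function(x, ...) {
  cat("<bpnn_model> ", x$config$input_dim, " -> ",
      paste(x$config$hidden_sizes, collapse = " -> "), " -> ",
      x$config$n_classes, " (", x$config$activation, ")", sep = "")
  if (length(x$loss_history)) {
    cat("; trained ", length(x$loss_history), " epochs, final loss ",
        format(utils::tail(x$loss_history, 1L), digits = 4), sep = "")
  }
  cat("\n")
  invisible(x)
}
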