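#' Shared configuration for the swarm optimizers
#'
#' All three metaheuristics minimise a scalar objective over a box. Search
#' variables flagged as integer are rounded after every position update, which
#' suits discrete spaces such as hidden-layer node counts.
#'
#' @param bounds 2 x d matrix (rows: lower, upper) or a list of
#'   \code{c(low, high)} pairs, one per dimension.
#' @param population swarm size (default 15).
#' @param iterations number of iterations (default 100).
#' @param integer_dims logical vector (length d) or indices of dimensions to
#'   round to integers; default none.
#' @param producer_fraction fraction of the population acting as producers in
#'   the sparrow search (default 0.2).
#' @param forewarner_fraction fraction acting as danger-aware forewarners
#'   (default 0.1).
#' @param safety_threshold alarm threshold ST in [0.5, 1] (default 0.8):
#'   producers forage widely while the alarm value stays below it.
#' @param inertia,cognitive,social PSO coefficients (defaults 0.7, 1.5, 1.5).
#' @param velocity_clamp PSO velocity limit as a fraction of the box span
#'   (default 0.2).
#' @param seed integer seed.
#' @return object of class \code{swarm_config}.
#' @export
swarm_config <- function(bounds, population = 15L, iterations = 100L,
                         integer_dims = NULL, producer_fraction = 0.2,
                         forewarner_fraction = 0.1, safety_threshold = 0.8,
                         inertia = 0.7, cognitive = 1.5, social = 1.5,
                         velocity_clamp = 0.2, seed = 1L) {
  if (is.list(bounds)) bounds <- vapply(bounds, function(b) as.numeric(b[1:2]), numeric(2L))
  bounds <- as.matrix(bounds)
  if (nrow(bounds) != 2L) stop("bounds must be a 2 x d matrix (lower; upper)")
  d <- ncol(bounds)
  if (any(bounds[1L, ] >= bounds[2L, ])) stop("each lower bound must be < upper bound")
  int <- rep(FALSE, d)
  if (!is.null(integer_dims)) {
    if (is.logical(integer_dims)) int <- integer_dims else int[integer_dims] <- TRUE
  }
  if (population < 2L) stop("population must be >= 2")
  if (iterations < 1L) stop("iterations must be >= 1")
  if (producer_fraction <= 0 || producer_fraction >= 1 ||
      forewarner_fraction <= 0 || forewarner_fraction >= 1) {
    stop("producer and forewarner fractions must lie in (0, 1)")
  }
  if (safety_threshold < 0.5 || safety_threshold > 1) {
    stop("safety_threshold must lie in [0.5, 1]")
  }
  structure(list(bounds = bounds, population = as.integer(population),
                 iterations = as.integer(iterations), integer_dims = int,
                 producer_fraction = producer_fraction,
                 forewarner_fraction = forewarner_fraction,
                 safety_threshold = safety_threshold,
                 inertia = inertia, cognitive = cognitive, social = social,
                 velocity_clamp = velocity_clamp, seed = as.integer(seed)),
            class = "swarm_config")
}

clip_round <- function(x, config) {
  x <- pmin(pmax(x, config$bounds[1L, ]), config$bounds[2L, ])
  x[config$integer_dims] <- round(x[config$integer_dims])
  x
}

make_counter_objective <- function(objective) {
  count <- 0L
  f <- function(x) {
    count <<- count + 1L
    val <- objective(x)
    if (length(val) != 1L || is.na(val) || is.nan(val)) {
      stop("objective returned a non-numeric value at position (",
           paste(format(x, digits = 6), collapse = ", "), ")")
    }
    val
  }
  list(f = f, count = function() count)
}

opt_result <- function(best_position, best_fitness, history, evaluations) {
  structure(list(best_position = best_position, best_fitness = best_fitness,
                 history = history, evaluations = evaluations),
            class = "opt_result")
}

#' @export
print.opt_result <- function(x, ...) {
  cat("<opt_result> best fitness ", format(x$best_fitness, digits = 6),
      " after ", length(x$history), " iterations (", x$evaluations,
      " evaluations)\n", sep = "")
  invisible(x)
}

#' Sparrow search algorithm
#'
#' Canonical sparrow search: each iteration the population is ranked by
#' fitness; the best \code{producer_fraction} act as producers, foraging
#' widely (multiplicative \eqn{x\,e^{-i/(\alpha T)}} decay while the alarm
#' value R2 stays below the safety threshold ST, otherwise a unit Gaussian
#' step); the remainder are scroungers following the best producer (the worse
#' half instead jump near the worst position); finally a random
#' \code{forewarner_fraction} relocate relative to the global best and worst.
#' Positions are clipped to the box (integer dimensions rounded) after every
#' update, and the best-so-far position is tracked across iterations.
#'
#' @param objective function of a d-vector returning a scalar to minimise.
#' @param config a \code{\link{swarm_config}}.
#' @return an \code{opt_result}: best position, best fitness, per-iteration
#'   best-so-far history (length \code{iterations}) and evaluation count.
#' @export
ssa_optimize <- function(objective, config) {
  oc <- make_counter_objective(objective)
  d <- ncol(config$bounds)
  n <- config$population
  Tm <- config$iterations
  set.seed(config$seed)
  X <- t(replicate(n, clip_round(stats::runif(d, config$bounds[1L, ],
                                              config$bounds[2L, ]), config)))
  if (d == 1L) X <- matrix(X, ncol = 1L)
  fit <- apply(X, 1L, oc$f)
  best_i <- which.min(fit)
  gbest <- X[best_i, ]; gbest_f <- fit[best_i]
  history <- numeric(Tm)
  nP <- max(1L, round(config$producer_fraction * n))
  nF <- max(1L, round(config$forewarner_fraction * n))
  eps <- 1e-8
  for (t in seq_len(Tm)) {
    ord <- order(fit)
    X <- X[ord, , drop = FALSE]; fit <- fit[ord]
    R2 <- stats::runif(1L)
    # producers
    for (i in seq_len(nP)) {
      if (R2 < config$safety_threshold) {
        alpha <- stats::runif(1L, .Machine$double.eps, 1)
        X[i, ] <- X[i, ] * exp(-i / (alpha * Tm))
      } else {
        X[i, ] <- X[i, ] + stats::rnorm(1L)
      }
      X[i, ] <- clip_round(X[i, ], config)
    }
    xp <- X[1L, ]  # best producer after its update
    xw <- X[n, ]   # worst individual of this iteration
    # scroungers
    for (i in (nP + 1L):n) {
      if (i > n / 2) {
        X[i, ] <- stats::rnorm(1L) * exp((xw - X[i, ]) / i^2)
      } else {
        a <- sample(c(-1, 1), d, replace = TRUE)
        X[i, ] <- xp + sum(abs(X[i, ] - xp) * a) / d
      }
      X[i, ] <- clip_round(X[i, ], config)
    }
    # forewarners relocate using the ranking fitnesses, so each individual is
    # evaluated exactly once per iteration
    fw <- sample.int(n, nF)
    f_best <- fit[1L]; f_worst <- fit[n]
    for (i in fw) {
      if (fit[i] > f_best) {
        X[i, ] <- gbest + stats::rnorm(1L) * abs(X[i, ] - gbest)
      } else {
        K <- stats::runif(1L, -1, 1)
        X[i, ] <- X[i, ] + K * abs(X[i, ] - xw) / (fit[i] - f_worst + eps)
      }
      X[i, ] <- clip_round(X[i, ], config)
    }
    fit <- apply(X, 1L, oc$f)
    it_best <- which.min(fit)
    if (fit[it_best] < gbest_f) {
      gbest_f <- fit[it_best]
      gbest <- X[it_best, ]
    }
    history[t] <- gbest_f
  }
  opt_result(gbest, gbest_f, history, oc$count())
}

#' Particle swarm optimization
#'
#' Standard inertial PSO with cognitive and social pulls toward the personal
#' and global best positions; velocities are clamped to
#' \code{velocity_clamp} of the box span per dimension.
#'
#' @inheritParams ssa_optimize
#' @return an \code{opt_result} (same contract as \code{\link{ssa_optimize}}).
#' @export
pso_optimize <- function(objective, config) {
  oc <- make_counter_objective(objective)
  d <- ncol(config$bounds)
  n <- config$population
  span <- config$bounds[2L, ] - config$bounds[1L, ]
  vmax <- config$velocity_clamp * span
  set.seed(config$seed)
  X <- t(replicate(n, clip_round(stats::runif(d, config$bounds[1L, ],
                                              config$bounds[2L, ]), config)))
  if (d == 1L) X <- matrix(X, ncol = 1L)
  V <- t(replicate(n, stats::runif(d, -vmax, vmax)))
  if (d == 1L) V <- matrix(V, ncol = 1L)
  fit <- apply(X, 1L, oc$f)
  P <- X; pfit <- fit
  g <- which.min(fit)
  gbest <- X[g, ]; gbest_f <- fit[g]
  history <- numeric(config$iterations)
  for (t in seq_len(config$iterations)) {
    for (i in seq_len(n)) {
      r1 <- stats::runif(d); r2 <- stats::runif(d)
      V[i, ] <- config$inertia * V[i, ] +
        config$cognitive * r1 * (P[i, ] - X[i, ]) +
        config$social * r2 * (gbest - X[i, ])
      V[i, ] <- pmin(pmax(V[i, ], -vmax), vmax)
      X[i, ] <- clip_round(X[i, ] + V[i, ], config)
      fit[i] <- oc$f(X[i, ])
      if (fit[i] < pfit[i]) { P[i, ] <- X[i, ]; pfit[i] <- fit[i] }
      if (fit[i] < gbest_f) { gbest <- X[i, ]; gbest_f <- fit[i] }
    }
    history[t] <- gbest_f
  }
  opt_result(gbest, gbest_f, history, oc$count())
}

#' Grey wolf optimizer
#'
#' Canonical GWO: the three best wolves (alpha, beta, delta) guide the pack;
#' each position moves to the mean of three encircling moves around them, with
#' the exploration coefficient decreasing linearly from 2 to 0.
#'
#' @inheritParams ssa_optimize
#' @return an \code{opt_result} (same contract as \code{\link{ssa_optimize}}).
#' @export
gwo_optimize <- function(objective, config) {
  oc <- make_counter_objective(objective)
  d <- ncol(config$bounds)
  n <- config$population
  set.seed(config$seed)
  X <- t(replicate(n, clip_round(stats::runif(d, config$bounds[1L, ],
                                              config$bounds[2L, ]), config)))
  if (d == 1L) X <- matrix(X, ncol = 1L)
  fit <- apply(X, 1L, oc$f)
  history <- numeric(config$iterations)
  leaders <- function() {
    ord <- order(fit)
    list(a = X[ord[1L], ], b = X[ord[min(2L, n)], ],
         c = X[ord[min(3L, n)], ], fa = fit[ord[1L]])
  }
  ld <- leaders()
  gbest <- ld$a; gbest_f <- ld$fa
  for (t in seq_len(config$iterations)) {
    a_coef <- 2 - 2 * (t - 1) / config$iterations
    for (i in seq_len(n)) {
      xs <- vapply(list(ld$a, ld$b, ld$c), function(lead) {
        A <- a_coef * (2 * stats::runif(d) - 1)
        C <- 2 * stats::runif(d)
        lead - A * abs(C * lead - X[i, ])
      }, numeric(d))
      X[i, ] <- clip_round(rowMeans(matrix(xs, nrow = d)), config)
      fit[i] <- oc$f(X[i, ])
    }
    ld <- leaders()
    if (ld$fa < gbest_f) { gbest_f <- ld$fa; gbest <- ld$a }
    history[t] <- gbest_f
  }
  opt_result(gbest, gbest_f, history, oc$count())
}

#' Run a swarm optimizer by name
#'
#' @param algorithm "ssa", "pso" or "gwo".
#' @param objective scalar objective to minimise.
#' @param config a \code{\link{swarm_config}}.
#' @return an \code{opt_result}.
#' @export
swarm_optimize <- function(algorithm, objective, config) {
  switch(match.arg(algorithm, c("ssa", "pso", "gwo")),
         ssa = ssa_optimize(objective, config),
         pso = pso_optimize(objective, config),
         gwo = gwo_optimize(objective, config))
}

#' Search the network's hidden-layer sizes with a swarm optimizer
#'
#' The fitness of a candidate architecture is the negative mean stratified
#' inner-k-fold validation accuracy of a network with those (integer) hidden
#' sizes on the supplied training data; the optimizer minimises it. Fitness
#' values are cached by rounded position so identical architectures are never
#' retrained.
#'
#' @param X training feature matrix (already reduced, if reduction is used).
#' @param labels per-row class labels.
#' @param algorithm "ssa" (default), "pso" or "gwo".
#' @param node_bounds \code{c(low, high)} node-count bounds applied to every
#'   hidden layer, or a 2 x L matrix for per-layer bounds (default 2..64 for
#'   two layers); low must be >= 1.
#' @param swarm a \code{\link{swarm_config}} without bounds (population,
#'   iterations, seed, ...); bounds are taken from \code{node_bounds}.
#'   Defaults: population 15, 100 iterations.
#' @param base_config a \code{\link{bpnn_config}} template whose
#'   \code{hidden_sizes} the search replaces.
#' @param inner_k folds of the inner stratified CV estimating the fitness
#'   (default 3).
#' @return list with \code{hidden_sizes} (best integer architecture),
#'   \code{result} (the \code{opt_result}) and \code{n_evaluated} (distinct
#'   architectures trained).
#' @export
optimize_bpnn_architecture <- function(X, labels, algorithm = "ssa",
                                       node_bounds = c(2L, 64L),
                                       swarm = NULL, base_config = NULL,
                                       inner_k = 3L) {
  X <- as.matrix(X)
  labels <- as.character(labels)
  if (is.null(base_config)) {
    base_config <- bpnn_config(input_dim = ncol(X),
                               n_classes = length(unique(labels)))
  }
  nb <- if (is.matrix(node_bounds)) node_bounds else
    matrix(rep(as.numeric(node_bounds), length(base_config$hidden_sizes)), 2L)
  if (any(nb[1L, ] < 1)) stop("node bounds must not permit 0-node layers")
  L <- ncol(nb)
  if (is.null(swarm)) swarm <- swarm_config(bounds = nb, integer_dims = rep(TRUE, L))
  swarm$bounds <- nb
  swarm$integer_dims <- rep(TRUE, L)
  folds <- stratified_kfold(labels, k = inner_k, seed = swarm$seed)
  cache <- new.env(parent = emptyenv())
  n_eval <- 0L
  objective <- function(v) {
    sizes <- pmax(1L, as.integer(round(v)))
    key <- paste(sizes, collapse = "x")
    if (!is.null(cache[[key]])) return(cache[[key]])
    cfg <- base_config
    cfg$hidden_sizes <- sizes
    accs <- vapply(folds, function(test_idx) {
      tr <- setdiff(seq_len(nrow(X)), test_idx)
      m <- train_bpnn(cfg, X[tr, , drop = FALSE], labels[tr])
      bpnn_accuracy(m, X[test_idx, , drop = FALSE], labels[test_idx])
    }, numeric(1L))
    n_eval <<- n_eval + 1L
    cache[[key]] <- -mean(accs)
    cache[[key]]
  }
  res <- swarm_optimize(algorithm, objective, swarm)
  list(hidden_sizes = pmax(1L, as.integer(round(res$best_position))),
       result = res, n_evaluated = n_eval)
}
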