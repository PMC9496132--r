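test_that("all three optimizers solve the 5-D sphere at the study budget", {
  b <- rbind(rep(-5, 5), rep(5, 5))
  meds <- vapply(list(ssa = ssa_optimize, pso = pso_optimize,
                      gwo = gwo_optimize), function(f) {
    stats::median(vapply(1:10, function(s) {
      f(sphere_fn, swarm_config(bounds = b, seed = s))$best_fitness
    }, numeric(1L)))
  }, numeric(1L))
  expect_lt(meds[["ssa"]], 1e-2)
  expect_lt(meds[["pso"]], 1e-1)
  expect_lt(meds[["gwo"]], 1e-2)
})

test_that("optimizer results honour the shared contract", {
  b <- rbind(c(-2, -2), c(2, 2))
  for (algo in c("ssa", "pso", "gwo")) {
    cfg <- swarm_config(bounds = b, population = 15L, iterations = 100L,
                        seed = 3L)
    # bounds respected at every evaluation
    guarded <- function(x) {
      if (any(x < b[1L, ] - 1e-9) || any(x > b[2L, ] + 1e-9)) {
        stop("position escaped the box")
      }
      sum(x^2)
    }
    res <- swarm_optimize(algo, guarded, cfg)
    expect_length(res$history, 100L)
    expect_true(all(diff(res$history) <= 0))  # best-so-far is monotone
    expect_equal(res$best_fitness, res$history[length(res$history)])
    expect_lte(res$evaluations, 15L * 101L)
    # same seed, same trajectory
    res2 <- swarm_optimize(algo, guarded, cfg)
    expect_identical(res$best_position, res2$best_position)
    expect_identical(res$history, res2$history)
    # constant objective: flat history at that constant
    flat <- swarm_optimize(algo, function(x) 4.2, cfg)
    expect_true(all(flat$history == 4.2))
    expect_equal(flat$best_fitness, 4.2)
  }
})

test_that("degenerate and error cases are handled", {
  b1 <- rbind(-3, 3)
  # GWO with only the three leaders still converges on a 1-D sphere
  res <- gwo_optimize(sphere_fn, swarm_config(bounds = b1, population = 3L,
                                              iterations = 50L, seed = 2L))
  expect_lt(res$best_fitness, 1e-2)
  # PSO with inertia and both pulls at zero keeps positions static
  cfg0 <- swarm_config(bounds = rbind(c(-1, -1), c(1, 1)), population = 5L,
                       iterations = 10L, inertia = 0, cognitive = 0,
                       social = 0, velocity_clamp = 0, seed = 4L)
  res0 <- pso_optimize(sphere_fn, cfg0)
  expect_equal(length(unique(res0$history)), 1L)
  # NaN objective names the position
  expect_error(
    ssa_optimize(function(x) NaN,
                 swarm_config(bounds = b1, population = 4L, iterations = 2L,
                              seed = 1L)),
    "position")
  expect_error(swarm_config(bounds = rbind(1, 0)), "lower bound")
  expect_error(swarm_config(bounds = b1, safety_threshold = 0.3),
               "safety_threshold")
})

test_that("integer dimensions stay integral throughout the search", {
  b <- rbind(c(2, 2), c(20, 20))
  seen <- list()
  obj <- function(x) {
    expect_identical(x, round(x))
    (x[1L] - 7)^2 + (x[2L] - 3)^2
  }
  cfg <- swarm_config(bounds = b, population = 10L, iterations = 30L,
                      integer_dims = c(TRUE, TRUE), seed = 5L)
  res <- ssa_optimize(obj, cfg)
  expect_identical(res$best_position, round(res$best_position))
  expect_lte(res$best_fitness, 2)
})

test_that("sparrow search matches particle swarm at a reduced paired budget", {
  b <- rbind(rep(-5, 5), rep(5, 5))
  wins <- vapply(1:20, function(s) {
    cfg <- swarm_config(bounds = b, population = 15L, iterations = 20L,
                        seed = s)
    ssa_optimize(sphere_fn, cfg)$best_fitness <=
      pso_optimize(sphere_fn, cfg)$best_fitness
  }, logical(1L))
  prop <- mean(wins)
  if (prop < 0.5) {
    message("sparrow search won only ", round(100 * prop),
            "% of paired sphere runs at the reduced budget")
  }
  expect_gte(prop, 0.4)
})

test_that("architecture search respects its budget and degenerate spaces", {
  set.seed(61)
  blobs <- make_blobs(n_per = 15L)
  base <- bpnn_config(input_dim = 2L, hidden_sizes = c(4L, 4L), n_classes = 2L,
                      epochs = 60L, seed = 1L)
  # search space collapsed to (almost) a single point returns that architecture
  sw <- swarm_config(bounds = rbind(c(3, 3), c(4, 4)), population = 4L,
                     iterations = 5L, integer_dims = c(TRUE, TRUE), seed = 2L)
  res <- optimize_bpnn_architecture(blobs$X, blobs$y, algorithm = "ssa",
                                    node_bounds = rbind(c(3, 3), c(4, 4)),
                                    swarm = sw, base_config = base,
                                    inner_k = 2L)
  expect_true(all(res$hidden_sizes %in% 3:4))
  expect_length(res$result$history, 5L)
  expect_lte(res$result$evaluations, 4L * 6L)
  # cached: distinct architectures in a 2x2 grid are at most 4
  expect_lte(res$n_evaluated, 4L)
  expect_error(optimize_bpnn_architecture(blobs$X, blobs$y,
                                          node_bounds = c(0L, 8L)),
               "0-node")
})
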