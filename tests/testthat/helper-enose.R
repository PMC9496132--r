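# Small shared fixtures, all generated in code.

# A fast generator configuration: short acquisition, few samples per class.
tiny_config <- function(seed = 1L, ...) {
  generator_config(n_per_class = 6L, duration_s = 310, seed = seed,
                   outlier_fraction = 0, ...)
}

# A curve with prescribed values on a 1 s grid starting at 0.
curve_from <- function(values, channel_id = 1L, dt = 1) {
  response_curve(channel_id, seq(0, by = dt, length.out = length(values)),
                 values)
}

# Separable 2-D Gaussian blobs for classifier sanity checks.
make_blobs <- function(n_per = 20L, gap = 6, sd = 0.5, seed = 1L) {
  set.seed(seed)
  X <- rbind(matrix(stats::rnorm(2 * n_per, 0, sd), ncol = 2),
             matrix(stats::rnorm(2 * n_per, gap, sd), ncol = 2))
  list(X = X, y = rep(c("a", "b"), each = n_per))
}

sphere_fn <- function(x) sum(x^2)
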