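#' k-point linear smoothing of a response curve
#'
#' Replaces each interior point by the unweighted mean of the k values centred
#' on it. The first and last (k-1)/2 points use the mean of the largest
#' symmetric window that fits, so the output has the same length as the input
#' and no phase shift is introduced.
#'
#' @param curve a \code{\link{response_curve}} or a numeric vector.
#' @param k odd window size in \{3, 5, 7, 9, 11\} (default 7, the window that
#'   best balances noise suppression against feature retention for these
#'   transients).
#' @return smoothed object of the same type as the input.
#' @export
smooth_linear <- function(curve, k = 7L) {
  if (length(k) != 1L || is.na(k) || k %% 2L == 0L || k < 3L || k > 11L) {
    stop("k must be an odd window size between 3 and 11")
  }
  v <- if (inherits(curve, "response_curve")) curve$values else as.numeric(curve)
  n <- length(v)
  if (n < k) stop("curve length (", n, ") must be >= k (", k, ")")
  h <- (k - 1L) %/% 2L
  # running mean via cumulative sums; shrunken symmetric windows at the edges
  cs <- c(0, cumsum(v))
  out <- numeric(n)
  for (i in seq_len(n)) {
    hi <- min(h, i - 1L, n - i)
    out[i] <- (cs[i + hi + 1L] - cs[i - hi]) / (2L * hi + 1L)
  }
  if (inherits(curve, "response_curve")) {
    response_curve(curve$channel_id, curve$times, out)
  } else {
    out
  }
}

#' Smooth every curve of every record in a dataset
#'
#' @param dataset an \code{enose_dataset}.
#' @param k odd smoothing window size (see \code{\link{smooth_linear}}).
#' @return the smoothed dataset.
#' @export
smooth_dataset <- function(dataset, k = 7L) {
  structure(lapply(dataset, function(rec) {
    rec$curves <- lapply(rec$curves, smooth_linear, k = k)
    rec
  }), class = "enose_dataset")
}

#' Duplicated-sensor consistency rule
#'
#' The acquisition hardware carries two identical sensors; if their readings
#' diverge by more than a threshold over the stable part of the acquisition,
#' the record is considered anomalous.
#'
#' @param channel_a,channel_b 1-based indices of the duplicated sensors
#'   (defaults 1 and 5).
#' @param window_s two-element window in seconds (default \code{c(150, 300)}).
#' @param threshold divergence threshold in mg/L (default 1.2).
#' @param aggregate how readings are compared over the window: \code{"max"}
#'   (strictest, default) or \code{"mean"} absolute difference.
#' @return object of class \code{pair_anomaly_rule}.
#' @export
pair_anomaly_rule <- function(channel_a = 1L, channel_b = 5L,
                              window_s = c(150, 300), threshold = 1.2,
                              aggregate = c("max", "mean")) {
  if (threshold <= 0) stop("threshold must be > 0")
  if (length(window_s) != 2L || window_s[1L] >= window_s[2L]) {
    stop("window_s must be an increasing [start, end] pair")
  }
  structure(list(channel_a = as.integer(channel_a),
                 channel_b = as.integer(channel_b),
                 window_s = as.numeric(window_s),
                 threshold = threshold,
                 aggregate = match.arg(aggregate)),
            class = "pair_anomaly_rule")
}

#' Flag a record whose duplicated sensors disagree
#'
#' @param record a \code{\link{sample_record}}.
#' @param rule a \code{\link{pair_anomaly_rule}}.
#' @return \code{TRUE} iff the aggregated absolute difference over the window
#'   strictly exceeds the threshold.
#' @export
flag_pair_anomaly <- function(record, rule = pair_anomaly_rule()) {
  ids <- vapply(record$curves, function(cu) cu$channel_id, integer(1L))
  ia <- match(rule$channel_a, ids)
  ib <- match(rule$channel_b, ids)
  if (is.na(ia)) stop("record has no channel ", rule$channel_a)
  if (is.na(ib)) stop("record has no channel ", rule$channel_b)
  times <- record$curves[[ia]]$times
  in_win <- times >= rule$window_s[1L] & times <= rule$window_s[2L]
  if (!any(in_win)) stop("anomaly window is empty on this time grid")
  d <- abs(record$curves[[ia]]$values[in_win] - record$curves[[ib]]$values[in_win])
  agg <- if (rule$aggregate == "max") max(d) else mean(d)
  agg > rule$threshold
}

#' Remove records flagged by the pair-consistency rule
#'
#' @param dataset an \code{enose_dataset}.
#' @param rule a \code{\link{pair_anomaly_rule}}.
#' @return list with \code{dataset} (surviving records) and \code{flagged}
#'   (indices of removed records in the input).
#' @export
apply_pair_rule <- function(dataset, rule = pair_anomaly_rule()) {
  flags <- vapply(dataset, flag_pair_anomaly, logical(1L), rule = rule)
  list(dataset = structure(dataset[!flags], class = "enose_dataset"),
       flagged = which(flags))
}

#' Drop channels that never respond
#'
#' A channel is dead iff every value of every record on that channel has
#' absolute value at most \code{epsilon}. Dead channels carry no information
#' and would make covariance estimates singular downstream.
#'
#' @param dataset an \code{enose_dataset}.
#' @param epsilon detection floor in mg/L (default 1e-6); the rule is strict,
#'   a single value above it keeps the channel.
#' @return list with \code{dataset} (records restricted to live channels) and
#'   \code{dropped} (1-based indices of removed channels).
#' @export
drop_dead_channels <- function(dataset, epsilon = 1e-6) {
  if (epsilon < 0) stop("epsilon must be >= 0")
  if (!length(dataset)) return(list(dataset = dataset, dropped = integer()))
  nch <- length(dataset[[1L]]$curves)
  alive <- rep(FALSE, nch)
  for (rec in dataset) {
    for (j in seq_len(nch)) {
      if (!alive[j] && any(abs(rec$curves[[j]]$values) > epsilon)) alive[j] <- TRUE
    }
    if (all(alive)) break
  }
  if (!any(alive)) stop("all channels are dead at epsilon = ", epsilon)
  dropped <- which(!alive)
  if (!length(dropped)) return(list(dataset = dataset, dropped = integer()))
  out <- lapply(dataset, function(rec) {
    rec$curves <- rec$curves[alive]
    rec
  })
  list(dataset = structure(out, class = "enose_dataset"), dropped = dropped)
}

# Ridge-regularize a covariance matrix when it is numerically ill-conditioned.
regularize_cov <- function(S, cond_limit = 1e10, lambda_rel = 1e-6) {
  d <- ncol(S)
  ev <- eigen(S, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 0 || max(ev) / max(min(ev), .Machine$double.xmin) > cond_limit) {
    S <- S + diag(lambda_rel * sum(diag(S)) / d, d)
  }
  S
}

#' Mahalanobis distances of rows from their own sample distribution
#'
#' Classical in-sample distances \eqn{\sqrt{(x_i-\mu)^T S^{-1} (x_i-\mu)}}
#' with \eqn{\mu} the column mean and S the unbiased sample covariance. When S
#' is ill-conditioned (condition number above 1e10) and \code{regularize} is
#' TRUE, a ridge \eqn{\lambda I} with \eqn{\lambda = 10^{-6}\,tr(S)/d} is
#' added; otherwise a singular S is an error.
#'
#' @param X numeric matrix (n x d), n > d for a meaningful estimate.
#' @param regularize add the ridge automatically when needed (default TRUE).
#' @return numeric vector of n non-negative distances.
#' @export
mahalanobis_distances <- function(X, regularize = TRUE) {
  X <- as.matrix(X)
  n <- nrow(X); d <- ncol(X)
  if (n < 2L) stop("need at least 2 rows")
  mu <- colMeans(X)
  S <- stats::cov(X)
  ev <- eigen(S, symmetric = TRUE, only.values = TRUE)$values
  ill <- min(ev) <= 0 ||
    max(ev) / max(min(ev), .Machine$double.xmin) > 1e10
  if (ill) {
    if (!regularize) {
      stop("sample covariance is singular or ill-conditioned; ",
           "enable regularization (regularize = TRUE) or reduce dimension")
    }
    S <- S + diag(1e-6 * sum(diag(S)) / d, d)
  }
  sqrt(pmax(stats::mahalanobis(X, mu, S), 0))
}

# Per-class covariance shrunk toward its own diagonal. With n close to d the
# full covariance absorbs any direction spanned by a clustered group of
# outliers (masking) and in-sample distances are capped at (n-1)/sqrt(n),
# below the chi-square cutoff; shrinking toward the diagonal keeps the
# Mahalanobis form while accumulating per-feature evidence instead.
shrunk_cov <- function(X, gamma) {
  S <- stats::cov(X)
  d <- ncol(S)
  Ss <- (1 - gamma) * S + gamma * diag(diag(S), d)
  # guard against constant features
  tr <- sum(diag(Ss))
  if (tr <= 0) tr <- 1
  Ss + diag(1e-8 * tr / d, d)
}

#' Per-class Mahalanobis outlier removal with a chi-square cutoff
#'
#' Distances are computed within each class (its own mean and covariance), and
#' samples whose distance exceeds the square root of the chi-square quantile
#' at \code{1 - alpha} with d degrees of freedom are removed.
#'
#' The class covariance is shrunk toward its diagonal: fully
#' (\code{gamma = 1}) when the class has fewer than 2d samples, mildly
#' (\code{gamma = d/n}) beyond that. In the regime this pipeline operates in
#' (36 features, about 40 samples per class) the classical full-covariance
#' estimate makes every in-sample distance at most \eqn{(n-1)/\sqrt{n}}, which
#' is below the chi-square cutoff, and clustered outliers mask each other by
#' inflating the covariance along their common direction; the diagonal metric
#' removes both failure modes while the rule reduces toward the classical
#' estimator as n grows. Set \code{shrinkage = 0} for the
#' classical estimator (requires each class to have at least d + 2 samples).
#'
#' @param X numeric feature matrix (n x d).
#' @param labels per-row class labels.
#' @param alpha tail probability of the chi-square cutoff, in (0, 0.5)
#'   (default 0.025).
#' @param shrinkage \code{"auto"} (default) or a fixed intensity in [0, 1].
#' @return list with \code{X} and \code{labels} (outliers removed) and
#'   \code{report}, an \code{outlier_report} holding per-sample distances, the
#'   cutoff, removed indices and per-class removal counts.
#' @export
remove_outliers <- function(X, labels, alpha = 0.025, shrinkage = "auto") {
  X <- as.matrix(X)
  labels <- as.character(labels)
  if (nrow(X) != length(labels)) stop("labels must match rows of X")
  if (alpha <= 0 || alpha >= 0.5) stop("alpha must lie in (0, 0.5)")
  d <- ncol(X)
  cutoff <- sqrt(stats::qchisq(1 - alpha, df = d))
  distances <- rep(NA_real_, nrow(X))
  for (cls in unique(labels)) {
    rows <- which(labels == cls)
    n_c <- length(rows)
    # auto rule: with fewer than 2d observations the off-diagonal estimates
    # are unstable enough that clustered outliers mask each other, so fall
    # back to the diagonal metric; beyond that shrink mildly by d/n
    gamma <- if (identical(shrinkage, "auto")) {
      if (n_c < 2L * d) 1 else d / n_c
    } else shrinkage
    if (gamma < 0 || gamma > 1) stop("shrinkage must be in [0, 1] or 'auto'")
    if (gamma < 1 && n_c < d + 2L) {
      stop("class '", cls, "' has ", n_c, " samples for ", d, " features; ",
           "use shrinkage = 'auto' (diagonal shrinkage) or a pooled covariance")
    }
    if (n_c < 3L) stop("class '", cls, "' has too few samples (", n_c, ")")
    Xc <- X[rows, , drop = FALSE]
    S <- shrunk_cov(Xc, gamma)
    distances[rows] <- sqrt(pmax(stats::mahalanobis(Xc, colMeans(Xc), S), 0))
  }
  removed <- which(distances > cutoff)
  per_class <- table(factor(labels[removed], levels = unique(labels)))
  report <- structure(list(
    removed_indices = removed,
    distances = distances,
    cutoff = cutoff,
    n_removed_per_class = as.integer(per_class),
    classes = names(per_class),
    alpha = alpha
  ), class = "outlier_report")
  keep <- setdiff(seq_len(nrow(X)), removed)
  list(X = X[keep, , drop = FALSE], labels = labels[keep], report = report)
}

#' @export
print.outlier_report <- function(x, ...) {
  cat("<outlier_report> cutoff ", format(x$cutoff, digits = 4),
      " (alpha = ", x$alpha, "): removed ", length(x$removed_indices),
      " of ", length(x$distances), " samples\n", sep = "")
  if (length(x$classes)) {
    cat("  per class:", paste(x$classes, x$n_removed_per_class,
                              sep = "=", collapse = ", "), "\n")
  }
  invisible(x)
}
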