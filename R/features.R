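#' Analysis window for the transient-response descriptors
#'
#' @param start_s window start in seconds (default 30, after the injection
#'   transient settles into a clean rise).
#' @param end_s window end in seconds (default 300, before purging).
#' @return object of class \code{feature_window}.
#' @export
feature_window <- function(start_s = 30, end_s = 300) {
  if (start_s < 0 || start_s >= end_s) {
    stop("need 0 <= start_s < end_s")
  }
  structure(list(start_s = start_s, end_s = end_s), class = "feature_window")
}

# Windowed values and the grid step; errors if the window leaves fewer than
# 3 samples or falls outside the time grid.
window_values <- function(curve, window) {
  times <- curve$times
  if (window$start_s < times[1L] || window$end_s > times[length(times)]) {
    stop("feature window [", window$start_s, ", ", window$end_s,
         "] outside the time grid [", times[1L], ", ", times[length(times)], "]")
  }
  sel <- times >= window$start_s & times <= window$end_s
  if (sum(sel) < 3L) stop("feature window contains fewer than 3 samples")
  list(v = curve$values[sel], dt = times[2L] - times[1L])
}

#' Integral value (trapezoidal area under the windowed curve)
#'
#' @param curve a \code{\link{response_curve}}.
#' @param window a \code{\link{feature_window}}.
#' @return area in mg.s/L.
#' @export
integral_value <- function(curve, window = feature_window()) {
  w <- window_values(curve, window)
  m <- length(w$v)
  sum((w$v[-m] + w$v[-1L]) / 2) * w$dt
}

#' Variance value (population variance of the windowed curve)
#'
#' @inheritParams integral_value
#' @return variance in (mg/L)^2, dividing by the number of points m.
#' @export
variance_value <- function(curve, window = feature_window()) {
  w <- window_values(curve, window)
  m <- length(w$v)
  sum((w$v - mean(w$v))^2) / m
}

#' Average differential value (mean slope over the window)
#'
#' Mean of the first differences divided by the grid step; by telescoping this
#' equals (last - first) / span.
#'
#' @inheritParams integral_value
#' @return slope in mg/L/s.
#' @export
average_differential <- function(curve, window = feature_window()) {
  w <- window_values(curve, window)
  m <- length(w$v)
  (w$v[m] - w$v[1L]) / ((m - 1L) * w$dt)
}

#' Maximum gradient value (largest one-step slope)
#'
#' @inheritParams integral_value
#' @param absolute take the largest absolute slope instead of the signed
#'   maximum (default FALSE: these sensors rise, so the signed maximum is the
#'   steepest uptake).
#' @return slope in mg/L/s.
#' @export
maximum_gradient <- function(curve, window = feature_window(), absolute = FALSE) {
  w <- window_values(curve, window)
  g <- diff(w$v) / w$dt
  if (absolute) max(abs(g)) else max(g)
}

#' Relatively stable average value (plateau mean)
#'
#' Mean of the final fraction of the windowed values, covering the region the
#' acquisition treats as stable (with the defaults, 165--300 s).
#'
#' @inheritParams integral_value
#' @param stable_fraction final fraction of the window to average over,
#'   in (0, 1] (default 0.5).
#' @return mean concentration in mg/L.
#' @export
stable_average <- function(curve, window = feature_window(),
                           stable_fraction = 0.5) {
  if (stable_fraction <= 0 || stable_fraction > 1) {
    stop("stable_fraction must lie in (0, 1]")
  }
  w <- window_values(curve, window)
  m <- length(w$v)
  n_stable <- max(1L, ceiling(m * stable_fraction))
  mean(w$v[(m - n_stable + 1L):m])
}

#' Energy value (discrete signal energy over the window)
#'
#' @inheritParams integral_value
#' @return \eqn{\sum v_i^2 \Delta t} in (mg/L)^2 s.
#' @export
energy_value <- function(curve, window = feature_window()) {
  w <- window_values(curve, window)
  sum(w$v^2) * w$dt
}

descriptor_names <- c("integral", "variance", "avg_diff", "max_grad",
                      "stable_avg", "energy")

#' Extract the six-descriptor feature table from a dataset
#'
#' For every record and every channel, computes integral value, variance
#' value, average differential value, maximum gradient value, relatively
#' stable average value and energy value over the analysis window, in that
#' fixed order, yielding d = 6 x n_channels features per sample. Columns are
#' named \code{ch<channel>_<descriptor>}.
#'
#' @param dataset an \code{enose_dataset}.
#' @param window a \code{\link{feature_window}}.
#' @param stable_fraction passed to \code{\link{stable_average}}.
#' @param absolute_gradient passed to \code{\link{maximum_gradient}}.
#' @return object of class \code{feature_table}: list with \code{X}
#'   (n x d numeric matrix with column names), \code{labels},
#'   \code{sample_ids} and \code{feature_names}.
#' @export
extract_features <- function(dataset, window = feature_window(),
                             stable_fraction = 0.5,
                             absolute_gradient = FALSE) {
  if (!length(dataset)) {
    return(feature_table(matrix(numeric(), 0L, 0L), character(), character()))
  }
  ids <- vapply(dataset[[1L]]$curves, function(cu) cu$channel_id, integer(1L))
  for (rec in dataset) {
    rid <- vapply(rec$curves, function(cu) cu$channel_id, integer(1L))
    if (!identical(rid, ids)) {
      stop("record '", rec$sample_id, "' has channel set [",
           paste(rid, collapse = ","), "], expected [",
           paste(ids, collapse = ","), "]")
    }
  }
  fnames <- as.vector(t(outer(paste0("ch", ids), descriptor_names, paste, sep = "_")))
  X <- matrix(NA_real_, length(dataset), length(fnames),
              dimnames = list(NULL, fnames))
  for (i in seq_along(dataset)) {
    row <- unlist(lapply(dataset[[i]]$curves, function(cu) {
      c(integral_value(cu, window),
        variance_value(cu, window),
        average_differential(cu, window),
        maximum_gradient(cu, window, absolute = absolute_gradient),
        stable_average(cu, window, stable_fraction = stable_fraction),
        energy_value(cu, window))
    }))
    X[i, ] <- row
  }
  feature_table(X,
                labels = vapply(dataset, function(r) r$label, character(1L)),
                sample_ids = vapply(dataset, function(r) r$sample_id, character(1L)))
}

#' Construct a feature table
#'
#' @param X n x d numeric matrix with feature names as column names.
#' @param labels per-row class labels.
#' @param sample_ids per-row identifiers.
#' @return object of class \code{feature_table}.
#' @export
feature_table <- function(X, labels, sample_ids = NULL) {
  X <- as.matrix(X)
  if (nrow(X) != length(labels)) stop("labels must match rows of X")
  if (is.null(sample_ids)) sample_ids <- sprintf("s%03d", seq_len(nrow(X)))
  if (nrow(X) && any(!is.finite(X))) stop("feature matrix contains non-finite values")
  structure(list(X = X, labels = as.character(labels),
                 sample_ids = as.character(sample_ids),
                 feature_names = colnames(X)),
            class = "feature_table")
}

#' @export
print.feature_table <- function(x, ...) {
  cat("<feature_table> ", nrow(x$X), " samples x ", ncol(x$X), " features\n",
      sep = "")
  if (length(x$labels)) print(table(x$labels))
  invisible(x)
}

#' Subset a feature table by row
#' @param ft a \code{feature_table}.
#' @param rows integer or logical row index.
#' @return the subsetted \code{feature_table}.
#' @export
ft_rows <- function(ft, rows) {
  feature_table(ft$X[rows, , drop = FALSE], ft$labels[rows], ft$sample_ids[rows])
}
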