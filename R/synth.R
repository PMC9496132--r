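#' Default class-by-channel plateau matrix
#'
#' Mean stable-window concentrations (mg/L) for the four sample groups across
#' the eight sensor channels. Channels 1 and 5 are duplicated sensors and share
#' a row-wise value so the pair-consistency rule is meaningful on clean data;
#' channels 3 and 7 are below their detection floor for all classes and are
#' identically zero. Levels are not fitted to any measured dataset: they are
#' round mg/L values chosen once to give partially overlapping classes under
#' the default noise settings.
#'
#' @param classes character vector of class labels (row names).
#' @param n_channels number of sensor channels (columns).
#' @param dead_channels 1-based indices of always-zero channels.
#' @return numeric matrix, \code{length(classes)} x \code{n_channels}.
#' @export
default_plateau_matrix <- function(classes = enose_classes(),
                                   n_channels = 8L,
                                   dead_channels = c(3L, 7L)) {
  base <- rbind(
    fresh       = c(2.0, 0.5, 0.9, 1.0, 2.0, 0.8, 1.1, 1.2),
    A_niger     = c(3.2, 0.9, 1.3, 1.8, 3.2, 1.5, 0.6, 0.9),
    P_expansum  = c(2.8, 1.4, 0.7, 1.4, 2.8, 1.1, 1.5, 1.6),
    P_crustosum = c(3.6, 1.1, 1.8, 2.2, 3.6, 0.7, 0.8, 1.3)
  )
  if (length(classes) > nrow(base) || n_channels > ncol(base)) {
    stop("default_plateau_matrix covers at most 4 classes and 8 channels; ",
         "supply plateau_matrix explicitly for larger designs")
  }
  m <- base[seq_along(classes), seq_len(n_channels), drop = FALSE]
  rownames(m) <- classes
  m[, intersect(dead_channels, seq_len(n_channels))] <- 0
  m
}

#' Canonical class labels of the fruit-infection study design
#'
#' One healthy group and three fungal inoculation groups.
#'
#' @return character vector of length 4.
#' @export
enose_classes <- function() {
  c("fresh", "A_niger", "P_expansum", "P_crustosum")
}

#' Configuration for the synthetic e-nose dataset generator
#'
#' Describes a class-conditioned acquisition: per-class mean plateau levels for
#' every channel, a first-order rise to plateau, additive Gaussian sensor
#' noise, per-sample biological amplitude variability, permanently-zero (dead)
#' channels, and optional injected whole-record outliers.
#'
#' A single dial controls all stochastic perturbation: \code{noise_sd} sets the
#' point-wise sensor noise (mg/L), and the per-sample multiplicative plateau
#' jitter has relative standard deviation \code{plateau_jitter * noise_sd}.
#' At \code{noise_sd = 0} the generator is fully deterministic given the class,
#' and the class-conditional mean over the stable 150--300 s window equals the
#' \code{plateau_matrix} entry exactly.
#'
#' @param n_per_class samples per class (default 40).
#' @param classes ordered class labels (default the 4 study groups).
#' @param n_channels number of sensor channels (default 8).
#' @param dead_channels 1-based indices of always-zero channels (default
#'   \code{c(3, 7)}, emulating the two sensors whose analyte never reaches the
#'   detection floor).
#' @param duration_s acquisition length in seconds (default 350).
#' @param dt_s sampling interval in seconds (default 1).
#' @param plateau_matrix class x channel matrix of mean stable-window
#'   concentrations (mg/L).
#' @param rise_tau_s time constant of the first-order rise (seconds).
#' @param noise_sd standard deviation of additive sensor noise (mg/L).
#' @param plateau_jitter converts \code{noise_sd} into the relative standard
#'   deviation of the per-sample plateau amplitude factor (1/(mg/L)).
#' @param outlier_fraction fraction of records (over the whole dataset) whose
#'   live channels are inflated, in [0, 1).
#' @param outlier_scale multiplicative inflation factor for injected outliers
#'   (> 1).
#' @param paired_channels two duplicated-sensor indices sharing one amplitude
#'   factor per sample (default \code{c(1, 5)}: identical sensors reading the
#'   same gas differ only by sensor noise), or NULL for none.
#' @param seed integer seed making the whole dataset reproducible.
#' @return object of class \code{generator_config}.
#' @export
generator_config <- function(n_per_class = 40L,
                             classes = enose_classes(),
                             n_channels = 8L,
                             dead_channels = c(3L, 7L),
                             duration_s = 350,
                             dt_s = 1,
                             plateau_matrix = NULL,
                             rise_tau_s = 25,
                             noise_sd = 0.08,
                             plateau_jitter = 2.75,
                             outlier_fraction = 0.1,
                             outlier_scale = 5,
                             paired_channels = c(1L, 5L),
                             seed = 1L) {
  if (is.null(plateau_matrix)) {
    plateau_matrix <- default_plateau_matrix(classes, n_channels, dead_channels)
  }
  cfg <- structure(list(
    n_per_class = as.integer(n_per_class),
    classes = as.character(classes),
    n_channels = as.integer(n_channels),
    dead_channels = as.integer(dead_channels),
    duration_s = duration_s,
    dt_s = dt_s,
    plateau_matrix = plateau_matrix,
    rise_tau_s = rise_tau_s,
    noise_sd = noise_sd,
    plateau_jitter = plateau_jitter,
    outlier_fraction = outlier_fraction,
    outlier_scale = outlier_scale,
    paired_channels = if (is.null(paired_channels)) NULL
                      else as.integer(paired_channels),
    seed = as.integer(seed)
  ), class = "generator_config")
  validate_generator_config(cfg)
  cfg
}

validate_generator_config <- function(cfg) {
  stopifnot(inherits(cfg, "generator_config"))
  if (cfg$n_per_class < 1L) stop("n_per_class must be >= 1")
  if (length(cfg$classes) < 1L) stop("at least one class is required")
  if (anyDuplicated(cfg$classes)) stop("class labels must be unique")
  n_t <- floor(cfg$duration_s / cfg$dt_s) + 1L
  if (n_t < 301L) {
    stop("duration_s/dt_s must yield >= 301 samples so the 30-300 s feature ",
         "window exists (got ", n_t, ")")
  }
  if (length(cfg$dead_channels) &&
      (any(cfg$dead_channels < 1L) || any(cfg$dead_channels > cfg$n_channels))) {
    stop("dead_channels must be 1-based channel indices within 1..n_channels")
  }
  pm <- cfg$plateau_matrix
  if (!is.matrix(pm) || nrow(pm) != length(cfg$classes) ||
      ncol(pm) != cfg$n_channels) {
    stop("plateau_matrix must be a ", length(cfg$classes), " x ",
         cfg$n_channels, " matrix")
  }
  if (anyDuplicated(apply(pm, 1L, paste, collapse = ","))) {
    stop("plateau_matrix rows (class signatures) must be pairwise distinct")
  }
  if (cfg$rise_tau_s <= 0) stop("rise_tau_s must be > 0")
  if (cfg$noise_sd < 0) stop("noise_sd must be >= 0")
  if (cfg$outlier_fraction < 0 || cfg$outlier_fraction >= 1) {
    stop("outlier_fraction must lie in [0, 1)")
  }
  if (cfg$outlier_scale <= 1) stop("outlier_scale must be > 1")
  if (!is.null(cfg$paired_channels) &&
      (length(cfg$paired_channels) != 2L ||
       any(cfg$paired_channels < 1L) ||
       any(cfg$paired_channels > cfg$n_channels))) {
    stop("paired_channels must be two channel indices within 1..n_channels")
  }
  invisible(cfg)
}

#' Single-channel response curve
#'
#' @param channel_id 1-based channel index.
#' @param times uniform time grid in seconds.
#' @param values concentrations (mg/L), same length as \code{times}.
#' @return object of class \code{response_curve}.
#' @export
response_curve <- function(channel_id, times, values) {
  if (length(times) != length(values)) {
    stop("times and values must have the same length")
  }
  if (length(times) >= 2L) {
    dts <- diff(times)
    if (any(dts <= 0) || max(abs(dts - dts[1L])) > 1e-9 * max(dts[1L], 1)) {
      stop("times must be strictly increasing with a constant step")
    }
  }
  if (any(!is.finite(values))) stop("curve values must be finite")
  structure(list(channel_id = as.integer(channel_id),
                 times = as.numeric(times),
                 values = as.numeric(values)),
            class = "response_curve")
}

#' One sample's acquisition: a curve per channel plus its class label
#'
#' @param sample_id identifier string.
#' @param label class label.
#' @param curves list of \code{response_curve}, one per channel, sharing one
#'   time grid.
#' @param is_injected_outlier generator-only ground-truth flag.
#' @return object of class \code{sample_record}.
#' @export
sample_record <- function(sample_id, label, curves, is_injected_outlier = FALSE) {
  if (!length(curves)) stop("a sample needs at least one channel curve")
  t0 <- curves[[1L]]$times
  for (cu in curves) {
    if (!inherits(cu, "response_curve")) stop("curves must be response_curve objects")
    if (!identical(length(cu$times), length(t0)) || max(abs(cu$times - t0)) > 0) {
      stop("all curves of a sample must share one time grid")
    }
  }
  structure(list(sample_id = as.character(sample_id),
                 label = as.character(label),
                 curves = curves,
                 is_injected_outlier = isTRUE(is_injected_outlier)),
            class = "sample_record")
}

# Deterministic noise-free curve shape: first-order rise normalised so that
# its mean over the stable 150-300 s window is exactly 1. The plateau entry is
# thereby defined as the mean stable-window concentration, which is also what
# a practitioner calibrates a sensor against.
curve_shape <- function(times, tau, stable_window = c(150, 300)) {
  shape <- 1 - exp(-times / tau)
  in_win <- times >= stable_window[1L] & times <= stable_window[2L]
  if (!any(in_win)) stop("time grid does not cover the stable window")
  shape / mean(shape[in_win])
}

#' Generate one synthetic response curve
#'
#' Live channels follow a first-order rise towards the class-channel plateau
#' (calibrated so the 150--300 s mean equals the plateau entry), with per-curve
#' Gaussian amplitude jitter and point-wise Gaussian noise, clipped at 0.
#' Dead channels are identically zero. Uses the current RNG state: seed the
#' stream (or call through \code{\link{generate_dataset}}) for reproducibility.
#'
#' @param label class label (must be one of \code{config$classes}).
#' @param channel 1-based channel index.
#' @param config a \code{\link{generator_config}}.
#' @param amp_factor optional pre-drawn per-sample amplitude factor (used by
#'   \code{\link{generate_record}} to let duplicated sensors share one
#'   factor); drawn internally when NULL.
#' @return a \code{\link{response_curve}}.
#' @export
generate_curve <- function(label, channel, config, amp_factor = NULL) {
  validate_generator_config(config)
  cls <- match(label, config$classes)
  if (is.na(cls)) {
    stop("unknown class label '", label, "'; expected one of: ",
         paste(config$classes, collapse = ", "))
  }
  if (channel < 1L || channel > config$n_channels) {
    stop("channel index ", channel, " outside 1..", config$n_channels)
  }
  times <- seq(0, config$duration_s, by = config$dt_s)
  if (channel %in% config$dead_channels) {
    return(response_curve(channel, times, rep(0, length(times))))
  }
  if (is.null(amp_factor)) {
    amp_factor <- 1 + stats::rnorm(1L) * config$plateau_jitter * config$noise_sd
  }
  amp <- config$plateau_matrix[cls, channel] * amp_factor
  v <- amp * curve_shape(times, config$rise_tau_s) +
    stats::rnorm(length(times), sd = config$noise_sd)
  response_curve(channel, times, pmax(v, 0))
}

#' Generate one full sample record
#'
#' Draws a per-channel amplitude factor (shared between the duplicated
#' sensors named in \code{paired_channels}: identical sensors reading the
#' same headspace differ only by sensor noise) and builds every channel's
#' curve. Uses the current RNG state.
#'
#' @param label class label.
#' @param sample_id identifier for the record.
#' @param config a \code{\link{generator_config}}.
#' @return a \code{\link{sample_record}}.
#' @export
generate_record <- function(label, sample_id, config) {
  amps <- 1 + stats::rnorm(config$n_channels) *
    config$plateau_jitter * config$noise_sd
  if (!is.null(config$paired_channels)) {
    amps[config$paired_channels[2L]] <- amps[config$paired_channels[1L]]
  }
  curves <- lapply(seq_len(config$n_channels), function(ch) {
    generate_curve(label, ch, config, amp_factor = amps[ch])
  })
  sample_record(sample_id, label, curves)
}

#' Generate a full class-balanced synthetic dataset
#'
#' Produces \code{n_per_class} records for each class, then inflates the live
#' channels of \code{floor(n_total * outlier_fraction)} records (chosen without
#' replacement) by \code{outlier_scale}, flagging them via
#' \code{is_injected_outlier}. Fully deterministic given \code{config$seed}.
#'
#' @param config a \code{\link{generator_config}}.
#' @return object of class \code{enose_dataset}: a list of
#'   \code{\link{sample_record}}s.
#' @export
generate_dataset <- function(config = generator_config()) {
  validate_generator_config(config)
  set.seed(config$seed)
  records <- vector("list", config$n_per_class * length(config$classes))
  idx <- 0L
  for (cls in config$classes) {
    for (r in seq_len(config$n_per_class)) {
      idx <- idx + 1L
      records[[idx]] <- generate_record(cls, sprintf("%s_%02d", cls, r), config)
    }
  }
  n_out <- floor(length(records) * config$outlier_fraction)
  if (n_out > 0L) {
    flagged <- sample.int(length(records), n_out)
    live <- setdiff(seq_len(config$n_channels), config$dead_channels)
    for (i in flagged) {
      rec <- records[[i]]
      for (ch in live) {
        rec$curves[[ch]]$values <- rec$curves[[ch]]$values * config$outlier_scale
      }
      rec$is_injected_outlier <- TRUE
      records[[i]] <- rec
    }
  }
  structure(records, class = "enose_dataset")
}

#' @export
print.enose_dataset <- function(x, ...) {
  labs <- vapply(x, function(r) r$label, character(1L))
  nch <- if (length(x)) length(x[[1L]]$curves) else 0L
  cat("<enose_dataset> ", length(x), " samples, ", nch, " channels\n", sep = "")
  if (length(labs)) print(table(labs))
  invisible(x)
}

#' Labels of a dataset
#' @param dataset an \code{enose_dataset}.
#' @return character vector of per-record class labels.
#' @export
dataset_labels <- function(dataset) {
  vapply(dataset, function(r) r$label, character(1L))
}

#' Ground-truth injected-outlier flags of a synthetic dataset
#' @param dataset an \code{enose_dataset}.
#' @return logical vector.
#' @export
dataset_outlier_flags <- function(dataset) {
  vapply(dataset, function(r) isTRUE(r$is_injected_outlier), logical(1L))
}
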