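#' Write a curve dataset to long-format CSV
#'
#' Columns \code{sample_id,label,channel_id,time_s,value}, one header line,
#' UTF-8, '.' decimal separator.
#'
#' @param dataset an \code{enose_dataset}.
#' @param path output file path.
#' @return the path, invisibly.
#' @export
write_curves_csv <- function(dataset, path) {
  rows <- lapply(dataset, function(rec) {
    do.call(rbind, lapply(rec$curves, function(cu) {
      data.frame(sample_id = rec$sample_id, label = rec$label,
                 channel_id = cu$channel_id, time_s = cu$times,
                 value = cu$values, stringsAsFactors = FALSE)
    }))
  })
  df <- do.call(rbind, rows)
  if (is.null(df)) {
    df <- data.frame(sample_id = character(), label = character(),
                     channel_id = integer(), time_s = numeric(),
                     value = numeric())
  }
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a curve dataset from long-format CSV
#'
#' Validates the column set, per-curve uniform time grids and a consistent
#' channel set across samples, reporting the offending line number on
#' failure.
#'
#' @param path CSV file written by \code{\link{write_curves_csv}} (or any file
#'   with the same columns).
#' @return an \code{enose_dataset}.
#' @export
read_curves_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("sample_id", "label", "channel_id", "time_s", "value")
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    stop("curves file '", path, "' is missing column(s) ",
         paste(missing, collapse = ", "), " (header, line 1)")
  }
  if (!nrow(df)) return(structure(list(), class = "enose_dataset"))
  bad <- which(!is.finite(df$value))
  if (length(bad)) {
    stop("non-finite value at line ", bad[1L] + 1L, " of '", path, "'")
  }
  # line number of the first row of each (sample, channel) block, for errors
  df$.line <- seq_len(nrow(df)) + 1L
  sample_ids <- unique(df$sample_id)
  ref_channels <- NULL
  records <- vector("list", length(sample_ids))
  for (s in seq_along(sample_ids)) {
    sub <- df[df$sample_id == sample_ids[s], , drop = FALSE]
    chans <- unique(sub$channel_id)
    if (is.null(ref_channels)) {
      ref_channels <- sort(chans)
    } else if (!identical(sort(chans), ref_channels)) {
      stop("sample '", sample_ids[s], "' (line ", sub$.line[1L],
           ") has channel set [", paste(sort(chans), collapse = ","),
           "], expected [", paste(ref_channels, collapse = ","), "]")
    }
    labs <- unique(sub$label)
    if (length(labs) != 1L) {
      stop("sample '", sample_ids[s], "' has conflicting labels near line ",
           sub$.line[1L])
    }
    curves <- lapply(ref_channels, function(ch) {
      cu <- sub[sub$channel_id == ch, , drop = FALSE]
      cu <- cu[order(cu$time_s), , drop = FALSE]
      tryCatch(response_curve(ch, cu$time_s, cu$value),
               error = function(e) {
                 stop("invalid curve for sample '", sample_ids[s],
                      "' channel ", ch, " (line ", cu$.line[1L], "): ",
                      conditionMessage(e))
               })
    })
    records[[s]] <- sample_record(sample_ids[s], labs, curves)
  }
  structure(records, class = "enose_dataset")
}

#' Write a feature table to CSV
#'
#' Header \code{sample_id,label,<feature names...>}.
#'
#' @param ft a \code{\link{feature_table}}.
#' @param path output file path.
#' @return the path, invisibly.
#' @export
write_features_csv <- function(ft, path) {
  df <- data.frame(sample_id = ft$sample_ids, label = ft$labels,
                   stringsAsFactors = FALSE)
  df <- cbind(df, as.data.frame(ft$X))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a feature table from CSV
#'
#' @param path CSV with columns \code{sample_id}, \code{label} and the feature
#'   columns.
#' @param n_channels when given, validates that the file carries exactly
#'   6 features per channel (column count = 6 x n_channels + 2).
#' @return a \code{\link{feature_table}}.
#' @export
read_features_csv <- function(path, n_channels = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (!all(c("sample_id", "label") %in% names(df))) {
    stop("feature file '", path, "' must start with sample_id,label columns")
  }
  if (!is.null(n_channels) && ncol(df) != 6L * n_channels + 2L) {
    stop("feature file has ", ncol(df), " columns; expected ",
         6L * n_channels + 2L, " for ", n_channels, " channels")
  }
  X <- as.matrix(df[, setdiff(names(df), c("sample_id", "label")), drop = FALSE])
  feature_table(X, df$label, df$sample_id)
}

#' Write an outlier report to CSV
#'
#' One row per sample: \code{sample_id,distance,removed}.
#'
#' @param report an \code{outlier_report}.
#' @param sample_ids per-sample identifiers aligned with the distances.
#' @param path output file path.
#' @return the path, invisibly.
#' @export
write_outlier_report_csv <- function(report, sample_ids, path) {
  df <- data.frame(sample_id = sample_ids,
                   distance = report$distances,
                   removed = seq_along(report$distances) %in%
                     report$removed_indices)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write an optimizer fitness history to CSV
#'
#' Columns \code{iteration,best_fitness}, suitable for convergence plots.
#'
#' @param result an \code{opt_result}.
#' @param path output file path.
#' @return the path, invisibly.
#' @export
write_history_csv <- function(result, path) {
  utils::write.csv(data.frame(iteration = seq_along(result$history),
                              best_fitness = result$history),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Serialize a projection model to text files
#'
#' Writes \code{<prefix>_mean.csv} (mean and optional scale vectors),
#' \code{<prefix>_components.csv} (d x k matrix) and \code{<prefix>.yaml}
#' (method, k, explained).
#'
#' @param model a \code{projection_model}.
#' @param prefix path prefix (no extension).
#' @return the prefix, invisibly.
#' @export
save_projection <- function(model, prefix) {
  mv <- data.frame(mean = model$mean)
  if (!is.null(model$scale)) mv$scale <- model$scale
  utils::write.csv(mv, paste0(prefix, "_mean.csv"), row.names = FALSE)
  utils::write.csv(as.data.frame(model$components),
                   paste0(prefix, "_components.csv"), row.names = FALSE)
  yaml::write_yaml(list(method = model$method, k = model$k,
                        explained = as.numeric(model$explained)),
                   paste0(prefix, ".yaml"))
  invisible(prefix)
}

#' Load a projection model saved by \code{\link{save_projection}}
#'
#' @param prefix path prefix used when saving.
#' @return a \code{projection_model}.
#' @export
load_projection <- function(prefix) {
  meta <- yaml::read_yaml(paste0(prefix, ".yaml"))
  mv <- utils::read.csv(paste0(prefix, "_mean.csv"))
  comp <- as.matrix(utils::read.csv(paste0(prefix, "_components.csv")))
  dimnames(comp) <- NULL
  projection_model(meta$method, mv$mean, comp, as.numeric(meta$explained),
                   scale = if ("scale" %in% names(mv)) mv$scale else NULL)
}

#' Serialize a trained network to a portable text file
#'
#' A YAML header (architecture, activation, training settings, class levels,
#' standardisation statistics) delimited by \code{---} lines, followed by one
#' CSV block per layer (\code{# W<l>} then the weight rows with the bias as
#' the final row).
#'
#' @param model a \code{bpnn_model}.
#' @param path output file path.
#' @return the path, invisibly.
#' @export
save_bpnn <- function(model, path) {
  cfg <- model$config
  header <- list(input_dim = cfg$input_dim,
                 hidden_sizes = as.integer(cfg$hidden_sizes),
                 n_classes = cfg$n_classes, activation = cfg$activation,
                 learning_rate = cfg$learning_rate, epochs = cfg$epochs,
                 standardize = cfg$standardize, seed = cfg$seed,
                 levels = model$levels,
                 has_standardization = !is.null(model$center))
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines("---", con)
  writeLines(yaml::as.yaml(header), con)
  writeLines("---", con)
  for (l in seq_along(model$weights)) {
    writeLines(paste0("# W", l), con)
    block <- rbind(model$weights[[l]], model$biases[[l]])
    # %.17g round-trips doubles exactly
    writeLines(apply(block, 1L, function(r) {
      paste(sprintf("%.17g", r), collapse = ",")
    }), con)
  }
  if (!is.null(model$center)) {
    writeLines("# standardization", con)
    writeLines(paste(sprintf("%.17g", model$center), collapse = ","), con)
    writeLines(paste(sprintf("%.17g", model$scale), collapse = ","), con)
  }
  invisible(path)
}

#' Load a network saved by \code{\link{save_bpnn}}
#'
#' @param path file written by \code{\link{save_bpnn}}.
#' @return a \code{bpnn_model} ready for prediction.
#' @export
load_bpnn <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  seps <- which(lines == "---")
  if (length(seps) < 2L) stop("'", path, "' lacks the YAML header delimiters")
  header <- yaml::yaml.load(paste(lines[(seps[1L] + 1L):(seps[2L] - 1L)],
                                  collapse = "\n"))
  cfg <- bpnn_config(input_dim = header$input_dim,
                     hidden_sizes = header$hidden_sizes,
                     n_classes = header$n_classes,
                     activation = header$activation,
                     learning_rate = header$learning_rate,
                     epochs = header$epochs,
                     standardize = header$standardize,
                     seed = header$seed)
  model <- init_bpnn(cfg)
  model$levels <- unlist(header$levels)
  body <- lines[(seps[2L] + 1L):length(lines)]
  smark <- grep("^# standardization", body)
  if (length(smark)) {
    model$center <- as.numeric(strsplit(body[smark + 1L], ",")[[1L]])
    model$scale <- as.numeric(strsplit(body[smark + 2L], ",")[[1L]])
    body <- body[seq_len(smark - 1L)]
  }
  marks <- grep("^# W", body)
  if (length(marks) != length(model$weights)) {
    stop("'", path, "' has ", length(marks), " weight blocks; expected ",
         length(model$weights))
  }
  ends <- c(marks[-1L] - 1L, length(body))
  for (l in seq_along(marks)) {
    block <- body[(marks[l] + 1L):ends[l]]
    m <- do.call(rbind, lapply(strsplit(block, ","), as.numeric))
    model$weights[[l]] <- m[-nrow(m), , drop = FALSE]
    model$biases[[l]] <- m[nrow(m), ]
  }
  model
}

#' Default end-to-end pipeline configuration
#'
#' Nested list mirroring the pipeline stages: generator, preprocess
#' (smoothing, pair rule, outlier alpha), features (window, stable fraction),
#' reduction, model, optimizer and evaluation. Unknown keys are rejected by
#' \code{\link{validate_pipeline_config}}.
#'
#' @param ... named overrides merged section-wise into the defaults, e.g.
#'   \code{pipeline_config(evaluation = list(seed = 7))}.
#' @return object of class \code{pipeline_config}.
#' @export
pipeline_config <- function(...) {
  cfg <- list(
    generator = list(seed = 1L),
    preprocess = list(smooth_k = 7L, pair_rule = TRUE, pair_channel_a = 1L,
                      pair_channel_b = 5L, pair_threshold = 1.2,
                      dead_epsilon = 1e-6, outlier_alpha = 0.025),
    features = list(window_start_s = 30, window_end_s = 300,
                    stable_fraction = 0.5),
    reduction = list(method = "lda", k = NULL),
    model = list(name = "bpnn", hidden_sizes = c(8L, 8L),
                 learning_rate = 0.3, epochs = 500L),
    optimizer = list(algorithm = "none", population = 15L, iterations = 100L,
                     node_low = 2L, node_high = 64L, inner_k = 3L),
    evaluation = list(k = 10L, seed = 1L, global_fit = FALSE)
  )
  overrides <- list(...)
  for (sec in names(overrides)) {
    if (!sec %in% names(cfg)) stop("unknown pipeline section '", sec, "'")
    # the generator section accepts the full generator_config surface
    allowed <- if (sec == "generator") {
      names(formals(generator_config))
    } else {
      names(cfg[[sec]])
    }
    for (key in names(overrides[[sec]])) {
      if (!key %in% allowed) {
        stop("unknown key '", key, "' in pipeline section '", sec, "'")
      }
      cfg[[sec]][[key]] <- overrides[[sec]][[key]]
    }
  }
  structure(cfg, class = "pipeline_config")
}

#' Validate a pipeline configuration (e.g. read from YAML)
#'
#' @param cfg nested list of pipeline sections.
#' @return a validated \code{pipeline_config}.
#' @export
validate_pipeline_config <- function(cfg) {
  do.call(pipeline_config, unclass(cfg))
}

#' Read a pipeline configuration from a YAML file
#'
#' @param path YAML file with any subset of the pipeline sections.
#' @return a validated \code{pipeline_config}.
#' @export
read_pipeline_config <- function(path) {
  validate_pipeline_config(yaml::read_yaml(path))
}

pipeline_log <- function(verbose, ...) {
  if (verbose) message("[enose] ", ...)
}

#' Run the full pipeline: simulate/load, preprocess, extract, reduce,
#' optionally tune, cross-validate
#'
#' Stages: generate (or accept) a curve dataset; k-point smoothing;
#' dead-channel exclusion; duplicated-sensor anomaly removal; six-descriptor
#' feature extraction; then stratified k-fold cross-validation in which
#' Mahalanobis outlier removal, the reduction projection and the classifier
#' are fit per training fold. When \code{optimizer$algorithm} is "ssa", "pso"
#' or "gwo", the network's hidden-layer sizes are first tuned on the feature
#' table with the chosen swarm. Deterministic given the configured seeds.
#'
#' @param config a \code{\link{pipeline_config}}.
#' @param dataset optional pre-loaded \code{enose_dataset}; by default a
#'   synthetic dataset is generated from the generator section.
#' @param out_dir optional directory for artifacts (features.csv,
#'   outlier_report.csv, history.csv, report.csv, summary.csv).
#' @param verbose log per-stage record counts (default TRUE).
#' @return list with \code{report} (a \code{cv_report}), \code{features},
#'   \code{outlier_report}, \code{tuning} (NULL without an optimizer),
#'   \code{dropped_channels} and \code{pair_flagged}.
#' @export
run_pipeline <- function(config = pipeline_config(), dataset = NULL,
                         out_dir = NULL, verbose = TRUE) {
  stopifnot(inherits(config, "pipeline_config"))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }
  if (is.null(dataset)) {
    dataset <- stage("simulate", {
      gcfg <- do.call(generator_config, config$generator)
      generate_dataset(gcfg)
    })
    pipeline_log(verbose, "simulate: ", length(dataset), " records")
  } else {
    pipeline_log(verbose, "load: ", length(dataset), " records")
  }
  pp <- config$preprocess
  dataset <- stage("smooth", smooth_dataset(dataset, k = pp$smooth_k))
  pipeline_log(verbose, "smooth: k = ", pp$smooth_k)
  dd <- stage("drop_dead", drop_dead_channels(dataset, epsilon = pp$dead_epsilon))
  dataset <- dd$dataset
  pipeline_log(verbose, "drop_dead: dropped ", length(dd$dropped),
               " channel(s) [", paste(dd$dropped, collapse = ","), "]")
  pair_flagged <- integer()
  if (isTRUE(pp$pair_rule)) {
    rule <- pair_anomaly_rule(channel_a = pp$pair_channel_a,
                              channel_b = pp$pair_channel_b,
                              threshold = pp$pair_threshold)
    pr <- stage("pair_rule", apply_pair_rule(dataset, rule))
    dataset <- pr$dataset
    pair_flagged <- pr$flagged
    pipeline_log(verbose, "pair_rule: removed ", length(pair_flagged),
                 " record(s), ", length(dataset), " remain")
  }
  fe <- config$features
  ft <- stage("extract", extract_features(
    dataset,
    window = feature_window(fe$window_start_s, fe$window_end_s),
    stable_fraction = fe$stable_fraction))
  pipeline_log(verbose, "extract: ", nrow(ft$X), " x ", ncol(ft$X), " features")
  # dataset-level outlier report (the CV below refits per training fold)
  outlier_report <- NULL
  if (!is.null(pp$outlier_alpha)) {
    outlier_report <- stage("outliers",
                            remove_outliers(ft$X, ft$labels,
                                            alpha = pp$outlier_alpha)$report)
    pipeline_log(verbose, "outliers: ", length(outlier_report$removed_indices),
                 " of ", nrow(ft$X), " samples beyond the cutoff")
  }
  model_params <- config$model[setdiff(names(config$model), "name")]
  if (!identical(config$model$name, "bpnn")) {
    # baseline learners ignore the network-specific defaults
    model_params <- model_params[setdiff(names(model_params),
                                         c("hidden_sizes", "learning_rate",
                                           "epochs"))]
  }
  tuning <- NULL
  opt <- config$optimizer
  if (!identical(opt$algorithm, "none")) {
    tuning <- stage("tune", {
      base_cfg <- bpnn_config(input_dim = 1L,
                              hidden_sizes = c(8L, 8L),
                              n_classes = length(unique(ft$labels)),
                              learning_rate = config$model$learning_rate,
                              epochs = config$model$epochs,
                              seed = config$evaluation$seed)
      # tune in the reduced space the classifier will see
      red <- fit_reduction(config$reduction$method, ft$X, ft$labels,
                           config$reduction$k)
      Xr <- if (is.null(red)) ft$X else predict(red, ft$X)
      base_cfg$input_dim <- ncol(Xr)
      sw <- swarm_config(bounds = rbind(rep(opt$node_low, 2L),
                                        rep(opt$node_high, 2L)),
                         population = opt$population,
                         iterations = opt$iterations,
                         integer_dims = c(TRUE, TRUE),
                         seed = config$evaluation$seed)
      optimize_bpnn_architecture(Xr, ft$labels, algorithm = opt$algorithm,
                                 node_bounds = rbind(rep(opt$node_low, 2L),
                                                     rep(opt$node_high, 2L)),
                                 swarm = sw, base_config = base_cfg,
                                 inner_k = opt$inner_k)
    })
    model_params$hidden_sizes <- tuning$hidden_sizes
    pipeline_log(verbose, "tune (", opt$algorithm, "): hidden sizes [",
                 paste(tuning$hidden_sizes, collapse = ", "),
                 "], fitness ", format(tuning$result$best_fitness, digits = 4))
  }
  ev <- config$evaluation
  report <- stage("evaluate", cross_validate(
    ft, classifier = config$model$name, classifier_params = model_params,
    reduction = config$reduction$method, reduction_k = config$reduction$k,
    outlier_alpha = pp$outlier_alpha, k = ev$k, seed = ev$seed,
    global_fit = isTRUE(ev$global_fit)))
  pipeline_log(verbose, "evaluate: accuracy ",
               sprintf("%.4f +/- %.4f", report$mean_accuracy,
                       report$std_accuracy))
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_features_csv(ft, file.path(out_dir, "features.csv"))
    if (!is.null(outlier_report)) {
      write_outlier_report_csv(outlier_report, ft$sample_ids,
                               file.path(out_dir, "outlier_report.csv"))
    }
    if (!is.null(tuning)) {
      write_history_csv(tuning$result, file.path(out_dir, "history.csv"))
    }
    utils::write.csv(data.frame(fold = seq_along(report$fold_accuracies),
                                accuracy = report$fold_accuracies),
                     file.path(out_dir, "report.csv"), row.names = FALSE,
                     quote = FALSE)
    utils::write.csv(data.frame(model = report$model,
                                TPR = report$macro_TPR,
                                F1 = report$macro_F1,
                                mean_accuracy = report$mean_accuracy,
                                sd_accuracy = report$std_accuracy,
                                train_time_s = report$train_time_s),
                     file.path(out_dir, "summary.csv"), row.names = FALSE,
                     quote = FALSE)
  }
  list(report = report, features = ft, outlier_report = outlier_report,
       tuning = tuning, dropped_channels = dd$dropped,
       pair_flagged = pair_flagged)
}
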