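#' Stratified k-fold partition
#'
#' Shuffles each class independently and deals its samples round-robin across
#' folds, so per-class counts differ by at most one between folds. Folds are
#' disjoint and their union is the full index set.
#'
#' @param labels per-sample class labels.
#' @param k number of folds (default 10).
#' @param seed integer seed.
#' @return list of k integer vectors (test indices per fold).
#' @export
stratified_kfold <- function(labels, k = 10L, seed = 1L) {
  labels <- as.character(labels)
  k <- as.integer(k)
  if (k < 2L) stop("k must be >= 2")
  set.seed(seed)
  folds <- vector("list", k)
  offset <- 0L
  for (cls in unique(labels)) {
    idx <- which(labels == cls)
    if (length(idx) < k) {
      warning("class '", cls, "' has ", length(idx), " samples for ", k,
              " folds; its stratification is degenerate")
    }
    idx <- idx[sample.int(length(idx))]
    # rotating offset balances fold sizes when class counts are not multiples of k
    assign_to <- ((seq_along(idx) - 1L + offset) %% k) + 1L
    for (f in seq_len(k)) {
      folds[[f]] <- c(folds[[f]], idx[assign_to == f])
    }
    offset <- (offset + length(idx)) %% k
  }
  lapply(folds, sort)
}

#' Confusion matrix of true versus predicted labels
#'
#' @param truth true labels.
#' @param pred predicted labels.
#' @param levels class order (default: union in order of appearance in truth).
#' @return square integer matrix, rows = truth, columns = prediction.
#' @export
confusion_matrix <- function(truth, pred, levels = NULL) {
  truth <- as.character(truth); pred <- as.character(pred)
  if (is.null(levels)) levels <- unique(c(truth, pred))
  tab <- table(factor(truth, levels = levels), factor(pred, levels = levels))
  m <- matrix(as.integer(tab), length(levels), length(levels),
              dimnames = list(truth = levels, predicted = levels))
  m
}

#' Macro-averaged true positive rate (recall)
#'
#' Per-class recall averaged unweighted over classes; classes with zero
#' support are excluded with a warning.
#'
#' @param confusion square confusion matrix, rows = truth.
#' @return proportion in [0, 1].
#' @export
macro_tpr <- function(confusion) {
  support <- rowSums(confusion)
  if (any(support == 0)) {
    warning("excluding zero-support classes: ",
            paste(rownames(confusion)[support == 0], collapse = ", "))
  }
  keep <- support > 0
  mean(diag(as.matrix(confusion))[keep] / support[keep])
}

#' Macro-averaged F1 score
#'
#' Harmonic mean of per-class precision and recall, averaged unweighted over
#' classes with non-zero support. A class never predicted and never recalled
#' contributes an F1 of 0.
#'
#' @param confusion square confusion matrix, rows = truth.
#' @return score in [0, 1].
#' @export
macro_f1 <- function(confusion) {
  confusion <- as.matrix(confusion)
  support <- rowSums(confusion)
  if (any(support == 0)) {
    warning("excluding zero-support classes: ",
            paste(rownames(confusion)[support == 0], collapse = ", "))
  }
  keep <- which(support > 0)
  f1 <- vapply(keep, function(i) {
    tp <- confusion[i, i]
    prec_den <- sum(confusion[, i])
    rec_den <- support[i]
    p <- if (prec_den > 0) tp / prec_den else 0
    r <- tp / rec_den
    if (p + r == 0) 0 else 2 * p * r / (p + r)
  }, numeric(1L))
  mean(f1)
}

#' Fit a classifier by name on a feature matrix
#'
#' Unified front for the bespoke back-propagation network and the standard
#' baseline learners (k-nearest neighbours, RBF support vector machine,
#' random forest).
#'
#' @param name "bpnn", "knn", "svm" or "rf".
#' @param X training matrix.
#' @param labels training labels.
#' @param params list of hyperparameters: for bpnn a \code{\link{bpnn_config}}
#'   or its fields; knn takes \code{k} (default 5); svm and rf pass through to
#'   \code{e1071::svm} / \code{randomForest::randomForest}.
#' @param seed integer seed.
#' @return object of class \code{enose_classifier}.
#' @export
fit_classifier <- function(name, X, labels, params = list(), seed = 1L) {
  name <- match.arg(name, c("bpnn", "knn", "svm", "rf"))
  X <- as.matrix(X)
  labels <- as.character(labels)
  fitted <- switch(name,
    bpnn = {
      cfg <- if (inherits(params, "bpnn_config")) params else {
        do.call(bpnn_config, c(list(input_dim = ncol(X),
                                    n_classes = length(unique(labels)),
                                    seed = seed),
                               params))
      }
      cfg$input_dim <- ncol(X)
      train_bpnn(cfg, X, labels)
    },
    knn = list(X = X, labels = labels,
               k = if (is.null(params$k)) 5L else params$k),
    svm = do.call(e1071::svm,
                  c(list(x = X, y = factor(labels), kernel = "radial",
                         probability = FALSE), params)),
    rf = {
      set.seed(seed)
      do.call(randomForest::randomForest,
              c(list(x = X, y = factor(labels)), params))
    })
  structure(list(name = name, fit = fitted), class = "enose_classifier")
}

#' @export
predict.enose_classifier <- function(object, newdata, ...) {
  X <- as.matrix(newdata)
  switch(object$name,
    bpnn = predict(object$fit, X),
    knn = as.character(class::knn(object$fit$X, X,
                                  factor(object$fit$labels),
                                  k = object$fit$k)),
    svm = as.character(predict(object$fit, X)),
    rf = as.character(predict(object$fit, X)))
}

#' Cross-validation report
#'
#' @param fold_accuracies per-fold accuracies.
#' @param confusion summed confusion matrix over all test folds.
#' @param train_time_s total wall-clock training time in seconds.
#' @param model_name classifier name.
#' @return object of class \code{cv_report}: per-fold accuracies, their mean
#'   and sample standard deviation, macro TPR, macro F1, the pooled confusion
#'   matrix and training time.
#' @export
cv_report <- function(fold_accuracies, confusion, train_time_s = NA_real_,
                      model_name = "model") {
  structure(list(model = model_name,
                 fold_accuracies = fold_accuracies,
                 mean_accuracy = mean(fold_accuracies),
                 std_accuracy = stats::sd(fold_accuracies),
                 macro_TPR = macro_tpr(confusion),
                 macro_F1 = macro_f1(confusion),
                 confusion = confusion,
                 train_time_s = train_time_s),
            class = "cv_report")
}

#' @export
print.cv_report <- function(x, ...) {
  cat("<cv_report> ", x$model, ": accuracy ",
      sprintf("%.4f +/- %.4f", x$mean_accuracy, x$std_accuracy),
      " over ", length(x$fold_accuracies), " folds; macro TPR ",
      sprintf("%.4f", x$macro_TPR), ", macro F1 ",
      sprintf("%.4f", x$macro_F1), ", train time ",
      sprintf("%.2f", x$train_time_s), " s\n", sep = "")
  invisible(x)
}

#' Stratified k-fold cross-validation of a feature-space pipeline
#'
#' For every fold: outlier removal, the reduction projection and the
#' classifier are fit on the training portion only; the held-out fold is
#' projected through the training-fold model and scored. A leakage guard
#' verifies that no test row reached any fitting step. With
#' \code{global_fit = TRUE} the outlier removal and projection are instead fit
#' once on the full dataset before folding (the statistically optimistic
#' variant some studies use); the guard is then bypassed by construction.
#'
#' @param ft a \code{\link{feature_table}}.
#' @param classifier classifier name ("bpnn", "knn", "svm", "rf").
#' @param classifier_params hyperparameters for \code{\link{fit_classifier}}.
#' @param reduction "lda", "pca", "fa" or "none" (default "lda").
#' @param reduction_k target dimension (method default when NULL).
#' @param outlier_alpha chi-square tail probability for training-fold outlier
#'   removal; NULL disables the stage.
#' @param k number of folds (default 10).
#' @param seed integer seed (folds, classifier initialisation).
#' @param global_fit fit outlier removal and reduction on all data first
#'   (default FALSE).
#' @return a \code{\link{cv_report}}.
#' @export
cross_validate <- function(ft, classifier = "bpnn", classifier_params = list(),
                           reduction = "lda", reduction_k = NULL,
                           outlier_alpha = NULL, k = 10L, seed = 1L,
                           global_fit = FALSE) {
  stopifnot(inherits(ft, "feature_table"))
  n <- nrow(ft$X)
  levels <- unique(ft$labels)
  folds <- stratified_kfold(ft$labels, k = k, seed = seed)
  if (global_fit) {
    Xg <- ft$X; lg <- ft$labels
    if (!is.null(outlier_alpha)) {
      cleaned <- remove_outliers(Xg, lg, alpha = outlier_alpha)
      keep <- setdiff(seq_len(n), cleaned$report$removed_indices)
      ft <- ft_rows(ft, keep)
      folds <- stratified_kfold(ft$labels, k = k, seed = seed)
      n <- nrow(ft$X)
    }
    gmodel <- fit_reduction(reduction, ft$X, ft$labels, reduction_k)
  }
  fold_acc <- numeric(length(folds))
  confusion <- matrix(0L, length(levels), length(levels),
                      dimnames = list(truth = levels, predicted = levels))
  t_train <- 0
  for (f in seq_along(folds)) {
    test_idx <- folds[[f]]
    train_idx <- setdiff(seq_len(n), test_idx)
    if (length(intersect(train_idx, test_idx))) {
      stop("leakage guard: training rows overlap the held-out fold")
    }
    Xtr <- ft$X[train_idx, , drop = FALSE]
    ytr <- ft$labels[train_idx]
    if (!global_fit && !is.null(outlier_alpha)) {
      cleaned <- remove_outliers(Xtr, ytr, alpha = outlier_alpha)
      Xtr <- cleaned$X; ytr <- cleaned$labels
    }
    pm <- if (global_fit) gmodel
          else fit_reduction(reduction, Xtr, ytr, reduction_k)
    if (!is.null(pm)) {
      if (!global_fit && nrow(Xtr) > length(train_idx)) {
        stop("leakage guard: projection fit saw more rows than the training fold")
      }
      Xtr_r <- predict(pm, Xtr)
      Xte_r <- predict(pm, ft$X[test_idx, , drop = FALSE])
    } else {
      Xtr_r <- Xtr
      Xte_r <- ft$X[test_idx, , drop = FALSE]
    }
    t0 <- proc.time()[["elapsed"]]
    clf <- fit_classifier(classifier, Xtr_r, ytr,
                          params = classifier_params, seed = seed + f)
    t_train <- t_train + (proc.time()[["elapsed"]] - t0)
    pred <- predict(clf, Xte_r)
    truth <- ft$labels[test_idx]
    fold_acc[f] <- mean(pred == truth)
    confusion <- confusion + confusion_matrix(truth, pred, levels = levels)
  }
  cv_report(fold_acc, confusion, t_train, model_name = classifier)
}
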