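#' Linear projection model shared by PCA, FA and LDA
#'
#' All three reducers return this common structure so downstream stages can
#' treat them interchangeably: new data is projected as
#' \code{(X - mean) \%*\% components} (with a per-column scaling for FA, which
#' is fit on the correlation matrix).
#'
#' @param method one of "pca", "fa", "lda".
#' @param mean d-vector of column means of the training data.
#' @param components d x k matrix with unit-norm columns.
#' @param explained per-component score: variance ratio for PCA, Fisher
#'   eigenvalue for LDA, eigenvalue share of the reduced correlation for FA.
#' @param scale optional d-vector of column scales applied before projecting
#'   (FA only).
#' @param extra method-specific fields (e.g. FA communalities).
#' @return object of class \code{projection_model}.
#' @keywords internal
projection_model <- function(method, mean, components, explained,
                             scale = NULL, extra = list()) {
  structure(c(list(method = method, mean = mean,
                   components = components, k = ncol(components),
                   explained = explained, scale = scale),
              extra),
            class = "projection_model")
}

# Fix eigenvector sign so each column's largest-magnitude entry is positive,
# making the decomposition deterministic.
fix_signs <- function(V) {
  for (j in seq_len(ncol(V))) {
    i <- which.max(abs(V[, j]))
    if (V[i, j] < 0) V[, j] <- -V[, j]
  }
  V
}

#' Principal component analysis
#'
#' Eigendecomposition of the covariance of the centred data; components are
#' the top-k eigenvectors in descending eigenvalue order, with signs fixed so
#' each component's largest-magnitude entry is positive.
#'
#' @param X numeric matrix (n x d).
#' @param k number of components; default: smallest k reaching 95\% explained
#'   variance.
#' @return a \code{projection_model} with \code{explained} the per-component
#'   variance ratios and \code{eigenvalues} the retained eigenvalues.
#' @export
fit_pca <- function(X, k = NULL) {
  X <- as.matrix(X)
  n <- nrow(X); d <- ncol(X)
  if (n < 2L) stop("need at least 2 rows")
  mu <- colMeans(X)
  S <- stats::cov(X)
  eg <- eigen(S, symmetric = TRUE)
  ev <- pmax(eg$values, 0)
  ratio <- if (sum(ev) > 0) ev / sum(ev) else rep(0, d)
  kmax <- min(n - 1L, d)
  if (is.null(k)) {
    k <- min(which(cumsum(ratio) >= 0.95), kmax)
  }
  if (k < 1L || k > kmax) {
    stop("k must lie in 1..min(n-1, d) = 1..", kmax)
  }
  V <- fix_signs(eg$vectors[, seq_len(k), drop = FALSE])
  projection_model("pca", mu, V, ratio[seq_len(k)],
                   extra = list(eigenvalues = ev[seq_len(k)],
                                all_eigenvalues = ev))
}

#' Linear discriminant analysis (Fisher's multiclass criterion)
#'
#' Solves the generalized eigenproblem \eqn{S_B w = \lambda S_W w} with
#' \eqn{S_B} the between-class and \eqn{S_W} the pooled within-class scatter
#' (ridge-regularized when ill-conditioned), keeping the k leading
#' discriminant directions. At most (number of classes - 1) components carry
#' discriminative information.
#'
#' @param X numeric matrix (n x d).
#' @param labels per-row class labels; every class needs >= 2 samples.
#' @param k number of discriminants (default \code{n_classes - 1}).
#' @return a \code{projection_model}; \code{explained} holds the Fisher
#'   eigenvalues.
#' @export
fit_lda <- function(X, labels, k = NULL) {
  X <- as.matrix(X)
  labels <- as.character(labels)
  if (nrow(X) != length(labels)) stop("labels must match rows of X")
  classes <- unique(labels)
  C <- length(classes)
  if (C < 2L) stop("need at least 2 classes")
  if (is.null(k)) k <- C - 1L
  if (k > C - 1L) {
    stop("k = ", k, " exceeds the LDA bound n_classes - 1 = ", C - 1L)
  }
  if (k < 1L) stop("k must be >= 1")
  d <- ncol(X)
  mu <- colMeans(X)
  Sw <- matrix(0, d, d)
  Sb <- matrix(0, d, d)
  for (cls in classes) {
    rows <- which(labels == cls)
    if (length(rows) < 2L) stop("class '", cls, "' has fewer than 2 samples")
    Xc <- X[rows, , drop = FALSE]
    mc <- colMeans(Xc)
    Sw <- Sw + crossprod(sweep(Xc, 2L, mc))
    Sb <- Sb + length(rows) * tcrossprod(mc - mu)
  }
  Sw <- regularize_cov(Sw)
  eg <- eigen(solve(Sw, Sb))
  ord <- order(Re(eg$values), decreasing = TRUE)[seq_len(k)]
  V <- Re(eg$vectors[, ord, drop = FALSE])
  V <- sweep(V, 2L, sqrt(colSums(V^2)), "/")
  V <- fix_signs(V)
  projection_model("lda", mu, V, Re(eg$values[ord]))
}

#' Factor analysis by iterated principal factors
#'
#' Fits a k-factor model on the correlation matrix: communalities are
#' initialised from squared multiple correlations and refined by repeated
#' eigendecomposition of the reduced correlation matrix until they stabilise.
#' Deterministic given X.
#'
#' @param X numeric matrix (n x d).
#' @param k number of factors (default 3).
#' @param max_iter iteration cap (default 200).
#' @param tol convergence tolerance on the communalities (default 1e-6).
#' @return a \code{projection_model}; \code{components} are the unit-norm
#'   loading directions, \code{loadings} the raw loadings, \code{communalities}
#'   the fitted communalities. The stored \code{scale} makes \code{predict}
#'   operate on standardised data.
#' @export
fit_fa <- function(X, k = 3L, max_iter = 200L, tol = 1e-6) {
  X <- as.matrix(X)
  d <- ncol(X)
  if (k < 1L || k > d) stop("k must lie in 1..d")
  mu <- colMeans(X)
  sds <- apply(X, 2L, stats::sd)
  if (any(sds <= 0)) stop("constant columns cannot be factor-analysed")
  R <- stats::cor(X)
  # initial communalities: squared multiple correlations, with a ridge
  # fallback when R is singular
  h2 <- tryCatch(1 - 1 / diag(solve(R)),
                 error = function(e) apply(abs(R - diag(d)), 1L, max))
  h2 <- pmin(pmax(h2, 0.05), 0.995)
  converged <- FALSE
  L <- NULL
  for (it in seq_len(max_iter)) {
    Rr <- R
    diag(Rr) <- h2
    eg <- eigen(Rr, symmetric = TRUE)
    ev <- eg$values[seq_len(k)]
    L <- eg$vectors[, seq_len(k), drop = FALSE] %*%
      diag(sqrt(pmax(ev, 0)), k)
    h2_new <- pmin(rowSums(L^2), 0.995)
    if (max(abs(h2_new - h2)) < tol) {
      h2 <- h2_new
      converged <- TRUE
      break
    }
    h2 <- h2_new
  }
  if (!converged) {
    stop("principal-factor iteration did not converge in ", max_iter,
         " iterations")
  }
  L <- fix_signs(L)
  V <- sweep(L, 2L, sqrt(colSums(L^2)), "/")
  ev <- pmax(eigen(`diag<-`(R, h2), symmetric = TRUE,
                   only.values = TRUE)$values[seq_len(k)], 0)
  projection_model("fa", mu, V, ev / d, scale = sds,
                   extra = list(loadings = L, communalities = h2,
                                iterations = it))
}

#' Project data through a fitted reduction model
#'
#' @param object a \code{projection_model}.
#' @param newdata numeric matrix with the training dimensionality.
#' @param ... unused.
#' @return n x k matrix of projected coordinates.
#' @export
predict.projection_model <- function(object, newdata, ...) {
  X <- as.matrix(newdata)
  if (ncol(X) != length(object$mean)) {
    stop("newdata has ", ncol(X), " columns; model expects ",
         length(object$mean))
  }
  Xc <- sweep(X, 2L, object$mean)
  if (!is.null(object$scale)) Xc <- sweep(Xc, 2L, object$scale, "/")
  Xc %*% object$components
}

#' @rdname predict.projection_model
#' @param model a \code{projection_model}.
#' @param X data matrix.
#' @export
project_features <- function(model, X) predict(model, X)

#' Reconstruct data from PCA scores
#'
#' @param model a PCA \code{projection_model}.
#' @param scores n x k score matrix.
#' @return n x d reconstruction in the original space.
#' @export
pca_reconstruct <- function(model, scores) {
  if (!identical(model$method, "pca")) stop("reconstruction requires a PCA model")
  sweep(as.matrix(scores) %*% t(model$components), 2L, model$mean, "+")
}

#' @export
print.projection_model <- function(x, ...) {
  cat("<projection_model> ", toupper(x$method), ", ", length(x$mean),
      " -> ", x$k, " dims; explained: ",
      paste(format(x$explained, digits = 3), collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Fit a reduction model by name
#'
#' Dispatch helper used by the pipeline configuration.
#'
#' @param method "pca", "fa", "lda" or "none".
#' @param X data matrix.
#' @param labels class labels (needed for LDA).
#' @param k target dimension (method-specific default when NULL).
#' @return a \code{projection_model}, or NULL when \code{method = "none"}.
#' @export
fit_reduction <- function(method, X, labels = NULL, k = NULL) {
  switch(match.arg(method, c("pca", "fa", "lda", "none")),
         pca = fit_pca(X, k),
         fa = fit_fa(X, if (is.null(k)) 3L else k),
         lda = fit_lda(X, labels, k),
         none = NULL)
}
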