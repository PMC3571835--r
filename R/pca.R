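#' Principal component analysis of a spectrum matrix
#'
#' Fits mean-centred PCA by singular value decomposition of the centred data
#' matrix (numerically stabler than eigendecomposing the covariance matrix;
#' the two agree up to column signs). The sign of each loading is fixed so
#' that its largest-magnitude element is positive, which makes fitted models
#' reproducible across platforms.
#'
#' @param X numeric matrix, n samples x p variables (bands), n >= 2.
#' @param k number of components to retain, `k <= min(n - 1, p)`.
#' @return An object of class `pca_model`: list with `mean` (length p),
#'   `loadings` (p x k, orthonormal columns), `explained_variance_ratio`
#'   (length k, fractions of total variance), and the training `scores`
#'   (n x k).
#' @seealso [project_pca()], [fit_kpca()]
#' @examples
#' X <- cbind(1:6, 2 * (1:6))          # rank-1 data on the line y = 2x
#' fit_pca(X, 1)$explained_variance_ratio
#' @export
fit_pca <- function(X, k = 3) {
  X <- as.matrix(X)
  n <- nrow(X); p <- ncol(X)
  if (n < 2L) stop("PCA needs at least 2 samples")
  if (k < 1L || k > min(n - 1L, p))
    stop("`k` must be between 1 and min(n - 1, p) = ", min(n - 1L, p))
  mu <- colMeans(X)
  Xc <- sweep(X, 2L, mu)
  sv <- svd(Xc, nu = k, nv = k)
  total <- sum(sv$d^2)
  evr <- if (total > 0) (sv$d^2 / total)[seq_len(k)] else rep(0, k)
  loadings <- sv$v
  scores <- Xc %*% loadings
  flip <- apply(loadings, 2L, function(v) sign(v[which.max(abs(v))]))
  flip[flip == 0] <- 1
  loadings <- sweep(loadings, 2L, flip, `*`)
  scores <- sweep(scores, 2L, flip, `*`)
  colnames(loadings) <- colnames(scores) <- paste0("pc_", seq_len(k))
  structure(list(mean = mu, loadings = loadings,
                 explained_variance_ratio = evr, scores = scores),
            class = "pca_model")
}

#' @export
print.pca_model <- function(x, ...) {
  cat(sprintf("<pca_model> %d variables -> %d components\n",
              length(x$mean), ncol(x$loadings)))
  cat("explained variance ratio:",
      paste(sprintf("%.4f", x$explained_variance_ratio), collapse = " "), "\n")
  invisible(x)
}

#' Project new samples onto fitted principal components
#'
#' Scores are `(X - mean) %*% loadings`.
#'
#' @param model a [fit_pca()] model.
#' @param X numeric matrix, m x p with p matching the model.
#' @return m x k score matrix.
#' @export
project_pca <- function(model, X) {
  stopifnot(inherits(model, "pca_model"))
  if (is.null(dim(X))) X <- matrix(X, nrow = 1L)
  X <- as.matrix(X)
  if (ncol(X) != length(model$mean))
    stop("column count does not match the fitted band count")
  sweep(X, 2L, model$mean) %*% model$loadings
}

#' @param object,newdata,... standard predict arguments; `newdata` defaults
#'   to the training scores.
#' @rdname project_pca
#' @export
predict.pca_model <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) return(object$scores)
  project_pca(object, newdata)
}

#' Kernel principal component analysis with an RBF kernel
#'
#' Performs PCA implicitly in the feature space induced by the Gaussian
#' kernel `K(u, v) = exp(-||u - v||^2 / (2 * sigma2_k))`: the training
#' kernel matrix is double-centred, eigendecomposed, and the eigenvectors
#' rescaled by `1/sqrt(eigenvalue)` so each feature-space component has unit
#' norm. Scores of training point i are row i of `Kc %*% alphas`.
#'
#' `sigma2_k = "auto"` applies the median heuristic (median of pairwise
#' squared distances). `kernel = "linear"` replaces the RBF kernel with the
#' plain inner product, in which case KPCA reduces exactly to [fit_pca()]
#' scores (up to column signs) — useful for validation.
#'
#' @param X numeric matrix, n x p, n >= 3.
#' @param sigma2_k positive kernel width (variance scale) or `"auto"`.
#' @param k number of components, `k <= n - 1`; silently reduced (with a
#'   recorded warning) if fewer positive eigenvalues exist.
#' @param kernel `"rbf"` (default) or `"linear"`.
#' @return An object of class `kpca_model`: `training_X`, `sigma2_k`,
#'   `alphas` (n x k), `eigenvalues`, centring statistics (`row_means`,
#'   `grand_mean`), training `scores` and a `warnings` character vector.
#' @export
fit_kpca <- function(X, sigma2_k = "auto", k = 3, kernel = c("rbf", "linear")) {
  kernel <- match.arg(kernel)
  X <- as.matrix(X)
  n <- nrow(X)
  if (n < 3L) stop("KPCA needs at least 3 samples")
  if (k < 1L || k > n - 1L) stop("`k` must be between 1 and n - 1")
  warnings <- character(0)

  if (kernel == "rbf") {
    D <- sq_dists(X, X)
    if (identical(sigma2_k, "auto")) {
      sigma2_k <- stats::median(D[upper.tri(D)])
      if (!is.finite(sigma2_k) || sigma2_k <= 0) sigma2_k <- 1
    }
    if (!is.numeric(sigma2_k) || sigma2_k <= 0)
      stop("`sigma2_k` must be a positive number or \"auto\"")
    K <- exp(-D / (2 * sigma2_k))
  } else {
    sigma2_k <- NA_real_
    K <- tcrossprod(X)
  }

  row_means <- rowMeans(K)
  grand <- mean(K)
  Kc <- K - outer(row_means, rep(1, n)) - outer(rep(1, n), row_means) + grand
  eig <- eigen(Kc, symmetric = TRUE)
  pos <- which(eig$values > max(eig$values[1L], 0) * 1e-12 & eig$values > 0)
  k_eff <- min(k, length(pos))
  if (k_eff < k) {
    warnings <- c(warnings, sprintf(
      "only %d positive eigenvalues; k reduced from %d to %d",
      length(pos), k, k_eff))
    k <- k_eff
  }
  if (k < 1L) stop("centred kernel has no positive eigenvalues")
  vals <- eig$values[seq_len(k)]
  alphas <- sweep(eig$vectors[, seq_len(k), drop = FALSE], 2L,
                  sqrt(vals), `/`)
  flip <- apply(alphas, 2L, function(v) sign(v[which.max(abs(v))]))
  flip[flip == 0] <- 1
  alphas <- sweep(alphas, 2L, flip, `*`)
  scores <- Kc %*% alphas
  colnames(alphas) <- colnames(scores) <- paste0("kpc_", seq_len(k))
  structure(list(training_X = X, sigma2_k = sigma2_k, kernel = kernel,
                 alphas = alphas, eigenvalues = vals, row_means = row_means,
                 grand_mean = grand, scores = scores, warnings = warnings),
            class = "kpca_model")
}

#' @export
print.kpca_model <- function(x, ...) {
  cat(sprintf("<kpca_model> %s kernel, %d training samples -> %d components\n",
              x$kernel, nrow(x$training_X), ncol(x$alphas)))
  if (x$kernel == "rbf") cat(sprintf("sigma2_k = %.6g\n", x$sigma2_k))
  invisible(x)
}

#' Out-of-sample kernel PCA projection
#'
#' Kernel rows of the new samples against the training set are centred with
#' the stored training statistics and multiplied by the scaled eigenvectors;
#' projecting the training data reproduces the fit-time scores.
#'
#' @param model a [fit_kpca()] model.
#' @param X numeric matrix, m x p (m may be 0).
#' @return m x k score matrix.
#' @export
project_kpca <- function(model, X) {
  stopifnot(inherits(model, "kpca_model"))
  p <- ncol(model$training_X)
  if (is.null(dim(X))) {
    X <- if (length(X)) matrix(X, nrow = 1L) else matrix(numeric(0), 0L, p)
  }
  X <- as.matrix(X)
  if (ncol(X) != p)
    stop("column count does not match the fitted band count")
  if (nrow(X) == 0L)
    return(matrix(numeric(0), 0L, ncol(model$alphas),
                  dimnames = list(NULL, colnames(model$alphas))))
  K <- if (model$kernel == "rbf") {
    exp(-sq_dists(X, model$training_X) / (2 * model$sigma2_k))
  } else {
    tcrossprod(X, model$training_X)
  }
  Kc <- K - matrix(rowMeans(K), nrow(K), ncol(K)) -
    matrix(model$row_means, nrow(K), ncol(K), byrow = TRUE) +
    model$grand_mean
  Kc %*% model$alphas
}

#' @rdname project_kpca
#' @param object,newdata,... standard predict arguments.
#' @export
predict.kpca_model <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) return(object$scores)
  project_kpca(object, newdata)
}

# Pairwise squared Euclidean distances between rows of A and rows of B.
sq_dists <- function(A, B) {
  an <- rowSums(A^2)
  bn <- rowSums(B^2)
  D <- outer(an, bn, `+`) - 2 * tcrossprod(A, B)
  D[D < 0] <- 0
  D
}
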