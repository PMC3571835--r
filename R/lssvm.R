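# RBF kernel as used by the LS-SVM: K(u, v) = exp(-||u - v||^2 / sigma2).
# Note the parameterization: sigma2 divides the squared distance directly
# (no factor 2), so the grid-searched sigma2 matches the conventional
# chemometrics symbol. KPCA in this package uses the 2*sigma2 form instead.
lssvm_kernel <- function(A, B, sigma2) exp(-sq_dists(A, B) / sigma2)

# Solve the LS-SVM dual for a precomputed kernel block:
#   [[0, y'], [y, Omega + I/gamma]] [b; alpha] = [0; 1],  Omega = (y y') * K
lssvm_solve <- function(K, y, gamma) {
  n <- length(y)
  Omega <- (y %o% y) * K
  A <- rbind(c(0, y), cbind(y, Omega + diag(n) / gamma))
  sol <- tryCatch(solve(A, c(0, rep(1, n))),
                  error = function(e)
                    stop("LS-SVM system is singular; a larger gamma ",
                         "jitter may help (", conditionMessage(e), ")",
                         call. = FALSE))
  sol <- unname(sol)
  list(b = sol[1L], alpha = sol[-1L])
}

#' Fit a binary least-squares SVM with RBF kernel
#'
#' The LS-SVM replaces the quadratic program of the classical SVM by one
#' linear system: with kernel `K(u, v) = exp(-||u - v||^2 / sigma2)` and
#' `Omega_ij = y_i y_j K(x_i, x_j)`, training solves
#' `[[0, y'], [y, Omega + I/gamma]] [b; alpha] = [0; 1]`. Every training
#' point becomes a support vector; the decision value of a query x is
#' `f(x) = sum_i alpha_i y_i K(x_i, x) + b`.
#'
#' @param X numeric matrix, n x d.
#' @param y labels in `{-1, +1}`, both classes present.
#' @param gamma regularization weight, > 0 (larger = less regularized).
#' @param sigma2 RBF kernel width, > 0.
#' @return An object of class `lssvm_binary`: `X`, `y`, `alpha`, `b`,
#'   `gamma`, `sigma2`.
#' @export
fit_lssvm_binary <- function(X, y, gamma, sigma2) {
  X <- as.matrix(X)
  y <- as.numeric(y)
  if (!all(y %in% c(-1, 1)) || length(unique(y)) < 2L)
    stop("`y` must contain both -1 and +1 labels")
  if (gamma <= 0 || sigma2 <= 0) stop("`gamma` and `sigma2` must be > 0")
  sol <- lssvm_solve(lssvm_kernel(X, X, sigma2), y, gamma)
  structure(list(X = X, y = y, alpha = sol$alpha, b = sol$b,
                 gamma = gamma, sigma2 = sigma2),
            class = "lssvm_binary")
}

#' Decision values of a binary LS-SVM
#'
#' @param model an `lssvm_binary`.
#' @param X query matrix, m x d.
#' @return Numeric vector of length m; positive means the `+1` class.
#' @export
decision_lssvm <- function(model, X) {
  stopifnot(inherits(model, "lssvm_binary"))
  if (is.null(dim(X))) X <- matrix(X, nrow = 1L)
  K <- lssvm_kernel(as.matrix(X), model$X, model$sigma2)
  drop(K %*% (model$alpha * model$y)) + model$b
}

#' Fit a multiclass LS-SVM (one-vs-one)
#'
#' Trains one binary LS-SVM per unordered class pair (`C(C-1)/2` machines
#' for C classes); the earlier class in `classes` is coded +1 in each
#' machine. Prediction is by majority vote with ties broken in favour of
#' the earliest class in `classes`.
#'
#' @param X numeric matrix, n x d.
#' @param y class labels (any atomic type), >= 2 classes.
#' @param gamma,sigma2 shared hyperparameters for all pairwise machines.
#' @param classes optional ordered class vector; defaults to
#'   `sort(unique(y))`.
#' @return An object of class `lssvm`: `classes`, `machines` (named list of
#'   `lssvm_binary`), `gamma`, `sigma2`.
#' @examples
#' X <- rbind(matrix(rnorm(20, 0), 10), matrix(rnorm(20, 4), 10))
#' y <- rep(c("a", "b"), each = 10)
#' fit <- fit_lssvm(X, y, gamma = 10, sigma2 = 4)
#' table(predict(fit, X), y)
#' @export
fit_lssvm <- function(X, y, gamma, sigma2, classes = NULL) {
  X <- as.matrix(X)
  y <- as.character(y)
  if (is.null(classes)) classes <- sort(unique(y))
  classes <- as.character(classes)
  if (length(classes) < 2L) stop("need at least two classes")
  if (!all(y %in% classes)) stop("labels outside `classes`")
  machines <- list()
  for (a in seq_along(classes)) {
    for (b in seq_along(classes)) {
      if (b <= a) next
      idx <- y %in% classes[c(a, b)]
      yy <- ifelse(y[idx] == classes[a], 1, -1)
      machines[[paste(classes[a], classes[b], sep = "|")]] <-
        fit_lssvm_binary(X[idx, , drop = FALSE], yy, gamma, sigma2)
    }
  }
  structure(list(classes = classes, machines = machines, gamma = gamma,
                 sigma2 = sigma2),
            class = "lssvm")
}

#' @export
print.lssvm <- function(x, ...) {
  cat(sprintf(
    "<lssvm> %d classes, %d pairwise machines, gamma = %.4g, sigma2 = %.4g\n",
    length(x$classes), length(x$machines), x$gamma, x$sigma2))
  invisible(x)
}

#' @param object an `lssvm` model.
#' @param newdata query matrix, m x d.
#' @param ... unused.
#' @rdname fit_lssvm
#' @export
predict.lssvm <- function(object, newdata, ...) {
  if (is.null(dim(newdata))) newdata <- matrix(newdata, nrow = 1L)
  newdata <- as.matrix(newdata)
  d <- ncol(object$machines[[1L]]$X)
  if (ncol(newdata) != d)
    stop("newdata has ", ncol(newdata), " columns; model expects ", d)
  votes <- matrix(0L, nrow(newdata), length(object$classes),
                  dimnames = list(NULL, object$classes))
  for (nm in names(object$machines)) {
    pair <- strsplit(nm, "|", fixed = TRUE)[[1L]]
    f <- decision_lssvm(object$machines[[nm]], newdata)
    win <- ifelse(f >= 0, pair[1L], pair[2L])
    for (cl in pair) votes[, cl] <- votes[, cl] + (win == cl)
  }
  object$classes[apply(votes, 1L, which.max)]
}

#' Grid search of LS-SVM hyperparameters by cross-validated RMSE
#'
#' Runs seeded stratified k-fold cross-validation of the one-vs-one LS-SVM
#' over the Cartesian `gamma_grid x sigma2_grid` and scores each pair by
#' RMSECV: the root mean squared difference between the integer class codes
#' (position in the sorted class list) of predicted and true labels over
#' all held-out samples. The default grids are `2^(-1..10)` for gamma and
#' `2^(1..15)` for sigma2. Ties are broken toward smaller `sigma2`, then
#' smaller `gamma` (smoother, more regularized models).
#'
#' @param X numeric matrix, n x d.
#' @param y class labels; every class must have at least `folds` members.
#' @param gamma_grid,sigma2_grid positive numeric grids.
#' @param folds number of CV folds, >= 2.
#' @param seed integer seed controlling the fold assignment.
#' @return An object of class `lssvm_grid`: `best_gamma`, `best_sigma2`,
#'   `cv_surface` (data.frame gamma/sigma2/rmsecv), `folds`, `seed`.
#' @export
grid_search_lssvm <- function(X, y, gamma_grid = 2^(-1:10),
                              sigma2_grid = 2^(1:15), folds = 10,
                              seed = 1) {
  X <- as.matrix(X)
  y <- as.character(y)
  if (length(gamma_grid) < 1L || length(sigma2_grid) < 1L)
    stop("hyperparameter grids must be non-empty")
  if (any(gamma_grid <= 0) || any(sigma2_grid <= 0))
    stop("grids must be positive")
  folds <- as.integer(folds)
  if (folds < 2L) stop("`folds` must be >= 2")
  classes <- sort(unique(y))
  if (min(table(y)) < folds)
    stop("every class needs at least `folds` = ", folds, " members")
  codes <- match(y, classes)

  fold_id <- integer(length(y))
  with_seed(seed, for (cl in classes) {
    idx <- sample(which(y == cl))
    fold_id[idx] <- rep_len(seq_len(folds), length(idx))
  })

  gamma_grid <- sort(gamma_grid)
  sigma2_grid <- sort(sigma2_grid)
  sse <- matrix(0, length(gamma_grid), length(sigma2_grid))
  pairs <- utils::combn(seq_along(classes), 2L)

  for (f in seq_len(folds)) {
    tr <- which(fold_id != f)
    te <- which(fold_id == f)
    ytr <- y[tr]
    Dtr <- sq_dists(X[tr, , drop = FALSE], X[tr, , drop = FALSE])
    Dte <- sq_dists(X[te, , drop = FALSE], X[tr, , drop = FALSE])
    for (si in seq_along(sigma2_grid)) {
      Ktr <- exp(-Dtr / sigma2_grid[si])
      Kte <- exp(-Dte / sigma2_grid[si])
      for (gi in seq_along(gamma_grid)) {
        votes <- matrix(0L, length(te), length(classes))
        for (pp in seq_len(ncol(pairs))) {
          a <- pairs[1L, pp]; b <- pairs[2L, pp]
          sub <- which(ytr %in% classes[c(a, b)])
          yy <- ifelse(ytr[sub] == classes[a], 1, -1)
          sol <- lssvm_solve(Ktr[sub, sub, drop = FALSE], yy,
                             gamma_grid[gi])
          fval <- drop(Kte[, sub, drop = FALSE] %*% (sol$alpha * yy)) +
            sol$b
          win <- ifelse(fval >= 0, a, b)
          votes[cbind(seq_along(te), win)] <-
            votes[cbind(seq_along(te), win)] + 1L
        }
        pred_code <- apply(votes, 1L, which.max)
        sse[gi, si] <- sse[gi, si] + sum((pred_code - codes[te])^2)
      }
    }
  }

  rmsecv <- sqrt(sse / length(y))
  surface <- data.frame(gamma = rep(gamma_grid, times = length(sigma2_grid)),
                        sigma2 = rep(sigma2_grid, each = length(gamma_grid)),
                        rmsecv = as.vector(rmsecv))
  best <- c(1L, 1L); best_val <- Inf
  for (si in seq_along(sigma2_grid)) {
    for (gi in seq_along(gamma_grid)) {
      if (rmsecv[gi, si] < best_val) {
        best_val <- rmsecv[gi, si]
        best <- c(gi, si)
      }
    }
  }
  structure(list(best_gamma = gamma_grid[best[1L]],
                 best_sigma2 = sigma2_grid[best[2L]],
                 cv_surface = surface, folds = folds, seed = seed),
            class = "lssvm_grid")
}

#' @export
print.lssvm_grid <- function(x, ...) {
  cat(sprintf(
    "<lssvm_grid> %d-fold CV over %d points; best gamma = %.4g, sigma2 = %.4g (RMSECV %.4f)\n",
    x$folds, nrow(x$cv_surface), x$best_gamma, x$best_sigma2,
    min(x$cv_surface$rmsecv)))
  invisible(x)
}
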