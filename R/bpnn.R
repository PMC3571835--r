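#' Fit a momentum back-propagation neural network
#'
#' A single-hidden-layer feed-forward network (d inputs -> `hidden` logistic
#' units -> one logistic output unit per class) trained by full-batch
#' gradient descent with classical momentum on the mean squared error
#' against one-hot targets. Training stops when the MSE reaches `goal_mse`
#' or after `max_epochs` epochs. Weights are initialized uniform(-0.5, 0.5)
#' from the seeded RNG, so fits are exactly reproducible.
#'
#' Inputs are min-max scaled to [0, 1] per column with training-set ranges
#' by default (`scale = TRUE`), the standard conditioning step for sigmoid
#' networks; the ranges are stored and reapplied at prediction time.
#'
#' @param X numeric matrix, n x d.
#' @param labels class labels; one-hot targets are built over
#'   `sort(unique(labels))`.
#' @param hidden hidden unit count (a 2000s-era seed study would use ~9).
#' @param learn_rate gradient step size.
#' @param momentum momentum coefficient in [0, 1) (the "dynamic parameter").
#' @param goal_mse target mean squared error.
#' @param max_epochs maximum training epochs.
#' @param seed integer seed for weight initialization.
#' @param scale logical; min-max scale inputs with training ranges.
#' @return An object of class `bpnn`: weight matrices `W1` (d x H), `W2`
#'   (H x C), biases `b1`, `b2`, `classes`, the `training_curve` of MSE per
#'   epoch, `epochs` run, and the configuration.
#' @export
fit_bpnn <- function(X, labels, hidden = 9, learn_rate = 0.5,
                     momentum = 0.6, goal_mse = 1e-5, max_epochs = 1000,
                     seed = 1, scale = TRUE) {
  X <- as.matrix(X)
  labels <- as.character(labels)
  if (hidden < 1L) stop("`hidden` must be >= 1")
  if (momentum < 0 || momentum >= 1) stop("`momentum` must be in [0, 1)")
  classes <- sort(unique(labels))
  if (length(classes) < 2L) stop("need at least two classes")
  n <- nrow(X); d <- ncol(X); C <- length(classes)
  Tg <- matrix(0, n, C)
  Tg[cbind(seq_len(n), match(labels, classes))] <- 1

  scale_min <- rep(0, d); scale_rng <- rep(1, d)
  if (scale) {
    scale_min <- apply(X, 2L, min)
    scale_rng <- apply(X, 2L, max) - scale_min
    scale_rng[scale_rng == 0] <- 1
  }
  Xs <- sweep(sweep(X, 2L, scale_min), 2L, scale_rng, `/`)

  init <- with_seed(seed, list(
    W1 = matrix(stats::runif(d * hidden, -0.5, 0.5), d, hidden),
    b1 = stats::runif(hidden, -0.5, 0.5),
    W2 = matrix(stats::runif(hidden * C, -0.5, 0.5), hidden, C),
    b2 = stats::runif(C, -0.5, 0.5)))
  W1 <- init$W1; b1 <- init$b1; W2 <- init$W2; b2 <- init$b2
  dW1 <- matrix(0, d, hidden); db1 <- rep(0, hidden)
  dW2 <- matrix(0, hidden, C); db2 <- rep(0, C)
  sigm <- function(z) 1 / (1 + exp(-z))

  curve <- numeric(0)
  epoch <- 0L
  while (epoch < max_epochs) {
    epoch <- epoch + 1L
    H <- sigm(sweep(Xs %*% W1, 2L, b1, `+`))
    O <- sigm(sweep(H %*% W2, 2L, b2, `+`))
    E <- O - Tg
    mse <- mean(E^2)
    if (!is.finite(mse))
      stop("BPNN training diverged (non-finite loss at epoch ", epoch, ")")
    curve <- c(curve, mse)
    if (mse <= goal_mse) break
    # classical delta rule, averaged per sample (summed over output units)
    dO <- (1 / n) * E * O * (1 - O)
    dH <- (dO %*% t(W2)) * H * (1 - H)
    dW2 <- momentum * dW2 - learn_rate * crossprod(H, dO)
    db2 <- momentum * db2 - learn_rate * colSums(dO)
    dW1 <- momentum * dW1 - learn_rate * crossprod(Xs, dH)
    db1 <- momentum * db1 - learn_rate * colSums(dH)
    W2 <- W2 + dW2; b2 <- b2 + db2
    W1 <- W1 + dW1; b1 <- b1 + db1
  }

  structure(list(W1 = W1, b1 = b1, W2 = W2, b2 = b2, classes = classes,
                 hidden = hidden, learn_rate = learn_rate,
                 momentum = momentum, goal_mse = goal_mse,
                 max_epochs = max_epochs, seed = seed,
                 scale_min = scale_min, scale_rng = scale_rng,
                 training_curve = curve, epochs = epoch),
            class = "bpnn")
}

#' @export
print.bpnn <- function(x, ...) {
  cat(sprintf(
    "<bpnn> %d-%d-%d network, momentum %.2f; %d epochs, final MSE %.3g\n",
    nrow(x$W1), x$hidden, length(x$classes), x$momentum, x$epochs,
    utils::tail(x$training_curve, 1)))
  invisible(x)
}

# The +/-0.5 recognition band on one-hot outputs: a sample is assigned class
# c only when output unit c lies within 0.5 of 1 and every other unit lies
# within 0.5 of 0; otherwise it is unrecognized (NA label).
bpnn_decide <- function(O, classes) {
  lab <- rep(NA_character_, nrow(O))
  for (r in seq_len(nrow(O))) {
    near1 <- which(abs(O[r, ] - 1) < 0.5)
    if (length(near1) == 1L && all(abs(O[r, -near1]) < 0.5))
      lab[r] <- classes[near1]
  }
  lab
}

#' Predict classes with a BPNN and the +/-0.5 recognition rule
#'
#' Runs the forward pass and applies the one-hot recognition band: a sample
#' is assigned class c when output unit c is within 0.5 of 1 *and* all
#' other units are within 0.5 of 0; otherwise it is flagged unrecognized
#' (`NA` label, `valid = FALSE`), which downstream accuracy counts as an
#' error.
#'
#' @param object a [fit_bpnn()] model.
#' @param newdata numeric matrix, m x d.
#' @param ... unused.
#' @return List with `labels` (character, `NA` when unrecognized), `valid`
#'   (logical) and `outputs` (m x C matrix of unit activations).
#' @export
predict.bpnn <- function(object, newdata, ...) {
  if (is.null(dim(newdata))) newdata <- matrix(newdata, nrow = 1L)
  newdata <- as.matrix(newdata)
  if (ncol(newdata) != nrow(object$W1))
    stop("newdata has ", ncol(newdata), " columns; model expects ",
         nrow(object$W1))
  Xs <- sweep(sweep(newdata, 2L, object$scale_min), 2L, object$scale_rng,
              `/`)
  sigm <- function(z) 1 / (1 + exp(-z))
  H <- sigm(sweep(Xs %*% object$W1, 2L, object$b1, `+`))
  O <- sigm(sweep(H %*% object$W2, 2L, object$b2, `+`))
  colnames(O) <- object$classes
  labels <- bpnn_decide(O, object$classes)
  list(labels = labels, valid = !is.na(labels), outputs = O)
}
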