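test_that("binary LS-SVM separates trivial data and satisfies the dual", {
  X <- rbind(c(-5, 0), c(5, 0))
  y <- c(-1, 1)
  fit <- fit_lssvm_binary(X, y, gamma = 10, sigma2 = 4)
  f <- decision_lssvm(fit, X)
  expect_identical(sign(f), y)
  expect_lt(abs(sum(fit$alpha * fit$y)), 1e-8)
  expect_error(fit_lssvm_binary(X, c(1, 1), 1, 1), "both")
  expect_error(fit_lssvm_binary(X, y, -1, 1), "gamma")
})

test_that("the LS-SVM solution matches a direct dense solve", {
  for (seed in 1:10) {
    set.seed(seed)
    X <- matrix(rnorm(12), 6, 2)
    y <- rep(c(1, -1), 3)
    gamma <- runif(1, 0.5, 20); sigma2 <- runif(1, 0.5, 10)
    fit <- fit_lssvm_binary(X, y, gamma, sigma2)
    # oracle: assemble the (n+1) system explicitly and solve generically
    K <- exp(-as.matrix(stats::dist(X))^2 / sigma2)
    Omega <- outer(y, y) * K
    A <- rbind(c(0, y), cbind(y, Omega + diag(6) / gamma))
    sol <- unname(solve(A, c(0, rep(1, 6))))
    expect_equal(fit$b, sol[1], tolerance = 1e-10)
    expect_equal(fit$alpha, sol[-1], tolerance = 1e-10)
    # residual of the linear system
    expect_lt(max(abs(A %*% c(fit$b, fit$alpha) - c(0, rep(1, 6)))), 1e-8)
  }
})

test_that("decision values are invariant to training permutation", {
  set.seed(51)
  X <- matrix(rnorm(30), 15, 2)
  y <- rep(c(1, -1), length.out = 15)
  q <- matrix(rnorm(10), 5, 2)
  fit1 <- fit_lssvm_binary(X, y, 5, 2)
  perm <- sample(15)
  fit2 <- fit_lssvm_binary(X[perm, ], y[perm], 5, 2)
  expect_equal(decision_lssvm(fit1, q), decision_lssvm(fit2, q),
               tolerance = 1e-8)
})

test_that("one-vs-one multiclass LS-SVM classifies a separable toy set", {
  set.seed(52)
  centers <- rbind(c(0, 0), c(6, 0), c(0, 6))
  X <- do.call(rbind, lapply(1:3, function(i)
    sweep(matrix(rnorm(20, sd = 0.3), 10, 2), 2, centers[i, ], `+`)))
  y <- rep(c("a", "b", "c"), each = 10)
  fit <- fit_lssvm(X, y, gamma = 10, sigma2 = 4)
  expect_length(fit$machines, 3L)
  expect_identical(predict(fit, X), y)
  # duplicate queries predict identically
  q <- rbind(X[3, ], X[3, ])
  expect_identical(predict(fit, q)[1], predict(fit, q)[2])
  expect_error(predict(fit, matrix(0, 1, 5)), "columns")
})

test_that("an exact three-way vote tie resolves to the first class", {
  # hand-built machines with constant decision values forcing a vote cycle:
  # a beats b, b beats c, c beats a -> one vote each
  const_machine <- function(b) {
    structure(list(X = matrix(0, 1, 2), y = 1, alpha = 0, b = b,
                   gamma = 1, sigma2 = 1), class = "lssvm_binary")
  }
  fit <- structure(list(classes = c("a", "b", "c"),
                        machines = list("a|b" = const_machine(1),
                                        "a|c" = const_machine(-1),
                                        "b|c" = const_machine(1)),
                        gamma = 1, sigma2 = 1), class = "lssvm")
  expect_identical(predict(fit, matrix(0, 1, 2)), "a")
})

test_that("large gamma drives training error to zero on separable data", {
  set.seed(53)
  X <- rbind(matrix(rnorm(16, 0, 0.4), 8, 2),
             matrix(rnorm(16, 4, 0.4), 8, 2))
  y <- rep(c("lo", "hi"), each = 8)
  hard <- fit_lssvm(X, y, gamma = 1e6, sigma2 = 4)
  expect_identical(predict(hard, X), y)
})

test_that("grid search honours its grids, ties and determinism", {
  set.seed(54)
  X <- rbind(matrix(rnorm(24, 0, 0.5), 12, 2),
             matrix(rnorm(24, 5, 0.5), 12, 2))
  y <- rep(c("a", "b"), each = 12)

  single <- grid_search_lssvm(X, y, gamma_grid = 4, sigma2_grid = 8,
                              folds = 3, seed = 2)
  expect_identical(single$best_gamma, 4)
  expect_identical(single$best_sigma2, 8)
  expect_identical(nrow(single$cv_surface), 1L)

  gs1 <- grid_search_lssvm(X, y, gamma_grid = 2^(0:2),
                           sigma2_grid = 2^(1:3), folds = 3, seed = 7)
  gs2 <- grid_search_lssvm(X, y, gamma_grid = 2^(0:2),
                           sigma2_grid = 2^(1:3), folds = 3, seed = 7)
  expect_identical(gs1$cv_surface, gs2$cv_surface)
  expect_true(gs1$best_gamma %in% 2^(0:2))
  expect_true(gs1$best_sigma2 %in% 2^(1:3))
  # the winner attains the minimum of the surface
  expect_equal(
    min(gs1$cv_surface$rmsecv),
    gs1$cv_surface$rmsecv[gs1$cv_surface$gamma == gs1$best_gamma &
                            gs1$cv_surface$sigma2 == gs1$best_sigma2])
  # fully separable data ties at 0; tie-break picks the smallest pair
  if (min(gs1$cv_surface$rmsecv) == 0 &&
      sum(gs1$cv_surface$rmsecv == 0) > 1) {
    zero <- gs1$cv_surface[gs1$cv_surface$rmsecv == 0, ]
    expect_identical(gs1$best_sigma2, min(zero$sigma2))
  }
  expect_error(grid_search_lssvm(X, y, folds = 20), "folds")
})

test_that("BPNN learns XOR for at least one initialization seed", {
  X <- rbind(c(0, 0), c(0, 1), c(1, 0), c(1, 1))
  y <- c("even", "odd", "odd", "even")
  reached <- FALSE
  for (s in 0:4) {
    fit <- fit_bpnn(X, y, hidden = 4, learn_rate = 2, momentum = 0.9,
                    goal_mse = 1e-5, max_epochs = 1000, seed = s)
    if (utils::tail(fit$training_curve, 1) < 0.01) { reached <- TRUE; break }
  }
  expect_true(reached)
})

test_that("BPNN training is deterministic and inert at zero step size", {
  set.seed(55)
  X <- matrix(rnorm(40), 20, 2)
  y <- rep(c("a", "b"), 10)
  f1 <- fit_bpnn(X, y, hidden = 3, max_epochs = 50, seed = 9)
  f2 <- fit_bpnn(X, y, hidden = 3, max_epochs = 50, seed = 9)
  expect_identical(f1$W1, f2$W1)
  expect_identical(f1$W2, f2$W2)

  frozen <- fit_bpnn(X, y, hidden = 3, learn_rate = 0, momentum = 0,
                     max_epochs = 50, seed = 9)
  init <- hyperseed:::with_seed(9, list(
    W1 = matrix(stats::runif(2 * 3, -0.5, 0.5), 2, 3),
    b1 = stats::runif(3, -0.5, 0.5)))
  expect_equal(frozen$W1, init$W1, tolerance = 1e-14)
  expect_equal(frozen$b1, init$b1, tolerance = 1e-14)
})

test_that("plain gradient descent with a small step never increases MSE", {
  set.seed(56)
  X <- matrix(rnorm(30), 15, 2)
  y <- rep(c("a", "b", "c"), 5)
  fit <- fit_bpnn(X, y, hidden = 4, learn_rate = 1e-3, momentum = 0,
                  max_epochs = 200, seed = 1)
  expect_true(all(diff(fit$training_curve) <= 1e-12))
})

test_that("the +/-0.5 recognition band accepts only clean one-hot outputs", {
  O <- rbind(c(0.7, 0.2, 0.1),
             c(0.4, 0.3, 0.3),
             c(0.9, 0.6, 0.0))
  lab <- hyperseed:::bpnn_decide(O, c("x", "y", "z"))
  expect_identical(lab, c("x", NA, NA))
})

test_that("BPNN prediction flags unrecognized samples", {
  set.seed(57)
  X <- rbind(matrix(rnorm(20, 0, 0.3), 10, 2),
             matrix(rnorm(20, 4, 0.3), 10, 2))
  y <- rep(c("a", "b"), each = 10)
  fit <- fit_bpnn(X, y, hidden = 4, seed = 2)
  pr <- predict(fit, X)
  expect_length(pr$labels, 20L)
  expect_identical(pr$valid, !is.na(pr$labels))
  expect_identical(dim(pr$outputs), c(20L, 2L))
  expect_error(predict(fit, matrix(0, 1, 5)), "columns")
})
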