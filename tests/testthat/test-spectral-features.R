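test_that("mean_spectrum averages pixels per band", {
  const <- as_roi(array(0.42, c(3, 3, 4)))
  expect_equal(unname(mean_spectrum(const)), rep(0.42, 4))

  mixed <- as_roi(array(c(0, 1, 0, 1), c(2, 2, 1)))
  expect_equal(unname(mean_spectrum(mixed)), 0.5)

  full <- as_roi(array(runif(4 * 4 * 512), c(4, 4, 512)),
                 seq(380, 1030, length.out = 512))
  expect_length(mean_spectrum(full), 512L)
})

test_that("rank-1 data loads entirely on one component", {
  X <- cbind(1:6, 2 * (1:6))
  fit <- fit_pca(X, 1)
  expect_equal(fit$explained_variance_ratio, 1)
  # the loading is the unit vector along (1, 2)
  expect_equal(abs(fit$loadings[, 1]), c(1, 2) / sqrt(5))
})

test_that("full-rank PCA reconstructs the data", {
  set.seed(21)
  X <- matrix(rnorm(40), 8, 5)
  fit <- fit_pca(X, 5)
  recon <- sweep(fit$scores %*% t(fit$loadings), 2, fit$mean, `+`)
  expect_equal(recon, X, tolerance = 1e-8, ignore_attr = TRUE)
  expect_equal(sum(fit$explained_variance_ratio), 1, tolerance = 1e-8)
})

test_that("SVD-based PCA agrees with a covariance eigendecomposition", {
  for (seed in 1:10) {
    set.seed(seed)
    X <- matrix(rnorm(60), 10, 6)
    fit <- fit_pca(X, 3)
    eg <- eigen(stats::cov(X), symmetric = TRUE)
    expect_equal(abs(fit$loadings), abs(eg$vectors[, 1:3]),
                 tolerance = 1e-8, ignore_attr = TRUE)
    sc_oracle <- sweep(X, 2, colMeans(X)) %*% eg$vectors[, 1:3]
    expect_equal(abs(fit$scores), abs(sc_oracle), tolerance = 1e-8,
                 ignore_attr = TRUE)
    expect_equal(fit$explained_variance_ratio,
                 (eg$values / sum(eg$values))[1:3], tolerance = 1e-8)
  }
})

test_that("PCA scores are centred with diagonal covariance", {
  set.seed(5)
  X <- matrix(rnorm(120), 15, 8)
  fit <- fit_pca(X, 4)
  expect_equal(colMeans(fit$scores), rep(0, 4), tolerance = 1e-10,
               ignore_attr = TRUE)
  cv <- stats::cov(fit$scores)
  expect_equal(cv, diag(diag(cv)), tolerance = 1e-8, ignore_attr = TRUE)
  expect_equal(crossprod(fit$loadings), diag(4), tolerance = 1e-8,
               ignore_attr = TRUE)
})

test_that("PCA projection is (X - mean) . loadings", {
  set.seed(6)
  X <- matrix(rnorm(50), 10, 5)
  fit <- fit_pca(X, 3)
  expect_equal(drop(project_pca(fit, fit$mean)), rep(0, 3),
               ignore_attr = TRUE)
  expect_equal(project_pca(fit, X), fit$scores, tolerance = 1e-10)
  x <- fit$mean + 1.7 * fit$loadings[, 1]
  expect_equal(drop(project_pca(fit, x)), c(1.7, 0, 0), tolerance = 1e-10,
               ignore_attr = TRUE)
  expect_error(project_pca(fit, matrix(0, 2, 4)), "band count")
  expect_error(fit_pca(X, 11), "k")
})

test_that("KPCA centring and duplicate handling behave", {
  set.seed(7)
  X <- matrix(rnorm(36), 12, 3)
  X[5, ] <- X[2, ]                      # duplicated training row
  fit <- fit_kpca(X, k = 3)
  expect_equal(fit$scores[5, ], fit$scores[2, ], tolerance = 1e-10)
  # centred-kernel identity: zero row sums
  K <- exp(-as.matrix(stats::dist(X))^2 / (2 * fit$sigma2_k))
  Kc <- K - matrix(fit$row_means, 12, 12) -
    matrix(fit$row_means, 12, 12, byrow = TRUE) + fit$grand_mean
  expect_equal(max(abs(rowSums(Kc))), 0, tolerance = 1e-10)
  expect_equal(colMeans(fit$scores), rep(0, 3), tolerance = 1e-10,
               ignore_attr = TRUE)
  expect_true(all(diff(fit$eigenvalues) <= 1e-10))
})

test_that("KPCA with a linear kernel reproduces PCA on random instances", {
  for (seed in 1:8) {
    set.seed(seed)
    n <- sample(5:30, 1); p <- sample(2:20, 1)
    X <- matrix(rnorm(n * p), n, p)
    k <- min(3, n - 1, p)
    kf <- fit_kpca(X, k = k, kernel = "linear")
    pf <- fit_pca(X, k)
    expect_equal(abs(kf$scores), abs(pf$scores), tolerance = 1e-6,
                 ignore_attr = TRUE)
  }
})

test_that("large-width RBF KPCA converges to linear PCA scores", {
  set.seed(8)
  X <- matrix(rnorm(60), 15, 4)
  diam2 <- max(as.matrix(stats::dist(X))^2)
  kf <- fit_kpca(X, sigma2_k = 1e6 * diam2, k = 3)
  pf <- fit_pca(X, 3)
  for (j in 1:3)
    expect_gt(abs(stats::cor(kf$scores[, j], pf$scores[, j])), 0.999)
})

test_that("KPCA out-of-sample projection matches fit-time scores", {
  set.seed(9)
  X <- matrix(rnorm(48), 12, 4)
  fit <- fit_kpca(X, k = 3)
  expect_equal(project_kpca(fit, X), fit$scores, tolerance = 1e-8,
               ignore_attr = TRUE)
  expect_equal(drop(project_kpca(fit, X[4, ])), fit$scores[4, ],
               tolerance = 1e-8, ignore_attr = TRUE)
  empty <- project_kpca(fit, matrix(numeric(0), 0, 4))
  expect_identical(dim(empty), c(0L, 3L))
  expect_error(project_kpca(fit, matrix(0, 2, 5)), "band count")
})

test_that("KPCA reduces k when the kernel is rank-deficient", {
  X <- cbind(1:6, 2 * (1:6))            # rank-1 configuration
  fit <- fit_kpca(X, k = 4, kernel = "linear")
  expect_lt(ncol(fit$alphas), 4L)
  expect_match(fit$warnings, "reduced", all = FALSE)
})

test_that("RBF KPCA scores agree with an independent implementation", {
  skip_if_not_installed("kernlab")
  set.seed(10)
  X <- matrix(rnorm(80), 20, 4)
  sigma2 <- 3
  fit <- fit_kpca(X, sigma2_k = sigma2, k = 3)
  ref <- kernlab::kpca(X, kernel = "rbfdot",
                       kpar = list(sigma = 1 / (2 * sigma2)), features = 3)
  sc <- kernlab::rotated(ref)
  for (j in 1:3)
    expect_gt(abs(stats::cor(fit$scores[, j], sc[, j])), 1 - 1e-8)
})

test_that("spectrum tables round-trip through CSV", {
  set.seed(11)
  X <- matrix(runif(12), 3, 4)
  wl <- c(500.5, 600, 700, 800)
  path <- tempfile(fileext = ".csv")
  write_spectra(X, wl, labels = c("I", "II", "I"), path = path)
  back <- read_spectra(path)
  expect_equal(back$X, X, ignore_attr = TRUE)
  expect_equal(back$wavelengths, wl)
  expect_identical(back$labels, c("I", "II", "I"))
})

test_that("fitted models survive JSON serialization", {
  set.seed(12)
  X <- matrix(rnorm(40), 10, 4)
  fit <- fit_pca(X, 2)
  path <- tempfile(fileext = ".json")
  write_model_json(fit, path)
  back <- read_model_json(path)
  expect_s3_class(back, "pca_model")
  expect_equal(back$loadings, fit$loadings, ignore_attr = TRUE)
  expect_equal(project_pca(back, X), project_pca(fit, X),
               ignore_attr = TRUE)
})
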