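#' Quantize a gray-scale image to Ng levels
#'
#' Linear min-max binning: `level = floor(Ng * (v - min) / (max - min))`,
#' with the maximum value mapped to `Ng - 1` and a constant image mapped to
#' level 0. Quantization is therefore invariant to adding or multiplying by
#' a positive constant, which keeps texture features comparable across
#' illumination levels.
#'
#' @param image 2-D numeric matrix with finite values.
#' @param Ng number of gray levels, >= 2.
#' @return An object of class `level_image`: list with integer matrix
#'   `levels` (entries in `0..Ng-1`) and `Ng`.
#' @export
quantize <- function(image, Ng = 8) {
  image <- as.matrix(image)
  Ng <- as.integer(Ng)
  if (Ng < 2L) stop("`Ng` must be >= 2")
  if (any(!is.finite(image))) stop("image contains non-finite values")
  rng <- range(image)
  # a spread below ~1e-10 relative is numerical noise, not structure;
  # min-max binning would otherwise blow it up to full-range texture
  lv <- if (rng[2L] - rng[1L] <= 1e-10 * max(abs(rng), 1)) {
    matrix(0L, nrow(image), ncol(image))
  } else {
    l <- floor(Ng * (image - rng[1L]) / (rng[2L] - rng[1L]))
    l[l > Ng - 1L] <- Ng - 1L
    matrix(as.integer(l), nrow(image), ncol(image))
  }
  structure(list(levels = lv, Ng = Ng), class = "level_image")
}

#' Gray-level co-occurrence matrix
#'
#' Counts ordered pairs of gray levels `(img[r, c], img[r + dr, c + dc])`
#' over all in-bounds positions and normalizes the counts to sum to 1. The
#' classical texture setting is `offset = c(0, 1)`: direction 0 degrees,
#' distance 1 pixel. With `symmetric = TRUE` (Haralick's original
#' definition) the transposed counts are added before normalization, so each
#' pixel pair is counted in both orders.
#'
#' @param img a [quantize()]d `level_image`.
#' @param offset integer `(dr, dc)` displacement.
#' @param symmetric logical; symmetrize the counts.
#' @return An object of class `glcm`: list with `P` (Ng x Ng matrix summing
#'   to 1), `offset` and `symmetric`.
#' @export
compute_glcm <- function(img, offset = c(0, 1), symmetric = TRUE) {
  stopifnot(inherits(img, "level_image"))
  offset <- as.integer(offset)
  lv <- img$levels
  nr <- nrow(lv); nc <- ncol(lv)
  dr <- offset[1L]; dc <- offset[2L]
  r0 <- max(1L, 1L - dr):min(nr, nr - dr)
  c0 <- max(1L, 1L - dc):min(nc, nc - dc)
  if (abs(dr) >= nr || abs(dc) >= nc || length(r0) < 1L || length(c0) < 1L)
    stop("offset (", dr, ", ", dc, ") exceeds the image extent")
  i <- lv[r0, c0, drop = FALSE]
  j <- lv[r0 + dr, c0 + dc, drop = FALSE]
  Ng <- img$Ng
  counts <- matrix(tabulate(as.vector(i) * Ng + as.vector(j) + 1L,
                            nbins = Ng * Ng),
                   Ng, Ng, byrow = TRUE)
  if (symmetric) counts <- counts + t(counts)
  structure(list(P = counts / sum(counts), offset = offset,
                 symmetric = symmetric),
            class = "glcm")
}

#' Haralick texture features of a GLCM
#'
#' Computes the four second-order statistics used throughout food and seed
#' imaging work, with `p(i, j)` the normalized co-occurrence matrix and
#' `i, j` the gray levels (0-based):
#' \itemize{
#'   \item contrast: `sum (i - j)^2 p(i, j)`
#'   \item homogeneity (inverse difference): `sum p(i, j) / (1 + |i - j|)`
#'   \item energy (angular second moment): `sum p(i, j)^2`
#'   \item correlation: `sum (i - mu_i)(j - mu_j) p(i, j) / (sd_i sd_j)`,
#'     with moments from the marginal distributions; defined as 0 when
#'     either marginal is degenerate (`sd_i sd_j = 0`).
#' }
#'
#' @param g a [compute_glcm()] object.
#' @return Named numeric vector `(contrast, homogeneity, energy,
#'   correlation)`.
#' @export
glcm_features <- function(g) {
  stopifnot(inherits(g, "glcm"))
  P <- g$P
  Ng <- nrow(P)
  lev <- seq_len(Ng) - 1
  I <- matrix(lev, Ng, Ng)
  J <- t(I)
  contrast <- sum((I - J)^2 * P)
  homogeneity <- sum(P / (1 + abs(I - J)))
  energy <- sum(P^2)
  pi_ <- rowSums(P); pj_ <- colSums(P)
  mu_i <- sum(lev * pi_); mu_j <- sum(lev * pj_)
  sd_i <- sqrt(sum((lev - mu_i)^2 * pi_))
  sd_j <- sqrt(sum((lev - mu_j)^2 * pj_))
  correlation <- if (sd_i * sd_j > 0) {
    sum((I - mu_i) * (J - mu_j) * P) / (sd_i * sd_j)
  } else 0
  c(contrast = contrast, homogeneity = homogeneity, energy = energy,
    correlation = correlation)
}

#' GLCM texture feature vector of an ROI at selected bands
#'
#' For each selected band image: quantize to `Ng` levels, build the
#' symmetric 0-degree distance-1 GLCM, and compute the four Haralick
#' features. Blocks are concatenated band-major in band-set order, feature
#' order (contrast, homogeneity, energy, correlation); three bands thus
#' yield the classical 12 texture variables per sample.
#'
#' @param x an [roi].
#' @param bands a `band_set` (see [select_bands()]) with valid band indices.
#' @param Ng gray-level count.
#' @param offset GLCM displacement, default `c(0, 1)`.
#' @return Named numeric vector of length `4 * nrow(bands)` with names
#'   `glcm_<wavelength>_<feature>`.
#' @export
texture_vector <- function(x, bands, Ng = 8, offset = c(0, 1)) {
  stopifnot(inherits(x, "roi"), inherits(bands, "band_set"))
  if (nrow(bands) == 0L) stop("`bands` is empty")
  nb <- dim(x$cube$data)[3L]
  if (any(bands$band_index < 1L) || any(bands$band_index > nb))
    stop("band indices outside the ROI's ", nb, " bands")
  out <- unlist(lapply(seq_len(nrow(bands)), function(i) {
    img <- x$cube$data[, , bands$band_index[i]]
    f <- glcm_features(compute_glcm(quantize(img, Ng), offset = offset,
                                    symmetric = TRUE))
    names(f) <- paste0("glcm_", format(bands$wavelength[i], trim = TRUE),
                       "_", names(f))
    f
  }))
  out
}
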