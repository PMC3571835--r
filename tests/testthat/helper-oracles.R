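# Shared fixtures and independent oracles, built in code at test time.

# random small hypercube with float32-exact (dyadic) values so ENVI
# round-trips are bit-exact
rand_cube <- function(r, c, b, seed = 1) {
  set.seed(seed)
  vals <- sample(0:4095, r * c * b, replace = TRUE) / 256
  hypercube(array(vals, c(r, c, b)),
            seq(400, 900, length.out = b), kind = "raw")
}

flat_refs <- function(r, c, b, white = 1, black = 0.2) {
  wl <- seq(400, 900, length.out = b)
  reference_pair(hypercube(array(white, c(r, c, b)), wl),
                 hypercube(array(black, c(r, c, b)), wl))
}

# wrap a matrix of pixel values (one band) as a 1-band reflectance ROI
as_roi <- function(values_3d, wavelengths = NULL) {
  d <- dim(values_3d)
  if (is.null(wavelengths)) wavelengths <- seq(500, 900, length.out = d[3L])
  cube <- hypercube(values_3d, wavelengths, "reflectance")
  roi(cube, c(1L, 1L), d[1L])
}

# build a loading_profile from raw loading vectors/matrices
loading_profile_for_test <- function(loadings, wavelengths) {
  hyperseed:::loading_profile(as.matrix(loadings), wavelengths)
}

make_band_set <- function(band_index, wavelength,
                          pc = rep(1L, length(band_index)),
                          kind = rep("max", length(band_index))) {
  structure(data.frame(wavelength = wavelength, band_index = band_index,
                       pc = pc, kind = kind,
                       loading = rep(1, length(band_index))),
            class = c("band_set", "data.frame"))
}

# independent GLCM + feature oracle: explicit double loop over pixel pairs
# and over all Ng^2 cells, no shared code with the implementation
brute_glcm_features <- function(levels, Ng, offset = c(0, 1),
                                symmetric = TRUE) {
  counts <- matrix(0, Ng, Ng)
  nr <- nrow(levels); nc <- ncol(levels)
  for (r in seq_len(nr)) {
    for (c in seq_len(nc)) {
      r2 <- r + offset[1L]; c2 <- c + offset[2L]
      if (r2 >= 1 && r2 <= nr && c2 >= 1 && c2 <= nc) {
        i <- levels[r, c] + 1L; j <- levels[r2, c2] + 1L
        counts[i, j] <- counts[i, j] + 1
        if (symmetric) counts[j, i] <- counts[j, i] + 1
      }
    }
  }
  P <- counts / sum(counts)
  contrast <- 0; homog <- 0; energy <- 0
  for (i in seq_len(Ng)) for (j in seq_len(Ng)) {
    contrast <- contrast + (i - j)^2 * P[i, j]
    homog <- homog + P[i, j] / (1 + abs(i - j))
    energy <- energy + P[i, j]^2
  }
  mu_i <- 0; mu_j <- 0
  for (i in seq_len(Ng)) mu_i <- mu_i + (i - 1) * sum(P[i, ])
  for (j in seq_len(Ng)) mu_j <- mu_j + (j - 1) * sum(P[, j])
  v_i <- 0; v_j <- 0
  for (i in seq_len(Ng)) v_i <- v_i + ((i - 1) - mu_i)^2 * sum(P[i, ])
  for (j in seq_len(Ng)) v_j <- v_j + ((j - 1) - mu_j)^2 * sum(P[, j])
  corr <- 0
  if (v_i > 0 && v_j > 0) {
    for (i in seq_len(Ng)) for (j in seq_len(Ng))
      corr <- corr + ((i - 1) - mu_i) * ((j - 1) - mu_j) * P[i, j]
    corr <- corr / sqrt(v_i * v_j)
  }
  c(contrast = contrast, homogeneity = homog, energy = energy,
    correlation = corr)
}

# small shared dataset for pipeline-level tests (built once per test run)
tiny_dataset <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- generate_dataset(n_per_variety = 6, side = 16, bands = 32,
                                 seed = 11)
    cache
  }
})
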