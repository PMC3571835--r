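#' Default six-variety specification set
#'
#' Builds six synthetic seed-variety specifications emulating a VIS-NIR
#' study of commodity maize: each variety has a smooth reflectance
#' signature over 380-1030 nm (a baseline plus Gaussian bumps) and a
#' spatial texture pattern (stripes, checker or blobs) with its own period
#' and contrast amplitude. Variety I is dark (low baseline, like a
#' black-testa seed). Two pairs — (II, V) and (IV, VI) — are deliberate
#' *spectral twins*: the second signature is an exact scalar multiple
#' (0.4% off) of the first, so their signature L2 distance is below 0.05
#' while per-sample illumination gain (a few percent) makes them
#' spectrally indistinguishable; they differ only in texture pattern.
#' Spectral features alone therefore cannot fully separate the set and
#' texture features are required, mirroring similarly coloured seed
#' varieties that differ in surface structure.
#'
#' @param seed integer seed; jitters the bump centres by up to +/-2 nm so
#'   distinct seeds give distinct (but equally valid) variety sets.
#' @return List of 6 objects of class `variety_spec`, each with fields
#'   `id`, `baseline`, `bumps` (data.frame center/width/amplitude),
#'   `texture` (list pattern/period_px/amplitude) and `noise_sd`.
#' @export
default_varieties <- function(seed = 1) {
  base_specs <- list(
    list(id = "I", baseline = 0.08,
         bumps = data.frame(center = c(620, 850), width = c(60, 90),
                            amplitude = c(0.05, 0.08)),
         texture = list(pattern = "blobs", period_px = 16, amplitude = 0.12)),
    list(id = "II", baseline = 0.25,
         bumps = data.frame(center = c(560, 740, 900),
                            width = c(40, 70, 80),
                            amplitude = c(0.18, 0.22, 0.10)),
         texture = list(pattern = "stripes", period_px = 4,
                        amplitude = 0.15)),
    list(id = "III", baseline = 0.22,
         bumps = data.frame(center = c(530, 680, 880),
                            width = c(35, 60, 90),
                            amplitude = c(0.25, 0.12, 0.18)),
         texture = list(pattern = "checker", period_px = 10,
                        amplitude = 0.12)),
    list(id = "IV", baseline = 0.30,
         bumps = data.frame(center = c(600, 790), width = c(55, 75),
                            amplitude = c(0.28, 0.15)),
         texture = list(pattern = "stripes", period_px = 20,
                        amplitude = 0.10)),
    list(id = "V", baseline = 0.25 * 1.004,
         bumps = data.frame(center = c(560, 740, 900),
                            width = c(40, 70, 80),
                            amplitude = 1.004 * c(0.18, 0.22, 0.10)),
         texture = list(pattern = "checker", period_px = 5,
                        amplitude = 0.18)),
    list(id = "VI", baseline = 0.30 * 0.996,
         bumps = data.frame(center = c(600, 790), width = c(55, 75),
                            amplitude = 0.996 * c(0.28, 0.15)),
         texture = list(pattern = "blobs", period_px = 8,
                        amplitude = 0.14)))
  jit <- with_seed(seed, stats::runif(length(base_specs), -2, 2))
  # twin pairs (II, V) and (IV, VI) share their jitter so each stays an
  # exact scalar multiple of its partner
  jit[5L] <- jit[2L]
  jit[6L] <- jit[4L]
  lapply(seq_along(base_specs), function(i) {
    s <- base_specs[[i]]
    s$bumps$center <- s$bumps$center + jit[i]
    s$noise_sd <- 0.01
    structure(s, class = "variety_spec")
  })
}

#' @export
print.variety_spec <- function(x, ...) {
  cat(sprintf("<variety_spec> %s: baseline %.2f, %d bumps, %s texture (period %d px)\n",
              x$id, x$baseline, nrow(x$bumps), x$texture$pattern,
              x$texture$period_px))
  invisible(x)
}

#' Evaluate a variety's reflectance signature on a wavelength grid
#'
#' `signature(lambda) = baseline + sum_b amplitude_b *
#' exp(-(lambda - center_b)^2 / (2 width_b^2))`; values stay in (0, 1) for
#' the default specifications.
#'
#' @param spec a `variety_spec`.
#' @param wavelengths numeric vector, nm.
#' @return Numeric vector of reflectances.
#' @export
variety_signature <- function(spec, wavelengths) {
  s <- rep(spec$baseline, length(wavelengths))
  for (b in seq_len(nrow(spec$bumps))) {
    s <- s + spec$bumps$amplitude[b] *
      exp(-(wavelengths - spec$bumps$center[b])^2 /
            (2 * spec$bumps$width[b]^2))
  }
  s
}

# Deterministic zero-mean spatial texture field in [-A, A].
texture_field <- function(texture, side) {
  r <- matrix(seq_len(side), side, side)
  c_ <- t(r)
  A <- texture$amplitude
  p <- texture$period_px
  switch(texture$pattern,
    stripes = A * sin(2 * pi * c_ / p),
    checker = A * sign(sin(2 * pi * r / p) * sin(2 * pi * c_ / p)),
    blobs   = A * sin(2 * pi * r / p) * sin(2 * pi * c_ / p),
    stop("unknown texture pattern: ", texture$pattern))
}

#' Synthetic white/black reference frames
#'
#' White frame: 0.95 nominal with a mild sinusoidal spatial gain ripple
#' (2%), so calibration is exercised non-trivially; black frame: constant
#' 0.02 dark level.
#'
#' @param side spatial side in pixels.
#' @param wavelengths band grid, nm.
#' @return A [reference_pair].
#' @export
generate_references <- function(side, wavelengths) {
  b <- length(wavelengths)
  col_gain <- 1 + 0.02 * sin(2 * pi * seq_len(side) / 32)
  white_plane <- 0.95 * matrix(col_gain, side, side, byrow = TRUE)
  white <- array(white_plane, c(side, side, b))
  black <- array(0.02, c(side, side, b))
  reference_pair(hypercube(white, wavelengths, "raw"),
                 hypercube(black, wavelengths, "raw"))
}

#' Generate one synthetic raw sample cube
#'
#' The reflectance field is
#' `gain * signature(lambda) * (1 + texture(r, c)) + noise`, with a
#' per-sample illumination gain (sd `gain_sd`, 1 when 0) and i.i.d.
#' Gaussian noise (sd `spec$noise_sd` unless overridden). The field is then
#' converted to raw intensities through the reference frames,
#' `raw = reflectance * (W - B) + B`, so that [calibrate_reflectance()]
#' exactly inverts the construction.
#'
#' @param spec a `variety_spec`.
#' @param side spatial side, >= 8 pixels.
#' @param bands band count, >= 8.
#' @param lo_nm,hi_nm wavelength range covered by the `bands` grid.
#' @param seed integer seed.
#' @param refs optional [reference_pair]; defaults to
#'   [generate_references()].
#' @param noise_sd override of the spec's noise sd (e.g. 0 for noiseless).
#' @param gain_sd sd of the per-sample multiplicative illumination gain.
#' @param texture_amplitude override of the spec's texture amplitude.
#' @return A raw [hypercube].
#' @export
generate_sample <- function(spec, side = 64, bands = 128, lo_nm = 380,
                            hi_nm = 1030, seed = 1, refs = NULL,
                            noise_sd = NULL, gain_sd = 0,
                            texture_amplitude = NULL) {
  stopifnot(inherits(spec, "variety_spec"))
  if (side < 8L) stop("`side` must be >= 8")
  if (bands < 8L) stop("`bands` must be >= 8")
  wl <- seq(lo_nm, hi_nm, length.out = bands)
  if (is.null(refs)) refs <- generate_references(side, wl)
  if (!all(dim(refs$white$data) == c(side, side, bands)))
    stop("reference frames do not match the requested geometry")
  if (is.null(noise_sd)) noise_sd <- spec$noise_sd
  tex <- spec$texture
  if (!is.null(texture_amplitude)) tex$amplitude <- texture_amplitude
  sig <- variety_signature(spec, wl)
  tf <- texture_field(tex, side)

  refl <- with_seed(seed, {
    gain <- if (gain_sd > 0) max(0.1, 1 + stats::rnorm(1L, 0, gain_sd)) else 1
    base <- outer(1 + tf, gain * sig)          # (side*side) x bands
    if (noise_sd > 0)
      base <- base + stats::rnorm(length(base), 0, noise_sd)
    array(base, c(side, side, bands))
  })
  if (any(refl <= 0))
    stop("generated reflectance not positive; texture amplitude/noise too ",
         "large for this signature")
  raw <- refl * (refs$white$data - refs$black$data) + refs$black$data
  hypercube(raw, wl, "raw")
}

#' Generate a full synthetic labeled dataset
#'
#' `6 * n_per_variety` raw sample cubes (one ROI-sized cube per sample)
#' with one shared white/black reference pair per session, class labels,
#' and a manifest of every generation parameter plus the seed — the
#' manifest alone regenerates the dataset bit-identically (see
#' [generate_from_manifest()]).
#'
#' @param n_per_variety samples per variety, >= 2 (55 emulates a 330-sample
#'   study).
#' @param side,bands,lo_nm,hi_nm cube geometry (defaults 64 x 64 x 128 over
#'   380-1030 nm, a desk-scale stand-in for 100 x 100 x 512).
#' @param noise_sd additive Gaussian noise sd.
#' @param gain_sd per-sample illumination gain sd.
#' @param seed integer master seed; per-sample seeds are derived from it.
#' @return An object of class `synthetic_dataset`: `cubes` (list of raw
#'   [hypercube]s), `labels`, `refs`, `varieties` and `manifest`.
#' @export
generate_dataset <- function(n_per_variety = 55, side = 64, bands = 128,
                             lo_nm = 380, hi_nm = 1030, noise_sd = 0.01,
                             gain_sd = 0.02, seed = 42) {
  if (n_per_variety < 2L) stop("`n_per_variety` must be >= 2")
  varieties <- default_varieties(seed)
  wl <- seq(lo_nm, hi_nm, length.out = bands)
  refs <- generate_references(side, wl)
  n <- 6L * n_per_variety
  cubes <- vector("list", n)
  labels <- character(n)
  i <- 0L
  for (v in seq_along(varieties)) {
    for (s in seq_len(n_per_variety)) {
      i <- i + 1L
      cubes[[i]] <- generate_sample(varieties[[v]], side = side,
                                    bands = bands, lo_nm = lo_nm,
                                    hi_nm = hi_nm,
                                    seed = derive_seed(seed, i),
                                    refs = refs, noise_sd = noise_sd,
                                    gain_sd = gain_sd)
      labels[i] <- varieties[[v]]$id
    }
  }
  manifest <- list(version = 1L, n_per_variety = n_per_variety, side = side,
                   bands = bands, lo_nm = lo_nm, hi_nm = hi_nm,
                   noise_sd = noise_sd, gain_sd = gain_sd, seed = seed)
  structure(list(cubes = cubes, labels = labels, refs = refs,
                 varieties = varieties, manifest = manifest),
            class = "synthetic_dataset")
}

#' @export
print.synthetic_dataset <- function(x, ...) {
  m <- x$manifest
  cat(sprintf(
    "<synthetic_dataset> %d samples (6 x %d), %dx%dx%d cubes, %g-%g nm, seed %d\n",
    length(x$cubes), m$n_per_variety, m$side, m$side, m$bands, m$lo_nm,
    m$hi_nm, m$seed))
  invisible(x)
}

#' Regenerate a dataset from its manifest
#'
#' @param manifest the `manifest` element of a `synthetic_dataset` (or the
#'   same list read back from JSON).
#' @return A `synthetic_dataset` identical to the original.
#' @export
generate_from_manifest <- function(manifest) {
  generate_dataset(n_per_variety = manifest$n_per_variety,
                   side = manifest$side, bands = manifest$bands,
                   lo_nm = manifest$lo_nm, hi_nm = manifest$hi_nm,
                   noise_sd = manifest$noise_sd, gain_sd = manifest$gain_sd,
                   seed = manifest$seed)
}

#' Write a synthetic dataset to disk as ENVI pairs + labels + manifest
#'
#' Writes `sample_<i>.hdr/.dat` for every cube, `white.hdr`/`black.hdr`
#' reference pairs, `labels.csv` (sample_id, file, label) and
#' `manifest.json` into `dir`.
#'
#' @param dataset a `synthetic_dataset`.
#' @param dir output directory (created if missing).
#' @param interleave ENVI interleave for all cubes.
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(dataset, dir, interleave = "bsq") {
  stopifnot(inherits(dataset, "synthetic_dataset"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- character(length(dataset$cubes))
  for (i in seq_along(dataset$cubes)) {
    files[i] <- file.path(dir, sprintf("sample_%03d.hdr", i))
    write_envi(dataset$cubes[[i]], files[i], interleave = interleave)
  }
  write_envi(dataset$refs$white, file.path(dir, "white.hdr"),
             interleave = interleave)
  write_envi(dataset$refs$black, file.path(dir, "black.hdr"),
             interleave = interleave)
  utils::write.csv(
    data.frame(sample_id = seq_along(files), file = basename(files),
               label = dataset$labels),
    file.path(dir, "labels.csv"), row.names = FALSE)
  jsonlite::write_json(dataset$manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
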