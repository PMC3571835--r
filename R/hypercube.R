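#' Hyperspectral data cube
#'
#' Constructs the central data structure of the package: a 3-D array of
#' per-pixel spectra (rows x cols x bands) together with the wavelength grid
#' of the spectral axis. Line-scan VIS-NIR imagers produce such cubes either
#' as raw camera intensities (`kind = "raw"`) or, after white/black reference
#' correction, as relative reflectance (`kind = "reflectance"`).
#'
#' @param data numeric 3-D array, dimensions rows x cols x bands.
#' @param wavelengths numeric vector of band-centre wavelengths in nm,
#'   strictly increasing, length equal to `dim(data)[3]`.
#' @param kind `"raw"` (camera counts, nonnegative) or `"reflectance"`.
#' @return An object of class `hypercube`: a list with elements `data`,
#'   `wavelengths` and `kind`.
#' @examples
#' cube <- hypercube(array(runif(4 * 5 * 3), c(4, 5, 3)), c(500, 600, 700))
#' dim(cube$data)
#' @export
hypercube <- function(data, wavelengths, kind = c("raw", "reflectance")) {
  kind <- match.arg(kind)
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("`data` must be a 3-D array (rows x cols x bands)")
  storage.mode(data) <- "double"
  wavelengths <- as.numeric(wavelengths)
  if (length(wavelengths) != dim(data)[3L])
    stop("length(wavelengths) [", length(wavelengths),
         "] must equal the band dimension [", dim(data)[3L], "]")
  if (length(wavelengths) > 1L && any(diff(wavelengths) <= 0))
    stop("`wavelengths` must be strictly increasing")
  if (kind == "raw" && any(data < 0, na.rm = TRUE))
    stop("raw cubes must be nonnegative")
  if (kind == "reflectance" && any(!is.finite(data)))
    stop("reflectance cubes must be finite")
  structure(list(data = data, wavelengths = wavelengths, kind = kind),
            class = "hypercube")
}

#' @export
print.hypercube <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<hypercube> %d x %d pixels, %d bands (%.1f-%.1f nm), kind: %s\n",
              d[1L], d[2L], d[3L], min(x$wavelengths), max(x$wavelengths),
              x$kind))
  invisible(x)
}

#' @export
dim.hypercube <- function(x) dim(x$data)

#' Square region of interest within a hypercube
#'
#' A `side x side` pixel window of a parent cube, treated as one sample in
#' downstream feature extraction. `origin` is the (row, col) of the
#' upper-left pixel, 1-based, rows counted from the top.
#'
#' @param cube parent [hypercube].
#' @param origin integer length-2 vector `(row, col)` of the upper-left
#'   corner, 1-based.
#' @param side window side length in pixels.
#' @return An object of class `roi`: list with the cropped `cube` (spatial
#'   dims `side x side`), `origin` and `side`.
#' @export
roi <- function(cube, origin, side) {
  stopifnot(inherits(cube, "hypercube"))
  origin <- as.integer(origin)
  side <- as.integer(side)
  d <- dim(cube$data)
  if (length(origin) != 2L || any(origin < 1L))
    stop("`origin` must be a 1-based (row, col) pair")
  if (side < 1L) stop("`side` must be >= 1")
  if (origin[1L] + side - 1L > d[1L] || origin[2L] + side - 1L > d[2L])
    stop("ROI exceeds parent image bounds")
  sub <- cube$data[origin[1L]:(origin[1L] + side - 1L),
                   origin[2L]:(origin[2L] + side - 1L), , drop = FALSE]
  structure(list(cube = hypercube(sub, cube$wavelengths, cube$kind),
                 origin = origin, side = side),
            class = "roi")
}

#' @export
print.roi <- function(x, ...) {
  cat(sprintf("<roi> %dx%d at (%d, %d), %d bands, kind: %s\n",
              x$side, x$side, x$origin[1L], x$origin[2L],
              length(x$cube$wavelengths), x$cube$kind))
  invisible(x)
}

# Evaluate `code` under a temporary RNG state seeded with `seed`; the global
# RNG stream is restored afterwards so package randomness never leaks.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed %% .Machine$integer.max))
  force(code)
}

# Deterministic sub-seed derivation, kept inside 32-bit integer range.
derive_seed <- function(seed, offset) {
  as.integer((as.double(seed) * 48271 + 7919 * as.double(offset)) %%
               2147483587)
}
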