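#' Pixel-wise PCA of an ROI image
#'
#' Treats every pixel of the ROI as one observation (its p-band spectrum)
#' and fits [fit_pca()] to the resulting `side^2 x p` matrix. The loading of
#' each component is a per-band weight profile: each PC image is the linear
#' combination of the monochromatic band images weighted by that profile, so
#' the extrema of the profile mark the wavelengths driving the component.
#'
#' @param x an [roi] with a reflectance cube.
#' @param k number of components.
#' @return An object of class `loading_profile`: list with `loadings`
#'   (p x k, orthonormal columns), `wavelengths` and
#'   `explained_variance_ratio`.
#' @seealso [select_bands()]
#' @export
fit_image_pca <- function(x, k = 3) {
  stopifnot(inherits(x, "roi"))
  if (x$cube$kind != "reflectance")
    stop("fit_image_pca expects a reflectance ROI; calibrate first")
  d <- dim(x$cube$data)
  M <- matrix(x$cube$data, nrow = d[1L] * d[2L], ncol = d[3L])
  fit <- fit_pca(M, k)
  loading_profile(fit$loadings, x$cube$wavelengths,
                  fit$explained_variance_ratio)
}

loading_profile <- function(loadings, wavelengths, evr = NULL) {
  stopifnot(nrow(loadings) == length(wavelengths))
  structure(list(loadings = loadings, wavelengths = wavelengths,
                 explained_variance_ratio = evr),
            class = "loading_profile")
}

#' @export
print.loading_profile <- function(x, ...) {
  cat(sprintf("<loading_profile> %d bands x %d components\n",
              nrow(x$loadings), ncol(x$loadings)))
  invisible(x)
}

#' Local extrema of a loading profile
#'
#' Finds the strict local maxima and minima of a per-band loading vector
#' within a centred window of `window` bands. Plateau ties are resolved to
#' the lowest index; the first and last band are eligible through the
#' truncated window but flagged as non-interior (spectrum edges are
#' noise-prone, so selection excludes them by default).
#'
#' @param loading numeric vector of length p.
#' @param window odd window width >= 3, at most p.
#' @return data.frame with columns `index`, `value`, `kind` ("max"/"min")
#'   and `interior` (logical).
#' @export
find_loading_extrema <- function(loading, window = 5) {
  p <- length(loading)
  window <- as.integer(window)
  if (window < 3L || window %% 2L == 0L)
    stop("`window` must be an odd integer >= 3")
  if (p < window) stop("loading shorter than the window")
  h <- (window - 1L) %/% 2L
  rows <- lapply(seq_len(p), function(i) {
    lo <- max(1L, i - h); hi <- min(p, i + h)
    w <- loading[lo:hi]
    before <- if (i > lo) loading[lo:(i - 1L)] else numeric(0)
    is_max <- loading[i] == max(w) && !any(before == loading[i])
    is_min <- loading[i] == min(w) && !any(before == loading[i])
    if (!is_max && !is_min) return(NULL)
    data.frame(index = i, value = loading[i],
               kind = if (is_max) "max" else "min",
               interior = i > 1L && i < p)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(index = integer(0), value = numeric(0),
                      kind = character(0), interior = logical(0))
  out
}

#' Select effective wavelengths from PC loading extrema
#'
#' Pools the interior loading extrema of the first `min(3, k)` components,
#' ranks candidates by absolute loading value, and greedily retains the top
#' `k_bands` subject to a minimum pairwise wavelength separation of
#' `merge_window_nm` (near-duplicate extrema collapse onto the stronger
#' one). Ties are broken by band index then component, so the selection is
#' deterministic and invariant to candidate order.
#'
#' @param profile a [loading_profile] (see [fit_image_pca()]).
#' @param k_bands number of wavelengths to keep.
#' @param merge_window_nm minimum separation between kept wavelengths, nm.
#' @param window extrema detection window (see [find_loading_extrema()]).
#' @param include_endpoints if TRUE, spectrum-edge extrema compete too.
#' @return An object of classes `band_set`/`data.frame` with columns
#'   `wavelength`, `band_index`, `pc`, `kind` and `loading`, sorted by
#'   wavelength. If fewer candidates than `k_bands` survive, all are
#'   returned with a warning.
#' @export
select_bands <- function(profile, k_bands = 3, merge_window_nm = 10,
                         window = 5, include_endpoints = FALSE) {
  stopifnot(inherits(profile, "loading_profile"))
  if (k_bands < 1L) stop("`k_bands` must be >= 1")
  n_pc <- min(3L, ncol(profile$loadings))
  cand <- do.call(rbind, lapply(seq_len(n_pc), function(j) {
    ex <- find_loading_extrema(profile$loadings[, j], window)
    if (!include_endpoints) ex <- ex[ex$interior, , drop = FALSE]
    if (nrow(ex) == 0L) return(NULL)
    data.frame(wavelength = profile$wavelengths[ex$index],
               band_index = ex$index, pc = j, kind = ex$kind,
               loading = ex$value)
  }))
  if (is.null(cand) || nrow(cand) == 0L) {
    warning("no interior loading extrema found; empty band set")
    cand <- data.frame(wavelength = numeric(0), band_index = integer(0),
                       pc = integer(0), kind = character(0),
                       loading = numeric(0))
    return(structure(cand, class = c("band_set", "data.frame")))
  }
  cand <- cand[order(-abs(cand$loading), cand$band_index, cand$pc), ,
               drop = FALSE]
  kept <- integer(0)
  for (i in seq_len(nrow(cand))) {
    if (length(kept) >= k_bands) break
    wl <- cand$wavelength[i]
    if (length(kept) == 0L ||
        all(abs(cand$wavelength[kept] - wl) >= merge_window_nm))
      kept <- c(kept, i)
  }
  if (length(kept) < k_bands)
    warning("only ", length(kept), " of ", k_bands,
            " requested bands could be selected")
  out <- cand[kept, , drop = FALSE]
  out <- out[order(out$wavelength), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, class = c("band_set", "data.frame"))
}

#' @export
print.band_set <- function(x, ...) {
  cat(sprintf("<band_set> %d effective wavelengths\n", nrow(x)))
  print.data.frame(x, ...)
  invisible(x)
}

#' Serialize a band set to JSON
#'
#' @param bands a `band_set` from [select_bands()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_band_set <- function(bands, path) {
  stopifnot(inherits(bands, "band_set"))
  jsonlite::write_json(
    list(version = 1L,
         bands = data.frame(wavelength_nm = bands$wavelength,
                            band_index = bands$band_index,
                            pc = bands$pc, kind = bands$kind)),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
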