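#' Write a spectrum table as CSV
#'
#' Columns: `sample_id`, `label`, then one column per wavelength
#' (`wl_<nm>`).
#'
#' @param X n x p matrix of mean spectra.
#' @param wavelengths length-p band grid, nm.
#' @param labels optional length-n labels (blank if omitted).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_spectra <- function(X, wavelengths, labels = NULL, path) {
  X <- as.matrix(X)
  stopifnot(ncol(X) == length(wavelengths))
  df <- data.frame(sample_id = seq_len(nrow(X)),
                   label = if (is.null(labels)) "" else as.character(labels))
  spec <- as.data.frame(X)
  names(spec) <- paste0("wl_", format(wavelengths, trim = TRUE))
  utils::write.csv(cbind(df, spec), path, row.names = FALSE)
  invisible(path)
}

#' Read a spectrum table written by [write_spectra()]
#'
#' @param path CSV path.
#' @return List with `X` (matrix), `wavelengths`, `labels`.
#' @export
read_spectra <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  wl_cols <- grep("^wl_", names(df))
  list(X = as.matrix(df[, wl_cols, drop = FALSE]),
       wavelengths = as.numeric(sub("^wl_", "", names(df)[wl_cols])),
       labels = as.character(df$label))
}

#' Serialize a fitted model to versioned JSON
#'
#' Supports `pca_model`, `kpca_model`, `lssvm`, `lssvm_binary` and `bpnn`
#' objects; all components are plain numeric vectors/matrices, so JSON is
#' lossless at full double precision.
#'
#' @param model a supported fitted model.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_model_json <- function(model, path) {
  cls <- class(model)[1L]
  if (!cls %in% c("pca_model", "kpca_model", "lssvm", "lssvm_binary",
                  "bpnn"))
    stop("unsupported model class: ", cls)
  payload <- list(container_version = 1L, model_class = cls,
                  fields = unclass_deep(model))
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Read a model written by [write_model_json()]
#'
#' @param path JSON path.
#' @return The fitted model with its class restored.
#' @export
read_model_json <- function(path) {
  payload <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(payload$container_version) || is.null(payload$model_class))
    stop("not a model container: ", path)
  model <- reclass_deep(payload$fields, payload$model_class)
  model
}

unclass_deep <- function(x) {
  if (inherits(x, "lssvm")) {
    x <- unclass(x)
    x$machines <- lapply(x$machines, unclass_deep)
    return(x)
  }
  if (is.list(x) && !is.data.frame(x)) return(lapply(unclass(x), unclass_deep))
  if (is.matrix(x)) return(list(.matrix = TRUE, dim = dim(x),
                                data = as.vector(x)))
  x
}

reclass_deep <- function(fields, cls) {
  restore <- function(x) {
    if (is.list(x)) {
      if (isTRUE(x$.matrix))
        return(matrix(as.numeric(x$data), x$dim[1L], x$dim[2L]))
      return(lapply(x, restore))
    }
    x
  }
  model <- restore(fields)
  if (cls == "lssvm")
    model$machines <- lapply(model$machines, function(m)
      structure(m, class = "lssvm_binary"))
  structure(model, class = cls)
}
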