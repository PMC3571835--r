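#' Stratified calibration/prediction split
#'
#' Draws `n_cal_per_class` samples per class without replacement (seeded)
#' into the calibration set; the remainder forms the prediction set. A
#' six-variety study with 55 samples each and 40 per class calibrates on
#' 240 and predicts on 90.
#'
#' @param labels length-n class labels.
#' @param n_cal_per_class calibration samples per class; every class must
#'   have strictly more members.
#' @param seed integer seed.
#' @return An object of class `split_plan`: `calibration` and `prediction`
#'   (sorted integer indices), `per_class` counts, `seed`.
#' @export
stratified_split <- function(labels, n_cal_per_class, seed = 1) {
  labels <- as.character(labels)
  classes <- sort(unique(labels))
  sizes <- table(labels)
  too_small <- names(sizes)[sizes <= n_cal_per_class]
  if (length(too_small))
    stop("class ", paste(too_small, collapse = ", "), " has <= ",
         n_cal_per_class, " members; cannot split")
  cal <- with_seed(seed, unlist(lapply(classes, function(cl) {
    idx <- which(labels == cl)
    idx[sample.int(length(idx), n_cal_per_class)]
  })))
  cal <- sort(cal)
  structure(list(calibration = cal,
                 prediction = setdiff(seq_along(labels), cal),
                 per_class = stats::setNames(rep(n_cal_per_class,
                                                 length(classes)), classes),
                 seed = seed),
            class = "split_plan")
}

#' @export
print.split_plan <- function(x, ...) {
  cat(sprintf("<split_plan> %d calibration / %d prediction samples (%d per class calibrated)\n",
              length(x$calibration), length(x$prediction),
              x$per_class[[1L]]))
  invisible(x)
}

#' Assemble a feature matrix for one input combination
#'
#' Concatenates the requested feature blocks, spectral block first, then
#' the texture block (band-major), for one of the four canonical input
#' combinations: `"PC"`, `"PC+GLCM"`, `"KPC"`, `"KPC+GLCM"`.
#'
#' @param pc_scores n x k PCA score matrix (or NULL if unused).
#' @param kpc_scores n x k KPCA score matrix (or NULL if unused).
#' @param texture_vectors n x (4 * bands) GLCM feature matrix (or NULL).
#' @param mode combination tag.
#' @param labels optional length-n labels carried along.
#' @return An object of class `feature_matrix`: `X` (named columns),
#'   `labels`, `mode`.
#' @export
assemble_features <- function(pc_scores = NULL, kpc_scores = NULL,
                              texture_vectors = NULL,
                              mode = c("PC", "PC+GLCM", "KPC", "KPC+GLCM"),
                              labels = NULL) {
  mode <- match.arg(mode)
  spectral <- if (startsWith(mode, "KPC")) kpc_scores else pc_scores
  if (is.null(spectral))
    stop("mode ", mode, " needs ",
         if (startsWith(mode, "KPC")) "kpc_scores" else "pc_scores")
  spectral <- as.matrix(spectral)
  if (is.null(colnames(spectral)))
    colnames(spectral) <- paste0(if (startsWith(mode, "KPC")) "kpc_"
                                 else "pc_", seq_len(ncol(spectral)))
  blocks <- list(spectral)
  if (endsWith(mode, "GLCM")) {
    if (is.null(texture_vectors))
      stop("mode ", mode, " needs texture_vectors")
    tex <- as.matrix(texture_vectors)
    if (nrow(tex) != nrow(spectral))
      stop("feature blocks disagree in row count (", nrow(spectral),
           " vs ", nrow(tex), ")")
    blocks <- c(blocks, list(tex))
  }
  X <- do.call(cbind, blocks)
  if (!is.null(labels) && length(labels) != nrow(X))
    stop("labels length does not match feature rows")
  structure(list(X = X, labels = labels, mode = mode),
            class = "feature_matrix")
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat(sprintf("<feature_matrix> %s: %d samples x %d features\n",
              x$mode, nrow(x$X), ncol(x$X)))
  invisible(x)
}

#' Classification accuracy report
#'
#' Accuracy in percent (`100 * correct / n`), the confusion matrix in fixed
#' class order, and the misclassified sample positions. `NA` predictions
#' (e.g. BPNN-unrecognized samples) count as errors and appear in an
#' `(unrecognized)` confusion column.
#'
#' @param true_labels,predicted_labels equal-length label vectors;
#'   `predicted_labels` may contain `NA`.
#' @param classes optional fixed class order; defaults to
#'   `sort(unique(true_labels))`.
#' @return An object of class `evaluation_report`: `accuracy_pct` (full
#'   precision), `accuracy_pct_2dp`, `confusion`, `misclassified`, `n`.
#' @export
evaluate <- function(true_labels, predicted_labels, classes = NULL) {
  true_labels <- as.character(true_labels)
  predicted_labels <- as.character(predicted_labels)
  if (length(true_labels) != length(predicted_labels))
    stop("label vectors differ in length")
  if (is.null(classes)) classes <- sort(unique(true_labels))
  correct <- !is.na(predicted_labels) & predicted_labels == true_labels
  acc <- 100 * mean(correct)
  pred_levels <- c(classes,
                   if (anyNA(predicted_labels)) "(unrecognized)")
  pred_f <- factor(ifelse(is.na(predicted_labels), "(unrecognized)",
                          predicted_labels), levels = pred_levels)
  confusion <- table(true = factor(true_labels, levels = classes),
                     predicted = pred_f)
  structure(list(accuracy_pct = acc, accuracy_pct_2dp = round(acc, 2),
                 confusion = confusion,
                 misclassified = which(!correct),
                 n = length(true_labels)),
            class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf("<evaluation_report> accuracy %.2f%% (%d/%d correct)\n",
              x$accuracy_pct_2dp, x$n - length(x$misclassified), x$n))
  print(x$confusion)
  invisible(x)
}

#' Run the full variety-discrimination experiment
#'
#' Executes the complete pipeline on a dataset of raw sample cubes:
#' calibrate -> spectral crop -> mean spectra -> stratified split ->
#' PCA/KPCA on calibration spectra -> effective-wavelength selection on a
#' calibration-pixel montage -> GLCM texture at the selected bands ->
#' per-combination LS-SVM grid search, LS-SVM and BPNN training ->
#' evaluation on calibration and prediction sets. Every data-driven choice
#' (split, PCA/KPCA fit, band selection, feature scaling, grid search) uses
#' calibration samples only. Fully deterministic for a fixed seed.
#'
#' @param dataset a `synthetic_dataset`, or any list with `cubes` (raw
#'   [hypercube]s), `labels` and `refs` (a [reference_pair]).
#' @param n_cal_per_class calibration samples per class; default
#'   `round(40/55 * min class size)`, the classical 240-of-330 proportion.
#' @param crop_nm spectral window kept for analysis, nm.
#' @param k_components retained PCA/KPCA components.
#' @param k_bands effective wavelengths to select.
#' @param Ng GLCM gray-level count.
#' @param merge_window_nm minimum separation of selected wavelengths.
#' @param extrema_window loading extrema detection window (bands).
#' @param montage_pixels pixels sampled per calibration ROI for the
#'   band-selection image PCA.
#' @param gamma_grid,sigma2_grid,folds LS-SVM grid-search settings.
#' @param bpnn_hidden,bpnn_learn_rate,bpnn_momentum,bpnn_goal_mse,bpnn_max_epochs
#'   BPNN settings.
#' @param autoscale z-score features with calibration statistics before
#'   classification.
#' @param seed master seed; all stage seeds derive from it.
#' @param modes feature combinations to run.
#' @return An object of class `experiment_result`: `summary` (data.frame
#'   with one row per mode and LS-SVM/BPNN calibration/prediction accuracy
#'   columns, 2 dp), `reports` (full [evaluate()] reports keyed
#'   `<mode>_<classifier>_<set>`), `band_set`, `split`, `grids`
#'   (per-mode `lssvm_grid`), leakage bookkeeping (`band_selection_ids`,
#'   `grid_search_ids`) and the `config` echo.
#' @export
run_experiment <- function(dataset,
                           n_cal_per_class = NULL,
                           crop_nm = c(500, 900),
                           k_components = 3,
                           k_bands = 3,
                           Ng = 8,
                           merge_window_nm = 10,
                           extrema_window = 5,
                           montage_pixels = 1000,
                           gamma_grid = 2^(-1:10),
                           sigma2_grid = 2^(1:15),
                           folds = 10,
                           bpnn_hidden = 9,
                           bpnn_learn_rate = 0.5,
                           bpnn_momentum = 0.6,
                           bpnn_goal_mse = 1e-5,
                           bpnn_max_epochs = 1000,
                           autoscale = TRUE,
                           seed = 42,
                           modes = c("PC", "PC+GLCM", "KPC", "KPC+GLCM")) {
  stopifnot(!is.null(dataset$cubes), !is.null(dataset$labels),
            !is.null(dataset$refs))
  labels <- as.character(dataset$labels)
  n <- length(dataset$cubes)
  if (is.null(n_cal_per_class))
    n_cal_per_class <- round(40 / 55 * min(table(labels)))

  # stage 1: calibrate + crop every sample; keep cropped cubes for texture
  stage <- function(what, expr) {
    tryCatch(expr, error = function(e)
      stop("stage [", what, "] failed: ", conditionMessage(e),
           call. = FALSE))
  }
  cropped <- stage("calibrate/crop", lapply(dataset$cubes, function(cb) {
    cal <- calibrate_reflectance(cb, dataset$refs)
    cal$qc <- NULL
    crop_spectral(cal, crop_nm[1L], crop_nm[2L])
  }))
  rois <- lapply(cropped, function(cb)
    roi(cb, c(1L, 1L), min(dim(cb$data)[1:2])))
  spectra <- stage("mean spectra",
                   t(vapply(rois, mean_spectrum,
                            numeric(length(cropped[[1L]]$wavelengths)))))

  # stage 2: split, then fit everything on calibration only
  split <- stage("split",
                 stratified_split(labels, n_cal_per_class,
                                  seed = derive_seed(seed, 1)))
  cal <- split$calibration
  classes <- sort(unique(labels))

  pca <- stage("pca", fit_pca(spectra[cal, , drop = FALSE], k_components))
  pc_scores <- project_pca(pca, spectra)
  kpca <- stage("kpca", fit_kpca(spectra[cal, , drop = FALSE],
                                 sigma2_k = "auto", k = k_components))
  kpc_scores <- project_kpca(kpca, spectra)

  # stage 3: band selection from a calibration-pixel montage
  wl <- cropped[[1L]]$wavelengths
  montage <- stage("band selection montage", {
    do.call(rbind, lapply(seq_along(cal), function(ii) {
      cb <- cropped[[cal[ii]]]
      d <- dim(cb$data)
      M <- matrix(cb$data, nrow = d[1L] * d[2L], ncol = d[3L])
      take <- min(montage_pixels, nrow(M))
      pick <- with_seed(derive_seed(seed, 100 + ii),
                       sample.int(nrow(M), take))
      M[pick, , drop = FALSE]
    }))
  })
  montage_pca <- stage("image pca", fit_pca(montage, min(3, k_components)))
  profile <- loading_profile(montage_pca$loadings, wl,
                             montage_pca$explained_variance_ratio)
  band_set <- stage("band selection",
                    select_bands(profile, k_bands = k_bands,
                                 merge_window_nm = merge_window_nm,
                                 window = extrema_window))

  # stage 4: GLCM texture at the selected bands, all samples
  tex <- stage("texture", t(vapply(rois, texture_vector,
                                   numeric(4L * nrow(band_set)),
                                   bands = band_set, Ng = Ng)))

  # stage 5: train + evaluate the 4 x 2 model grid
  reports <- list()
  grids <- list()
  summary_rows <- list()
  for (mode in modes) {
    fm <- assemble_features(pc_scores = pc_scores, kpc_scores = kpc_scores,
                            texture_vectors = tex, mode = mode,
                            labels = labels)
    X <- fm$X
    if (autoscale) {
      mu <- colMeans(X[cal, , drop = FALSE])
      sd_ <- apply(X[cal, , drop = FALSE], 2L, stats::sd)
      sd_[sd_ == 0] <- 1
      X <- sweep(sweep(X, 2L, mu), 2L, sd_, `/`)
    }
    Xcal <- X[cal, , drop = FALSE]
    Xpred <- X[split$prediction, , drop = FALSE]
    ycal <- labels[cal]
    ypred <- labels[split$prediction]

    gs <- stage(paste0("grid search ", mode),
                grid_search_lssvm(Xcal, ycal, gamma_grid = gamma_grid,
                                  sigma2_grid = sigma2_grid, folds = folds,
                                  seed = derive_seed(seed, 2)))
    grids[[mode]] <- gs
    svm <- stage(paste0("lssvm ", mode),
                 fit_lssvm(Xcal, ycal, gamma = gs$best_gamma,
                           sigma2 = gs$best_sigma2, classes = classes))
    reports[[paste0(mode, "_lssvm_calibration")]] <-
      evaluate(ycal, predict(svm, Xcal), classes)
    reports[[paste0(mode, "_lssvm_prediction")]] <-
      evaluate(ypred, predict(svm, Xpred), classes)

    nn <- stage(paste0("bpnn ", mode),
                fit_bpnn(Xcal, ycal, hidden = bpnn_hidden,
                         learn_rate = bpnn_learn_rate,
                         momentum = bpnn_momentum,
                         goal_mse = bpnn_goal_mse,
                         max_epochs = bpnn_max_epochs,
                         seed = derive_seed(seed, 3)))
    reports[[paste0(mode, "_bpnn_calibration")]] <-
      evaluate(ycal, predict(nn, Xcal)$labels, classes)
    reports[[paste0(mode, "_bpnn_prediction")]] <-
      evaluate(ypred, predict(nn, Xpred)$labels, classes)

    summary_rows[[mode]] <- data.frame(
      method = mode,
      lssvm_calibration =
        reports[[paste0(mode, "_lssvm_calibration")]]$accuracy_pct_2dp,
      lssvm_prediction =
        reports[[paste0(mode, "_lssvm_prediction")]]$accuracy_pct_2dp,
      bpnn_calibration =
        reports[[paste0(mode, "_bpnn_calibration")]]$accuracy_pct_2dp,
      bpnn_prediction =
        reports[[paste0(mode, "_bpnn_prediction")]]$accuracy_pct_2dp)
  }
  summary <- do.call(rbind, summary_rows)
  rownames(summary) <- NULL

  structure(list(summary = summary, reports = reports,
                 band_set = band_set, split = split, grids = grids,
                 band_selection_ids = cal, grid_search_ids = cal,
                 config = list(n_cal_per_class = n_cal_per_class,
                               crop_nm = crop_nm,
                               k_components = k_components,
                               k_bands = k_bands, Ng = Ng,
                               merge_window_nm = merge_window_nm,
                               extrema_window = extrema_window,
                               montage_pixels = montage_pixels,
                               gamma_grid = gamma_grid,
                               sigma2_grid = sigma2_grid, folds = folds,
                               bpnn_hidden = bpnn_hidden,
                               bpnn_learn_rate = bpnn_learn_rate,
                               bpnn_momentum = bpnn_momentum,
                               bpnn_goal_mse = bpnn_goal_mse,
                               bpnn_max_epochs = bpnn_max_epochs,
                               autoscale = autoscale, seed = seed,
                               modes = modes)),
            class = "experiment_result")
}

#' @export
print.experiment_result <- function(x, ...) {
  cat("<experiment_result> accuracy (%) by input combination:\n")
  print(x$summary, row.names = FALSE)
  cat(sprintf("effective wavelengths: %s nm\n",
              paste(round(x$band_set$wavelength, 1), collapse = ", ")))
  invisible(x)
}

#' Write the experiment summary table as CSV
#'
#' @param result an `experiment_result`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_summary <- function(result, path) {
  stopifnot(inherits(result, "experiment_result"))
  utils::write.csv(result$summary, path, row.names = FALSE)
  invisible(path)
}
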