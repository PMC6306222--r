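#' Fit the ensemble-of-trees climate envelope model
#'
#' Trains an ensemble of classification trees (backed by \pkg{ranger})
#' associating the coarse vegetation class of each climate cell with its
#' bioclimatic predictors. Each tree is grown on a seeded random subsample of
#' `1 - holdout` of the assigned cells drawn without replacement; the
#' excluded 20% (by default) accumulates an out-of-bag misclassification
#' estimate. Variable importance is mean impurity (Gini) decrease. The fit
#' is deterministic given the seed.
#'
#' @param climate [climate_surface()] of predictors.
#' @param veg Coarse [categorical_raster()] on the same grid (the response).
#' @param n_trees Number of trees (default 200).
#' @param holdout Per-tree holdout fraction in (0, 1) (default 0.2).
#' @param seed Integer seed (required).
#' @param replace Draw per-tree subsamples with replacement (bootstrap)
#'   instead of the default without-replacement subsampling.
#' @param variables Predictor layers to use; default all layers.
#' @return An `envelope_fit` with the fitted ensemble, out-of-bag error and
#'   confusion matrix, impurity importance, the class vocabulary and the
#'   training-cell index.
#' @export
fit_envelope <- function(climate, veg, n_trees = 200, holdout = 0.2, seed,
                         replace = FALSE,
                         variables = names(climate$layers)) {
  stopifnot(inherits(climate, "climate_surface"),
            inherits(veg, "categorical_raster"))
  check_same_grid(c(climate$nrow, climate$ncol), dim(veg$values))
  if (n_trees < 1) stop("n_trees must be >= 1", call. = FALSE)
  if (holdout <= 0 || holdout >= 1) {
    stop("holdout must be in (0, 1)", call. = FALSE)
  }
  if (missing(seed) || is.null(seed)) stop("seed is required", call. = FALSE)
  require_layers(climate, variables)
  valid <- surface_mask(climate) & !is.na(veg$values)
  idx <- which(valid)  # column-major cell index into the grid
  if (length(idx) < 2L) stop("too few assigned cells to fit", call. = FALSE)
  preds <- lapply(climate$layers[variables], function(l) l[idx])
  for (v in variables) {
    bad <- which(!is.finite(preds[[v]]))
    if (length(bad)) {
      cell <- arrayInd(idx[bad[1]], c(climate$nrow, climate$ncol))
      stop("non-finite predictor '", v, "' at assigned cell (row ",
           cell[1], ", col ", cell[2], ")", call. = FALSE)
    }
  }
  y_codes <- veg$values[idx]
  counts <- tabulate(y_codes, nbins = length(veg$classes))
  present <- veg$classes[counts > 0]
  if (length(present) < 2L) {
    stop("need >= 2 classes present to fit an envelope", call. = FALSE)
  }
  rare <- veg$classes[counts > 0 & counts < 2]
  if (length(rare)) {
    warning("class(es) with < 2 cells retained: ",
            paste(rare, collapse = ", "), call. = FALSE)
  }
  df <- as.data.frame(preds)
  df$.class <- factor(veg$classes[y_codes], levels = present)
  forest <- ranger::ranger(
    dependent.variable.name = ".class", data = df,
    num.trees = n_trees, sample.fraction = 1 - holdout, replace = replace,
    importance = "impurity", seed = seed, num.threads = 1,
    oob.error = TRUE)
  structure(list(forest = forest, classes = veg$classes,
                 trained_classes = present, variables = variables,
                 n_trees = n_trees, holdout = holdout, replace = replace,
                 seed = seed, training_cells = idx,
                 oob_error = forest$prediction.error,
                 oob_confusion = forest$confusion.matrix,
                 importance = forest$variable.importance),
            class = "envelope_fit")
}

#' @export
print.envelope_fit <- function(x, ...) {
  cat("<envelope_fit> ", x$n_trees, " trees, per-tree holdout ",
      x$holdout, ", ", length(x$training_cells), " cells, ",
      length(x$trained_classes), " classes\n", sep = "")
  cat("out-of-bag misclassification: ",
      sprintf("%.1f%%", 100 * x$oob_error), "\n", sep = "")
  imp <- sort(x$importance, decreasing = TRUE)
  cat("importance ranking: ", paste(names(imp), collapse = " > "), "\n",
      sep = "")
  invisible(x)
}

#' Predict per-class relative likelihoods
#'
#' Applies the fitted ensemble to a climate surface and returns, per cell,
#' the fraction of trees voting for each class: a K-vector in `[0, 1]`
#' summing to 1 over the full class vocabulary (classes absent from training
#' get 0). Cells that are masked or have a non-finite predictor get an
#' all-`NA` row.
#'
#' @param fit An `envelope_fit`.
#' @param climate [climate_surface()] providing every predictor used in
#'   fitting.
#' @param provenance Optional label recorded on the output (e.g. the
#'   scenario label).
#' @return A [likelihood_map()].
#' @export
predict_likelihood <- function(fit, climate, provenance = character()) {
  stopifnot(inherits(fit, "envelope_fit"),
            inherits(climate, "climate_surface"))
  require_layers(climate, fit$variables)
  valid <- surface_mask(climate)
  for (v in fit$variables) valid <- valid & is.finite(climate$layers[[v]])
  idx <- which(valid)
  k <- length(fit$classes)
  scores_cm <- matrix(NA_real_, climate$nrow * climate$ncol, k)
  if (length(idx)) {
    df <- as.data.frame(lapply(climate$layers[fit$variables],
                               function(l) l[idx]))
    votes <- stats::predict(fit$forest, data = df, predict.all = TRUE,
                            num.threads = 1)$predictions
    lev <- fit$forest$forest$levels
    frac <- matrix(0, length(idx), k)
    for (j in seq_along(lev)) {
      col <- match(lev[j], fit$classes)
      frac[, col] <- rowSums(votes == j) / ncol(votes)
    }
    scores_cm[idx, ] <- frac
  }
  # column-major cell rows -> row-major order used by likelihood_map
  rm_order <- matrix_to_cells(matrix(seq_len(climate$nrow * climate$ncol),
                                     climate$nrow, climate$ncol))
  likelihood_map(scores_cm[rm_order, , drop = FALSE],
                 climate$nrow, climate$ncol, fit$classes,
                 provenance = provenance)
}

#' Assess envelope model predictions against a vegetation map
#'
#' Predicts on the supplied climate, assigns by argmax, and compares with
#' the reference map: confusion matrix (true rows x predicted columns),
#' misclassification rate, per-class accuracy (diagonal over row sum; `NA`
#' for classes absent from `veg`), and the impurity-importance ranking (ties
#' broken by variable order).
#'
#' @param fit An `envelope_fit`.
#' @param climate [climate_surface()] to predict on.
#' @param veg Reference [categorical_raster()] on the same grid.
#' @return A `model_assessment` list: `confusion`,
#'   `misclassification_rate`, `per_class_accuracy`, `importance_ranking`
#'   (data frame `variable`, `importance`), `oob_error`.
#' @export
evaluate <- function(fit, climate, veg) {
  stopifnot(inherits(veg, "categorical_raster"))
  check_same_grid(c(climate$nrow, climate$ncol), dim(veg$values))
  lik <- predict_likelihood(fit, climate)
  pred <- assign_argmax(lik)
  truth <- as.vector(veg$values)
  guess <- as.vector(pred$values)
  ok <- !is.na(truth) & !is.na(guess)
  classes <- fit$classes
  confusion <- table(
    true = factor(classes[truth[ok]], levels = classes),
    predicted = factor(classes[guess[ok]], levels = classes))
  confusion <- unclass(confusion)
  total <- sum(confusion)
  rate <- if (total > 0) 1 - sum(diag(confusion)) / total else NA_real_
  rowsums <- rowSums(confusion)
  acc <- ifelse(rowsums > 0, diag(confusion) / rowsums, NA_real_)
  names(acc) <- classes
  imp <- fit$importance
  ord <- order(-imp, seq_along(imp))
  structure(list(confusion = confusion, misclassification_rate = rate,
                 per_class_accuracy = acc,
                 importance_ranking = data.frame(
                   variable = names(imp)[ord],
                   importance = unname(imp[ord]),
                   stringsAsFactors = FALSE),
                 oob_error = fit$oob_error),
            class = "model_assessment")
}

#' @export
print.model_assessment <- function(x, ...) {
  cat("<model_assessment> misclassification ",
      sprintf("%.1f%%", 100 * x$misclassification_rate),
      " (out-of-bag ", sprintf("%.1f%%", 100 * x$oob_error), ")\n", sep = "")
  cat("per-class accuracy:\n")
  print(round(100 * x$per_class_accuracy))
  cat("importance ranking: ",
      paste(x$importance_ranking$variable, collapse = " > "), "\n", sep = "")
  invisible(x)
}

#' Expected misclassification of uniform random assignment
#'
#' Assigning each of `k` classes uniformly at random misclassifies a cell
#' unless the draw hits the true class, so the expected error is
#' `(k - 1) / k` regardless of the true class frequencies (for 10 classes:
#' 90%).
#'
#' @param k Number of classes (>= 1).
#' @return `(k - 1) / k`.
#' @export
random_baseline_misclassification <- function(k) {
  if (length(k) != 1L || is.na(k) || k < 1 || k != as.integer(k)) {
    stop("k must be a positive integer", call. = FALSE)
  }
  (k - 1) / k
}
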