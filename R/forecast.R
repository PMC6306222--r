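#' Average relative-likelihood maps across scenario outputs
#'
#' Per-cell, per-class arithmetic mean of the input maps. Means of
#' normalised vectors are normalised, so no re-normalisation is applied.
#'
#' @param maps List of [likelihood_map()] objects on one grid with one class
#'   vocabulary.
#' @return A [likelihood_map()] whose provenance concatenates the inputs'.
#' @export
ensemble_average <- function(maps) {
  if (inherits(maps, "likelihood_map")) maps <- list(maps)
  if (!length(maps)) stop("at least one likelihood map required",
                          call. = FALSE)
  ref <- maps[[1]]
  for (m in maps[-1]) {
    if (!identical(m$classes, ref$classes)) {
      stop("class vocabularies differ: [",
           paste(setdiff(union(m$classes, ref$classes),
                         intersect(m$classes, ref$classes)),
                 collapse = ", "), "]", call. = FALSE)
    }
    check_same_grid(c(m$nrow, m$ncol), c(ref$nrow, ref$ncol))
  }
  avg <- Reduce(`+`, lapply(maps, `[[`, "scores")) / length(maps)
  likelihood_map(avg, ref$nrow, ref$ncol, ref$classes,
                 provenance = unlist(lapply(maps, `[[`, "provenance")))
}

#' Assign vegetation by maximum relative likelihood
#'
#' Per cell, the class with the largest likelihood component; ties are
#' broken by the smallest class index. Cells with `NA` score rows stay
#' no-data; a non-finite component in an otherwise valid row is an error.
#'
#' @param map A normalised [likelihood_map()].
#' @return A [categorical_raster()] with `rule = "argmax"`.
#' @export
assign_argmax <- function(map) {
  stopifnot(inherits(map, "likelihood_map"))
  s <- map$scores
  valid <- !apply(is.na(s), 1, all)
  partial <- valid & !apply(is.finite(s), 1, all)
  if (any(partial)) {
    stop("non-finite likelihood component at cell_id ",
         which(partial)[1] - 1L, call. = FALSE)
  }
  code <- rep(NA_integer_, nrow(s))
  if (any(valid)) {
    code[valid] <- max.col(s[valid, , drop = FALSE], ties.method = "first")
  }
  categorical_raster(cells_to_matrix(code, map$nrow, map$ncol),
                     map$classes, rule = "argmax")
}

#' Assign vegetation with the legacy-persistence threshold rule
#'
#' Ecological legacies (soils, seed banks, dispersal from intact stands)
#' favour re-establishment of the standing vegetation unless its climate
#' niche has radically shifted. The rule retains the historical class
#' wherever its own likelihood component is strictly greater than
#' `threshold` (default `1/K`), even when another class scores higher;
#' otherwise, and wherever no historical class exists, the argmax class is
#' assigned.
#'
#' @param map A normalised [likelihood_map()].
#' @param historical Coarse [categorical_raster()] of historical vegetation
#'   on the same grid; its classes must be contained in the map vocabulary.
#' @param threshold Retention threshold in `[0, 1)`; default
#'   [default_threshold()] of the vocabulary size.
#' @return A [categorical_raster()] with `rule = "legacy_threshold"`.
#' @export
assign_with_legacy_threshold <- function(map, historical, threshold = NULL) {
  stopifnot(inherits(map, "likelihood_map"),
            inherits(historical, "categorical_raster"))
  check_same_grid(c(map$nrow, map$ncol), dim(historical$values))
  if (is.null(threshold)) threshold <- default_threshold(length(map$classes))
  # threshold >= 1 is permitted: retention then never fires (pure argmax)
  if (threshold < 0) stop("threshold must be >= 0", call. = FALSE)
  hist_in_vocab <- match(historical$classes, map$classes)
  if (anyNA(hist_in_vocab)) {
    stop("historical class(es) absent from vocabulary: ",
         paste(historical$classes[is.na(hist_in_vocab)], collapse = ", "),
         call. = FALSE)
  }
  out <- assign_argmax(map)
  hist_code <- hist_in_vocab[matrix_to_cells(historical$values)]
  code <- matrix_to_cells(out$values)
  cells <- which(!is.na(hist_code) & !is.na(code))
  if (length(cells)) {
    hl <- map$scores[cbind(cells, hist_code[cells])]
    keep <- cells[hl > threshold]
    code[keep] <- hist_code[keep]
  }
  categorical_raster(cells_to_matrix(code, map$nrow, map$ncol),
                     map$classes, rule = "legacy_threshold")
}

#' Default legacy-persistence threshold
#'
#' With `k` classes splitting a relative likelihood that sums to one, the
#' neutral retention threshold is `1/k` (0.1 for 10 classes).
#'
#' @param k Number of classes (>= 1).
#' @return `1/k`.
#' @export
default_threshold <- function(k) {
  if (length(k) != 1L || is.na(k) || k < 1 || k != as.integer(k)) {
    stop("k must be a positive integer", call. = FALSE)
  }
  1 / k
}
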