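#' Majority-area rescaling of a fine categorical map to climate cells
#'
#' Aggregates a fine vegetation map into climate cells of
#' `fine_factor x fine_factor` pixel blocks. Per cell, class area fractions
#' are computed over *classified* (non no-data) pixels only; the cell is
#' assigned the class with the largest fraction, ties broken by the smallest
#' class index. Cells with zero classified pixels become no-data.
#'
#' @param fine A [categorical_raster()] whose dimensions are exact integer
#'   multiples of the climate grid.
#' @param fine_factor Pixels per cell side; defaults to the raster's own
#'   `fine_factor`.
#' @return A list with `map` (coarse [categorical_raster()]) and
#'   `composition` (class `cell_composition`: `fractions`, an
#'   `nrow x ncol x K` array summing to 1 over classes wherever the cell has
#'   classified pixels, and `classified_fraction`, the per-cell fraction of
#'   classified fine pixels).
#' @export
majority_rescale <- function(fine, fine_factor = fine$fine_factor) {
  stopifnot(inherits(fine, "categorical_raster"))
  if (is.null(fine_factor)) stop("fine_factor is required", call. = FALSE)
  f <- as.integer(fine_factor)
  nrf <- nrow(fine$values); ncf <- ncol(fine$values)
  if (nrf %% f != 0L || ncf %% f != 0L) {
    stop("fine grid ", nrf, "x", ncf, " is not divisible by fine_factor ",
         f, " (coarse grid would be ", nrf / f, "x", ncf / f, ")",
         call. = FALSE)
  }
  nr <- nrf %/% f; nc <- ncf %/% f
  k <- length(fine$classes)
  # block id per fine pixel, then per-class counts via tabulation
  block_row <- (seq_len(nrf) - 1L) %/% f
  block_col <- (seq_len(ncf) - 1L) %/% f
  block_id <- outer(block_row, block_col * nr, "+") + 1L  # column-major ids
  counts <- matrix(0L, nr * nc, k)
  vals <- as.vector(fine$values)
  ids <- as.vector(block_id)
  ok <- !is.na(vals)
  for (cls in seq_len(k)) {
    counts[, cls] <- tabulate(ids[ok & vals == cls], nbins = nr * nc)
  }
  n_classified <- rowSums(counts)
  assign <- max.col(counts, ties.method = "first")  # smallest index wins
  assign[n_classified == 0] <- NA_integer_
  fractions <- counts / ifelse(n_classified > 0, n_classified, 1)
  fractions[n_classified == 0, ] <- NA_real_
  comp <- structure(
    list(fractions = array(fractions, dim = c(nr, nc, k)),
         classified_fraction = matrix(n_classified / (f * f), nr, nc),
         classes = fine$classes),
    class = "cell_composition")
  list(map = categorical_raster(matrix(assign, nr, nc), fine$classes),
       composition = comp)
}

#' Composition and co-occurrence statistics of rescaled cells
#'
#' For each vegetation class `c`: the mean area fraction of `c` over cells
#' assigned `c` ("percent area", i.e. how much of an assigned cell the class
#' actually covered before rescaling), and the other classes whose mean
#' fraction over those cells is at least `co_threshold` (co-occurring
#' classes, sorted by decreasing share). A class never assigned has no
#' defined percent area and is reported `NA` with an empty co-occurrence
#' list.
#'
#' @param comp `cell_composition` from [majority_rescale()].
#' @param assign Coarse [categorical_raster()] on the same grid.
#' @param co_threshold Inclusion threshold for co-occurrence (default 0.10;
#'   the rule is inclusive, `>=`).
#' @return A list with `table` (data frame: `class`, `n_cells`,
#'   `percent_area` in percent) and `co_occurring` (named list of named
#'   percent vectors).
#' @export
composition_stats <- function(comp, assign, co_threshold = 0.10) {
  stopifnot(inherits(comp, "cell_composition"),
            inherits(assign, "categorical_raster"))
  check_same_grid(dim(comp$fractions)[1:2], dim(assign$values))
  classes <- comp$classes
  k <- length(classes)
  fr <- matrix(comp$fractions, ncol = k)  # cells x classes, column-major
  av <- as.vector(assign$values)
  percent_area <- rep(NA_real_, k)
  n_cells <- integer(k)
  co <- stats::setNames(vector("list", k), classes)
  for (cls in seq_len(k)) {
    rows <- which(!is.na(av) & av == cls)
    n_cells[cls] <- length(rows)
    co[[cls]] <- stats::setNames(numeric(0), character(0))
    if (!length(rows)) next
    means <- colMeans(fr[rows, , drop = FALSE])
    percent_area[cls] <- 100 * means[cls]
    others <- means[-cls]
    names(others) <- classes[-cls]
    others <- sort(others[others >= co_threshold], decreasing = TRUE)
    co[[cls]] <- 100 * others
  }
  list(table = data.frame(class = classes, n_cells = n_cells,
                          percent_area = percent_area,
                          stringsAsFactors = FALSE),
       co_occurring = co)
}

#' Dominant misclassification targets per class
#'
#' From a confusion matrix (true classes in rows, predicted in columns),
#' reports for each true class the predicted classes receiving at least
#' `share_threshold` of that class's misclassified cells, sorted by
#' decreasing share. Classes with zero misclassified cells get an empty
#' entry.
#'
#' @param confusion Square numeric matrix with matching row/column names
#'   over the class vocabulary.
#' @param share_threshold Inclusion threshold (default 0.20, inclusive).
#' @return Named list (per true class) of named share vectors in percent.
#' @export
misclassification_profile <- function(confusion, share_threshold = 0.20) {
  stopifnot(is.matrix(confusion), nrow(confusion) == ncol(confusion))
  classes <- rownames(confusion)
  if (is.null(classes)) classes <- as.character(seq_len(nrow(confusion)))
  out <- stats::setNames(vector("list", length(classes)), classes)
  for (i in seq_along(classes)) {
    row <- confusion[i, ]
    wrong <- row
    wrong[i] <- 0
    total <- sum(wrong)
    if (total == 0) {
      out[[i]] <- stats::setNames(numeric(0), character(0))
      next
    }
    shares <- wrong / total
    names(shares) <- classes
    shares <- shares[-i]
    shares <- sort(shares[shares >= share_threshold], decreasing = TRUE)
    out[[i]] <- 100 * shares
  }
  out
}
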