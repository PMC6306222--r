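#' Gridded climate surface
#'
#' A `climate_surface` holds one numeric layer per bioclimatic variable on a
#' common coarse grid, plus a logical validity mask (`TRUE` = data present).
#' Layers are plain matrices indexed `[row, col]` with row 1 at the top
#' (north-up); cell identifiers used in exported tables are 0-based row-major.
#'
#' @param layers Named list of numeric matrices, all with identical dimensions.
#' @param mask Optional logical matrix of the same dimensions; `NULL` means
#'   every cell is valid.
#' @return An object of class `climate_surface` with elements `layers`,
#'   `nrow`, `ncol`, `mask`.
#' @export
climate_surface <- function(layers, mask = NULL) {
  if (!is.list(layers) || length(layers) == 0L) {
    stop("`layers` must be a non-empty named list of matrices", call. = FALSE)
  }
  nms <- names(layers)
  if (is.null(nms) || any(!nzchar(nms))) {
    stop("every layer must be named", call. = FALSE)
  }
  if (anyDuplicated(nms)) {
    stop("duplicate layer names: ",
         paste(unique(nms[duplicated(nms)]), collapse = ", "), call. = FALSE)
  }
  dims <- vapply(layers, dim, integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1])) {
    stop("all layers must share one grid", call. = FALSE)
  }
  nr <- dims[1, 1]; nc <- dims[2, 1]
  if (!is.null(mask)) {
    stopifnot(is.logical(mask), all(dim(mask) == c(nr, nc)))
  }
  structure(list(layers = layers, nrow = nr, ncol = nc, mask = mask),
            class = "climate_surface")
}

#' @export
print.climate_surface <- function(x, ...) {
  cat("<climate_surface> ", x$nrow, "x", x$ncol, " cells, ",
      length(x$layers), " variable(s): ",
      paste(names(x$layers), collapse = ", "), "\n", sep = "")
  invisible(x)
}

# valid-cell logical matrix (all TRUE when mask is NULL)
surface_mask <- function(surface) {
  if (is.null(surface$mask)) {
    matrix(TRUE, surface$nrow, surface$ncol)
  } else {
    surface$mask
  }
}

require_layers <- function(surface, vars) {
  missing <- setdiff(vars, names(surface$layers))
  if (length(missing)) {
    stop("missing climate layer(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  invisible(TRUE)
}

#' Categorical raster
#'
#' Integer-coded categorical grid (vegetation map or class assignment) with a
#' declared class vocabulary. `NA` encodes no-data. Codes index into
#' `classes` (code `k` means `classes[k]`).
#'
#' @param values Integer matrix of class codes (`NA` = no-data).
#' @param classes Character vector: the class vocabulary.
#' @param fine_factor Optional integer ratio of this grid to the climate grid.
#' @param rule Optional label describing the assignment rule that produced
#'   the map (e.g. `"argmax"`, `"legacy_threshold"`).
#' @return An object of class `categorical_raster`.
#' @export
categorical_raster <- function(values, classes, fine_factor = NULL,
                               rule = NULL) {
  stopifnot(is.matrix(values))
  storage.mode(values) <- "integer"
  classes <- as.character(classes)
  if (anyDuplicated(classes)) stop("duplicate class names", call. = FALSE)
  rng <- suppressWarnings(range(values, na.rm = TRUE))
  if (all(is.finite(rng)) && (rng[1] < 1L || rng[2] > length(classes))) {
    stop("class codes outside the declared vocabulary [1, ",
         length(classes), "]", call. = FALSE)
  }
  structure(list(values = values, classes = classes,
                 fine_factor = fine_factor, rule = rule),
            class = "categorical_raster")
}

#' @export
print.categorical_raster <- function(x, ...) {
  cat("<categorical_raster> ", nrow(x$values), "x", ncol(x$values),
      " cells, ", length(x$classes), " classes",
      if (!is.null(x$rule)) paste0(" [rule: ", x$rule, "]"), "\n", sep = "")
  tab <- table(factor(x$classes[x$values], levels = x$classes))
  print(tab)
  invisible(x)
}

#' Per-cell relative-likelihood map
#'
#' Scores are stored as an `n_cells x K` matrix in 0-based row-major cell
#' order (cell_id = row * ncol + col); rows for no-data cells are `NA`.
#' Every valid row sums to 1.
#'
#' @param scores Numeric matrix, one row per cell, one column per class.
#' @param nrow,ncol Grid dimensions.
#' @param classes Class vocabulary (column order of `scores`).
#' @param provenance Character vector of scenario labels that contributed.
#' @return An object of class `likelihood_map`.
#' @export
likelihood_map <- function(scores, nrow, ncol, classes,
                           provenance = character()) {
  stopifnot(is.matrix(scores), nrow(scores) == nrow * ncol,
            ncol(scores) == length(classes))
  colnames(scores) <- classes
  structure(list(scores = scores, nrow = nrow, ncol = ncol,
                 classes = as.character(classes),
                 provenance = as.character(provenance)),
            class = "likelihood_map")
}

#' @export
print.likelihood_map <- function(x, ...) {
  cat("<likelihood_map> ", x$nrow, "x", x$ncol, " cells, ",
      length(x$classes), " classes",
      if (length(x$provenance)) paste0(
        " [", paste(x$provenance, collapse = " + "), "]"), "\n", sep = "")
  invisible(x)
}

# row-major (top-left origin, by rows) flattening used for cell ids and
# score tables; inverse of cells_to_matrix
matrix_to_cells <- function(m) as.vector(t(m))

cells_to_matrix <- function(v, nrow, ncol) matrix(v, nrow, ncol, byrow = TRUE)

check_same_grid <- function(a_dim, b_dim, what = "grids") {
  if (!all(a_dim == b_dim)) {
    stop(what, " are not aligned: ", paste(a_dim, collapse = "x"),
         " vs ", paste(b_dim, collapse = "x"), call. = FALSE)
  }
  invisible(TRUE)
}
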