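#' Write a grid layer as an ESRI ASCII raster
#'
#' Plain-text north-up raster format (`.asc`): a six-line header
#' (`ncols`, `nrows`, `xllcorner`, `yllcorner`, `cellsize`,
#' `NODATA_value`) followed by rows top to bottom. Integer layers are
#' written as integers; floating-point layers with 17 significant digits so
#' the round trip is exact at double precision.
#'
#' @param layer Numeric or integer matrix (`NA` = no-data).
#' @param path Output file path.
#' @param xllcorner,yllcorner,cellsize Georeference of the lower-left
#'   corner and the (square) cell size.
#' @param nodata No-data sentinel written for `NA` cells.
#' @return `path`, invisibly.
#' @export
write_raster <- function(layer, path, xllcorner = 0, yllcorner = 0,
                         cellsize = 1, nodata = -9999) {
  stopifnot(is.matrix(layer))
  is_int <- is.integer(layer) ||
    all(layer == round(layer), na.rm = TRUE)
  fmt <- function(x) {
    out <- if (is_int) sprintf("%d", as.integer(round(x)))
           else sprintf("%.17g", x)
    out[is.na(x)] <- as.character(nodata)
    out
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(paste("ncols", ncol(layer)),
               paste("nrows", nrow(layer)),
               paste("xllcorner", xllcorner),
               paste("yllcorner", yllcorner),
               paste("cellsize", cellsize),
               paste("NODATA_value", nodata)), con)
  for (r in seq_len(nrow(layer))) {
    writeLines(paste(fmt(layer[r, ]), collapse = " "), con)
  }
  invisible(path)
}

#' Read an ESRI ASCII raster
#'
#' Inverse of [write_raster()]. No-data cells become `NA`. The georeference
#' is attached as attributes `xllcorner`, `yllcorner`, `cellsize`.
#'
#' @param path Input `.asc` file.
#' @param expect_dim Optional `c(nrows, ncols)`; a mismatch is an error
#'   reporting both geometries.
#' @return Numeric matrix.
#' @export
read_raster <- function(path, expect_dim = NULL) {
  lines <- readLines(path)
  header <- list()
  i <- 1L
  while (grepl("^[A-Za-z]", lines[i])) {
    kv <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    header[[tolower(kv[1])]] <- as.numeric(kv[2])
    i <- i + 1L
  }
  nr <- as.integer(header$nrows); nc <- as.integer(header$ncols)
  vals <- scan(text = lines[i:length(lines)], quiet = TRUE)
  if (length(vals) != nr * nc) {
    stop("raster body has ", length(vals), " values, expected ", nr * nc,
         call. = FALSE)
  }
  m <- matrix(vals, nr, nc, byrow = TRUE)
  if (!is.null(header$nodata_value)) m[m == header$nodata_value] <- NA
  if (!is.null(expect_dim) && !all(dim(m) == expect_dim)) {
    stop("raster geometry ", nr, "x", nc, " does not match expected ",
         expect_dim[1], "x", expect_dim[2], call. = FALSE)
  }
  attr(m, "xllcorner") <- header$xllcorner
  attr(m, "yllcorner") <- header$yllcorner
  attr(m, "cellsize") <- header$cellsize
  m
}

#' Write / read a categorical raster with its class table
#'
#' The integer-coded grid goes to `path` (ESRI ASCII) and the code-to-name
#' vocabulary to a sidecar CSV `<path without .asc>_classes.csv` with
#' columns `code`, `class`.
#'
#' @param raster A [categorical_raster()].
#' @param path `.asc` path.
#' @return `write_categorical_raster()`: `path` invisibly;
#'   `read_categorical_raster()`: a [categorical_raster()].
#' @export
write_categorical_raster <- function(raster, path) {
  stopifnot(inherits(raster, "categorical_raster"))
  write_raster(raster$values, path)
  utils::write.csv(
    data.frame(code = seq_along(raster$classes), class = raster$classes,
               stringsAsFactors = FALSE),
    class_table_path(path), row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_categorical_raster
#' @export
read_categorical_raster <- function(path) {
  m <- read_raster(path)
  tab <- utils::read.csv(class_table_path(path), stringsAsFactors = FALSE)
  values <- matrix(as.integer(m), nrow(m), ncol(m))
  categorical_raster(values, tab$class[order(tab$code)])
}

class_table_path <- function(path) {
  paste0(sub("\\.asc$", "", path), "_classes.csv")
}

#' Write per-scenario score tables
#'
#' Exports relative-likelihood maps as a CSV with one row per valid cell:
#' `cell_id` (0-based row-major), `x`, `y` (cell centres, north-up, in cell
#' units), then one column per class per scenario label, named
#' `<class>.<label>`. Only cells valid in every map are written.
#'
#' @param maps Named list of [likelihood_map()] objects on one grid (names
#'   are the scenario labels).
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_score_table <- function(maps, path) {
  if (inherits(maps, "likelihood_map")) maps <- list(average = maps)
  stopifnot(length(maps) >= 1L, !is.null(names(maps)))
  ref <- maps[[1]]
  for (m in maps[-1]) check_same_grid(c(m$nrow, m$ncol), c(ref$nrow, ref$ncol))
  valid <- Reduce(`&`, lapply(maps, function(m) !apply(is.na(m$scores), 1,
                                                       all)))
  cell_id <- which(valid) - 1L
  row <- cell_id %/% ref$ncol
  col <- cell_id %% ref$ncol
  out <- data.frame(cell_id = cell_id, x = col + 0.5,
                    y = ref$nrow - row - 0.5)
  for (lab in names(maps)) {
    s <- maps[[lab]]$scores[valid, , drop = FALSE]
    colnames(s) <- paste(maps[[lab]]$classes, lab, sep = ".")
    out <- cbind(out, as.data.frame(s))
  }
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a score table back into likelihood maps
#'
#' Inverse of [write_score_table()]. Grid dimensions are inferred from the
#' coordinate columns unless given; cells absent from the table are
#' no-data. Duplicate `cell_id`s are rejected.
#'
#' @param path CSV path.
#' @param nrow,ncol Optional grid dimensions.
#' @return Named list of [likelihood_map()] objects.
#' @export
read_score_table <- function(path, nrow = NULL, ncol = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (anyDuplicated(df$cell_id)) {
    stop("duplicate cell_id in score table", call. = FALSE)
  }
  if (is.null(ncol)) ncol <- as.integer(max(df$x) + 0.5)
  if (is.null(nrow)) nrow <- as.integer(max(df$y) + 0.5)
  score_cols <- setdiff(names(df), c("cell_id", "x", "y"))
  parts <- strsplit(score_cols, ".", fixed = TRUE)
  labels <- unique(vapply(parts, function(p) paste(p[-1], collapse = "."),
                          character(1)))
  out <- list()
  for (lab in labels) {
    cols <- score_cols[vapply(parts, function(p)
      paste(p[-1], collapse = ".") == lab, logical(1))]
    classes <- vapply(strsplit(cols, ".", fixed = TRUE), `[[`, character(1),
                      1)
    scores <- matrix(NA_real_, nrow * ncol, length(classes))
    scores[df$cell_id + 1L, ] <- as.matrix(df[, cols])
    out[[lab]] <- likelihood_map(scores, nrow, ncol, classes,
                                 provenance = lab)
  }
  out
}
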