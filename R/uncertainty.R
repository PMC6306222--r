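# assignments -> cells x M integer matrix with aligned grids
stack_assignments <- function(assignments) {
  if (inherits(assignments, "categorical_raster")) {
    assignments <- list(assignments)
  }
  if (!length(assignments)) {
    stop("at least one assignment map required", call. = FALSE)
  }
  ref <- dim(assignments[[1]]$values)
  for (a in assignments[-1]) check_same_grid(dim(a$values), ref)
  vals <- vapply(assignments, function(a) as.vector(a$values),
                 integer(prod(ref)))
  if (!is.matrix(vals)) vals <- matrix(vals, nrow = prod(ref))
  list(values = vals, dim = ref, n_maps = length(assignments),
       classes = assignments[[1]]$classes)
}

#' Model agreement (convergence) map
#'
#' Per cell, the number of scenario outputs that converge on the same
#' (modal) forecast class: with M outputs the count ranges 1..M, M meaning
#' every output forecasts one class, 1 meaning all outputs disagree. Used as
#' an uncertainty surface.
#'
#' @param assignments List of aligned [categorical_raster()] maps (one per
#'   scenario output).
#' @return Integer matrix of modal vote counts (`NA` where any input is
#'   no-data).
#' @export
agreement_map <- function(assignments) {
  st <- stack_assignments(assignments)
  v <- st$values
  counts <- apply(v, 1, function(row) {
    if (anyNA(row)) return(NA_integer_)
    max(tabulate(row))
  })
  matrix(as.integer(counts), st$dim[1], st$dim[2])
}

#' Forecast diversity map
#'
#' Per cell, the number of distinct vegetation classes forecast across the
#' outputs (1..min(M, K)). `diversity == 1` exactly where agreement equals
#' the number of outputs.
#'
#' @inheritParams agreement_map
#' @return Integer matrix of distinct-class counts.
#' @export
diversity_map <- function(assignments) {
  st <- stack_assignments(assignments)
  v <- st$values
  counts <- apply(v, 1, function(row) {
    if (anyNA(row)) return(NA_integer_)
    length(unique(row))
  })
  matrix(as.integer(counts), st$dim[1], st$dim[2])
}

#' Temporal-stability (transition count) map
#'
#' Per cell, the number of class conversions along the ordered time series
#' of assignment maps (baseline, 2020s, 2050s, 2080s gives counts 0..3):
#' the count of consecutive pairs whose class differs.
#'
#' @param series Time-ordered list of >= 2 aligned [categorical_raster()]
#'   maps.
#' @return Integer matrix of transition counts.
#' @export
transition_count <- function(series) {
  if (inherits(series, "categorical_raster") || length(series) < 2L) {
    stop("need >= 2 time-ordered assignment maps", call. = FALSE)
  }
  st <- stack_assignments(series)
  v <- st$values
  changes <- matrix(0L, nrow(v), 1)
  anyna <- rep(FALSE, nrow(v))
  for (t in seq_len(ncol(v) - 1L)) {
    anyna <- anyna | is.na(v[, t]) | is.na(v[, t + 1L])
    changes <- changes + (v[, t] != v[, t + 1L])
  }
  changes[anyna] <- NA_integer_
  matrix(as.integer(changes), st$dim[1], st$dim[2])
}

#' Per-class area of an assignment map
#'
#' Counts cells per class and multiplies by the cell area (default 100 ha
#' for 1-km cells). No-data cells are excluded; classes with no cells get 0.
#'
#' @param assign A [categorical_raster()].
#' @param cell_area_ha Area of one cell in hectares (> 0).
#' @return Named numeric vector of hectares over the class vocabulary.
#' @export
area_by_class <- function(assign, cell_area_ha = 100) {
  stopifnot(inherits(assign, "categorical_raster"))
  if (cell_area_ha <= 0) stop("cell_area_ha must be > 0", call. = FALSE)
  v <- assign$values[!is.na(assign$values)]
  counts <- tabulate(v, nbins = length(assign$classes))
  stats::setNames(counts * cell_area_ha, assign$classes)
}

#' Per-class area trajectory across scenario outputs
#'
#' For each class, summarises the final-time-step forecast areas across the
#' scenario outputs (min / mean / max) against the baseline area and
#' classifies the trend: `"-"` when even the largest forecast is below
#' baseline (`max < baseline`), `"+"` when even the smallest exceeds it
#' (`min > baseline`), and `"unk"` when the range straddles (or touches)
#' the baseline. A class missing from an output counts as 0 ha there.
#'
#' @param baseline_areas Named numeric vector of baseline hectares per
#'   class.
#' @param output_areas List (one element per scenario output) of named
#'   numeric vectors of final-time-step hectares.
#' @return A data frame (`trajectory_table`): `class`, `baseline_ha`,
#'   `mean_ha`, `min_ha`, `max_ha`, `trend`.
#' @export
trajectory_table <- function(baseline_areas, output_areas) {
  stopifnot(!is.null(names(baseline_areas)))
  if (!is.list(output_areas) || !length(output_areas)) {
    stop("output_areas must be a non-empty list of named vectors",
         call. = FALSE)
  }
  classes <- names(baseline_areas)
  m <- vapply(output_areas, function(a) {
    out <- stats::setNames(numeric(length(classes)), classes)
    common <- intersect(names(a), classes)
    out[common] <- a[common]
    out
  }, numeric(length(classes)))
  if (!is.matrix(m)) m <- matrix(m, nrow = length(classes))
  min_ha <- apply(m, 1, min)
  max_ha <- apply(m, 1, max)
  mean_ha <- rowMeans(m)
  trend <- ifelse(max_ha < baseline_areas, "-",
                  ifelse(min_ha > baseline_areas, "+", "unk"))
  data.frame(class = classes, baseline_ha = unname(baseline_areas),
             mean_ha = unname(mean_ha), min_ha = unname(min_ha),
             max_ha = unname(max_ha), trend = unname(trend),
             stringsAsFactors = FALSE)
}
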