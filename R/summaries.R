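#' Regional means of climate layers
#'
#' Arithmetic mean of each requested layer over valid (non-no-data) cells.
#' A layer with no valid cells is reported `NA`.
#'
#' @param surface A [climate_surface()].
#' @param variables Layers to summarise (default all).
#' @return Named numeric vector of means.
#' @export
regional_means <- function(surface, variables = names(surface$layers)) {
  require_layers(surface, variables)
  valid <- surface_mask(surface)
  vapply(surface$layers[variables], function(l) {
    v <- l[valid]
    v <- v[!is.na(v)]
    if (!length(v)) NA_real_ else mean(v)
  }, numeric(1))
}

#' Percent change of scenario means from baseline
#'
#' `100 * (future - baseline) / baseline` per variable; undefined (`NA`,
#' with a warning) where the baseline mean is zero. Values are kept at full
#' precision; round only at the report layer.
#'
#' @param baseline_means Named numeric vector of baseline means.
#' @param scenario_means Named numeric vector (one scenario) or named list
#'   of such vectors (one row per scenario).
#' @return Data frame with a `scenario` column and one column per variable.
#' @export
percent_change <- function(baseline_means, scenario_means) {
  stopifnot(!is.null(names(baseline_means)))
  if (!is.list(scenario_means)) {
    scenario_means <- list(scenario = scenario_means)
  }
  vars <- names(baseline_means)
  rows <- lapply(scenario_means, function(sm) {
    missing <- setdiff(vars, names(sm))
    if (length(missing)) {
      stop("scenario means missing variable(s): ",
           paste(missing, collapse = ", "), call. = FALSE)
    }
    pc <- 100 * (sm[vars] - baseline_means) / baseline_means
    if (any(baseline_means == 0)) {
      warning("zero baseline mean: percent change undefined for ",
              paste(vars[baseline_means == 0], collapse = ", "),
              call. = FALSE)
      pc[baseline_means == 0] <- NA_real_
    }
    pc
  })
  out <- as.data.frame(do.call(rbind, rows))
  names(out) <- vars
  cbind(data.frame(scenario = names(scenario_means),
                   stringsAsFactors = FALSE),
        out, row.names = NULL)
}

#' Climate summarised by vegetation community
#'
#' Per class and variable: mean, minimum and maximum of the layer over the
#' cells assigned to the class. Classes with no assigned cells are reported
#' `NA` (rendered as empty, "na"-style entries at the report layer).
#'
#' @param surface A [climate_surface()].
#' @param veg An aligned [categorical_raster()] (historical map or a
#'   forecast assignment).
#' @param variables Layers to summarise (default all).
#' @return Long data frame: `class`, `variable`, `mean`, `min`, `max`,
#'   `n_cells`.
#' @export
climate_by_vegetation <- function(surface, veg,
                                  variables = names(surface$layers)) {
  stopifnot(inherits(veg, "categorical_raster"))
  check_same_grid(c(surface$nrow, surface$ncol), dim(veg$values))
  require_layers(surface, variables)
  valid <- surface_mask(surface) & !is.na(veg$values)
  cls <- veg$values[valid]
  out <- expand.grid(class = veg$classes, variable = variables,
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  out$mean <- NA_real_; out$min <- NA_real_; out$max <- NA_real_
  out$n_cells <- 0L
  for (v in variables) {
    vals <- surface$layers[[v]][valid]
    agg_mean <- tapply(vals, cls, mean)
    agg_min <- tapply(vals, cls, min)
    agg_max <- tapply(vals, cls, max)
    agg_n <- tapply(vals, cls, length)
    codes <- as.integer(names(agg_mean))
    rows <- match(paste(veg$classes[codes], v),
                  paste(out$class, out$variable))
    out$mean[rows] <- agg_mean
    out$min[rows] <- agg_min
    out$max[rows] <- agg_max
    out$n_cells[rows] <- agg_n
  }
  out
}
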