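#' Specification of one synthetic bioclimatic variable
#'
#' Describes how a single climate layer is simulated: a regional baseline
#' mean, a centred linear gradient across rows and columns (e.g. a
#' latitudinal or rain-shadow trend), and spatially autocorrelated noise
#' (Gaussian-filtered white noise).
#'
#' @param name Variable identifier (see [bioclim_variables()] for the
#'   standard vocabulary, e.g. `"MAT"`, `"MAP"`, `"PAS"`, `"Eref"`).
#' @param baseline_mean Regional mean of the layer, in the variable's units.
#' @param units Unit string (documentation only).
#' @param grad_row,grad_col Total change from first to last row / column.
#'   The gradient is centred so it does not shift the regional mean.
#' @param noise_amplitude Standard deviation of the autocorrelated noise
#'   field; must be >= 0. Zero gives a deterministic surface.
#' @param correlation_length Gaussian smoothing length of the noise, in
#'   cells; must be > 0.
#' @param lower Optional lower clamp (e.g. 0 for precipitation).
#' @return An object of class `variable_spec`.
#' @export
variable_spec <- function(name, baseline_mean, units = "",
                          grad_row = 0, grad_col = 0,
                          noise_amplitude = 0, correlation_length = 5,
                          lower = -Inf) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name),
            is.numeric(baseline_mean), length(baseline_mean) == 1L)
  if (noise_amplitude < 0) stop("noise_amplitude must be >= 0", call. = FALSE)
  if (correlation_length <= 0) {
    stop("correlation_length must be > 0", call. = FALSE)
  }
  structure(list(name = name, baseline_mean = baseline_mean, units = units,
                 grad_row = grad_row, grad_col = grad_col,
                 noise_amplitude = noise_amplitude,
                 correlation_length = correlation_length, lower = lower),
            class = "variable_spec")
}

# separable Gaussian smoothing of a matrix: row/column weight matrices with
# renormalised truncated kernels so edges are not darkened
gaussian_smooth <- function(m, sigma) {
  smooth_1d <- function(n) {
    d <- abs(outer(seq_len(n), seq_len(n), "-"))
    w <- exp(-0.5 * (d / sigma)^2)
    w / rowSums(w)
  }
  wr <- smooth_1d(nrow(m))
  wc <- smooth_1d(ncol(m))
  wr %*% m %*% t(wc)
}

#' Generate a synthetic baseline climate surface
#'
#' Builds one layer per [variable_spec()] on a common grid: baseline mean +
#' centred linear gradient + mean-centred autocorrelated noise rescaled to
#' the requested amplitude. The regional mean of each layer therefore equals
#' `baseline_mean` exactly (up to clamping at `lower`). Output is a pure
#' function of the inputs and the seed.
#'
#' @param grid_rows,grid_cols Grid dimensions (each >= 2).
#' @param specs List of [variable_spec()] objects with unique names.
#' @param seed Integer RNG seed (required; no wall-clock default).
#' @param mask Optional logical validity mask.
#' @return A [climate_surface()].
#' @export
generate_climate_baseline <- function(grid_rows, grid_cols, specs, seed,
                                      mask = NULL) {
  if (grid_rows < 2 || grid_cols < 2) {
    stop("grid dimensions must be >= 2x2 (got ", grid_rows, "x", grid_cols,
         ")", call. = FALSE)
  }
  if (!is.list(specs) || length(specs) == 0L) {
    stop("at least one variable_spec is required", call. = FALSE)
  }
  if (missing(seed) || is.null(seed)) stop("seed is required", call. = FALSE)
  nms <- vapply(specs, function(s) s$name, character(1))
  if (anyDuplicated(nms)) {
    stop("duplicate variable name(s): ",
         paste(unique(nms[duplicated(nms)]), collapse = ", "), call. = FALSE)
  }
  set.seed(seed)
  rowpos <- (seq_len(grid_rows) - 0.5) / grid_rows - 0.5
  colpos <- (seq_len(grid_cols) - 0.5) / grid_cols - 0.5
  layers <- lapply(specs, function(s) {
    field <- s$baseline_mean +
      outer(rowpos * s$grad_row, colpos * s$grad_col, "+")
    if (s$noise_amplitude > 0) {
      noise <- gaussian_smooth(matrix(stats::rnorm(grid_rows * grid_cols),
                                      grid_rows, grid_cols),
                               s$correlation_length)
      noise <- noise - mean(noise)
      sd0 <- stats::sd(as.vector(noise))
      if (sd0 > 0) noise <- noise * (s$noise_amplitude / sd0)
      field <- field + noise
    }
    pmax(field, s$lower)
  })
  names(layers) <- nms
  climate_surface(layers, mask = mask)
}

#' Add derived bioclimatic layers
#'
#' Computes the annual heat:moisture index per cell,
#' `AHM = (MAT + 10) / (MAP / 1000)`, from the mean annual temperature and
#' mean annual precipitation layers, and appends it as layer `"AHM"`.
#' Existing layers are unchanged.
#'
#' @param surface A [climate_surface()] containing layers `"MAT"` (deg C)
#'   and `"MAP"` (mm).
#' @return The surface with an `"AHM"` layer added (replaced if present).
#' @export
compute_derived_variables <- function(surface) {
  require_layers(surface, c("MAT", "MAP"))
  mat <- surface$layers[["MAT"]]
  map <- surface$layers[["MAP"]]
  valid <- surface_mask(surface)
  bad <- which(valid & !is.na(map) & map <= 0, arr.ind = TRUE)
  if (nrow(bad)) {
    stop("MAP <= 0 at cell (row ", bad[1, 1], ", col ", bad[1, 2],
         "); AHM is undefined there", call. = FALSE)
  }
  surface$layers[["AHM"]] <- (mat + 10) / (map / 1000)
  surface
}

#' Bioclimatic variable vocabulary
#'
#' The standard ClimateNA-style bioclimatic variable list with short codes,
#' full names, and units. The generator and pipeline accept any subset; the
#' shipped defaults use the five summarised variables (AHM, PAS, MAP, Eref,
#' MAT).
#'
#' @return A data frame with columns `code`, `name`, `units`.
#' @export
bioclim_variables <- function() {
  data.frame(
    code = c("MAT", "MWMT", "MCMT", "TD", "MAP", "MSP", "AHM", "DD_0",
             "DD5", "DD_18", "DD18", "NFFD", "bFFP", "eFFP", "FFP", "PAS",
             "EMT", "EXT", "Eref", "CMI", "MAR", "RH"),
    name = c("mean annual temperature",
             "mean temperature of the warmest month",
             "mean temperature of the coldest month",
             "difference between coldest and warmest month (continentality)",
             "mean annual precipitation",
             "mean summer (May to Sep) precipitation",
             "annual heat moisture index",
             "degree-days below 0 degC", "degree-days above 5 degC",
             "degree-days below 18 degC", "degree-days above 18 degC",
             "number of frost-free days",
             "Julian date on which the frost-free period begins",
             "Julian date on which the frost-free period ends",
             "frost-free period", "precipitation as snow",
             "extreme minimum temperature over 30 years",
             "extreme maximum temperature over 30 years",
             "Hargreaves reference evaporation",
             "Hargreaves climatic moisture index",
             "mean annual solar radiation", "mean annual relative humidity"),
    units = c("degC", "degC", "degC", "degC", "mm", "mm", "", "dd", "dd",
              "dd", "dd", "days", "julian", "julian", "days", "mm", "degC",
              "degC", "mm", "", "MJ m-2 d-1", "%"),
    stringsAsFactors = FALSE
  )
}

#' Default variable specifications for the demonstration region
#'
#' Five-variable default emulating a maritime-to-continental subarctic
#' landscape: regional means MAT 1.9 degC, MAP 1735 mm, PAS 862 mm and
#' Eref 351 mm, an along-row temperature/snow gradient (elevation proxy) and
#' an along-column precipitation gradient (rain shadow), with modest
#' autocorrelated noise. AHM is derived, not simulated (see
#' [compute_derived_variables()]).
#'
#' @return A named list of [variable_spec()] objects.
#' @export
default_variable_specs <- function() {
  specs <- list(
    variable_spec("MAT", 1.9, "degC", grad_row = 2.8,
                  noise_amplitude = 0.12, correlation_length = 8),
    variable_spec("MAP", 1735, "mm", grad_col = 1500,
                  noise_amplitude = 55, correlation_length = 8, lower = 1),
    variable_spec("PAS", 862, "mm", grad_row = -1100,
                  noise_amplitude = 35, correlation_length = 8, lower = 1),
    variable_spec("Eref", 351, "mm", grad_row = 110,
                  noise_amplitude = 9, correlation_length = 8, lower = 1)
  )
  names(specs) <- vapply(specs, `[[`, character(1), "name")
  specs
}
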