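#' Scenario specification (GCM x RCP x time step)
#'
#' Describes one future climate output as fractional per-variable changes
#' from baseline: each layer is multiplied by `1 + delta`. A delta of 0.28
#' means +28%; -0.76 means -76%; temperature deltas are expressed the same
#' way (a delta of 3.65 on a 1.9 degC mean gives ~8.84 degC).
#'
#' @param gcm_label Climate-model exposure label (e.g. `"INM-CM4"` for low,
#'   `"15-GCM-avg"` for mid, `"GFDL-CM3"` for high exposure).
#' @param rcp_label Emission pathway label (`"RCP45"`, `"RCP85"`).
#' @param timestep One of `"2020s"`, `"2050s"`, `"2080s"`.
#' @param deltas Named numeric vector of fractional changes.
#' @return An object of class `scenario_spec` with a `label` field
#'   `"<gcm> <rcp> <timestep>"`.
#' @export
scenario_spec <- function(gcm_label, rcp_label, timestep, deltas) {
  timestep <- match.arg(timestep, c("2020s", "2050s", "2080s"))
  stopifnot(is.numeric(deltas), !is.null(names(deltas)))
  structure(list(gcm_label = gcm_label, rcp_label = rcp_label,
                 timestep = timestep, deltas = deltas,
                 label = paste(gcm_label, rcp_label, timestep)),
            class = "scenario_spec")
}

# 2080 fractional changes from baseline for the six default outputs
# (3 GCM exposure levels x 2 RCPs); columns AHM, PAS, MAP, Eref, MAT
scenario_deltas_2080 <- function() {
  m <- rbind(
    "INM-CM4 RCP45"    = c(0.10, -0.27, 0.09, 0.07, 1.13),
    "15-GCM-avg RCP45" = c(0.16, -0.42, 0.14, 0.19, 1.93),
    "INM-CM4 RCP85"    = c(0.17, -0.59, 0.18, 0.17, 2.37),
    "15-GCM-avg RCP85" = c(0.22, -0.69, 0.25, 0.31, 3.15),
    "GFDL-CM3 RCP45"   = c(0.23, -0.60, 0.17, 0.29, 2.69),
    "GFDL-CM3 RCP85"   = c(0.26, -0.76, 0.28, 0.37, 3.65)
  )
  colnames(m) <- c("AHM", "PAS", "MAP", "Eref", "MAT")
  m
}

#' Default six-output scenario set
#'
#' Builds the default scenario specifications: three GCM exposure levels
#' (low = INM-CM4, mid = 15-GCM average, high = GFDL-CM3) crossed with
#' RCP 4.5 and RCP 8.5. The 2080s deltas are the canonical per-variable
#' fractional changes; 2020s and 2050s deltas are linear interpolations at
#' fractions 1/3 and 2/3 of the 2080s delta, preserving scenario ordering.
#'
#' @param timesteps Subset of `c("2020s", "2050s", "2080s")`.
#' @param variables Variables to carry deltas for (default all five).
#' @return A list of [scenario_spec()] objects (6 per time step), ordered by
#'   time step then scenario.
#' @export
default_scenarios <- function(timesteps = c("2020s", "2050s", "2080s"),
                              variables = c("AHM", "PAS", "MAP", "Eref",
                                            "MAT")) {
  timesteps <- match.arg(timesteps, c("2020s", "2050s", "2080s"),
                         several.ok = TRUE)
  frac <- c("2020s" = 1 / 3, "2050s" = 2 / 3, "2080s" = 1)
  full <- scenario_deltas_2080()[, variables, drop = FALSE]
  gcm <- sub(" RCP\\d+$", "", rownames(full))
  rcp <- sub("^.* ", "", rownames(full))
  out <- list()
  for (ts in timesteps) {
    for (i in seq_len(nrow(full))) {
      out[[length(out) + 1L]] <- scenario_spec(
        gcm[i], rcp[i], ts, full[i, ] * frac[[ts]])
    }
  }
  out
}

#' Apply scenario deltas to a baseline climate surface
#'
#' For each scenario, every delta-bearing layer is scaled per cell by
#' `1 + delta`; optionally a small seeded autocorrelated perturbation is
#' added. When `recompute_derived = TRUE` (the default) the derived AHM
#' layer is recomputed from the perturbed MAT and MAP layers rather than
#' scaled independently, keeping the surface internally consistent.
#'
#' @param baseline A [climate_surface()].
#' @param specs A list of [scenario_spec()] objects.
#' @param seed Integer seed (used only when `noise_amplitude > 0`).
#' @param noise_amplitude Standard deviation of additional spatial noise
#'   (same units as each variable), default 0.
#' @param correlation_length Smoothing length for that noise.
#' @param recompute_derived Recompute `"AHM"` from perturbed `"MAT"`/`"MAP"`
#'   when those layers exist.
#' @return A list with one element per scenario: `list(spec=, surface=)`.
#' @export
generate_future_scenarios <- function(baseline, specs, seed = NULL,
                                      noise_amplitude = 0,
                                      correlation_length = 5,
                                      recompute_derived = TRUE) {
  if (inherits(specs, "scenario_spec")) specs <- list(specs)
  if (noise_amplitude > 0) {
    if (is.null(seed)) stop("seed is required when noise is added",
                            call. = FALSE)
    set.seed(seed)
  }
  lapply(specs, function(sp) {
    require_layers(baseline, names(sp$deltas))
    out <- baseline
    for (v in names(sp$deltas)) {
      d <- sp$deltas[[v]]
      layer <- baseline$layers[[v]]
      if (d < -1 && min(layer, na.rm = TRUE) >= 0) {
        stop("delta ", d, " for nonnegative variable '", v,
             "' would produce negative values", call. = FALSE)
      }
      layer <- layer * (1 + d)
      if (noise_amplitude > 0) {
        noise <- gaussian_smooth(
          matrix(stats::rnorm(length(layer)), nrow(layer), ncol(layer)),
          correlation_length)
        noise <- noise - mean(noise)
        sd0 <- stats::sd(as.vector(noise))
        if (sd0 > 0) layer <- layer + noise * (noise_amplitude / sd0)
      }
      out$layers[[v]] <- layer
    }
    if (recompute_derived && "AHM" %in% names(out$layers) &&
        all(c("MAT", "MAP") %in% names(out$layers))) {
      out <- compute_derived_variables(out)
    }
    list(spec = sp, surface = out)
  })
}
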