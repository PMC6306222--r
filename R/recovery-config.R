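#' Four-class box-niche recovery configuration
#'
#' A purpose-built synthetic landscape for validating trajectory recovery:
#' four box niches over a strictly positive climate (Dry: MAP < 750 mm;
#' Cold: MAT < 0.7 degC; Warm: MAT >= 3.9 degC; Mild: everything else) on a
#' `rows x cols` grid whose MAT spans ~0.5-4.5 degC and MAP ~600-1600 mm.
#' Because scenario deltas are multiplicative and all six default 2080
#' outputs warm MAT by factors 2.13-4.65, every cell of the Cold niche
#' (MAT < 0.7) is displaced into the interior of the broad Mild band
#' ([0.7, 3.9)) under every output, while its own niche becomes empty: the
#' pipeline should recover a "-" trend for Cold with full six-output
#' agreement over its former extent, and a "+" trend for Warm, whose niche
#' gains cells under every output. Label noise is 0: the configuration is a
#' clean recovery check of the climate signal, not of classification error.
#'
#' @param rows,cols Grid dimensions (default 100 x 100).
#' @param seed Base RNG seed.
#' @return A `pipeline_config` with a single `"2080s"` time step and the
#'   six default scenario outputs.
#' @export
box_recovery_config <- function(rows = 100, cols = 100, seed = 4105L) {
  specs <- list(
    variable_spec("MAT", 2.5, "degC", grad_row = 4.0,
                  noise_amplitude = 0.08, correlation_length = 6,
                  lower = 0.01),
    variable_spec("MAP", 1100, "mm", grad_col = 1000,
                  noise_amplitude = 30, correlation_length = 6, lower = 1),
    variable_spec("PAS", 900, "mm", grad_row = -1400,
                  noise_amplitude = 25, correlation_length = 6, lower = 1),
    variable_spec("Eref", 350, "mm", grad_row = 100,
                  noise_amplitude = 8, correlation_length = 6, lower = 1)
  )
  rules <- list(
    niche_rule("Dry", list(MAP = c(-Inf, 750)), priority = 1),
    niche_rule("Cold", list(MAT = c(-Inf, 0.7)), priority = 2),
    niche_rule("Warm", list(MAT = c(3.9, Inf)), priority = 3),
    niche_rule("Mild", list(), priority = 4)
  )
  pipeline_config(list(
    grid = list(rows = rows, cols = cols, fine_factor = 1L,
                cell_area_ha = 100),
    seed = as.integer(seed),
    label_noise = 0,
    variables = specs,
    rules = rules,
    classes = c("Dry", "Cold", "Warm", "Mild"),
    timesteps = "2080s",
    scenarios = "default"
  ))
}
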