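#' Reference ecological-trajectory table (Kenai Peninsula)
#'
#' Reference area trajectories for the ten vegetation communities of the
#' Kenai Peninsula, Alaska: baseline (1960-1990) hectares and the mean,
#' minimum and maximum hectares forecast for the 2080s across six model
#' outputs (3 GCM exposure levels x 2 RCPs), together with the reported
#' trend classification. Shipped as a fixture for validating the trend rule
#' of [trajectory_table()]: feeding the baseline/min/max columns through the
#' rule must reproduce the `trend` column.
#'
#' @return A data frame with columns `class`, `baseline_ha`, `mean_ha`,
#'   `min_ha`, `max_ha`, `trend`.
#' @export
kenai_trajectory_reference <- function() {
  data.frame(
    class = c("Alpine", "BlackSpruce", "Deciduous", "Herbaceous",
              "MixedConifer", "MixedForest", "MountainHemlock", "Shrub",
              "SnowOrIce", "WhiteSitkaLutzSpruce"),
    baseline_ha = c(432000, 216300, 131400, 167000, 157600, 236400,
                    114400, 346300, 486500, 243500),
    mean_ha = c(1750, 103950, 628267, 716333, 613917, 0, 369917, 0,
                58267, 0),
    min_ha = c(0, 2400, 173200, 168300, 198800, 0, 264200, 0, 0, 0),
    max_ha = c(8500, 256300, 754900, 1058500, 890100, 0, 490700, 0,
               218700, 0),
    trend = c("-", "unk", "+", "+", "+", "-", "+", "-", "-", "-"),
    stringsAsFactors = FALSE
  )
}

#' Reference regional climate summary (Kenai Peninsula)
#'
#' Reference regional baseline means of the five summarised bioclimatic
#' variables for the Kenai Peninsula (annual heat:moisture index,
#' precipitation as snow, mean annual precipitation, Hargreaves reference
#' evaporation, mean annual temperature) and the rounded percent change
#' from baseline for the six 2080 model outputs. The fractional deltas used
#' by [default_scenarios()] are derived from these percent changes.
#'
#' @return A list with `baseline` (named numeric vector) and
#'   `percent_change_2080` (matrix: scenario x variable, whole percent).
#' @export
kenai_climate_reference <- function() {
  list(
    baseline = c(AHM = 12, PAS = 862, MAP = 1735, Eref = 351, MAT = 1.9),
    percent_change_2080 = scenario_deltas_2080() * 100
  )
}
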