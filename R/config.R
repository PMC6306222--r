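#' Default ten-class vegetation vocabulary
#'
#' The ten generalized vegetation communities of a subarctic
#' maritime/boreal landscape used throughout the demonstration
#' configuration: alpine tundra, black spruce forest, deciduous forest,
#' herbaceous, perennial ice/snow, mixed conifer, mixed forest, mountain
#' hemlock, shrub, and the white-Lutz-Sitka spruce complex.
#'
#' @return Character vector of ten class names.
#' @export
default_classes <- function() {
  c("Alpine", "BlackSpruce", "Deciduous", "Herbaceous", "Ice",
    "MixedConifer", "MixedForest", "MountainHemlock", "Shrub",
    "WhiteSitkaSpruce")
}

#' Default niche rules for the demonstration landscape
#'
#' Ten box niches partitioning the default climate space: five mean annual
#' temperature bands (cold to warm, an elevation proxy) crossed with a
#' dry/wet split at the regional mean annual precipitation. Cold-wet is
#' perennial ice, cold-dry alpine tundra, warm bands grade through the
#' forest types. The rules fully cover the plane, so no fallback is needed.
#'
#' @param map_split MAP value (mm) separating the dry and wet halves.
#' @return List of ten [niche_rule()] objects.
#' @export
default_niche_rules <- function(map_split = 1735) {
  bands <- list(c(-Inf, 0.9), c(0.9, 1.6), c(1.6, 2.3), c(2.3, 3.0),
                c(3.0, Inf))
  dry <- c(-Inf, map_split); wet <- c(map_split, Inf)
  layout <- list(
    list("Alpine", bands[[1]], dry), list("Ice", bands[[1]], wet),
    list("Shrub", bands[[2]], dry), list("MountainHemlock", bands[[2]], wet),
    list("BlackSpruce", bands[[3]], dry),
    list("MixedConifer", bands[[3]], wet),
    list("MixedForest", bands[[4]], dry),
    list("WhiteSitkaSpruce", bands[[4]], wet),
    list("Deciduous", bands[[5]], dry), list("Herbaceous", bands[[5]], wet)
  )
  lapply(seq_along(layout), function(i) {
    niche_rule(layout[[i]][[1]],
               list(MAT = layout[[i]][[2]], MAP = layout[[i]][[3]]),
               priority = i)
  })
}

#' Assemble and validate a pipeline configuration
#'
#' Fills defaults and validates the fields driving [run_pipeline()]. The
#' string `"default"` (or omission) selects the shipped defaults for
#' `variables`, `rules`, `classes` and `scenarios`.
#'
#' @param x A named list (e.g. parsed from YAML): `grid` (`rows`, `cols`,
#'   `fine_factor`, `cell_area_ha`), `seed`, `label_noise`, `variables`,
#'   `classes`, `rules`, `scenarios`, `timesteps`, `model` (`n_trees`,
#'   `holdout`, `replace`, `threshold`; `threshold: ~` means `1/K`).
#' @return A validated `pipeline_config` list.
#' @export
pipeline_config <- function(x = list()) {
  grid <- utils::modifyList(
    list(rows = 40L, cols = 40L, fine_factor = 5L, cell_area_ha = 100),
    as.list(x$grid))
  model <- utils::modifyList(
    list(n_trees = 200L, holdout = 0.2, replace = FALSE, threshold = NULL),
    as.list(x$model))
  cfg <- list(
    grid = grid,
    seed = if (is.null(x$seed)) 20260926L else as.integer(x$seed),
    label_noise = if (is.null(x$label_noise)) 0.1 else x$label_noise,
    timesteps = if (is.null(x$timesteps)) c("2020s", "2050s", "2080s")
                else as.character(x$timesteps),
    model = model
  )
  cfg$variables <- if (is.null(x$variables) ||
                       identical(x$variables, "default")) {
    default_variable_specs()
  } else {
    specs <- lapply(x$variables, function(v) {
      if (inherits(v, "variable_spec")) v else do.call(variable_spec, v)
    })
    names(specs) <- vapply(specs, `[[`, character(1), "name")
    specs
  }
  cfg$rules <- if (is.null(x$rules) || identical(x$rules, "default")) {
    default_niche_rules()
  } else if (all(vapply(x$rules, inherits, logical(1), "niche_rule"))) {
    x$rules
  } else {
    lapply(x$rules, function(r) {
      niche_rule(r$class,
                 lapply(r$bounds, function(b) {
                   b <- vapply(b, function(z) {
                     if (is.null(z)) NA_real_ else as.numeric(z)
                   }, numeric(1))
                   # open ends may be written as null in YAML
                   if (is.na(b[1])) b[1] <- -Inf
                   if (is.na(b[2])) b[2] <- Inf
                   b
                 }),
                 priority = r$priority)
    })
  }
  cfg$classes <- if (is.null(x$classes) || identical(x$classes, "default")) {
    if (is.null(x$rules) || identical(x$rules, "default")) default_classes()
    else rule_classes(cfg$rules)
  } else as.character(x$classes)
  cfg$scenarios <- if (is.null(x$scenarios) ||
                       identical(x$scenarios, "default")) {
    default_scenarios(cfg$timesteps)
  } else if (all(vapply(x$scenarios, inherits, logical(1),
                        "scenario_spec"))) {
    x$scenarios
  } else {
    lapply(x$scenarios, function(s) {
      scenario_spec(s$gcm_label, s$rcp_label, s$timestep,
                    unlist(s$deltas))
    })
  }
  stopifnot(grid$rows >= 2, grid$cols >= 2, grid$fine_factor >= 1,
            grid$cell_area_ha > 0,
            cfg$label_noise >= 0, cfg$label_noise < 1,
            model$n_trees >= 1, model$holdout > 0, model$holdout < 1)
  missing_cls <- setdiff(rule_classes(cfg$rules), cfg$classes)
  if (length(missing_cls)) {
    stop("rule classes not in vocabulary: ",
         paste(missing_cls, collapse = ", "), call. = FALSE)
  }
  structure(cfg, class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file path.
#' @return A validated `pipeline_config` (see [pipeline_config()]).
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path,
                               call. = FALSE)
  pipeline_config(yaml::read_yaml(path))
}
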