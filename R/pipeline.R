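#' Run the climate-envelope trajectory pipeline
#'
#' Executes the full analysis on a synthetic landscape defined by the
#' configuration: simulate (baseline climate + derived layers + niche-driven
#' fine vegetation + scenario climates), rescale (majority-area aggregation
#' and composition statistics), fit (the tree-ensemble envelope model with
#' out-of-bag assessment), forecast (per-scenario likelihoods, six-output
#' averages, argmax and legacy-threshold assignments per time step),
#' uncertainty (agreement, diversity, transition and trajectory products)
#' and summarize (regional percent-change and climate-by-vegetation
#' tables). All products are written under `outdir` (`rasters/`, `tables/`,
#' `manifest.json`); a re-run with the same configuration reproduces them
#' byte for byte.
#'
#' @param config A `pipeline_config` (see [pipeline_config()]) or a path to
#'   a YAML file.
#' @param outdir Output directory (created if needed).
#' @param stages Contiguous leading subset of
#'   `c("simulate", "rescale", "fit", "forecast", "uncertainty",
#'   "summarize")`; the pipeline always runs from the start and stops after
#'   the last requested stage.
#' @param quiet Suppress stage-boundary log messages.
#' @return Invisibly, a list of in-memory products (`baseline`, `veg_fine`,
#'   `veg_coarse`, `composition`, `fit`, `assessment`, `forecasts`,
#'   `assignments`, `agreement`, `diversity`, `transitions`, `trajectory`,
#'   `summaries`, `outdir`).
#' @export
run_pipeline <- function(config, outdir,
                         stages = c("simulate", "rescale", "fit",
                                    "forecast", "uncertainty", "summarize"),
                         quiet = FALSE) {
  if (is.character(config)) config <- read_pipeline_config(config)
  stopifnot(inherits(config, "pipeline_config"))
  all_stages <- c("simulate", "rescale", "fit", "forecast", "uncertainty",
                  "summarize")
  stages <- match.arg(stages, all_stages, several.ok = TRUE)
  last <- max(match(stages, all_stages))
  stages <- all_stages[seq_len(last)]
  dir.create(file.path(outdir, "rasters"), recursive = TRUE,
             showWarnings = FALSE)
  dir.create(file.path(outdir, "tables"), recursive = TRUE,
             showWarnings = FALSE)
  say <- function(...) if (!quiet) message("[envtraj] ", ...)
  products <- list(outdir = outdir, config = config)
  g <- config$grid
  tpath <- function(f) file.path(outdir, "tables", f)
  rpath <- function(f) file.path(outdir, "rasters", f)

  ## --- simulate -----------------------------------------------------------
  say("simulate: ", g$rows, "x", g$cols, " cells, fine_factor ",
      g$fine_factor, ", seed ", config$seed)
  baseline <- generate_climate_baseline(g$rows, g$cols, config$variables,
                                        seed = config$seed)
  if (all(c("MAT", "MAP") %in% names(baseline$layers))) {
    baseline <- compute_derived_variables(baseline)
  }
  veg <- generate_vegetation(baseline, config$rules,
                             fine_factor = g$fine_factor,
                             label_noise = config$label_noise,
                             seed = config$seed + 1L,
                             classes = config$classes)
  scen <- generate_future_scenarios(baseline, config$scenarios,
                                    recompute_derived = TRUE)
  for (v in names(baseline$layers)) {
    write_raster(baseline$layers[[v]], rpath(paste0("baseline_", v, ".asc")))
  }
  write_categorical_raster(veg$map, rpath("vegetation_fine.asc"))
  products$baseline <- baseline
  products$veg_fine <- veg$map
  products$veg_truth <- veg$truth
  products$scenarios <- scen
  if (last == 1L) return(finish_pipeline(products, outdir, config, quiet))

  ## --- rescale ------------------------------------------------------------
  say("rescale: ", nrow(veg$map$values), "x", ncol(veg$map$values),
      " fine pixels -> ", g$rows, "x", g$cols, " cells")
  res <- majority_rescale(veg$map)
  stats <- composition_stats(res$composition, res$map)
  write_categorical_raster(res$map, rpath("vegetation_coarse.asc"))
  utils::write.csv(stats$table, tpath("composition_stats.csv"),
                   row.names = FALSE)
  utils::write.csv(flatten_named_shares(stats$co_occurring, "co_class"),
                   tpath("cooccurrence.csv"), row.names = FALSE)
  products$veg_coarse <- res$map
  products$composition <- res$composition
  products$composition_stats <- stats
  if (last == 2L) return(finish_pipeline(products, outdir, config, quiet))

  ## --- fit ----------------------------------------------------------------
  say("fit: ", config$model$n_trees, " trees, holdout ",
      config$model$holdout, ", seed ", config$seed + 2L)
  fit <- fit_envelope(baseline, res$map, n_trees = config$model$n_trees,
                      holdout = config$model$holdout,
                      seed = config$seed + 2L,
                      replace = isTRUE(config$model$replace))
  assessment <- evaluate(fit, baseline, res$map)
  profile <- misclassification_profile(assessment$confusion)
  utils::write.csv(
    data.frame(class = names(assessment$per_class_accuracy),
               accuracy = unname(assessment$per_class_accuracy),
               percent_area = stats$table$percent_area[
                 match(names(assessment$per_class_accuracy),
                       stats$table$class)],
               stringsAsFactors = FALSE),
    tpath("model_assessment.csv"), row.names = FALSE)
  utils::write.csv(as.data.frame(assessment$confusion),
                   tpath("confusion.csv"), row.names = FALSE)
  utils::write.csv(assessment$importance_ranking, tpath("importance.csv"),
                   row.names = FALSE)
  utils::write.csv(flatten_named_shares(profile, "predicted"),
                   tpath("misclassified_as.csv"), row.names = FALSE)
  products$fit <- fit
  products$assessment <- assessment
  if (last == 3L) return(finish_pipeline(products, outdir, config, quiet))

  ## --- forecast -----------------------------------------------------------
  threshold <- config$model$threshold
  if (is.null(threshold)) threshold <- default_threshold(
    length(config$classes))
  forecasts <- list()    # per timestep: list(per_output=, average=)
  assignments <- list()  # per timestep: list(argmax=, legacy=)
  for (ts in config$timesteps) {
    sel <- Filter(function(s) s$spec$timestep == ts, scen)
    say("forecast ", ts, ": ", length(sel), " scenario outputs")
    per_output <- lapply(sel, function(s) {
      predict_likelihood(fit, s$surface, provenance = s$spec$label)
    })
    names(per_output) <- vapply(sel, function(s)
      paste(s$spec$gcm_label, s$spec$rcp_label), character(1))
    avg <- ensemble_average(per_output)
    write_score_table(c(per_output, list(average = avg)),
                      tpath(paste0("scores_", ts, ".csv")))
    arg <- assign_argmax(avg)
    leg <- assign_with_legacy_threshold(avg, res$map, threshold)
    write_categorical_raster(arg, rpath(paste0("assignment_argmax_", ts,
                                               ".asc")))
    write_categorical_raster(leg, rpath(paste0("assignment_legacy_", ts,
                                               ".asc")))
    forecasts[[ts]] <- list(per_output = per_output, average = avg)
    assignments[[ts]] <- list(argmax = arg, legacy = leg)
  }
  products$forecasts <- forecasts
  products$assignments <- assignments
  products$threshold <- threshold
  if (last == 4L) return(finish_pipeline(products, outdir, config, quiet))

  ## --- uncertainty --------------------------------------------------------
  final_ts <- config$timesteps[length(config$timesteps)]
  per_output_assign <- lapply(forecasts[[final_ts]]$per_output,
                              assign_argmax)
  say("uncertainty: agreement over ", length(per_output_assign),
      " outputs at ", final_ts)
  agreement <- agreement_map(per_output_assign)
  diversity <- diversity_map(per_output_assign)
  series <- c(list(res$map), lapply(assignments, `[[`, "argmax"))
  transitions <- transition_count(series)
  write_raster(agreement, rpath("agreement.asc"))
  write_raster(diversity, rpath("diversity.asc"))
  write_raster(transitions, rpath("transitions.asc"))
  baseline_areas <- area_by_class(res$map, g$cell_area_ha)
  output_areas <- lapply(per_output_assign, area_by_class,
                         cell_area_ha = g$cell_area_ha)
  trajectory <- trajectory_table(baseline_areas, output_areas)
  utils::write.csv(trajectory, tpath("trajectory.csv"), row.names = FALSE)
  products$per_output_assign <- per_output_assign
  products$agreement <- agreement
  products$diversity <- diversity
  products$transitions <- transitions
  products$trajectory <- trajectory
  if (last == 5L) return(finish_pipeline(products, outdir, config, quiet))

  ## --- summarize ----------------------------------------------------------
  say("summarize: regional change and climate by vegetation")
  vars <- names(baseline$layers)
  base_means <- regional_means(baseline)
  final_scen <- Filter(function(s) s$spec$timestep == final_ts, scen)
  scen_means <- lapply(final_scen, function(s) regional_means(s$surface))
  names(scen_means) <- vapply(final_scen, function(s)
    paste(s$spec$gcm_label, s$spec$rcp_label), character(1))
  change <- percent_change(base_means, scen_means)
  change_tbl <- rbind(
    cbind(data.frame(scenario = "baseline_mean"),
          as.data.frame(as.list(base_means))),
    stats::setNames(change, c("scenario", vars)))
  utils::write.csv(change_tbl, tpath("climate_change_summary.csv"),
                   row.names = FALSE)
  byveg_base <- climate_by_vegetation(baseline, res$map)
  byveg_base$period <- "baseline"
  byveg_fut <- climate_by_vegetation(baseline,
                                     assignments[[final_ts]]$argmax)
  byveg_fut$period <- paste0(final_ts, "_forecast_cells")
  utils::write.csv(rbind(byveg_base, byveg_fut),
                   tpath("climate_by_vegetation.csv"), row.names = FALSE)
  products$summaries <- list(regional = change_tbl,
                             by_vegetation = rbind(byveg_base, byveg_fut))
  finish_pipeline(products, outdir, config, quiet)
}

# named list of named percent vectors -> long data frame
flatten_named_shares <- function(x, value_name) {
  rows <- lapply(names(x), function(cls) {
    v <- x[[cls]]
    if (!length(v)) return(NULL)
    data.frame(class = cls, other = names(v), percent = unname(v),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(class = character(), other = character(),
                      percent = numeric(), stringsAsFactors = FALSE)
  }
  names(out)[2] <- value_name
  out
}

finish_pipeline <- function(products, outdir, config, quiet) {
  manifest <- list(
    package = "envtraj",
    version = as.character(utils::packageVersion("envtraj")),
    coordinate_convention = paste(
      "0-based (row, col), row-major cell ids, cell centres;",
      "rasters north-up ESRI ASCII"),
    seed = config$seed,
    derived_seeds = list(climate = config$seed, vegetation = config$seed + 1L,
                         envelope = config$seed + 2L),
    grid = config$grid,
    classes = config$classes,
    variables = names(config$variables),
    n_scenarios = length(config$scenarios),
    timesteps = config$timesteps,
    model = config$model,
    label_noise = config$label_noise,
    files = local({
      f <- sort(list.files(outdir, recursive = TRUE))
      f <- setdiff(f, "manifest.json")
      as.list(stats::setNames(
        unname(tools::md5sum(file.path(outdir, f))), f))
    })
  )
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA,
                       null = "null")
  if (!quiet) message("[envtraj] done: ", outdir)
  invisible(products)
}
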