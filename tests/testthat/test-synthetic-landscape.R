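test_that("baseline generator is deterministic and honours degenerate noise", {
  specs <- list(variable_spec("MAT", 1.9, grad_row = 2,
                              noise_amplitude = 0.3),
                variable_spec("MAP", 1735, grad_col = 500,
                              noise_amplitude = 40, lower = 1))
  s1 <- generate_climate_baseline(20, 20, specs, seed = 5)
  s2 <- generate_climate_baseline(20, 20, specs, seed = 5)
  s3 <- generate_climate_baseline(20, 20, specs, seed = 6)
  expect_identical(s1$layers, s2$layers)
  expect_false(identical(s1$layers$MAT, s3$layers$MAT))

  flat <- list(variable_spec("MAT", 1.9), variable_spec("MAP", 1735))
  s0 <- generate_climate_baseline(10, 10, flat, seed = 1)
  expect_true(all(s0$layers$MAT == 1.9))
  expect_true(all(s0$layers$MAP == 1735))
})

test_that("baseline generator rejects bad input", {
  expect_error(generate_climate_baseline(1, 10,
                                         list(variable_spec("MAT", 1)),
                                         seed = 1), ">= 2x2")
  dup <- list(variable_spec("MAT", 1), variable_spec("MAT", 2))
  expect_error(generate_climate_baseline(5, 5, dup, seed = 1), "MAT")
  expect_error(generate_climate_baseline(5, 5, list(), seed = 1),
               "variable_spec")
  expect_error(variable_spec("MAT", 1, correlation_length = 0))
  expect_error(variable_spec("MAT", 1, noise_amplitude = -1))
})

test_that("default specs recover the regional baseline means at 100x100", {
  surface <- generate_climate_baseline(100, 100, default_variable_specs(),
                                       seed = 42)
  means <- regional_means(surface)
  expect_lt(abs(means[["MAT"]] - 1.9) / 1.9, 0.01)
  expect_lt(abs(means[["MAP"]] - 1735) / 1735, 0.01)
  expect_lt(abs(means[["PAS"]] - 862) / 862, 0.01)
  expect_lt(abs(means[["Eref"]] - 351) / 351, 0.01)
})

test_that("annual heat moisture index follows the per-cell formula", {
  surface <- climate_surface(list(
    MAT = matrix(c(0, 1.9, 4, -2), 2, 2),
    MAP = matrix(c(1000, 1735, 500, 2000), 2, 2)))
  out <- compute_derived_variables(surface)
  expect_equal(out$layers$AHM[1, 1], 10)                 # MAT 0, MAP 1000
  expect_equal(out$layers$AHM[2, 1], 11.9 / 1.735)       # approx 6.859
  expect_identical(out$layers$MAT, surface$layers$MAT)

  doubled <- surface
  doubled$layers$MAP <- surface$layers$MAP * 2
  expect_equal(compute_derived_variables(doubled)$layers$AHM,
               out$layers$AHM / 2)

  surface$layers$MAP[1, 2] <- 0
  expect_error(compute_derived_variables(surface), "row 1, col 2")
  expect_error(compute_derived_variables(
    climate_surface(list(MAT = matrix(0, 2, 2)))), "MAP")
})

test_that("vegetation labels follow the rules and noise statistics", {
  specs <- list(variable_spec("MAT", 2, grad_row = 3,
                              noise_amplitude = 0.1))
  surface <- generate_climate_baseline(20, 20, specs, seed = 9)

  one <- generate_vegetation(surface, list(niche_rule("A", list(), 1)),
                             fine_factor = 2, label_noise = 0, seed = 1)
  expect_true(all(one$map$values == 1L))

  rules <- list(niche_rule("cold", list(MAT = c(-Inf, 2)), 1),
                niche_rule("warm", list(MAT = c(2, Inf)), 2))
  veg <- generate_vegetation(surface, rules, fine_factor = 3,
                             label_noise = 0, seed = 1)
  expect_identical(dim(veg$map$values), c(60L, 60L))
  expect_identical(veg$map$values, veg$truth$values)
  # per-pixel oracle: label is decided by the interpolated MAT threshold
  fine_mat <- envtraj:::bilinear_upsample(surface$layers$MAT, 3L)
  expect_identical(veg$map$values, ifelse(fine_mat < 2, 1L, 2L))
})

test_that("label noise flips the expected fraction of pixels", {
  specs <- list(variable_spec("MAT", 2, grad_row = 3))
  surface <- generate_climate_baseline(40, 40, specs, seed = 2)
  rules <- lapply(1:4, function(i) {
    niche_rule(paste0("K", i), list(MAT = c(0.5 + 0.75 * (i - 1),
                                            0.5 + 0.75 * i)), i)
  })
  rules[[5]] <- niche_rule("K5", list(), 5)
  veg <- generate_vegetation(surface, rules, fine_factor = 4,
                             label_noise = 0.2, seed = 77)
  differ <- mean(veg$map$values != veg$truth$values)
  # flips always land on another class, so E[differ] = 0.2 exactly
  expect_lt(abs(differ - 0.2), 0.02)
  again <- generate_vegetation(surface, rules, fine_factor = 4,
                               label_noise = 0.2, seed = 77)
  expect_identical(again$map$values, veg$map$values)
})

test_that("uncovered climate without a fallback rule is an error", {
  specs <- list(variable_spec("MAT", 2, grad_row = 3))
  surface <- generate_climate_baseline(10, 10, specs, seed = 3)
  only_cold <- list(niche_rule("cold", list(MAT = c(-Inf, 1)), 1))
  expect_error(generate_vegetation(surface, only_cold, 1, 0, seed = 1),
               "no niche rule matches")
})

test_that("scenario surfaces apply multiplicative deltas per cell", {
  base <- climate_surface(list(MAT = matrix(1.9, 4, 4),
                               MAP = matrix(1735, 4, 4),
                               PAS = matrix(862, 4, 4)))
  null_spec <- scenario_spec("none", "none", "2080s",
                             c(MAT = 0, MAP = 0, PAS = 0))
  same <- generate_future_scenarios(base, list(null_spec),
                                    recompute_derived = FALSE)[[1]]$surface
  expect_equal(same$layers, base$layers)

  gfdl <- scenario_spec("GFDL-CM3", "RCP85", "2080s",
                        c(MAT = 3.65, MAP = 0.28, PAS = -0.76))
  fut <- generate_future_scenarios(base, list(gfdl),
                                   recompute_derived = FALSE)[[1]]$surface
  expect_equal(fut$layers$PAS[1, 1], 862 * 0.24, tolerance = 1e-12) # 206.9
  expect_equal(fut$layers$MAT[1, 1], 1.9 * 4.65, tolerance = 1e-12) # 8.84
  expect_equal(fut$layers$MAP[2, 3], 1735 * 1.28, tolerance = 1e-12)

  bad <- scenario_spec("x", "y", "2080s", c(PAS = -1.2))
  expect_error(generate_future_scenarios(base, list(bad)), "negative")
})

test_that("derived AHM is recomputed from perturbed primaries", {
  base <- compute_derived_variables(
    climate_surface(list(MAT = matrix(2, 3, 3), MAP = matrix(1000, 3, 3))))
  sp <- scenario_spec("g", "r", "2080s", c(MAT = 1, MAP = 0.25, AHM = 99))
  fut <- generate_future_scenarios(base, list(sp),
                                   recompute_derived = TRUE)[[1]]$surface
  expect_equal(fut$layers$AHM[1, 1], (4 + 10) / (1250 / 1000))
})

test_that("regional mean change is monotone in delta magnitude", {
  surface <- generate_climate_baseline(30, 30, default_variable_specs(),
                                       seed = 12)
  surface <- compute_derived_variables(surface)
  scen <- generate_future_scenarios(surface, default_scenarios("2080s"))
  for (v in c("MAP", "PAS", "Eref", "MAT")) {
    deltas <- vapply(scen, function(s) s$spec$deltas[[v]], numeric(1))
    means <- vapply(scen, function(s) regional_means(s$surface, v),
                    numeric(1))
    expect_equal(order(deltas), order(means))
  }
})

test_that("time-step interpolation scales 2080 deltas by thirds", {
  all_ts <- default_scenarios()
  expect_length(all_ts, 18)
  d2020 <- Filter(function(s) s$timestep == "2020s", all_ts)
  d2080 <- Filter(function(s) s$timestep == "2080s", all_ts)
  expect_equal(d2020[[1]]$deltas, d2080[[1]]$deltas / 3)
})
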