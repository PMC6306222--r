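cat_from <- function(v, classes = paste0("C", 1:10)) {
  categorical_raster(matrix(as.integer(v), 1, length(v)), classes)
}

test_that("agreement counts the modal vote", {
  six_same <- replicate(6, cat_from(c(1, 2)), simplify = FALSE)
  expect_true(all(agreement_map(six_same) == 6))
  votes <- lapply(c(1, 1, 1, 2, 2, 3), cat_from)   # (A,A,A,B,B,C) per cell
  expect_equal(agreement_map(votes)[1, 1], 3L)
  distinct <- lapply(1:6, cat_from)
  expect_true(all(agreement_map(distinct) == 1))
})

test_that("diversity counts distinct forecasts and pairs with agreement", {
  six_same <- replicate(6, cat_from(c(1, 2)), simplify = FALSE)
  expect_true(all(diversity_map(six_same) == 1))
  votes <- lapply(c(1, 1, 1, 2, 2, 3), cat_from)
  expect_equal(diversity_map(votes)[1, 1], 3L)
  set.seed(9)
  maps <- replicate(6, random_cat_raster(8, 8, 4), simplify = FALSE)
  ag <- agreement_map(maps)
  dv <- diversity_map(maps)
  expect_identical(dv == 1L, ag == 6L)
  expect_true(all(ag[dv == 6L] == 1L))
})

test_that("transition counts follow the time series", {
  series <- function(v) lapply(v, cat_from)
  expect_equal(transition_count(series(c(1, 1, 1, 1)))[1, 1], 0L)
  expect_equal(transition_count(series(c(1, 2, 1, 2)))[1, 1], 3L)
  expect_equal(transition_count(series(c(1, 1, 2, 2)))[1, 1], 1L)
  expect_error(transition_count(series(1)), ">= 2")
})

test_that("agreement, diversity and transitions match brute force", {
  set.seed(202)
  for (i in 1:25) {
    nr <- sample(2:20, 1); nc <- sample(2:20, 1)
    k <- sample(2:10, 1)
    m_out <- sample(2:6, 1)
    maps <- replicate(m_out,
                      random_cat_raster(nr, nc, k, na_frac = 0.05),
                      simplify = FALSE)
    mats <- lapply(maps, `[[`, "values")
    expect_identical(agreement_map(maps), bf_agreement(mats))
    expect_identical(diversity_map(maps), bf_diversity(mats))
    t_steps <- sample(2:4, 1)
    series <- replicate(t_steps, random_cat_raster(nr, nc, k),
                        simplify = FALSE)
    expect_identical(transition_count(series),
                     bf_transitions(lapply(series, `[[`, "values")))
  }
})

test_that("area accounting is conservative", {
  set.seed(3)
  a <- random_cat_raster(12, 12, 5, na_frac = 0.1)
  areas <- area_by_class(a, cell_area_ha = 100)
  expect_equal(sum(areas), sum(!is.na(a$values)) * 100)
  empty <- area_by_class(categorical_raster(matrix(1L, 2, 2), c("A", "B")))
  expect_equal(empty[["B"]], 0)
  expect_error(area_by_class(a, cell_area_ha = 0), "> 0")
})

test_that("trend rule classifies min/max spread against baseline", {
  base <- c(Alpine = 432000, Spruce = 216300, Hemlock = 114400)
  outputs <- list(c(Alpine = 0, Spruce = 2400, Hemlock = 264200),
                  c(Alpine = 8500, Spruce = 256300, Hemlock = 490700))
  tt <- trajectory_table(base, outputs)
  expect_equal(tt$trend, c("-", "unk", "+"))
  expect_true(all(tt$min_ha <= tt$mean_ha & tt$mean_ha <= tt$max_ha))
  # boundary: max == baseline and min == baseline are both "unk"
  tt2 <- trajectory_table(c(X = 100), list(c(X = 50), c(X = 100)))
  expect_equal(tt2$trend, "unk")
  tt3 <- trajectory_table(c(X = 100), list(c(X = 100), c(X = 150)))
  expect_equal(tt3$trend, "unk")
  # class missing from an output counts as 0 ha
  tt4 <- trajectory_table(c(X = 100, Y = 10),
                          list(c(X = 120), c(X = 130, Y = 5)))
  expect_equal(tt4$min_ha[tt4$class == "Y"], 0)
  expect_equal(tt4$trend[tt4$class == "Y"], "-")
})

test_that("a class whose niche contracts in every scenario trends down", {
  cfg <- box_recovery_config(rows = 40, cols = 40)
  out <- run_pipeline(cfg, file.path(tempdir(), "rec40"), quiet = TRUE)
  traj <- out$trajectory
  expect_equal(traj$trend[traj$class == "Cold"], "-")
  expect_equal(traj$max_ha[traj$class == "Cold"], 0)
  expect_equal(traj$trend[traj$class == "Warm"], "+")
})
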