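test_that("separable box niches give near-zero out-of-bag error", {
  land <- separable_landscape()
  fit <- fit_envelope(land$surface, land$veg, n_trees = 100, seed = 21)
  expect_lt(fit$oob_error, 0.05)
})

test_that("fitting is deterministic given the seed", {
  land <- separable_landscape()
  f1 <- fit_envelope(land$surface, land$veg, n_trees = 60, seed = 3)
  f2 <- fit_envelope(land$surface, land$veg, n_trees = 60, seed = 3)
  expect_identical(f1$oob_error, f2$oob_error)
  expect_identical(f1$importance, f2$importance)
  l1 <- predict_likelihood(f1, land$surface)
  l2 <- predict_likelihood(f2, land$surface)
  expect_identical(l1$scores, l2$scores)
})

test_that("permuted labels destroy the signal down to the random baseline", {
  land <- separable_landscape(24, 24)
  veg <- land$veg
  set.seed(99)
  # permute labels while keeping class frequencies
  veg$values <- matrix(sample(as.vector(veg$values)), nrow(veg$values))
  fit <- fit_envelope(land$surface, veg, n_trees = 100, seed = 5)
  k <- 4
  expect_lt(abs(fit$oob_error - random_baseline_misclassification(k)), 0.1)
})

test_that("likelihood vectors are normalised vote fractions", {
  land <- separable_landscape()
  fit <- fit_envelope(land$surface, land$veg, n_trees = 80, seed = 13)
  lik <- predict_likelihood(fit, land$surface)
  sums <- rowSums(lik$scores)
  expect_true(all(abs(sums - 1) < 1e-9))
  expect_true(all(lik$scores >= 0 & lik$scores <= 1))

  # deep inside a pure niche the vote concentrates
  mat <- land$surface$layers$MAT
  map <- land$surface$layers$MAP
  deep <- which(mat < 1.3 & map < 800)[1]
  cell <- arrayInd(deep, dim(mat))
  row_major <- (cell[1] - 1) * land$surface$ncol + cell[2]
  expect_gt(lik$scores[row_major, "A"], 0.9)
})

test_that("argmax prediction reproduces labels on separable training data", {
  land <- separable_landscape()
  fit <- fit_envelope(land$surface, land$veg, n_trees = 100, seed = 2)
  pred <- assign_argmax(predict_likelihood(fit, land$surface))
  expect_gt(mean(pred$values == land$veg$values), 0.99)
})

test_that("evaluation bookkeeping is exact for perfect prediction", {
  land <- separable_landscape()
  fit <- fit_envelope(land$surface, land$veg, n_trees = 100, seed = 2)
  a <- evaluate(fit, land$surface, land$veg)
  expect_equal(rowSums(a$confusion),
               table(factor(land$veg$classes[land$veg$values],
                            levels = land$veg$classes)) |> as.vector() |>
                 setNames(land$veg$classes))
  expect_equal(a$misclassification_rate,
               1 - sum(diag(a$confusion)) / sum(a$confusion))
  if (a$misclassification_rate == 0) {
    expect_true(all(a$per_class_accuracy == 1))
  }
})

test_that("box-defining variables top the importance ranking", {
  land <- separable_landscape()
  # add two pure-noise predictors that play no role in the niches
  set.seed(31)
  land$surface$layers$noise1 <- matrix(rnorm(900), 30, 30)
  land$surface$layers$noise2 <- matrix(rnorm(900), 30, 30)
  fit <- fit_envelope(land$surface, land$veg, n_trees = 100, seed = 17)
  a <- evaluate(fit, land$surface, land$veg)
  expect_setequal(a$importance_ranking$variable[1:2], c("MAT", "MAP"))
})

test_that("out-of-bag variance shrinks as the ensemble grows", {
  land <- separable_landscape(20, 20, label_noise = 0.3, seed = 44)
  errs <- function(n_trees) {
    vapply(1:6, function(s) {
      fit_envelope(land$surface, land$veg, n_trees = n_trees,
                   seed = s)$oob_error
    }, numeric(1))
  }
  expect_lt(var(errs(150)), var(errs(5)) + 1e-12)
})

test_that("random assignment baseline is (k-1)/k", {
  expect_equal(random_baseline_misclassification(10), 0.9)
  expect_equal(random_baseline_misclassification(1), 0)
  expect_equal(random_baseline_misclassification(4), 0.75)
  expect_error(random_baseline_misclassification(0), "positive integer")
})

test_that("fit input validation catches bad cells and degenerate classes", {
  land <- separable_landscape(10, 10)
  broken <- land$surface
  broken$layers$MAT[3, 4] <- NaN
  expect_error(fit_envelope(broken, land$veg, n_trees = 10, seed = 1),
               "MAT.*row 3, col 4")
  single <- categorical_raster(matrix(1L, 10, 10), c("A", "B"))
  expect_error(fit_envelope(land$surface, single, n_trees = 10, seed = 1),
               ">= 2 classes")
  expect_error(fit_envelope(land$surface, land$veg, n_trees = 10,
                            holdout = 1, seed = 1), "holdout")
  missing_layer <- climate_surface(list(MAT = land$surface$layers$MAT))
  fit <- fit_envelope(land$surface, land$veg, n_trees = 10, seed = 1)
  expect_error(predict_likelihood(fit, missing_layer), "MAP")
})
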