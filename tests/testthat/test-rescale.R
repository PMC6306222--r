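test_that("majority rescaling matches hand-counted 3x3 blocks", {
  classes <- c("A", "B")
  pure <- categorical_raster(matrix(1L, 3, 3), classes, fine_factor = 3)
  res <- majority_rescale(pure)
  expect_identical(res$map$values[1, 1], 1L)
  expect_equal(res$composition$fractions[1, 1, ], c(1, 0))

  five_four <- categorical_raster(
    matrix(c(1, 1, 1, 1, 1, 2, 2, 2, 2), 3, 3), classes, fine_factor = 3)
  res <- majority_rescale(five_four)
  expect_identical(res$map$values[1, 1], 1L)
  expect_equal(res$composition$fractions[1, 1, ], c(5 / 9, 4 / 9))

  tied <- categorical_raster(
    matrix(c(1, 1, 1, 1, 2, 2, 2, 2, NA), 3, 3), classes, fine_factor = 3)
  res <- majority_rescale(tied)
  expect_equal(res$composition$fractions[1, 1, ], c(0.5, 0.5))
  expect_identical(res$map$values[1, 1], 1L)  # smallest-index tie-break
  expect_equal(res$composition$classified_fraction[1, 1], 8 / 9)
})

test_that("cells with zero classified pixels become no-data", {
  fine <- categorical_raster(
    cbind(matrix(NA_integer_, 2, 2), matrix(1L, 2, 2)), c("A", "B"),
    fine_factor = 2)
  res <- majority_rescale(fine)
  expect_identical(res$map$values[1, ], c(NA_integer_, 1L))
  expect_true(all(is.na(res$composition$fractions[1, 1, ])))
  expect_equal(res$composition$classified_fraction[1, 1], 0)
})

test_that("majority rescaling equals the brute-force counter", {
  set.seed(101)
  for (i in 1:25) {
    f <- sample(1:4, 1)
    nr <- sample(1:20, 1) * f
    nc <- sample(1:20, 1) * f
    k <- sample(2:10, 1)
    fine <- random_cat_raster(nr, nc, k, na_frac = runif(1, 0, 0.3))
    fine$fine_factor <- f
    res <- majority_rescale(fine)
    oracle <- bf_majority(fine$values, fine$classes, f)
    expect_identical(res$map$values, oracle$assign)
    expect_equal(res$composition$fractions, oracle$fractions)
  }
})

test_that("composition fractions sum to one over classified cells", {
  set.seed(7)
  fine <- random_cat_raster(24, 24, 6, na_frac = 0.2)
  fine$fine_factor <- 3L
  res <- majority_rescale(fine)
  sums <- apply(res$composition$fractions, c(1, 2), sum)
  classified <- res$composition$classified_fraction > 0
  expect_true(all(abs(sums[classified] - 1) < 1e-9))
})

test_that("rescaling at fine_factor 1 is the identity on classified cells", {
  set.seed(8)
  fine <- random_cat_raster(15, 12, 5, na_frac = 0.1)
  fine$fine_factor <- 1L
  res <- majority_rescale(fine)
  expect_identical(res$map$values, fine$values)
})

test_that("dimension mismatch is rejected with both shapes", {
  fine <- categorical_raster(matrix(1L, 10, 9), "A", fine_factor = 4)
  expect_error(majority_rescale(fine), "10x9")
})

test_that("composition statistics average over assigned cells", {
  # 1x2 coarse grid via 10x10 blocks: cell 1 = 60 A + 40 B,
  # cell 2 = 70 A + 30 B -> both assigned A
  block <- function(na, nb) {
    matrix(c(rep(1L, na), rep(2L, nb)), 10, 10)
  }
  fine <- categorical_raster(cbind(block(60, 40), block(70, 30)),
                             c("A", "B"), fine_factor = 10)
  res <- majority_rescale(fine)
  st <- composition_stats(res$composition, res$map)
  expect_equal(st$table$percent_area[st$table$class == "A"], 65)
  expect_equal(st$co_occurring$A, c(B = 35))
  # B never assigned: percent area missing, not zero
  expect_true(is.na(st$table$percent_area[st$table$class == "B"]))
  expect_length(st$co_occurring$B, 0)
})

test_that("co-occurrence threshold is inclusive at exactly 10%", {
  fine <- categorical_raster(
    matrix(c(rep(1L, 90), rep(2L, 10)), 10, 10), c("A", "B"),
    fine_factor = 10)
  res <- majority_rescale(fine)
  st <- composition_stats(res$composition, res$map)
  expect_equal(st$co_occurring$A, c(B = 10))
})

test_that("misclassification profile reports >= 20% shares, sorted", {
  classes <- c("A", "B", "C", "D")
  conf <- matrix(0, 4, 4, dimnames = list(classes, classes))
  diag(conf) <- 50
  conf["A", c("B", "C", "D")] <- c(6, 3, 1)
  prof <- misclassification_profile(conf)
  expect_equal(prof$A, c(B = 60, C = 30))
  expect_length(prof$B, 0)   # no misclassified cells -> empty

  conf2 <- diag(10, 3)
  dimnames(conf2) <- list(c("x", "y", "z"), c("x", "y", "z"))
  prof2 <- misclassification_profile(conf2)
  expect_true(all(lengths(prof2) == 0))

  # exactly 20% share is included
  conf["A", c("B", "C", "D")] <- c(6, 2, 2)
  prof3 <- misclassification_profile(conf)
  expect_equal(prof3$A, c(B = 60, C = 20, D = 20))
})
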