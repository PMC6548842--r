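test_that("green-red index matches its defining ratio", {
  px <- array(0, c(1, 3, 3))
  px[1, 1, ] <- c(100, 100, 0)   # G = R -> 0
  px[1, 2, ] <- c(0, 100, 0)     # R = 0 -> 1
  px[1, 3, ] <- c(50, 150, 20)   # (150-50)/(150+50)
  s <- green_red_index(px)
  expect_equal(as.numeric(s$values), c(0, 1, 0.5))
})

test_that("green-red index is scale-free and neutral on zero-sum pixels", {
  set.seed(7)
  px <- array(runif(5 * 4 * 3, 0, 255), c(5, 4, 3))
  s8 <- green_red_index(px)
  s16 <- green_red_index(px * 257)   # same image on a 16-bit scale
  expect_equal(s8$values, s16$values)
  expect_true(all(s8$values >= -1 & s8$values <= 1))

  px0 <- px
  px0[2, 3, 1:2] <- 0               # pure blue pixel: G + R = 0
  expect_equal(green_red_index(px0)$values[2, 3], 0)

  mask <- matrix(FALSE, 5, 4); mask[1, 1] <- TRUE
  expect_equal(green_red_index(px, nodata_mask = mask)$values[1, 1], 0)
})

test_that("malformed images are rejected", {
  expect_error(green_red_index(matrix(1, 3, 3)), "3-channel")
  expect_error(green_red_index(array(-1, c(2, 2, 3))), "non-negative")
})

test_that("summed-area table reproduces every brute-force rectangle sum", {
  expect_equal(summed_area_table(matrix(3))$cumulative[2, 2], 3)
  expect_equal(summed_area_table(matrix(1, 4, 6))$cumulative[5, 7], 24)

  set.seed(11)
  v <- matrix(runif(25, -1, 1), 5, 5)
  sat <- summed_area_table(v)
  for (x1 in 0:4) for (x2 in (x1 + 1):5) for (y1 in 0:4) for (y2 in (y1 + 1):5)
    expect_equal(rect_sum(sat, x1, x2, y1, y2),
                 sum(v[(y1 + 1):y2, (x1 + 1):x2]))
})

test_that("rectangle sums clip, vanish on empty rectangles, and add up", {
  set.seed(12)
  v <- matrix(runif(30, -1, 1), 5, 6)
  sat <- summed_area_table(v)
  expect_equal(rect_sum(sat, 2, 2, 0, 5), 0)          # degenerate
  expect_equal(rect_sum(sat, -10, 99, -5, 99), sum(v)) # clipped to full field
  expect_equal(rect_sum(sat, 10, 20, 10, 20), 0)       # fully outside
  # additivity over a disjoint split
  whole <- rect_sum(sat, 0, 6, 0, 5)
  expect_equal(rect_sum(sat, 0, 3, 0, 5) + rect_sum(sat, 3, 6, 0, 5), whole)
  # |sum| bounded by area * max |S|
  expect_lte(abs(rect_sum(sat, 1, 4, 1, 3)), 6 * max(abs(v)))
  expect_error(summed_area_table(matrix(numeric(0), 0, 0)), "empty")
})

test_that("plant segmentation thresholds strictly and counts correctly", {
  expect_equal(sum(segment_plants(scalar_field(matrix(0, 3, 3)), 0)), 0)
  m <- segment_plants(scalar_field(matrix(c(-1, 1), 1, 2)), 0)
  expect_equal(as.logical(m), c(FALSE, TRUE))

  set.seed(13)
  v <- matrix(runif(200, -1, 1), 10, 20)
  for (t in c(-0.5, 0, 0.4))
    expect_equal(sum(segment_plants(scalar_field(v), t)), sum(v > t))
  expect_error(segment_plants(scalar_field(v), 2), "threshold")
})

test_that("automatic threshold separates a bimodal field", {
  set.seed(14)
  soil <- rnorm(4000, -0.05, 0.04)
  plants <- rnorm(1000, 0.35, 0.06)
  f <- scalar_field(matrix(c(soil, plants), 50, 100))
  thr <- attr(segment_plants(f, "auto"), "threshold")
  expect_gt(thr, 0.03)
  expect_lt(thr, 0.3)
})
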