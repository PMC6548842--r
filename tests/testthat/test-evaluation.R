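test_that("alignment error is the per-cell displacement distance in cm", {
  z <- displacement_field(matrix(0, 2, 2), matrix(0, 2, 2))
  expect_true(all(alignment_error(z, z)$per_cell == 0))

  t345 <- displacement_field(matrix(3, 1, 1), matrix(4, 1, 1))
  z1 <- displacement_field(matrix(0, 1, 1), matrix(0, 1, 1))
  expect_equal(alignment_error(t345, z1, 1)$per_cell[1, 1], 5)
  expect_equal(alignment_error(t345, z1, 0.8)$per_cell[1, 1], 4)

  set.seed(61)
  a <- displacement_field(matrix(rnorm(12), 3, 4), matrix(rnorm(12), 3, 4))
  b <- displacement_field(matrix(rnorm(12), 3, 4), matrix(rnorm(12), 3, 4))
  er <- alignment_error(a, b, 2)
  for (i in 1:3) for (j in 1:4)
    expect_equal(er$per_cell[i, j],
                 2 * sqrt((a$du[i, j] - b$du[i, j])^2 +
                          (a$dv[i, j] - b$dv[i, j])^2))
  expect_error(alignment_error(z, z1), "mismatch")
})

test_that("boxplot summaries follow the 1.5-IQR convention", {
  cs <- boxplot_summary(rep(4.2, 10))
  expect_equal(cs$q3 - cs$q1, 0)
  expect_length(cs$outliers, 0)

  s <- boxplot_summary(c(1:100, 1000))
  expect_equal(s$outliers, 1000)
  expect_lte(s$whisker_high, 100)

  set.seed(62)
  x <- rexp(500)
  s <- boxplot_summary(x)
  q <- quantile(x, c(0.25, 0.5, 0.75), names = FALSE)
  expect_equal(c(s$q1, s$median, s$q3), q)
  expect_equal(s$whisker_high, max(x[x <= q[3] + 1.5 * (q[3] - q[1])]))
  expect_gte(s$median, s$q1)
  expect_lte(s$median, s$q3)
  expect_error(boxplot_summary(numeric(0)), "empty")
})

test_that("trimming shortens the along-plot dimension about fixed centers", {
  g <- field_grid(2, 3, 150, 500, pitch_u = 200, pitch_v = 625)
  expect_equal(trim_grid(g, 0), g)
  gt <- trim_grid(g, 0.5)
  expect_equal(unique(as.numeric(gt$H)), 250)
  expect_equal(unique(as.numeric(gt$W)), 150)
  expect_equal(gt$u, g$u)
  expect_equal(gt$v, g$v)
  # containment in the original cell
  expect_true(all(gt$v - gt$H / 2 >= g$v - g$H / 2))
  expect_true(all(gt$v + gt$H / 2 <= g$v + g$H / 2))
  expect_error(trim_grid(g, 1), "trim_fraction")
  # wide cells are trimmed in width instead
  gw <- trim_grid(field_grid(1, 1, 500, 100), 0.4)
  expect_equal(gw$W[1, 1], 300)
  expect_equal(gw$H[1, 1], 100)
})

test_that("canopy coverage counts plant pixels per cell", {
  g <- field_grid(1, 1, 10, 10, origin = c(10, 10))
  expect_equal(canopy_coverage(matrix(TRUE, 20, 20), g)[1, 1], 1)
  expect_equal(canopy_coverage(matrix(FALSE, 20, 20), g)[1, 1], 0)

  # a plant rectangle straddling the right half of the cell
  m <- matrix(FALSE, 20, 20)
  m[, 11:20] <- TRUE                    # plants where u >= 10
  expect_equal(canopy_coverage(m, g)[1, 1], 0.5)
  m2 <- matrix(FALSE, 20, 20)
  m2[14:20, 13:20] <- TRUE
  # cell pixels are rows 6:15 x cols 6:15; patch intersects rows 14:15 and
  # cols 13:15 -> 2 * 3 plant pixels of 100
  expect_equal(canopy_coverage(m2, g)[1, 1], 6 / 100)
})

test_that("coverage ANOVA matches the textbook decomposition", {
  g <- field_grid(2, 3, 4, 4, origin = c(4, 4), pitch_u = 8, pitch_v = 8)
  m <- matrix(runif(400) < 0.3, 20, 20)
  same <- coverage_comparison(m, list(a = g, b = g, c = g, d = g))
  expect_equal(same$anova$SS_between, 0)
  expect_equal(same$anova$F, 0)

  # degenerate groups with zero within-variance: unbounded F, p ~ 0
  gin <- field_grid(2, 3, 4, 4, origin = c(4, 4), pitch_u = 6, pitch_v = 6)
  g2 <- transform_grid(gin, "translate", du = 100, dv = 100)  # off-mask: all 0
  m1 <- matrix(TRUE, 20, 20)
  deg <- coverage_comparison(m1, list(on = gin, off = g2))
  expect_true(is.infinite(deg$anova$F))
  expect_equal(deg$anova$p, 0)

  # random 4-group data against a long-hand oracle
  set.seed(63)
  grids <- list(
    truth = g,
    regular = transform_grid(g, "translate", du = 1, dv = 0),
    trimmed = trim_grid(g, 0.5),
    refined = transform_grid(g, "translate", du = 0, dv = 2))
  m3 <- matrix(runif(400) < 0.4, 20, 20)
  rep <- coverage_comparison(m3, grids)
  vals <- unlist(lapply(grids, function(gr) as.numeric(canopy_coverage(m3, gr))))
  grp <- rep(names(grids), each = 6)
  gm <- mean(vals)
  ssb <- sum(tapply(vals, grp, function(v) length(v) * (mean(v) - gm)^2))
  ssw <- sum(unlist(tapply(vals, grp, function(v) (v - mean(v))^2)))
  f_oracle <- (ssb / 3) / (ssw / (24 - 4))
  expect_equal(rep$anova$F, f_oracle, tolerance = 1e-12)
  expect_equal(rep$anova$SS_total, rep$anova$SS_between + rep$anova$SS_within)
  expect_equal(nrow(rep$scatter), 3 * 6)
  expect_error(coverage_comparison(m3, list(a = g)), "at least two")
})
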