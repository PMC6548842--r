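test_that("random displacement draws respect their bounds and center on zero", {
  set.seed(51)
  z <- sample_displacements(3, 4, 0, 0)
  expect_true(all(z$du == 0) && all(z$dv == 0))

  d <- sample_displacements(50, 200, 50, 30)     # 10,000 draws
  expect_lte(max(abs(d$du)), 50)
  expect_lte(max(abs(d$dv)), 30)
  expect_lt(abs(mean(d$du)), 2)
  expect_lt(abs(mean(d$dv)), 2)

  a <- sample_displacements(5, 5, 40, 40, anisotropy = c(0.1, 1))
  expect_lte(max(abs(a$du)), 4)
  expect_equal(a$bound_u, 4)

  set.seed(99); d1 <- sample_displacements(4, 4, 10, 10)
  set.seed(99); d2 <- sample_displacements(4, 4, 10, 10)
  expect_identical(d1, d2)
})

test_that("rendered trials carry a consistent ground truth", {
  spec <- mini_trial_spec(seed = 3)
  sim <- simulate_trial(spec)
  expect_equal(apply_displacements(sim$uniform_grid, sim$truth_displacements),
               sim$truth_grid)
  expect_equal(dim(sim$field$values), dim(sim$image$pixels)[1:2])

  sim2 <- simulate_trial(mini_trial_spec(seed = 3))
  expect_identical(sim2$field$values, sim$field$values)   # seeded determinism

  # vegetation is where the truth says it is: mean index inside truth cells
  # exceeds the outside mean
  inside <- matrix(FALSE, nrow(sim$field$values), ncol(sim$field$values))
  for (p in 1:spec$P) for (q in 1:spec$Q) {
    r <- oracle_cell_rect(sim$truth_grid$u[p, q], sim$truth_grid$v[p, q],
                          sim$truth_grid$W[p, q], sim$truth_grid$H[p, q], 0, 0)
    inside[(r[3] + 1):r[4], (r[1] + 1):r[2]] <- TRUE
  }
  expect_gt(mean(sim$field$values[inside]), mean(sim$field$values[!inside]) + 0.05)
})

test_that("zero emergence draws no plants", {
  sim <- simulate_trial(mini_trial_spec(seed = 4, emergence_rate = 0))
  # nothing in the image differs systematically from soil: at a threshold
  # beyond the soil-noise tail the plant mask is empty
  expect_lt(mean(sim$field$values > 0.25), 1e-3)
})

test_that("plant mass sits at the displaced plot center", {
  # full 0.8 cm/px resolution: at coarser sampling the 5.5 cm plant rows
  # are ~1 px wide and the mask centroid gets too noisy for a 3 px check
  spec <- trial_spec("validation", P = 1L, Q = 1L, seed = 5)
  disp <- displacement_field(matrix(30, 1, 1), matrix(-12, 1, 1))
  sim <- simulate_trial(spec, displacements = disp)
  mask <- sim$field$values > 0.15
  cx <- mean(col(mask)[mask]) - 0.5
  cy <- mean(row(mask)[mask]) - 0.5
  expect_lt(abs(cx - sim$truth_grid$u[1, 1]), 3)
  expect_lt(abs(cy - sim$truth_grid$v[1, 1]), 3)
})

test_that("alignment is rewarded by construction", {
  sim <- simulate_trial(mini_trial_spec(seed = 6), keep_image = FALSE)
  sat <- summed_area_table(sim$field)
  expect_lt(grid_cost(sat, sim$uniform_grid, sim$truth_displacements),
            grid_cost(sat, sim$uniform_grid))
})

test_that("reflected displacement moves plots without creating voids", {
  spec <- mini_trial_spec(seed = 7)
  aligned <- simulate_trial(spec, displacements =
    displacement_field(matrix(0, 2, 3), matrix(0, 2, 3)))
  img <- aligned$image
  g <- aligned$truth_grid

  zero <- displacement_field(matrix(0, 2, 3), matrix(0, 2, 3))
  expect_equal(displace_plots_reflect(img, g, zero, margin = 20)$pixels,
               img$pixels)

  set.seed(71)
  before_plants <- sum(green_red_index(img)$values > 0.15)
  for (i in 1:25) {
    d <- sample_displacements(2, 3, 12, 15)
    out <- displace_plots_reflect(img, g, d, margin = 16)
    expect_false(anyNA(out$pixels))           # no voids, ever
    expect_true(min(out$pixels) >= 0)
  }
  after_plants <- sum(green_red_index(out)$values > 0.15)
  expect_lt(abs(after_plants - before_plants) / before_plants, 0.05)

  big <- displacement_field(matrix(30, 2, 3), matrix(0, 2, 3))
  expect_error(displace_plots_reflect(img, g, big, margin = 10), "margin")
})

test_that("linear displacement leaves a constant-filled void of the right size", {
  spec <- mini_trial_spec(P = 1L, Q = 1L, seed = 8)
  sim <- simulate_trial(spec)
  g <- sim$truth_grid
  zero <- displacement_field(matrix(0, 1, 1), matrix(0, 1, 1))
  expect_equal(displace_plots_linear(sim$image, g, zero)$pixels,
               sim$image$pixels)

  d <- displacement_field(matrix(9, 1, 1), matrix(4, 1, 1))
  out <- displace_plots_linear(sim$image, g, d, fill = 0)
  r <- oracle_cell_rect(g$u[1, 1], g$v[1, 1], g$W[1, 1], g$H[1, 1], 0, 0)
  W <- r[2] - r[1]; H <- r[4] - r[3]
  void <- out$pixels[(r[3] + 1):r[4], (r[1] + 1):r[2], 1] == 0 &
          out$pixels[(r[3] + 1):r[4], (r[1] + 1):r[2], 2] == 0
  expected_void <- W * H - (W - 9) * (H - 4)   # rectangle-overlap arithmetic
  expect_equal(sum(void), expected_void)
})
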