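test_that("uniform grids have the layouts of real trials", {
  g1 <- field_grid(1, 1, 10, 20, origin = c(5, 7))
  expect_equal(c(g1$u[1, 1], g1$v[1, 1]), c(5, 7))

  gv <- field_grid(5, 12, 150, 500, pitch_u = 200, pitch_v = 625)
  expect_equal(length(gv$u), 60)           # validation trial: 60 plots
  gt <- field_grid(48, 12, 37, 625)
  expect_equal(length(gt$u), 576)          # test trial: 576 single-row plots
  # center formula: origin + ((q-1) pitch_u, (p-1) pitch_v)
  expect_equal(gv$u[3, 7], 0 + 6 * 200)
  expect_equal(gv$v[3, 7], 0 + 2 * 625)
  expect_error(field_grid(2, 2, -1, 5), "positive")
})

test_that("grid transforms compose and preserve the layout", {
  g <- field_grid(3, 4, 10, 12, origin = c(20, 30), pitch_u = 15, pitch_v = 18)
  expect_equal(transform_grid(g, "translate", du = 0, dv = 0), g)
  g360 <- transform_grid(g, "rotate", angle_deg = 360)
  expect_equal(grid_polygons(g360), grid_polygons(g), tolerance = 1e-12)

  tab <- transform_grid(transform_grid(g, "translate", du = 3, dv = -2),
                        "translate", du = -1, dv = 7)
  tsum <- transform_grid(g, "translate", du = 2, dv = 5)
  expect_equal(tab$u, tsum$u)
  expect_equal(tab$v, tsum$v)

  gs <- transform_grid(g, "scale", cell_w = 8, cell_h = 40)
  expect_equal(unique(as.numeric(gs$W)), 8)
  expect_equal(gs$u, g$u)                      # centers untouched
  expect_error(transform_grid(g, "scale", cell_w = 0), "positive")

  gm <- transform_grid(g, "shift_margin", pitch_u = 30, pitch_v = 9)
  expect_equal(gm$W, g$W)                      # cell size untouched
  expect_equal(gm$u[1, 1], g$u[1, 1])          # anchored at cell (1,1)
  expect_equal(gm$u[1, 2] - gm$u[1, 1], 30)
  expect_equal(gm$v[2, 1] - gm$v[1, 1], 9)
  # P, Q never change
  expect_equal(dim(gm), c(3L, 4L))
})

test_that("von Neumann neighborhoods have 2-4 members and are symmetric", {
  expect_setequal(asplit(grid_neighbors(1, 1, 5, 12), 1),
                  list(c(p = 2, q = 1), c(p = 1, q = 2)))
  expect_equal(nrow(grid_neighbors(3, 6, 5, 12)), 4)   # internal cell
  expect_equal(nrow(grid_neighbors(1, 1, 1, 1)), 0)    # singleton grid
  expect_error(grid_neighbors(0, 1, 5, 12), "out of range")

  P <- 4; Q <- 5
  sizes <- 0
  for (p in seq_len(P)) for (q in seq_len(Q)) {
    nb <- grid_neighbors(p, q, P, Q)
    sizes <- sizes + nrow(nb)
    for (i in seq_len(nrow(nb))) {
      back <- grid_neighbors(nb[i, 1], nb[i, 2], P, Q)
      expect_true(any(back[, 1] == p & back[, 2] == q))
    }
  }
  # handshake: sum of degrees = 2 * number of grid-graph edges
  expect_equal(sizes, 2 * (P * (Q - 1) + Q * (P - 1)))
})

test_that("displacement fields move centers and invert cleanly", {
  g <- field_grid(2, 3, 10, 10, pitch_u = 12, pitch_v = 12)
  z <- displacement_field(matrix(0, 2, 3), matrix(0, 2, 3))
  expect_equal(apply_displacements(g, z), g)

  d3 <- displacement_field(matrix(3, 2, 3), matrix(0, 2, 3))
  expect_equal(apply_displacements(g, d3)$u, g$u + 3)

  set.seed(5)
  d <- displacement_field(matrix(rnorm(6), 2, 3), matrix(rnorm(6), 2, 3))
  neg <- displacement_field(-d$du, -d$dv)
  expect_equal(apply_displacements(apply_displacements(g, d), neg), g)

  bad <- displacement_field(matrix(0, 3, 3), matrix(0, 3, 3))
  expect_error(apply_displacements(g, bad), "dimensions")
  expect_error(displacement_field(matrix(5, 2, 2), matrix(0, 2, 2),
                                  bound_u = 2, bound_v = 2), "bounds")
})

test_that("grid-frame resampling preserves an unrotated or constant field", {
  f <- scalar_field(matrix(runif(400), 20, 20))
  g <- field_grid(2, 2, 4, 4, origin = c(8, 8), pitch_u = 6, pitch_v = 6)
  expect_identical(resample_to_grid_frame(f, g), f)

  g$rotation_deg <- 17
  fc <- scalar_field(matrix(0.6, 40, 40))
  r <- resample_to_grid_frame(fc, g)
  # interior pixels of a constant field stay constant under rotation
  expect_equal(r$values[15:25, 15:25], matrix(0.6, 11, 11), tolerance = 1e-9)
})
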