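test_that("intra-cell energy sums the field under the displaced cell", {
  sat_u <- summed_area_table(matrix(0.25, 40, 40))
  cell <- list(u = 20, v = 20, W = 6, H = 4)
  expect_equal(intra_cell_energy(sat_u, cell), 0.25 * 6 * 4)
  sat_0 <- summed_area_table(matrix(0, 40, 40))
  for (d in list(c(0, 0), c(3, -5), c(-7.2, 1.9)))
    expect_equal(intra_cell_energy(sat_0, cell, d), 0)

  set.seed(21)
  v <- matrix(runif(400, -1, 1), 20, 20)
  sat <- summed_area_table(v)
  cell <- list(u = 10, v = 9, W = 6, H = 4)
  for (i in 1:5) {
    d <- runif(2, -4, 4)
    r <- oracle_cell_rect(cell$u, cell$v, cell$W, cell$H, d[1], d[2])
    expect_equal(intra_cell_energy(sat, cell, d),
                 oracle_rect_sum(v, r[1], r[2], r[3], r[4]))
  }
})

test_that("overlap regions follow the interval-intersection geometry", {
  a <- list(u = 10, v = 10, W = 4, H = 4)
  same <- overlap_region(a, c(2, -1), a, c(2, -1))
  expect_false(same$empty)
  expect_equal(c(same$x2 - same$x1, same$y2 - same$y1), c(4, 4))

  b <- list(u = 18, v = 10, W = 4, H = 4)    # centers 8 px apart
  expect_true(overlap_region(a, c(0, 0), b, c(0, 0))$empty)

  c2 <- list(u = 12, v = 10, W = 4, H = 4)   # centers 2 px apart
  ov <- overlap_region(a, c(0, 0), c2, c(0, 0))
  expect_equal(c(ov$x2 - ov$x1, ov$y2 - ov$y1), c(2, 4))
})

test_that("inter-cell energy attributes shared mass proportionally", {
  # two horizontally adjacent cells pushed into symmetric overlap on a
  # uniform field: equal intra energies -> each gets half the overlap mass
  v <- matrix(0.5, 30, 40)
  sat <- summed_area_table(v)
  g <- field_grid(1, 2, 8, 8, origin = c(10, 15), pitch_u = 10)
  disp <- displacement_field(matrix(c(2, -2), 1, 2), matrix(0, 1, 2))
  g11 <- inter_cell_energy(sat, g, disp, 1, 1)
  g12 <- inter_cell_energy(sat, g, disp, 1, 2)
  # displaced centers 12 and 18, width 8 -> overlap [14, 16) x H
  overlap_mass <- 0.5 * 2 * 8
  expect_equal(g11, overlap_mass / 2)
  expect_equal(g11 + g12, overlap_mass)

  # no overlap -> zero
  expect_equal(inter_cell_energy(sat, g, zero_displacements(g), 1, 1), 0)
  expect_error(inter_cell_energy(sat, g, disp, 2, 1), "out of range")
})

test_that("net energy and closed-form cost limits hold", {
  expect_equal(net_cell_energy(7, 7, 3, 2), 0)
  expect_equal(net_cell_energy(12, 0, 3, 4), 1)
  expect_equal(net_cell_energy(10, 4, 3, 2), 1)
  expect_error(net_cell_energy(1, 0, 0, 5), "positive")

  # zero field -> cost exp(0) = 1
  g <- field_grid(2, 2, 6, 6, origin = c(10, 10), pitch_u = 10, pitch_v = 10)
  expect_equal(grid_cost(summed_area_table(matrix(0, 40, 40)), g), 1)
  # uniform unit field, non-overlapping interior cells -> exp(-1)
  expect_equal(grid_cost(summed_area_table(matrix(1, 40, 40)), g), exp(-1))
})

test_that("fast paths agree with the brute-force oracle on random instances", {
  set.seed(31)
  for (i in 1:40) {
    inst <- random_instance()
    o <- oracle_energies(inst$vals, inst$grid, inst$disp)
    sat <- summed_area_table(inst$field)
    ce <- cell_energies(sat, inst$grid, inst$disp)
    expect_equal(matrix(ce$d, inst$grid$P, inst$grid$Q), o$d, tolerance = 1e-12)
    expect_equal(matrix(ce$g, inst$grid$P, inst$grid$Q), o$g, tolerance = 1e-12)
    expect_equal(grid_cost(sat, inst$grid, inst$disp), o$cost, tolerance = 1e-12)
    # compiled batch path
    expect_equal(
      as.numeric(plotalign:::grid_cost_batch(sat, inst$grid,
                                             disp_as_matrix(inst$disp))),
      o$cost, tolerance = 1e-12)
    # ablation variant
    o0 <- oracle_energies(inst$vals, inst$grid, inst$disp, intra_only = TRUE)
    expect_equal(grid_cost_intra_only(sat, inst$grid, inst$disp), o0$cost,
                 tolerance = 1e-12)
  }
})

test_that("overlap shares conserve mass and the penalty behaves monotonically", {
  set.seed(32)
  for (i in 1:20) {
    inst <- random_instance(non_negative = TRUE)
    sat <- summed_area_table(inst$field)
    full <- grid_cost(sat, inst$grid, inst$disp)
    intra <- grid_cost_intra_only(sat, inst$grid, inst$disp)
    # removing a non-negative penalty can only lower the cost
    expect_lte(intra, full + 1e-12)
    ce <- cell_energies(sat, inst$grid, inst$disp)
    if (all(ce$g == 0)) expect_equal(intra, full)
  }

  # explicit share conservation for an overlapping pair with unequal intras
  v <- matrix(runif(30 * 40, 0, 1), 30, 40)
  sat <- summed_area_table(v)
  g <- field_grid(1, 2, 8, 8, origin = c(10, 15), pitch_u = 10)
  disp <- displacement_field(matrix(c(3, -1), 1, 2), matrix(c(1, -2), 1, 2))
  ra <- oracle_cell_rect(10, 15, 8, 8, 3, 1)
  rb <- oracle_cell_rect(20, 15, 8, 8, -1, -2)
  mass <- oracle_rect_sum(v, max(ra[1], rb[1]), min(ra[2], rb[2]),
                          max(ra[3], rb[3]), min(ra[4], rb[4]))
  expect_gt(mass, 0)
  expect_equal(inter_cell_energy(sat, g, disp, 1, 1) +
                 inter_cell_energy(sat, g, disp, 1, 2), mass)
})

test_that("energies are equivariant under joint integer translations", {
  set.seed(33)
  v <- matrix(runif(60 * 60, -1, 1), 60, 60)
  g <- field_grid(2, 2, 6, 5, origin = c(20, 20), pitch_u = 8, pitch_v = 7)
  disp <- displacement_field(matrix(runif(4, -2, 2), 2, 2),
                             matrix(runif(4, -2, 2), 2, 2))
  base <- grid_cost(summed_area_table(v), g, disp)
  shift <- c(5, -3)
  # shift the field content by (+5, -3): S2(u, v) = S(u - 5, v + 3)
  v2 <- matrix(0, 60, 60)
  v2[1:(60 - 3), 6:60] <- v[4:60, 1:55]
  g2 <- transform_grid(g, "translate", du = shift[1], dv = shift[2])
  expect_equal(grid_cost(summed_area_table(v2), g2, disp), base)
})

test_that("hard-limited overlap variant only diverges when cells overlap", {
  set.seed(34)
  for (i in 1:10) {
    inst <- random_instance(non_negative = TRUE)
    o_soft <- oracle_energies(inst$vals, inst$grid, inst$disp)
    o_hard <- oracle_energies(inst$vals, inst$grid, inst$disp, hard = TRUE)
    overlapping <- any(o_soft$g != 0)
    if (overlapping) {
      expect_true(is.infinite(o_hard$cost) || o_hard$cost == Inf)
    } else {
      expect_equal(o_hard$cost, o_soft$cost)
    }
  }
})
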