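# End-to-end fits on miniature trials (coarse 4 cm/px resolution keeps these
# fast; the acceptance suite runs the full-scale 0.8 cm/px world).

fit_mini <- function(seed = 1, ...) {
  sim <- simulate_trial(mini_trial_spec(seed = seed), keep_image = FALSE)
  fit <- align_plots(sim$field, sim$uniform_grid,
                     control = pso_control(seed = seed * 7, ...),
                     truth = sim$truth_displacements)
  list(sim = sim, fit = fit)
}

test_that("align_plots recovers a miniature trial and improves on the uniform grid", {
  r <- fit_mini(1)
  expect_s3_class(r$fit, "plot_alignment")
  expect_lt(r$fit$cost, r$fit$uniform_cost)
  expect_true(all(diff(r$fit$cost_trace) <= 0))
  err <- alignment_error(r$sim$truth_displacements, r$fit$displacements,
                         r$sim$field$resolution_cm_per_px)
  expect_lt(err$median,
            success_threshold(r$sim$uniform_grid,
                              r$sim$field$resolution_cm_per_px))
  # feasibility: fitted displacements inside the half-pitch bounds
  expect_lte(max(abs(r$fit$displacements$du)), r$sim$uniform_grid$pitch_u / 2)
  expect_lte(max(abs(r$fit$displacements$dv)), r$sim$uniform_grid$pitch_v / 2)
})

test_that("plot_alignment methods expose the fit coherently", {
  r <- fit_mini(2)
  fit <- r$fit
  cf <- coef(fit)
  expect_equal(dim(cf), c(6L, 2L))
  expect_equal(cf["cell[1,2]", "du"], fit$displacements$du[1, 2])

  refined <- predict(fit)
  expect_equal(refined$u, r$sim$uniform_grid$u + fit$displacements$du)
  other <- field_grid(2, 3, 5, 5, pitch_u = 40, pitch_v = 40)
  expect_equal(predict(fit, other)$u, other$u + fit$displacements$du)

  res <- residuals(fit)
  expect_equal(unname(res[, "du"] + as.vector(t(fit$displacements$du))),
               as.vector(t(r$sim$truth_displacements$du)))

  expect_output(print(fit), "cost")
  expect_output(print(summary(fit)), "median")

  pdf(NULL)
  on.exit(dev.off())
  expect_silent(plot(fit, which = "trace"))
  expect_silent(plot(fit, which = "grid"))
})

test_that("fits are reproducible given a seed", {
  a <- fit_mini(3)
  b <- fit_mini(3)
  expect_identical(coef(a$fit), coef(b$fit))
  expect_identical(a$fit$cost_trace, b$fit$cost_trace)
})

test_that("residuals demand a ground truth", {
  sim <- simulate_trial(mini_trial_spec(seed = 4), keep_image = FALSE)
  fit <- align_plots(sim$field, sim$uniform_grid, control = pso_control(seed = 5))
  expect_error(residuals(fit), "ground-truth")
})
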