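#' Scripted validation studies
#'
#' Re-runs of the validation experiments on synthetic trials at
#' configurable scale: sensitivity to swarm initialization, adaptability
#' across random trials, tolerance and swarm-density sweeps, and the
#' cost-function ablation. Every study is fully reproducible from its seed
#' arguments. Full-scale studies use 50 replicates (the defaults); every
#' function takes reduced counts for quick runs.
#'
#' @name experiments
NULL

# Align one simulated trial and summarise its error in cm.
align_and_score <- function(sim, control, intra_only = FALSE) {
  fit <- align_plots(sim$field, sim$uniform_grid, control = control,
                     truth = sim$truth_displacements, intra_only = intra_only)
  err <- alignment_error(sim$truth_displacements, fit$displacements,
                         sim$field$resolution_cm_per_px)
  list(fit = fit, error = err)
}

#' Initialization robustness study
#'
#' Runs the optimizer repeatedly on one fixed simulated trial, each run
#' with a different random swarm, and counts how many runs reach a
#' successful alignment (median error at most \code{success_cm}).
#'
#' @param sim a \code{\link{simulate_trial}} result (the fixed trial).
#' @param n_runs number of independent swarm initializations.
#' @param seeds one RNG seed per run (default \code{1:n_runs}).
#' @param control a \code{\link{pso_control}}; its seed field is replaced
#'   per run.
#' @param success_cm success threshold in cm; default
#'   \code{\link{success_threshold}} of the trial's grid.
#' @return A data.frame with one row per run (\code{run}, \code{seed},
#'   \code{median_cm}, \code{q1_cm}, \code{q3_cm}, \code{success}), with
#'   the success count in attribute \code{"n_success"}.
#' @export
run_initialization_study <- function(sim, n_runs = 50L, seeds = NULL,
                                     control = pso_control(),
                                     success_cm = NULL) {
  if (is.null(seeds)) seeds <- seq_len(n_runs)
  stopifnot(length(seeds) == n_runs, !anyDuplicated(seeds))
  if (is.null(success_cm))
    success_cm <- success_threshold(sim$uniform_grid,
                                    sim$field$resolution_cm_per_px)
  rows <- lapply(seq_len(n_runs), function(i) {
    control$seed <- seeds[i]
    sc <- align_and_score(sim, control)
    data.frame(run = i, seed = seeds[i], median_cm = sc$error$median,
               q1_cm = sc$error$q1, q3_cm = sc$error$q3,
               success = sc$error$median <= success_cm)
  })
  out <- do.call(rbind, rows)
  attr(out, "n_success") <- sum(out$success)
  attr(out, "success_cm") <- success_cm
  out
}

#' Random trials study
#'
#' Generates independent random misaligned trials from one specification
#' and aligns each, pooling the per-cell errors.
#'
#' @param spec a \code{\link{trial_spec}}.
#' @param n_trials number of independently simulated trials.
#' @param seeds per-trial seeds (drive both the trial simulation and the
#'   swarm); default \code{1:n_trials}.
#' @param control a \code{\link{pso_control}}.
#' @return A data.frame with one row per trial, with the pooled per-cell
#'   errors (cm) in attribute \code{"pooled_errors"}.
#' @export
run_random_trials_study <- function(spec, n_trials = 50L, seeds = NULL,
                                    control = pso_control()) {
  if (is.null(seeds)) seeds <- seq_len(n_trials)
  stopifnot(length(seeds) == n_trials, !anyDuplicated(seeds))
  pooled <- numeric(0)
  rows <- vector("list", n_trials)
  for (i in seq_len(n_trials)) {
    spec$seed <- seeds[i]
    sim <- simulate_trial(spec, keep_image = FALSE)
    control$seed <- seeds[i] + 500000L
    sc <- align_and_score(sim, control)
    pooled <- c(pooled, as.numeric(sc$error$per_cell))
    rows[[i]] <- data.frame(trial = i, seed = seeds[i],
                            median_cm = sc$error$median,
                            q1_cm = sc$error$q1, q3_cm = sc$error$q3,
                            n_outliers = length(sc$error$outliers))
  }
  out <- do.call(rbind, rows)
  attr(out, "pooled_errors") <- pooled
  attr(out, "pooled_median") <- stats::median(pooled)
  out
}

#' Parameter sweeps
#'
#' Error summaries over a grid of optimizer settings x replicate trials:
#' either the stopping tolerance (five orders of magnitude are the
#' interesting range) or the swarm density (particles per coordinate).
#'
#' @param spec a \code{\link{trial_spec}}.
#' @param variable \code{"tolerance"} or \code{"swarm_density"}.
#' @param levels values of the swept variable.
#' @param n_trials replicate trials per level (same trials across levels).
#' @param seeds per-trial seeds.
#' @param control base \code{\link{pso_control}}.
#' @return A data.frame with one row per (level, trial).
#' @export
run_sweep <- function(spec, variable = c("tolerance", "swarm_density"),
                      levels, n_trials = 5L, seeds = NULL,
                      control = pso_control()) {
  variable <- match.arg(variable)
  if (length(levels) == 0L) stop("levels must be non-empty")
  if (is.null(seeds)) seeds <- seq_len(n_trials)
  stopifnot(length(seeds) == n_trials, !anyDuplicated(seeds))
  sims <- lapply(seeds, function(s) {
    spec$seed <- s
    simulate_trial(spec, keep_image = FALSE)
  })
  rows <- list()
  for (lv in levels) {
    for (i in seq_len(n_trials)) {
      ctl <- control
      ctl[[variable]] <- lv
      ctl$seed <- seeds[i] + 500000L
      sc <- align_and_score(sims[[i]], ctl)
      rows[[length(rows) + 1L]] <-
        data.frame(level = lv, trial = i, seed = seeds[i],
                   median_cm = sc$error$median, q1_cm = sc$error$q1,
                   q3_cm = sc$error$q3, iterations = sc$fit$iterations)
    }
  }
  do.call(rbind, rows)
}

# Overlap statistics of a refined grid: total overlap area between
# neighboring displaced cells and the fraction of overlap pixels that are
# vegetated (above the segmentation threshold).
overlap_stats <- function(mask, grid, disp) {
  m <- mask + 0
  sat <- summed_area_table(m)
  x1 <- floor(grid$u + disp$du - grid$W / 2 + 0.5)
  y1 <- floor(grid$v + disp$dv - grid$H / 2 + 0.5)
  x2 <- x1 + floor(grid$W + 0.5); y2 <- y1 + floor(grid$H + 0.5)
  edges <- grid_edges(grid$P, grid$Q)
  area <- 0; veg <- 0
  for (e in seq_len(nrow(edges))) {
    a <- edges[e, 1]; b <- edges[e, 2]
    ox1 <- max(x1[a], x1[b]); ox2 <- min(x2[a], x2[b])
    oy1 <- max(y1[a], y1[b]); oy2 <- min(y2[a], y2[b])
    if (ox1 >= ox2 || oy1 >= oy2) next
    area <- area + (ox2 - ox1) * (oy2 - oy1)
    veg <- veg + rect_sum(sat, ox1, ox2, oy1, oy2)
  }
  list(overlap_px = area, veg_fraction = if (area > 0) veg / area else 0)
}

#' Cost-function ablation
#'
#' The hard scenario for the overlap penalty: alternate pairs of plot rows
#' touch with no gap and each pair couples a vigorous with a weak row, so
#' a purely intra-cell cost drags weak-plot cells onto their greener
#' neighbors. The trial is optimized twice from the same swarm seed, with
#' the full cost and with the intra-only cost, and the paired error
#' distributions and overlap statistics are reported.
#'
#' @param spec a \code{\link{trial_spec}}; \code{row_pairing} is forced on.
#' @param seed RNG seed for the trial and both swarms.
#' @param control a \code{\link{pso_control}}.
#' @return A list: \code{full} and \code{intra_only}, each with
#'   \code{error} (an \code{error_report}) and \code{overlap}
#'   (\code{overlap_px}, \code{veg_fraction}); plus the \code{sim}.
#' @export
run_ablation <- function(spec, seed = 1L, control = pso_control()) {
  if (!isTRUE(spec$row_pairing)) {
    spec$row_pairing <- TRUE
    spec$vigor_layout <- "row_pairs"
    # default hard-scenario contrast: fertilized vs unfertilized rows
    if (identical(spec$vigor_levels, c(1, 0.75)))
      spec$vigor_levels <- c(1, 0.55)
  }
  spec$seed <- seed
  sim <- simulate_trial(spec, keep_image = FALSE)
  mask <- segment_plants(sim$field)
  control$seed <- seed + 700000L
  full <- align_and_score(sim, control, intra_only = FALSE)
  control$seed <- seed + 700000L        # identical swarm for the pair
  intra <- align_and_score(sim, control, intra_only = TRUE)
  list(full = list(error = full$error,
                   overlap = overlap_stats(mask, sim$uniform_grid,
                                           full$fit$displacements)),
       intra_only = list(error = intra$error,
                         overlap = overlap_stats(mask, sim$uniform_grid,
                                                 intra$fit$displacements)),
       sim = sim)
}
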