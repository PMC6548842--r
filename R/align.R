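#' Align a plot grid with the vegetation in an orthomosaic
#'
#' Fits per-cell displacements that move every cell of a coarse uniform
#' grid onto its underlying field plot. The estimator maximises the
#' vegetation-index mass captured inside each cell while penalising overlap
#' between neighboring cells (see \link{energies}), i.e. it minimises
#' \code{grid_cost} over the \code{2*P*Q} bound-constrained displacement
#' coordinates with an adaptive particle swarm (\code{\link{pso_optimize}}).
#' One swarm particle always starts at the unmodified uniform grid.
#'
#' If the grid is rotated relative to the image axes, the field is first
#' resampled into the grid frame (\code{\link{resample_to_grid_frame}}) so
#' all energies stay axis-aligned.
#'
#' @param field a \code{\link{scalar_field}} (vegetation index).
#' @param grid the coarse uniform \code{\link{field_grid}} laid over the
#'   trial.
#' @param bounds displacement bounds \code{c(bound_u, bound_v)} in pixels;
#'   default half the grid pitch in each direction, so a cell cannot jump
#'   to a neighboring plot.
#' @param control a \code{\link{pso_control}}; set \code{control$seed} for a
#'   reproducible fit.
#' @param truth optional ground-truth \code{\link{displacement_field}}
#'   (known for simulated trials); enables \code{residuals()} and the error
#'   summary.
#' @param intra_only drop the overlap penalty (cost-function ablation).
#' @return An object of class \code{plot_alignment} with components
#'   \code{displacements} (the fitted \code{displacement_field}),
#'   \code{refined_grid}, \code{cost}, \code{uniform_cost},
#'   \code{cost_trace}, \code{iterations}, \code{terminated_by} and the
#'   inputs needed by the methods.
#' @seealso \code{\link{alignment_error}}, \code{\link{simulate_trial}}
#' @export
align_plots <- function(field, grid, bounds = NULL, control = pso_control(),
                        truth = NULL, intra_only = FALSE) {
  stopifnot(inherits(field, "scalar_field"), inherits(grid, "field_grid"))
  field <- resample_to_grid_frame(field, grid)
  sat <- summed_area_table(field)
  M <- grid$P * grid$Q
  if (is.null(bounds)) bounds <- c(grid$pitch_u / 2, grid$pitch_v / 2)
  if (length(bounds) == 1L) bounds <- c(bounds, bounds)
  bvec <- c(rep(bounds[1], M), rep(bounds[2], M))
  cost_fn <- function(X) grid_cost_batch(sat, grid, X, intra_only = intra_only)
  uniform_cost <- cost_fn(matrix(0, 2L * M, 1L))
  res <- pso_optimize(cost_fn, n = 2L * M, bounds = bvec, control = control)
  du <- matrix(res$par[seq_len(M)], grid$P, grid$Q)
  dv <- matrix(res$par[M + seq_len(M)], grid$P, grid$Q)
  disp <- displacement_field(du, dv, bound_u = bounds[1], bound_v = bounds[2])
  structure(
    list(displacements = disp,
         grid = grid,
         refined_grid = apply_displacements(grid, disp),
         cost = res$value,
         uniform_cost = uniform_cost,
         cost_trace = res$cost_trace,
         iterations = res$iterations,
         terminated_by = res$terminated_by,
         n_particles = res$n_particles,
         bounds = bounds,
         control = control,
         truth = truth,
         intra_only = intra_only,
         resolution_cm_per_px = field$resolution_cm_per_px),
    class = "plot_alignment")
}

#' @export
print.plot_alignment <- function(x, ...) {
  cat(sprintf("Plot-grid alignment (%d x %d cells)\n", x$grid$P, x$grid$Q))
  cat(sprintf("  cost: %.6f (uniform grid: %.6f), %d iterations (%s)\n",
              x$cost, x$uniform_cost, x$iterations, x$terminated_by))
  cat(sprintf("  displacement bounds: (%g, %g) px; max fitted |d|: (%.1f, %.1f) px\n",
              x$bounds[1], x$bounds[2],
              max(abs(x$displacements$du)), max(abs(x$displacements$dv))))
  if (!is.null(x$truth)) {
    err <- alignment_error(x$truth, x$displacements, x$resolution_cm_per_px)
    cat(sprintf("  median error vs ground truth: %.2f cm\n", err$median))
  }
  invisible(x)
}

#' @export
summary.plot_alignment <- function(object, ...) {
  out <- list(P = object$grid$P, Q = object$grid$Q,
              cost = object$cost, uniform_cost = object$uniform_cost,
              iterations = object$iterations,
              terminated_by = object$terminated_by,
              n_particles = object$n_particles,
              bounds = object$bounds,
              displacement_summary = rbind(
                du = summary(as.vector(object$displacements$du)),
                dv = summary(as.vector(object$displacements$dv))),
              error = if (!is.null(object$truth))
                alignment_error(object$truth, object$displacements,
                                object$resolution_cm_per_px))
  class(out) <- "summary.plot_alignment"
  out
}

#' @export
print.summary.plot_alignment <- function(x, ...) {
  cat(sprintf("Plot-grid alignment, %d x %d cells, %d particles\n",
              x$P, x$Q, x$n_particles))
  cat(sprintf("  cost %.6f after %d iterations (%s); uniform-grid cost %.6f\n",
              x$cost, x$iterations, x$terminated_by, x$uniform_cost))
  cat("  fitted displacements (px):\n")
  print(x$displacement_summary)
  if (!is.null(x$error)) {
    cat(sprintf("  alignment error vs truth: median %.2f cm [IQR %.2f-%.2f]\n",
                x$error$median, x$error$q1, x$error$q3))
  }
  invisible(x)
}

#' @describeIn align_plots fitted per-cell displacements as a
#'   \code{P*Q x 2} matrix (columns \code{du}, \code{dv}, pixels), cells in
#'   row-major order.
#' @param object,x a \code{plot_alignment}.
#' @param ... unused.
#' @export
coef.plot_alignment <- function(object, ...) {
  g <- object$grid
  m <- cbind(du = as.vector(t(object$displacements$du)),
             dv = as.vector(t(object$displacements$dv)))
  rownames(m) <- sprintf("cell[%d,%d]",
                         rep(seq_len(g$P), each = g$Q),
                         rep(seq_len(g$Q), times = g$P))
  m
}

#' @describeIn align_plots the refined grid: the fitted displacements
#'   applied to \code{newdata} (default: the grid the model was fitted on).
#' @param newdata optional \code{field_grid} to displace.
#' @export
predict.plot_alignment <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) return(object$refined_grid)
  apply_displacements(newdata, object$displacements)
}

#' @describeIn align_plots displacement residuals (truth minus fitted, in
#'   pixels) as a \code{P*Q x 2} matrix; requires \code{truth}.
#' @export
residuals.plot_alignment <- function(object, ...) {
  if (is.null(object$truth))
    stop("no ground-truth displacements were supplied to align_plots()")
  g <- object$grid
  m <- cbind(du = as.vector(t(object$truth$du - object$displacements$du)),
             dv = as.vector(t(object$truth$dv - object$displacements$dv)))
  rownames(m) <- sprintf("cell[%d,%d]",
                         rep(seq_len(g$P), each = g$Q),
                         rep(seq_len(g$Q), times = g$P))
  m
}

#' @describeIn align_plots diagnostic plots: the best-cost trace
#'   (\code{which = "trace"}) or the uniform and refined grids drawn over
#'   the field (\code{which = "grid"}).
#' @param which plot type.
#' @param field optional \code{scalar_field} backdrop for
#'   \code{which = "grid"}.
#' @export
plot.plot_alignment <- function(x, which = c("trace", "grid"), field = NULL, ...) {
  which <- match.arg(which)
  if (which == "trace") {
    graphics::plot(seq_along(x$cost_trace), x$cost_trace, type = "l",
                   xlab = "iteration", ylab = "best cost",
                   main = "Swarm best cost", ...)
  } else {
    draw <- function(grid, border) {
      for (poly in grid_polygons(grid))
        graphics::polygon(poly[, 1], poly[, 2], border = border)
    }
    if (!is.null(field)) {
      v <- field$values
      graphics::image(x = seq_len(ncol(v)) - 0.5, y = seq_len(nrow(v)) - 0.5,
                      z = t(v), ylim = c(nrow(v), 0),
                      col = grDevices::hcl.colors(64, "Greens", rev = TRUE),
                      xlab = "u (px)", ylab = "v (px)", useRaster = TRUE, ...)
    } else {
      g <- x$refined_grid
      graphics::plot(NA, xlim = range(g$u) + c(-1, 1) * max(g$W),
                     ylim = rev(range(g$v) + c(-1, 1) * max(g$H)),
                     xlab = "u (px)", ylab = "v (px)", ...)
    }
    draw(x$grid, "blue")
    draw(x$refined_grid, "red")
  }
  invisible(x)
}
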