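#' Alignment error against ground truth
#'
#' Per-cell Euclidean distance between the ground-truth displacement vector
#' and the computed displacement vector, converted to centimetres via the
#' ground resolution. This is the error metric behind all validation
#' studies.
#'
#' @param truth,computed \code{\link{displacement_field}}s of identical
#'   dimensions.
#' @param resolution_cm_per_px centimetres per pixel.
#' @return An object of class \code{error_report}: \code{per_cell} (P x Q
#'   matrix, cm), the \code{\link{boxplot_summary}} statistics, and
#'   \code{units = "cm"}.
#' @export
alignment_error <- function(truth, computed, resolution_cm_per_px = 1) {
  if (!identical(dim(truth$du), dim(computed$du)))
    stop("displacement fields have mismatched dimensions")
  err <- sqrt((truth$du - computed$du)^2 + (truth$dv - computed$dv)^2) *
    resolution_cm_per_px
  out <- c(list(per_cell = err, units = "cm"), boxplot_summary(err))
  class(out) <- "error_report"
  out
}

#' @export
print.error_report <- function(x, ...) {
  cat(sprintf("<error_report> %d cells: median %.2f %s [IQR %.2f-%.2f], %d outliers\n",
              length(x$per_cell), x$median, x$units, x$q1, x$q3,
              length(x$outliers)))
  invisible(x)
}

#' Boxplot summary statistics
#'
#' Median, quartiles, 1.5-IQR whiskers and individually flagged outliers --
#' the convention used to display error distributions. Quartiles are
#' \code{\link[stats]{quantile}} type 7; whiskers reach the most extreme
#' observations within 1.5 IQR of the quartiles.
#'
#' @param x numeric data (vector or matrix), non-empty.
#' @return A list: \code{median}, \code{q1}, \code{q3},
#'   \code{whisker_low}, \code{whisker_high}, \code{outliers}, \code{n}.
#' @export
boxplot_summary <- function(x) {
  v <- as.numeric(x)
  v <- v[!is.na(v)]
  if (length(v) == 0L) stop("cannot summarise an empty sample")
  q <- stats::quantile(v, c(0.25, 0.5, 0.75), names = FALSE)
  iqr <- q[3] - q[1]
  lo <- q[1] - 1.5 * iqr
  hi <- q[3] + 1.5 * iqr
  inside <- v >= lo & v <= hi
  list(median = q[2], q1 = q[1], q3 = q[3],
       whisker_low = min(v[inside]), whisker_high = max(v[inside]),
       outliers = sort(v[!inside]), n = length(v))
}

#' Trim cells to their central portion
#'
#' The common workaround for misaligned uniform grids: every cell's length
#' (its longer, along-plot dimension) is reduced to
#' \code{(1 - trim_fraction)} of itself about the same center; the other
#' dimension is unchanged. A trimmed cell is always contained in the
#' original cell.
#'
#' @param grid a \code{\link{field_grid}}.
#' @param trim_fraction fraction removed, in \[0, 1).
#' @return A new \code{field_grid}.
#' @export
trim_grid <- function(grid, trim_fraction) {
  if (trim_fraction < 0 || trim_fraction >= 1)
    stop("trim_fraction must be in [0, 1)")
  g <- grid
  longer_h <- g$H >= g$W
  g$H[longer_h] <- g$H[longer_h] * (1 - trim_fraction)
  g$W[!longer_h] <- g$W[!longer_h] * (1 - trim_fraction)
  g
}

#' Canopy coverage per cell
#'
#' Fraction of each cell's pixels classified as plant: the count of mask
#' pixels inside the cell's integer rectangle divided by the cell's pixel
#' count. Cells partly outside the mask are clipped (outside pixels count
#' as non-plant).
#'
#' @param mask logical/0-1 plant mask (from \code{\link{segment_plants}}).
#' @param grid a \code{\link{field_grid}} in the mask's frame.
#' @param disp optional \code{\link{displacement_field}} applied to the
#'   grid first.
#' @return P x Q matrix of coverage fractions in \[0, 1\].
#' @export
canopy_coverage <- function(mask, grid, disp = NULL) {
  m <- if (is.logical(mask)) mask + 0 else as.matrix(mask)
  sat <- summed_area_table(m)
  if (is.null(disp)) disp <- zero_displacements(grid)
  counts <- intra_energy_matrix(sat, grid, disp)
  counts / (floor(grid$W + 0.5) * floor(grid$H + 0.5))
}

#' Compare coverage estimates from several grids
#'
#' Computes per-cell canopy coverage for each supplied grid variant
#' (typically regular, trimmed, refined and ground truth), runs a one-way
#' ANOVA across the variants and a Tukey honest-significant-difference
#' multiple comparison at \code{alpha}, and pairs each variant's coverage
#' with the truth grid's for scatter plots.
#'
#' @param mask plant mask (see \code{\link{canopy_coverage}}).
#' @param grids named list of at least two \code{\link{field_grid}}s of
#'   identical P x Q; a grid named \code{"truth"} (if present) is the
#'   reference for the scatter pairs.
#' @param alpha significance level of the multiple comparison.
#' @return An object of class \code{coverage_report}: \code{coverage}
#'   (named list of P x Q matrices), \code{anova} (\code{SS_between},
#'   \code{SS_within}, \code{df}, \code{MS}, \code{F}, \code{p}),
#'   \code{tukey}, \code{pairwise_differences} (pairs differing at
#'   \code{alpha}) and \code{scatter} (data.frame variant/truth/coverage).
#' @export
coverage_comparison <- function(mask, grids, alpha = 0.05) {
  if (length(grids) < 2L) stop("need at least two grids to compare")
  if (is.null(names(grids)) || any(names(grids) == ""))
    stop("grids must be a named list")
  dims <- lapply(grids, dim)
  if (!all(vapply(dims, identical, TRUE, dims[[1L]])))
    stop("all grids must share the same P x Q layout")
  cov <- lapply(grids, function(g) canopy_coverage(mask, g))
  value <- unlist(lapply(cov, as.numeric), use.names = FALSE)
  group <- factor(rep(names(grids), each = length(cov[[1L]])),
                  levels = names(grids))

  k <- nlevels(group); n <- length(value)
  gm <- mean(value)
  means <- tapply(value, group, mean)
  ss_between <- sum(tabulate(group) * (means - gm)^2)
  ss_within <- sum((value - means[group])^2)
  df1 <- k - 1L; df2 <- n - k
  ms_b <- ss_between / df1
  ms_w <- ss_within / df2
  fstat <- if (ms_w == 0) Inf else ms_b / ms_w
  pval <- if (is.infinite(fstat)) 0 else stats::pf(fstat, df1, df2, lower.tail = FALSE)
  anova_tab <- list(SS_between = ss_between, SS_within = ss_within,
                    SS_total = ss_between + ss_within,
                    df = c(between = df1, within = df2),
                    MS = c(between = ms_b, within = ms_w),
                    F = fstat, p = pval)

  tukey <- NULL; pairs_diff <- character(0)
  if (ms_w > 0) {
    fit <- stats::aov(value ~ group)
    tukey <- stats::TukeyHSD(fit, conf.level = 1 - alpha)$group
    pairs_diff <- rownames(tukey)[tukey[, "p adj"] < alpha]
  } else {
    cmb <- utils::combn(levels(group), 2L)
    pairs_diff <- apply(cmb[, means[cmb[1L, ]] != means[cmb[2L, ]], drop = FALSE],
                        2L, paste, collapse = "-")
  }

  scatter <- NULL
  if ("truth" %in% names(grids)) {
    others <- setdiff(names(grids), "truth")
    scatter <- do.call(rbind, lapply(others, function(nm) {
      data.frame(variant = nm,
                 truth = as.numeric(cov[["truth"]]),
                 coverage = as.numeric(cov[[nm]]),
                 stringsAsFactors = FALSE)
    }))
  }
  structure(list(coverage = cov, anova = anova_tab, tukey = tukey,
                 pairwise_differences = pairs_diff, scatter = scatter,
                 alpha = alpha),
            class = "coverage_report")
}

#' @export
print.coverage_report <- function(x, ...) {
  a <- x$anova
  cat(sprintf("<coverage_report> %d grids x %d cells\n",
              length(x$coverage), length(x$coverage[[1L]])))
  cat(sprintf("  one-way ANOVA: F(%d, %d) = %.4g, p = %.3g\n",
              a$df[1], a$df[2], a$F, a$p))
  for (nm in names(x$coverage))
    cat(sprintf("  mean coverage (%s): %.4f\n", nm, mean(x$coverage[[nm]])))
  if (length(x$pairwise_differences))
    cat("  pairs differing at alpha:",
        paste(x$pairwise_differences, collapse = ", "), "\n")
  invisible(x)
}

#' Success threshold for an alignment run
#'
#' A run counts as a successful alignment when its median per-cell error is
#' at most one quarter of the smaller grid pitch; this package-level
#' criterion makes "x of 50 initializations succeeded" reproducible.
#'
#' @param grid a \code{\link{field_grid}}.
#' @param resolution_cm_per_px centimetres per pixel (threshold returned in
#'   cm).
#' @return Threshold in cm.
#' @export
success_threshold <- function(grid, resolution_cm_per_px = 1) {
  0.25 * min(grid$pitch_u, grid$pitch_v) * resolution_cm_per_px
}
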