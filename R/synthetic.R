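#' Synthetic trial specification
#'
#' Describes an emulated aerial orthomosaic of a sown trial: a P x Q layout
#' of rectangular plots, each drawn as parallel plant rows on a soil
#' background at a given ground resolution. Two presets mirror the trials
#' the method targets: \code{"validation"}, a 5 x 12 split-block of
#' 1.2 x 4 m plots with 6 plant rows at 0.2 m spacing, and \code{"test"},
#' a 48 x 12 layout of 0.3 x 5 m single-row plots; both at 0.8 cm/px.
#' Pitches (1.6 and 5.0 m for validation, 0.4 and 6.0 m for test) are
#' typical seeder wheel-track and alley spacings for such plots.
#'
#' @param preset \code{"validation"} or \code{"test"}; any field can be
#'   overridden through \code{...}.
#' @param ... overrides: \code{P}, \code{Q}, \code{plot_w_m},
#'   \code{plot_h_m}, \code{pitch_u_m}, \code{pitch_v_m},
#'   \code{resolution_cm_per_px}, \code{n_plant_rows},
#'   \code{row_spacing_m}, \code{row_halfwidth_m}, \code{emergence_rate}
#'   (probability that a canopy pixel is filled), \code{end_taper_fraction}
#'   (fraction of plot length over which emergence thins toward each plot
#'   end), \code{vigor_levels} (per-plot greenness multipliers, e.g.
#'   fertilized vs unfertilized), \code{vigor_layout} (\code{"random"},
#'   \code{"row_pairs"}, \code{"uniform"}), \code{soil_color},
#'   \code{plant_color} (RGB, 8-bit scale), \code{noise_sd},
#'   \code{displacement_frac} (true-displacement bounds as a fraction of
#'   pitch), \code{row_pairing} (hard scenario: alternate pairs of plot
#'   rows touch with no gap and pair a vigorous with a weak row),
#'   \code{seed}.
#' @return A list of class \code{trial_spec}.
#' @export
trial_spec <- function(preset = c("validation", "test"), ...) {
  preset <- match.arg(preset)
  spec <- list(
    P = 5L, Q = 12L,
    plot_w_m = 1.2, plot_h_m = 4,
    pitch_u_m = 1.6, pitch_v_m = 5,
    resolution_cm_per_px = 0.8,
    n_plant_rows = 6L,
    row_spacing_m = 0.2,
    row_halfwidth_m = 0.055,
    emergence_rate = 0.92,
    end_taper_fraction = 0.12,
    vigor_levels = c(1, 0.75),
    vigor_layout = "random",
    soil_color = c(105, 100, 78),
    plant_color = c(60, 130, 45),
    noise_sd = 8,
    displacement_frac = 0.5,
    row_pairing = FALSE,
    seed = NULL)
  if (preset == "test") {
    spec$P <- 48L; spec$Q <- 12L
    spec$plot_w_m <- 0.3; spec$plot_h_m <- 5
    spec$pitch_u_m <- 0.4; spec$pitch_v_m <- 6
    spec$n_plant_rows <- 1L
    # sowing-track misalignment: lateral error is small (~12 cm), the
    # longitudinal start-of-row error reaches ~1 m
    spec$displacement_frac <- c(0.3, 0.17)
  }
  ov <- list(...)
  unknown <- setdiff(names(ov), names(spec))
  if (length(unknown)) stop("unknown trial_spec fields: ",
                            paste(unknown, collapse = ", "))
  spec[names(ov)] <- ov
  spec$P <- as.integer(spec$P)
  spec$Q <- as.integer(spec$Q)
  stopifnot(spec$P >= 1, spec$Q >= 1, spec$plot_w_m > 0, spec$plot_h_m > 0,
            spec$emergence_rate >= 0, spec$emergence_rate <= 1,
            spec$resolution_cm_per_px > 0)
  if (spec$row_pairing) {
    spec$vigor_layout <- "row_pairs"
    # the hard scenario pairs fertilized with unfertilized rows: a strong
    # greenness contrast is the point of the exercise
    if (!"vigor_levels" %in% names(ov)) spec$vigor_levels <- c(1, 0.55)
  }
  class(spec) <- "trial_spec"
  spec
}

#' @export
print.trial_spec <- function(x, ...) {
  cat(sprintf("<trial_spec> %d x %d plots of %g x %g m at %g cm/px, pitch (%g, %g) m\n",
              x$P, x$Q, x$plot_w_m, x$plot_h_m, x$resolution_cm_per_px,
              x$pitch_u_m, x$pitch_v_m))
  invisible(x)
}

#' Draw a random per-plot displacement field
#'
#' i.i.d. uniform displacements within \code{[-bound_u, bound_u] x
#' [-bound_v, bound_v]} per cell, the "known but random" misalignment used
#' to build validation trials. An anisotropy factor biases the draw toward
#' one direction by scaling the bounds.
#'
#' @param P,Q grid dimensions.
#' @param bound_u,bound_v non-negative displacement bounds in pixels.
#' @param anisotropy length-2 multiplier applied to the bounds.
#' @return A \code{\link{displacement_field}} whose bounds are the
#'   effective (scaled) draw bounds.
#' @export
sample_displacements <- function(P, Q, bound_u, bound_v, anisotropy = c(1, 1)) {
  bu <- bound_u * anisotropy[1]
  bv <- bound_v * anisotropy[2]
  if (bu < 0 || bv < 0) stop("bounds must be non-negative")
  displacement_field(matrix(stats::runif(P * Q, -bu, bu), P, Q),
                     matrix(stats::runif(P * Q, -bv, bv), P, Q),
                     bound_u = bu, bound_v = bv)
}

# Smooth low-frequency noise field (bilinear-upsampled coarse uniform
# noise), used for soil texture.
smooth_noise <- function(V, U, scale = 48, amplitude = 1) {
  nv <- ceiling(V / scale) + 2L
  nu <- ceiling(U / scale) + 2L
  coarse <- matrix(stats::runif(nv * nu, -1, 1), nv, nu)
  gx <- rep(seq_len(U) / scale + 1, each = V)
  gy <- rep(seq_len(V) / scale + 1, times = U)
  amplitude * matrix(bilinear_sample(coarse, gx, gy), V, U)
}

#' Render a synthetic misaligned trial
#'
#' Builds an orthomosaic-like RGB image with known ground truth: a
#' soil-textured background with one plant-row textured rectangle per plot,
#' each plot centered at its displaced position. Plant pixels are Bernoulli
#' draws whose probability follows Gaussian row profiles across the plot
#' width, thinned by the emergence rate and tapered toward the plot ends
#' (seeder rows start and finish thin); per-plot vigor multipliers scale
#' the green channel, emulating fertilized versus unfertilized plots. Only
#' the statistics of the resulting vegetation-index field matter to the
#' alignment algorithm, not photorealism.
#'
#' With \code{spec$row_pairing} the truth displacements are structured so
#' alternate pairs of plot rows touch with no gap (strong misalignment in
#' one direction) and each touching pair has one vigorous and one weak row
#' -- the hard scenario for the overlap-penalty ablation.
#'
#' @param spec a \code{\link{trial_spec}}.
#' @param displacements optional \code{\link{displacement_field}} of true
#'   per-plot displacements; by default drawn uniformly within
#'   \code{displacement_frac} of the pitch (using \code{spec$seed} if set).
#' @param keep_image keep the RGB image in the result (set \code{FALSE} to
#'   save memory when only the index field is needed).
#' @return An object of class \code{trial_simulation}: \code{image}
#'   (\code{\link{rgb_image}} or \code{NULL}), \code{field} (the green-red
#'   index \code{\link{scalar_field}}), \code{uniform_grid},
#'   \code{truth_grid}, \code{truth_displacements}, \code{spec}. The truth
#'   grid always equals the uniform grid displaced by the truth field.
#' @export
simulate_trial <- function(spec, displacements = NULL, keep_image = TRUE) {
  stopifnot(inherits(spec, "trial_spec"))
  if (!is.null(spec$seed)) set.seed(spec$seed)
  m_per_px <- spec$resolution_cm_per_px / 100
  cw <- spec$plot_w_m / m_per_px
  ch <- spec$plot_h_m / m_per_px
  pu <- spec$pitch_u_m / m_per_px
  pv <- spec$pitch_v_m / m_per_px
  origin_u <- cw / 2 + pu / 2 + 2
  origin_v <- ch / 2 + pv / 2 + 2
  U <- as.integer(ceiling(2 * origin_u + (spec$Q - 1) * pu))
  V <- as.integer(ceiling(2 * origin_v + (spec$P - 1) * pv))
  uniform <- field_grid(spec$P, spec$Q, cw, ch, origin = c(origin_u, origin_v),
                        pitch_u = pu, pitch_v = pv)

  if (is.null(displacements)) {
    if (spec$row_pairing) {
      # pairs (1,2), (3,4), ... pushed together until they touch
      shift <- (pv - ch) / 2
      dv_struct <- matrix(ifelse(seq_len(spec$P) %% 2L == 1L, shift, -shift),
                          spec$P, spec$Q)
      jit <- 0.08
      du <- matrix(stats::runif(spec$P * spec$Q, -jit * pu, jit * pu),
                   spec$P, spec$Q)
      dv <- dv_struct + matrix(stats::runif(spec$P * spec$Q, -jit * pv, jit * pv),
                               spec$P, spec$Q)
      displacements <- displacement_field(du, dv,
                                          bound_u = jit * pu,
                                          bound_v = shift + jit * pv)
    } else {
      frac <- rep_len(spec$displacement_frac, 2L)
      displacements <- sample_displacements(spec$P, spec$Q,
                                            frac[1] * pu, frac[2] * pv)
    }
  }
  if (!identical(dim(displacements$du), c(spec$P, spec$Q)))
    stop("displacement field dimensions do not match the trial layout")
  truth <- apply_displacements(uniform, displacements)
  if (cw > pu || ch > pv)
    warning("plots are larger than the pitch; neighbouring plots may touch")

  # soil background: brightness texture common to all channels (the index
  # is a channel ratio, so this stays neutral) plus per-channel speckle
  soil <- spec$soil_color
  bright <- 1 + smooth_noise(V, U, scale = round(40 / spec$resolution_cm_per_px),
                             amplitude = 0.12)
  img <- array(0, dim = c(V, U, 3L))
  for (ch_i in 1:3)
    img[, , ch_i] <- soil[ch_i] * bright +
      matrix(stats::rnorm(V * U, 0, spec$noise_sd), V, U)

  # per-plot vigor multipliers
  vig <- switch(spec$vigor_layout,
    uniform = matrix(spec$vigor_levels[1], spec$P, spec$Q),
    random = matrix(sample(spec$vigor_levels, spec$P * spec$Q, replace = TRUE),
                    spec$P, spec$Q),
    row_pairs = matrix(rep(spec$vigor_levels,
                           length.out = spec$P), spec$P, spec$Q),
    stop("unknown vigor_layout"))

  hw <- spec$row_halfwidth_m / m_per_px
  row_off <- (seq_len(spec$n_plant_rows) -
                (spec$n_plant_rows + 1) / 2) * spec$row_spacing_m / m_per_px
  taper_len <- spec$end_taper_fraction * ch
  plant <- spec$plant_color

  for (p in seq_len(spec$P)) for (q in seq_len(spec$Q)) {
    uc <- truth$u[p, q]; vc <- truth$v[p, q]
    x1 <- max(0L, floor(uc - cw / 2)); x2 <- min(U, ceiling(uc + cw / 2))
    y1 <- max(0L, floor(vc - ch / 2)); y2 <- min(V, ceiling(vc + ch / 2))
    if (x1 >= x2 || y1 >= y2) next
    ub <- (x1 + 1):x2; vb <- (y1 + 1):y2     # 1-based matrix indices
    du_px <- (ub - 0.5) - uc                 # lateral offset from plot center
    dv_px <- (vb - 0.5) - vc
    prof_u <- rep(0, length(du_px))
    for (ro in row_off)
      prof_u <- pmax(prof_u, exp(-((du_px - ro) / hw)^2))
    prof_u[abs(du_px) > cw / 2] <- 0
    edge <- pmin(ch / 2 - dv_px, ch / 2 + dv_px)       # distance to plot end
    taper <- ifelse(edge < 0, 0,
                    0.35 + 0.65 * pmin(1, edge / max(taper_len, 1)))
    pr <- spec$emergence_rate * outer(taper, prof_u)
    mask <- matrix(stats::runif(length(pr)) < pr, nrow(pr), ncol(pr))
    if (!any(mask)) next
    mix <- 0.7 + 0.3 * stats::runif(sum(mask))
    pc <- c(plant[1], plant[2] * vig[p, q], plant[3])
    for (ch_i in 1:3) {
      block <- img[vb, ub, ch_i]
      block[mask] <- (1 - mix) * block[mask] + mix * pc[ch_i]
      img[vb, ub, ch_i] <- block
    }
  }
  img[img < 0] <- 0
  img[img > 255] <- 255

  image <- rgb_image(img, resolution_cm_per_px = spec$resolution_cm_per_px)
  field <- green_red_index(image)
  structure(list(image = if (keep_image) image else NULL,
                 field = field,
                 uniform_grid = uniform,
                 truth_grid = truth,
                 truth_displacements = displacements,
                 spec = spec),
            class = "trial_simulation")
}

#' @export
print.trial_simulation <- function(x, ...) {
  cat(sprintf("<trial_simulation> %d x %d plots, field %d x %d px, max truth |d| = (%.1f, %.1f) px\n",
              x$spec$P, x$spec$Q, ncol(x$field$values), nrow(x$field$values),
              max(abs(x$truth_displacements$du)),
              max(abs(x$truth_displacements$dv))))
  invisible(x)
}

# Mirror-fold a coordinate vector into [lo, hi) (reflective boundary).
reflect_fold <- function(x, lo, hi) {
  n <- hi - lo
  if (n <= 0) return(rep(lo, length(x)))
  y <- (x - lo) %% (2 * n)
  ifelse(y < n, y, 2 * n - 1 - y) + lo
}

#' Simulate misalignment by reflected region displacement
#'
#' Moves each plot of an existing mosaic to a displaced position by
#' remapping an enlarged region around the plot: region content is
#' translated by the plot's displacement, and pixels whose source would
#' fall outside the region are filled by mirror reflection of the region's
#' own content. The result contains no voids, and seams fall in the
#' low-texture soil margin around each plot.
#'
#' @param image an \code{\link{rgb_image}}.
#' @param grid the \code{\link{field_grid}} of original plot positions.
#' @param displacements a \code{\link{displacement_field}} (rounded to
#'   whole pixels).
#' @param margin margin in pixels added around each cell to form the
#'   remapped region; must be at least the largest displacement magnitude.
#' @return A new \code{rgb_image} of identical dimensions.
#' @export
displace_plots_reflect <- function(image, grid, displacements, margin) {
  stopifnot(inherits(image, "rgb_image"))
  maxd <- max(abs(displacements$du), abs(displacements$dv))
  if (margin < maxd)
    stop(sprintf("margin (%g px) smaller than the largest displacement (%g px)",
                 margin, maxd))
  px <- image$pixels
  V <- dim(px)[1]; U <- dim(px)[2]
  for (p in seq_len(grid$P)) for (q in seq_len(grid$Q)) {
    du <- round(displacements$du[p, q]); dv <- round(displacements$dv[p, q])
    if (du == 0 && dv == 0) next
    uc <- grid$u[p, q]; vc <- grid$v[p, q]
    x1 <- max(0, floor(uc - grid$W[p, q] / 2 - margin))
    x2 <- min(U, ceiling(uc + grid$W[p, q] / 2 + margin))
    y1 <- max(0, floor(vc - grid$H[p, q] / 2 - margin))
    y2 <- min(V, ceiling(vc + grid$H[p, q] / 2 + margin))
    if (x1 >= x2 || y1 >= y2) next
    tx <- (x1 + 1):x2; ty <- (y1 + 1):y2
    sx <- reflect_fold(tx - du, x1 + 1, x2 + 1)
    sy <- reflect_fold(ty - dv, y1 + 1, y2 + 1)
    px[ty, tx, ] <- px[sy, sx, , drop = FALSE]
  }
  rgb_image(px, resolution_cm_per_px = image$resolution_cm_per_px,
            geotransform = image$geotransform)
}

#' Simulate misalignment by naive cut-and-paste
#'
#' The contrast case to \code{\link{displace_plots_reflect}}: each plot
#' rectangle is cut out, pasted at the displaced position, and the vacated
#' area is filled with a constant, leaving visible voids at the original
#' plot positions.
#'
#' @inheritParams displace_plots_reflect
#' @param fill RGB constant (length 1 or 3) for vacated pixels.
#' @return A new \code{rgb_image}.
#' @export
displace_plots_linear <- function(image, grid, displacements, fill = 0) {
  stopifnot(inherits(image, "rgb_image"))
  px <- image$pixels
  V <- dim(px)[1]; U <- dim(px)[2]
  fill <- rep_len(fill, 3L)
  for (p in seq_len(grid$P)) for (q in seq_len(grid$Q)) {
    du <- round(displacements$du[p, q]); dv <- round(displacements$dv[p, q])
    if (du == 0 && dv == 0) next
    r <- cell_pixel_rect(grid$u[p, q], grid$v[p, q],
                         grid$W[p, q], grid$H[p, q])
    x1 <- max(0, r["x1"]); x2 <- min(U, r["x2"])
    y1 <- max(0, r["y1"]); y2 <- min(V, r["y2"])
    if (x1 >= x2 || y1 >= y2) next
    src <- px[(y1 + 1):y2, (x1 + 1):x2, , drop = FALSE]
    # blank the original rectangle
    for (ch_i in 1:3) px[(y1 + 1):y2, (x1 + 1):x2, ch_i] <- fill[ch_i]
    # paste at the displaced position, clipped to the image
    nx1 <- x1 + du; nx2 <- x2 + du; ny1 <- y1 + dv; ny2 <- y2 + dv
    cx1 <- max(0, nx1); cx2 <- min(U, nx2)
    cy1 <- max(0, ny1); cy2 <- min(V, ny2)
    if (cx1 >= cx2 || cy1 >= cy2) next
    px[(cy1 + 1):cy2, (cx1 + 1):cx2, ] <-
      src[(cy1 - ny1 + 1):(cy2 - ny1), (cx1 - nx1 + 1):(cx2 - nx1), , drop = FALSE]
  }
  rgb_image(px, resolution_cm_per_px = image$resolution_cm_per_px,
            geotransform = image$geotransform)
}
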