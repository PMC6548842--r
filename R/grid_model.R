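#' Uniform plot grids
#'
#' A \code{field_grid} is a P x Q lattice of fixed-size rectangular cells,
#' one per field plot. Cell centers are stored in the grid frame in pixel
#' units; a nonzero \code{rotation_deg} relates the grid frame to the image
#' axes by a rotation about the grid centroid. Cell (p, q) of a fresh
#' uniform grid is centered at \code{origin + ((q-1)*pitch_u, (p-1)*pitch_v)}.
#'
#' @param P,Q number of rows (ranges) and columns of plots, each >= 1.
#' @param cell_w,cell_h cell width and height in pixels (> 0).
#' @param origin center of cell (1, 1) in pixels, \code{c(u, v)}.
#' @param pitch_u,pitch_v nominal center-to-center spacing in pixels;
#'   default: the cell dimensions (cells touch).
#' @param rotation_deg grid-frame rotation relative to the image axes,
#'   degrees counter-clockwise about the grid centroid.
#' @param labeling plot sequence used for \code{plot_id}: \code{"row_major"}
#'   (default) or \code{"serpentine"} (alternate rows reversed).
#' @return An object of class \code{field_grid}.
#' @export
field_grid <- function(P, Q, cell_w, cell_h, origin = c(0, 0),
                       pitch_u = cell_w, pitch_v = cell_h,
                       rotation_deg = 0,
                       labeling = c("row_major", "serpentine")) {
  labeling <- match.arg(labeling)
  if (P < 1 || Q < 1) stop("P and Q must be >= 1")
  if (cell_w <= 0 || cell_h <= 0) stop("cell dimensions must be positive")
  if (pitch_u < 0 || pitch_v < 0) stop("pitch must be non-negative")
  P <- as.integer(P); Q <- as.integer(Q)
  u <- outer(rep(1, P), origin[1] + (seq_len(Q) - 1) * pitch_u)
  v <- outer(origin[2] + (seq_len(P) - 1) * pitch_v, rep(1, Q))
  ids <- matrix(NA_integer_, P, Q)
  for (p in seq_len(P)) {
    cols <- if (labeling == "serpentine" && p %% 2L == 0L) rev(seq_len(Q)) else seq_len(Q)
    ids[p, cols] <- (p - 1L) * Q + seq_len(Q)
  }
  structure(
    list(P = P, Q = Q,
         u = u, v = v,
         W = matrix(cell_w, P, Q), H = matrix(cell_h, P, Q),
         pitch_u = pitch_u, pitch_v = pitch_v,
         rotation_deg = rotation_deg,
         plot_id = ids),
    class = "field_grid")
}

#' @export
print.field_grid <- function(x, ...) {
  cat(sprintf(
    "<field_grid> %d x %d cells (%g x %g px), pitch (%g, %g) px, rotation %g deg\n",
    x$P, x$Q, x$W[1, 1], x$H[1, 1], x$pitch_u, x$pitch_v, x$rotation_deg))
  invisible(x)
}

#' @export
dim.field_grid <- function(x) c(x$P, x$Q)

#' Extract one cell of a grid
#'
#' @param grid a \code{\link{field_grid}}.
#' @param p,q 1-based row and column indices.
#' @return A list with the cell center \code{u}, \code{v}, size \code{W},
#'   \code{H}, indices and \code{plot_id}.
#' @export
grid_cell <- function(grid, p, q) {
  if (p < 1 || p > grid$P || q < 1 || q > grid$Q)
    stop("cell index out of range")
  list(p = p, q = q, u = grid$u[p, q], v = grid$v[p, q],
       W = grid$W[p, q], H = grid$H[p, q], plot_id = grid$plot_id[p, q])
}

#' Geometric grid transforms
#'
#' The four interactive placement operations used to lay a grid over an
#' orthomosaic, composable in any order and as many times as necessary:
#' \describe{
#'   \item{translate}{displace the whole grid by \code{c(du, dv)} pixels.}
#'   \item{rotate}{orient the grid at an angle; adds \code{angle_deg} to the
#'     grid rotation (about the grid centroid).}
#'   \item{scale}{resize all cells to \code{cell_w} x \code{cell_h} pixels,
#'     centers unchanged.}
#'   \item{shift_margin}{change the pitch to \code{pitch_u}/\code{pitch_v},
#'     rescaling center spacing about cell (1, 1) without changing cell
#'     sizes (removes or widens alleyways).}
#' }
#'
#' @param grid a \code{\link{field_grid}}.
#' @param op one of \code{"translate"}, \code{"rotate"}, \code{"scale"},
#'   \code{"shift_margin"}.
#' @param ... parameters of the operation (see Details above).
#' @return A new \code{field_grid}; P and Q never change.
#' @export
transform_grid <- function(grid, op = c("translate", "rotate", "scale", "shift_margin"),
                           ...) {
  op <- match.arg(op)
  prm <- list(...)
  g <- grid
  switch(op,
    translate = {
      d <- if (!is.null(prm$by)) prm$by else c(prm$du %||% 0, prm$dv %||% 0)
      g$u <- g$u + d[1]
      g$v <- g$v + d[2]
    },
    rotate = {
      g$rotation_deg <- g$rotation_deg + (prm$angle_deg %||% 0)
    },
    scale = {
      w <- prm$cell_w %||% g$W[1, 1]
      h <- prm$cell_h %||% g$H[1, 1]
      if (w <= 0 || h <= 0) stop("cannot scale cells to non-positive size")
      g$W[] <- w
      g$H[] <- h
    },
    shift_margin = {
      pu <- prm$pitch_u %||% g$pitch_u
      pv <- prm$pitch_v %||% g$pitch_v
      if (pu < 0 || pv < 0) stop("pitch must be non-negative")
      su <- if (g$pitch_u > 0) pu / g$pitch_u else 1
      sv <- if (g$pitch_v > 0) pv / g$pitch_v else 1
      g$u <- g$u[1, 1] + (g$u - g$u[1, 1]) * su
      g$v <- g$v[1, 1] + (g$v - g$v[1, 1]) * sv
      g$pitch_u <- pu
      g$pitch_v <- pv
    })
  g
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Von Neumann neighborhood of a grid cell
#'
#' The up/down/left/right lattice neighbors of cell (p, q); a cell has 2, 3
#' or 4 neighbors depending on whether it is a corner, side or internal
#' cell.
#'
#' @param p,q 1-based cell indices.
#' @param P,Q grid dimensions.
#' @return Integer matrix with columns \code{p}, \code{q}, one row per
#'   neighbor (possibly zero rows for a 1 x 1 grid).
#' @export
grid_neighbors <- function(p, q, P, Q) {
  if (p < 1 || p > P || q < 1 || q > Q) stop("cell index out of range")
  cand <- rbind(c(p - 1, q), c(p, q - 1), c(p + 1, q), c(p, q + 1))
  keep <- cand[, 1] >= 1 & cand[, 1] <= P & cand[, 2] >= 1 & cand[, 2] <= Q
  m <- cand[keep, , drop = FALSE]
  colnames(m) <- c("p", "q")
  m
}

# All undirected neighbor pairs (edges of the grid graph), as a matrix of
# 0-based column-major cell indices; used by the batch cost evaluator.
grid_edges <- function(P, Q) {
  a <- integer(0); b <- integer(0)
  idx <- function(p, q) (q - 1L) * P + p  # 1-based column-major
  if (P > 1) {
    for (q in seq_len(Q)) {
      a <- c(a, idx(seq_len(P - 1L), q))
      b <- c(b, idx(seq_len(P - 1L) + 1L, q))
    }
  }
  if (Q > 1) {
    for (q in seq_len(Q - 1L)) {
      a <- c(a, idx(seq_len(P), q))
      b <- c(b, idx(seq_len(P), q + 1L))
    }
  }
  cbind(a = a, b = b)
}

#' Per-cell displacement fields
#'
#' Holds one 2D displacement vector per grid cell, with component-wise
#' bounds: \code{|du| <= bound_u} and \code{|dv| <= bound_v} everywhere.
#'
#' @param du,dv numeric P x Q matrices of displacements in pixels.
#' @param bound_u,bound_v non-negative bounds on the displacement
#'   components.
#' @return An object of class \code{displacement_field}.
#' @export
displacement_field <- function(du, dv, bound_u = Inf, bound_v = Inf) {
  du <- as.matrix(du); dv <- as.matrix(dv)
  if (!identical(dim(du), dim(dv)))
    stop("du and dv must have identical dimensions")
  if (bound_u < 0 || bound_v < 0) stop("bounds must be non-negative")
  if (any(abs(du) > bound_u + 1e-9) || any(abs(dv) > bound_v + 1e-9))
    stop("displacements exceed the stated bounds")
  structure(list(du = du, dv = dv, bound_u = bound_u, bound_v = bound_v),
            class = "displacement_field")
}

#' @export
print.displacement_field <- function(x, ...) {
  cat(sprintf(
    "<displacement_field> %d x %d, bounds (%g, %g) px, max |d| = (%g, %g)\n",
    nrow(x$du), ncol(x$du), x$bound_u, x$bound_v,
    max(abs(x$du)), max(abs(x$dv))))
  invisible(x)
}

# Zero displacement field matching a grid.
zero_displacements <- function(grid, bound_u = Inf, bound_v = Inf) {
  displacement_field(matrix(0, grid$P, grid$Q), matrix(0, grid$P, grid$Q),
                     bound_u, bound_v)
}

#' Apply a displacement field to a grid
#'
#' Moves every cell center by its per-cell displacement; cell sizes, pitch
#' and rotation are unchanged.
#'
#' @param grid a \code{\link{field_grid}}.
#' @param disp a \code{\link{displacement_field}} of matching dimensions.
#' @return A new \code{field_grid}.
#' @export
apply_displacements <- function(grid, disp) {
  stopifnot(inherits(grid, "field_grid"), inherits(disp, "displacement_field"))
  if (!identical(dim(disp$du), c(grid$P, grid$Q)))
    stop("displacement field dimensions do not match the grid")
  g <- grid
  g$u <- g$u + disp$du
  g$v <- g$v + disp$dv
  g
}

# Map grid-frame coordinates to image-frame coordinates (rotation about the
# grid centroid). x, y are vectors.
grid_to_image_frame <- function(grid, x, y) {
  if (grid$rotation_deg == 0) return(cbind(x = x, y = y))
  th <- grid$rotation_deg * pi / 180
  cx <- mean(grid$u); cy <- mean(grid$v)
  cbind(x = cx + cos(th) * (x - cx) - sin(th) * (y - cy),
        y = cy + sin(th) * (x - cx) + cos(th) * (y - cy))
}

#' Cell corner polygons
#'
#' Corner coordinates of every cell, mapped from the grid frame to the image
#' frame when the grid is rotated. Used for shapefile export and plotting.
#'
#' @param grid a \code{\link{field_grid}}.
#' @return A list of 4 x 2 corner matrices (counter-clockwise, unclosed) in
#'   row-major cell order.
#' @export
grid_polygons <- function(grid) {
  out <- vector("list", grid$P * grid$Q)
  k <- 1L
  for (p in seq_len(grid$P)) {
    for (q in seq_len(grid$Q)) {
      u <- grid$u[p, q]; v <- grid$v[p, q]
      w2 <- grid$W[p, q] / 2; h2 <- grid$H[p, q] / 2
      cx <- c(u - w2, u + w2, u + w2, u - w2)
      cy <- c(v - h2, v - h2, v + h2, v + h2)
      out[[k]] <- grid_to_image_frame(grid, cx, cy)
      k <- k + 1L
    }
  }
  out
}

#' Resample a scalar field into the grid frame
#'
#' When the grid is rotated relative to the image axes, the field is
#' resampled once by inverse rotation with bilinear interpolation so that
#' all energies can use axis-aligned rectangles in the grid frame. Pixels
#' sampled from outside the source field are 0 (neutral).
#'
#' @param field a \code{\link{scalar_field}}.
#' @param grid a \code{\link{field_grid}}; only its rotation and centroid
#'   are used.
#' @return A \code{scalar_field} of the same dimensions in the grid frame
#'   (the input itself when \code{rotation_deg == 0}).
#' @export
resample_to_grid_frame <- function(field, grid) {
  if (grid$rotation_deg == 0) return(field)
  vals <- field$values
  V <- nrow(vals); U <- ncol(vals)
  # target pixel centers (grid frame) -> source position (image frame)
  gx <- rep(seq_len(U) - 0.5, each = V)
  gy <- rep(seq_len(V) - 0.5, times = U)
  src <- grid_to_image_frame(grid, gx, gy)
  out <- bilinear_sample(vals, src[, 1], src[, 2])
  scalar_field(matrix(out, V, U),
               resolution_cm_per_px = field$resolution_cm_per_px,
               geotransform = field$geotransform)
}

# Bilinear interpolation at continuous pixel positions (x right, y down,
# pixel centers at half-integers); outside the raster -> 0.
bilinear_sample <- function(vals, x, y) {
  V <- nrow(vals); U <- ncol(vals)
  fx <- x - 0.5; fy <- y - 0.5
  x0 <- floor(fx); y0 <- floor(fy)
  tx <- fx - x0; ty <- fy - y0
  at <- function(xx, yy) {
    ok <- xx >= 0 & xx <= U - 1 & yy >= 0 & yy <= V - 1
    r <- numeric(length(xx))
    r[ok] <- vals[cbind(yy[ok] + 1, xx[ok] + 1)]
    r
  }
  (1 - tx) * (1 - ty) * at(x0, y0) +
    tx * (1 - ty) * at(x0 + 1, y0) +
    (1 - tx) * ty * at(x0, y0 + 1) +
    tx * ty * at(x0 + 1, y0 + 1)
}
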