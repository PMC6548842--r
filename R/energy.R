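#' Cell energies on a vegetation-index field
#'
#' The alignment cost is built from two competing energies. The intra-cell
#' energy \code{d_pq} is the vegetation-index mass accumulated inside a
#' displaced cell, rewarding cells that cover canopy. The inter-cell energy
#' \code{g_pq} is the index mass inside a cell's overlap with its von
#' Neumann neighbors, attributed to the pair in proportion to their
#' intra-cell energies, penalising cells that pile onto the same plot. The
#' net energy per unit area is \code{f_pq = (d_pq - g_pq) / (W * H)} and the
#' grid cost is \code{exp(-mean(f_pq))}, so lower cost means better
#' alignment and the exponential keeps the cost positive and numerically
#' tame.
#'
#' Displaced cell rectangles are discretised to the integer pixel lattice:
#' the left edge is \code{floor(u + du - W/2 + 0.5)} and the rectangle spans
#' exactly \code{round(W) x round(H)} pixels, so a cell always contributes
#' the same number of samples regardless of its sub-pixel position.
#' Portions outside the field contribute 0 (cells may hang over the mosaic
#' border).
#'
#' @name energies
NULL

# Integer pixel rectangle [x1, x2) x [y1, y2) of a displaced cell.
# Half-away-from-zero rounding, identical to the compiled path.
cell_pixel_rect <- function(u, v, W, H, du = 0, dv = 0) {
  x1 <- floor(u + du - W / 2 + 0.5)
  y1 <- floor(v + dv - H / 2 + 0.5)
  c(x1 = x1, x2 = x1 + floor(W + 0.5), y1 = y1, y2 = y1 + floor(H + 0.5))
}

#' Intra-cell energy
#'
#' Sum of the scalar field over the W x H pixel rectangle of a cell
#' displaced by \code{delta}; the level of vegetation inside the cell at
#' that position.
#'
#' @param sat a \code{\link{summed_area_table}} of the field.
#' @param cell a cell as returned by \code{\link{grid_cell}} (or any list
#'   with \code{u}, \code{v}, \code{W}, \code{H}).
#' @param delta displacement \code{c(du, dv)} in pixels.
#' @return Scalar energy (field units x pixels^2).
#' @export
intra_cell_energy <- function(sat, cell, delta = c(0, 0)) {
  r <- cell_pixel_rect(cell$u, cell$v, cell$W, cell$H, delta[1], delta[2])
  rect_sum(sat, r["x1"], r["x2"], r["y1"], r["y2"])
}

#' Overlap region of two displaced cells
#'
#' Axis-aligned intersection of two displaced cell rectangles in continuous
#' coordinates: the left/top edges are the maxima of the displaced cell
#' edges and the right/bottom edges the minima; the region is empty when
#' either interval is degenerate or inverted.
#'
#' @param cell_a,cell_b cells (lists with \code{u}, \code{v}, \code{W},
#'   \code{H}).
#' @param delta_a,delta_b displacements \code{c(du, dv)}.
#' @return A list \code{x1, y1, x2, y2, empty}.
#' @export
overlap_region <- function(cell_a, delta_a, cell_b, delta_b) {
  x1 <- max(cell_a$u + delta_a[1] - cell_a$W / 2,
            cell_b$u + delta_b[1] - cell_b$W / 2)
  y1 <- max(cell_a$v + delta_a[2] - cell_a$H / 2,
            cell_b$v + delta_b[2] - cell_b$H / 2)
  x2 <- min(cell_a$u + delta_a[1] + cell_a$W / 2,
            cell_b$u + delta_b[1] + cell_b$W / 2)
  y2 <- min(cell_a$v + delta_a[2] + cell_a$H / 2,
            cell_b$v + delta_b[2] + cell_b$H / 2)
  list(x1 = x1, y1 = y1, x2 = x2, y2 = y2, empty = (x1 >= x2 || y1 >= y2))
}

#' Inter-cell energy of one cell
#'
#' Overlap penalty of cell (p, q): for every von Neumann neighbor whose
#' displaced rectangle overlaps this cell's, the field mass in the overlap
#' is attributed with coefficient \code{d_neighbor / (d_cell + d_neighbor)},
#' so the two members of a pair always split the pair's overlap mass
#' exactly. Non-overlapping neighbors contribute 0, and a pair whose
#' intra-cell energies sum to exactly 0 (both cells over index-free ground)
#' contributes 0.
#'
#' @param sat a \code{\link{summed_area_table}}.
#' @param grid a \code{\link{field_grid}}.
#' @param disp a \code{\link{displacement_field}}.
#' @param p,q 1-based cell indices.
#' @param intra optional P x Q matrix of intra-cell energies at \code{disp}
#'   (computed if missing).
#' @return Scalar inter-cell energy.
#' @export
inter_cell_energy <- function(sat, grid, disp, p, q, intra = NULL) {
  if (p < 1 || p > grid$P || q < 1 || q > grid$Q)
    stop("cell index out of range")
  if (is.null(intra)) intra <- intra_energy_matrix(sat, grid, disp)
  nb <- grid_neighbors(p, q, grid$P, grid$Q)
  if (nrow(nb) == 0L) return(0)
  ra <- cell_pixel_rect(grid$u[p, q], grid$v[p, q], grid$W[p, q], grid$H[p, q],
                        disp$du[p, q], disp$dv[p, q])
  g <- 0
  for (i in seq_len(nrow(nb))) {
    pp <- nb[i, 1]; qq <- nb[i, 2]
    rb <- cell_pixel_rect(grid$u[pp, qq], grid$v[pp, qq],
                          grid$W[pp, qq], grid$H[pp, qq],
                          disp$du[pp, qq], disp$dv[pp, qq])
    x1 <- max(ra["x1"], rb["x1"]); x2 <- min(ra["x2"], rb["x2"])
    y1 <- max(ra["y1"], rb["y1"]); y2 <- min(ra["y2"], rb["y2"])
    if (x1 >= x2 || y1 >= y2) next
    den <- intra[p, q] + intra[pp, qq]
    if (den == 0) next
    g <- g + intra[pp, qq] / den * rect_sum(sat, x1, x2, y1, y2)
  }
  g
}

# P x Q matrix of intra-cell energies at the given displacements
# (vectorised over cells).
intra_energy_matrix <- function(sat, grid, disp) {
  x1 <- floor(grid$u + disp$du - grid$W / 2 + 0.5)
  y1 <- floor(grid$v + disp$dv - grid$H / 2 + 0.5)
  d <- rect_sum(sat, x1, x1 + floor(grid$W + 0.5), y1, y1 + floor(grid$H + 0.5))
  matrix(d, grid$P, grid$Q)
}

#' Net cell energy
#'
#' Intra-cell minus inter-cell energy, normalised by the cell area:
#' \code{f = (d - g) / (W * H)}.
#'
#' @param d,g intra- and inter-cell energies.
#' @param W,H cell dimensions in pixels.
#' @return Net energy per unit area.
#' @export
net_cell_energy <- function(d, g, W, H) {
  if (any(W * H <= 0)) stop("cell area must be positive")
  (d - g) / (W * H)
}

#' Per-cell energy table
#'
#' Intra, inter and net energies of every cell at the given displacements;
#' the per-cell breakdown behind \code{\link{grid_cost}}, useful for
#' debugging and for the cost-function ablation.
#'
#' @inheritParams inter_cell_energy
#' @param intra_only force all inter-cell energies to 0.
#' @return A data.frame with columns \code{p}, \code{q}, \code{d}, \code{g},
#'   \code{f}.
#' @export
cell_energies <- function(sat, grid, disp = NULL, intra_only = FALSE) {
  if (is.null(disp)) disp <- zero_displacements(grid)
  intra <- intra_energy_matrix(sat, grid, disp)
  g <- matrix(0, grid$P, grid$Q)
  if (!intra_only) {
    for (p in seq_len(grid$P))
      for (q in seq_len(grid$Q))
        g[p, q] <- inter_cell_energy(sat, grid, disp, p, q, intra = intra)
  }
  f <- net_cell_energy(intra, g, grid$W, grid$H)
  data.frame(p = rep(seq_len(grid$P), times = grid$Q),
             q = rep(seq_len(grid$Q), each = grid$P),
             d = as.vector(intra), g = as.vector(g), f = as.vector(f))
}

#' Grid alignment cost
#'
#' The scalar objective minimised by the optimizer:
#' \code{f = exp(-(1/(P*Q)) * sum(f_pq))}, the exponential of the negated
#' mean net cell energy. Always positive; lower is better; equals 1 on a
#' zero field and \code{exp(-1)} for non-overlapping interior cells on a
#' unit field.
#'
#' @inheritParams cell_energies
#' @return Scalar cost.
#' @export
grid_cost <- function(sat, grid, disp = NULL, intra_only = FALSE) {
  ce <- cell_energies(sat, grid, disp, intra_only = intra_only)
  exp(-mean(ce$f))
}

#' @rdname grid_cost
#' @details \code{grid_cost_intra_only} is the ablation variant with all
#'   inter-cell energies forced to 0 (no overlap penalty); on non-negative
#'   fields it is never larger than the full cost.
#' @export
grid_cost_intra_only <- function(sat, grid, disp = NULL) {
  grid_cost(sat, grid, disp, intra_only = TRUE)
}

# Batch cost over a swarm: X is an N x K matrix of flattened displacement
# fields (du for all cells column-major, then dv). Compiled hot path.
grid_cost_batch <- function(sat, grid, X, intra_only = FALSE) {
  edges <- grid_edges(grid$P, grid$Q)
  cost_batch_cpp(sat$cumulative,
                 as.numeric(grid$u), as.numeric(grid$v),
                 as.numeric(grid$W), as.numeric(grid$H),
                 edges - 1L, X, isTRUE(intra_only))
}
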