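# Independent brute-force implementations of the cell energies and the grid
# cost: straight nested loops over pixels and neighbor pairs, no summed-area
# tables. These are the reference against which the package's fast paths are
# checked, and deliberately share no code with them.

oracle_rect_sum <- function(vals, x1, x2, y1, y2) {
  V <- nrow(vals); U <- ncol(vals)
  x1 <- max(0, x1); y1 <- max(0, y1)
  x2 <- min(U, x2); y2 <- min(V, y2)
  if (x1 >= x2 || y1 >= y2) return(0)
  s <- 0
  for (y in (y1 + 1):y2) for (x in (x1 + 1):x2) s <- s + vals[y, x]
  s
}

oracle_cell_rect <- function(u, v, W, H, du, dv) {
  x1 <- floor(u + du - W / 2 + 0.5)
  y1 <- floor(v + dv - H / 2 + 0.5)
  c(x1, x1 + floor(W + 0.5), y1, y1 + floor(H + 0.5))
}

# Per-cell d, g, f and the grid cost, evaluated term by term.
# hard = TRUE applies the infinite-penalty overlap variant (any overlap of a
# pair makes both members' g infinite).
oracle_energies <- function(vals, grid, disp, intra_only = FALSE, hard = FALSE) {
  P <- grid$P; Q <- grid$Q
  d <- matrix(0, P, Q); g <- matrix(0, P, Q)
  rects <- array(0, c(P, Q, 4))
  for (p in seq_len(P)) for (q in seq_len(Q)) {
    r <- oracle_cell_rect(grid$u[p, q], grid$v[p, q], grid$W[p, q],
                          grid$H[p, q], disp$du[p, q], disp$dv[p, q])
    rects[p, q, ] <- r
    d[p, q] <- oracle_rect_sum(vals, r[1], r[2], r[3], r[4])
  }
  if (!intra_only) {
    for (p in seq_len(P)) for (q in seq_len(Q)) {
      for (nb in list(c(p - 1, q), c(p, q - 1), c(p + 1, q), c(p, q + 1))) {
        pp <- nb[1]; qq <- nb[2]
        if (pp < 1 || pp > P || qq < 1 || qq > Q) next
        x1 <- max(rects[p, q, 1], rects[pp, qq, 1])
        x2 <- min(rects[p, q, 2], rects[pp, qq, 2])
        y1 <- max(rects[p, q, 3], rects[pp, qq, 3])
        y2 <- min(rects[p, q, 4], rects[pp, qq, 4])
        if (x1 >= x2 || y1 >= y2) next
        if (hard) { g[p, q] <- Inf; next }
        den <- d[p, q] + d[pp, qq]
        if (den == 0) next
        g[p, q] <- g[p, q] +
          d[pp, qq] / den * oracle_rect_sum(vals, x1, x2, y1, y2)
      }
    }
  }
  f <- (d - g) / (grid$W * grid$H)
  list(d = d, g = g, f = f, cost = exp(-mean(f)))
}

# Random small energy instance: field up to 50 x 50, grid up to 3 x 3,
# random cell sizes, pitches and in-bound displacements.
random_instance <- function(non_negative = FALSE) {
  U <- sample(20:50, 1); V <- sample(20:50, 1)
  lo <- if (non_negative) 0 else -1
  vals <- matrix(stats::runif(U * V, lo, 1), V, U)
  P <- sample(1:3, 1); Q <- sample(1:3, 1)
  W <- sample(3:8, 1); H <- sample(3:8, 1)
  pu <- W + sample(0:4, 1); pv <- H + sample(0:4, 1)
  grid <- field_grid(P, Q, W, H, origin = c(5 + W / 2, 5 + H / 2),
                     pitch_u = pu, pitch_v = pv)
  b <- sample(2:6, 1)
  disp <- displacement_field(matrix(stats::runif(P * Q, -b, b), P, Q),
                             matrix(stats::runif(P * Q, -b, b), P, Q), b, b)
  list(vals = vals, field = scalar_field(vals), grid = grid, disp = disp)
}

# Small, cheap synthetic trial for fast end-to-end tests (coarse ground
# resolution so images stay tiny; not the acceptance-scale world).
mini_trial_spec <- function(P = 2L, Q = 3L, seed = 1L, ...) {
  trial_spec("validation", P = P, Q = Q, resolution_cm_per_px = 4,
             seed = seed, ...)
}

disp_as_matrix <- function(disp) {
  matrix(c(as.numeric(disp$du), as.numeric(disp$dv)), ncol = 1)
}
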