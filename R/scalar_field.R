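#' Scalar vegetation-index fields
#'
#' A scalar field is the per-pixel vegetation index layer on which all grid
#' energies are computed. Values lie in \[-1, 1\]; high values mark green
#' canopy, low values soil. The field keeps the image raster convention:
#' a matrix with one row per image row, so element \code{[v + 1, u + 1]} is
#' pixel \code{(u, v)} with \code{u} the 0-based column (x) and \code{v} the
#' 0-based row (y).
#'
#' @param values numeric matrix of index values in \[-1, 1\].
#' @param resolution_cm_per_px ground sampling distance in centimetres per
#'   pixel (positive scalar), used to convert alignment errors and cell sizes
#'   between pixels and physical units.
#' @param geotransform optional length-6 affine vector
#'   \code{c(x0, dx, rx, y0, ry, dy)} mapping pixel \code{(u, v)} to world
#'   coordinates \code{(x0 + dx*u + rx*v, y0 + ry*u + dy*v)}.
#' @return An object of class \code{scalar_field}.
#' @export
scalar_field <- function(values, resolution_cm_per_px = 1, geotransform = NULL) {
  values <- as.matrix(values)
  if (length(values) == 0L)
    stop("scalar field must be non-empty")
  if (!is.numeric(values))
    stop("scalar field values must be numeric")
  if (!is.numeric(resolution_cm_per_px) || length(resolution_cm_per_px) != 1L ||
      resolution_cm_per_px <= 0)
    stop("resolution_cm_per_px must be a positive scalar")
  structure(
    list(values = values,
         resolution_cm_per_px = resolution_cm_per_px,
         geotransform = geotransform),
    class = "scalar_field")
}

#' @export
print.scalar_field <- function(x, ...) {
  cat(sprintf("<scalar_field> %d x %d px (%.3g cm/px), range [%.3f, %.3f]\n",
              ncol(x$values), nrow(x$values), x$resolution_cm_per_px,
              min(x$values), max(x$values)))
  invisible(x)
}

#' @export
dim.scalar_field <- function(x) dim(x$values)

#' Green-red difference vegetation index
#'
#' Computes the per-pixel index \code{S = (G - R) / (G + R)} from the red and
#' green channels of an RGB image. The ratio form makes the index invariant
#' to uniform channel scaling, so 8-bit, 16-bit or \[0, 1\] pixel values all
#' give the same field. Pixels with \code{G + R == 0} (pure black or pure
#' blue, typically the nodata border of an orthomosaic) map to 0, a neutral
#' value that neither attracts nor repels grid cells; pixels flagged by an
#' alpha/nodata mask are likewise set to 0.
#'
#' @param image an \code{rgb_image} (see \code{\link{rgb_image}}) or a plain
#'   numeric array with three channels along the third dimension.
#' @param nodata_mask optional logical matrix, \code{TRUE} where the mosaic
#'   has no data; those pixels are set to 0.
#' @return A \code{\link{scalar_field}} with values in \[-1, 1\].
#' @export
green_red_index <- function(image, nodata_mask = NULL) {
  res <- 1
  geo <- NULL
  if (inherits(image, "rgb_image")) {
    res <- image$resolution_cm_per_px
    geo <- image$geotransform
    if (is.null(nodata_mask)) nodata_mask <- image$nodata_mask
    image <- image$pixels
  }
  if (length(dim(image)) != 3L || dim(image)[3L] < 3L)
    stop("green_red_index() needs a 3-channel RGB image")
  d <- dim(image)
  r <- matrix(image[, , 1L], d[1L], d[2L])
  g <- matrix(image[, , 2L], d[1L], d[2L])
  if (any(r < 0) || any(g < 0))
    stop("channel intensities must be non-negative")
  den <- g + r
  s <- matrix(0, d[1L], d[2L])
  ok <- den > 0
  s[ok] <- (g[ok] - r[ok]) / den[ok]
  if (!is.null(nodata_mask)) s[nodata_mask] <- 0
  scalar_field(s, resolution_cm_per_px = res, geotransform = geo)
}

#' Summed-area table of a scalar field
#'
#' Prefix-sum table allowing any axis-aligned integer-rectangle sum over the
#' field to be recovered in O(1) with four lookups (\code{\link{rect_sum}}).
#' The table is (V+1) x (U+1) with a zero first row and column.
#'
#' @param field a \code{\link{scalar_field}} or numeric matrix.
#' @return An object of class \code{summed_area_table}.
#' @export
summed_area_table <- function(field) {
  v <- if (inherits(field, "scalar_field")) field$values else as.matrix(field)
  if (length(v) == 0L) stop("cannot build a summed-area table of an empty field")
  nr <- nrow(v); nc <- ncol(v)
  cum <- matrix(0, nr + 1L, nc + 1L)
  cs <- v
  if (nr > 1L) cs <- apply(cs, 2L, cumsum)
  if (nc > 1L) cs <- t(apply(matrix(cs, nr, nc), 1L, cumsum))
  cum[-1L, -1L] <- cs
  structure(list(cumulative = cum, U = nc, V = nr), class = "summed_area_table")
}

#' @export
print.summed_area_table <- function(x, ...) {
  cat(sprintf("<summed_area_table> over a %d x %d px field\n", x$U, x$V))
  invisible(x)
}

#' Rectangle sums in O(1)
#'
#' Sum of field values over the half-open pixel rectangle
#' \code{[x1, x2) x [y1, y2)} (0-based, x = column, y = row). Rectangles are
#' clipped to the field bounds; an empty or fully outside rectangle sums
#' to 0. All four coordinate arguments are vectorised and recycled.
#'
#' @param sat a \code{\link{summed_area_table}}.
#' @param x1,x2,y1,y2 integer rectangle bounds (vectors allowed).
#' @return Numeric vector of rectangle sums.
#' @export
rect_sum <- function(sat, x1, x2, y1, y2) {
  stopifnot(inherits(sat, "summed_area_table"))
  n <- max(length(x1), length(x2), length(y1), length(y2))
  x1 <- pmin(pmax(rep_len(as.numeric(x1), n), 0), sat$U)
  x2 <- pmin(pmax(rep_len(as.numeric(x2), n), 0), sat$U)
  y1 <- pmin(pmax(rep_len(as.numeric(y1), n), 0), sat$V)
  y2 <- pmin(pmax(rep_len(as.numeric(y2), n), 0), sat$V)
  bad <- x1 >= x2 | y1 >= y2
  x2[bad] <- x1[bad]
  y2[bad] <- y1[bad]
  cum <- sat$cumulative
  nr <- sat$V + 1L
  # linear indexing into the (V+1) x (U+1) table
  at <- function(y, x) cum[y + x * nr + 1]
  at(y2, x2) - at(y1, x2) - at(y2, x1) + at(y1, x1)
}

#' Otsu threshold of a scalar field
#'
#' Maximises the between-class variance of the value histogram; used as the
#' reproducible default for plant/soil segmentation where a threshold is not
#' supplied.
#'
#' @param values numeric vector or matrix of index values.
#' @param n_bins number of histogram bins.
#' @return The threshold (bin upper edge) as a scalar.
#' @export
otsu_threshold <- function(values, n_bins = 256L) {
  v <- as.numeric(values)
  v <- v[is.finite(v)]
  rng <- range(v)
  if (diff(rng) == 0) return(rng[1L])
  breaks <- seq(rng[1L], rng[2L], length.out = n_bins + 1L)
  h <- tabulate(findInterval(v, breaks, rightmost.closed = TRUE), n_bins)
  p <- h / sum(h)
  mids <- (breaks[-1L] + breaks[-(n_bins + 1L)]) / 2
  w0 <- cumsum(p)
  mu <- cumsum(p * mids)
  mu_t <- mu[n_bins]
  w1 <- 1 - w0
  ok <- w0 > 0 & w1 > 0
  sigma_b <- rep(-Inf, n_bins)
  sigma_b[ok] <- (mu_t * w0[ok] - mu[ok])^2 / (w0[ok] * w1[ok])
  breaks[which.max(sigma_b) + 1L]
}

#' Segment plant pixels
#'
#' Thresholds the vegetation-index field into a binary plant mask:
#' \code{mask(u, v) = 1} iff \code{S(u, v) > threshold} (strict). With
#' \code{threshold = "auto"} the threshold is chosen by Otsu's criterion on
#' the index histogram, a reproducible stand-in for a visually tuned value.
#'
#' @param field a \code{\link{scalar_field}}.
#' @param threshold numeric in \[-1, 1\], or \code{"auto"}.
#' @return A logical matrix of the field's dimensions, with the threshold
#'   used attached as attribute \code{"threshold"}.
#' @export
segment_plants <- function(field, threshold = "auto") {
  v <- if (inherits(field, "scalar_field")) field$values else as.matrix(field)
  if (identical(threshold, "auto")) {
    threshold <- otsu_threshold(v)
  } else {
    if (!is.numeric(threshold) || length(threshold) != 1L ||
        threshold < -1 || threshold > 1)
      stop("threshold must be a scalar in [-1, 1] or \"auto\"")
  }
  structure(v > threshold, threshold = threshold)
}
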