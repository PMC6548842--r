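#' Export and import grids as ESRI shapefiles
#'
#' Writes one closed rectangular polygon per grid cell (corners mapped
#' through the grid rotation, and through the affine geotransform when one
#' is supplied) together with a \code{.shx} index and a \code{.dbf}
#' attribute table carrying the \code{ROW}, \code{COL} and \code{PLOT_ID}
#' of every cell, for use in external GIS software. Without a geotransform
#' coordinates are pixels; polygon vertices survive a write/read round trip
#' to well below 1e-6 px.
#'
#' The codec is deliberately minimal (polygon type 5, one ring per record,
#' dBase III attributes) because no shapefile library ships with this R
#' installation.
#'
#' @param grid a \code{\link{field_grid}}.
#' @param path path to the \code{.shp} file (extension optional); the
#'   \code{.shx} and \code{.dbf} siblings are written alongside.
#' @param geotransform optional length-6 affine \code{c(x0, dx, rx, y0,
#'   ry, dy)} applied to pixel coordinates before writing.
#' @return \code{write_grid_shapefile} returns \code{path} invisibly;
#'   \code{read_grid_shapefile} returns a \code{field_grid}.
#' @export
write_grid_shapefile <- function(grid, path, geotransform = NULL) {
  stopifnot(inherits(grid, "field_grid"))
  base <- sub("\\.shp$", "", path, ignore.case = TRUE)
  polys <- grid_polygons(grid)
  if (!is.null(geotransform)) {
    polys <- lapply(polys, function(m) {
      cbind(x = geotransform[1] + geotransform[2] * m[, 1] + geotransform[3] * m[, 2],
            y = geotransform[4] + geotransform[5] * m[, 1] + geotransform[6] * m[, 2])
    })
  }
  rings <- lapply(polys, function(m) rbind(m, m[1L, , drop = FALSE]))  # close
  n <- length(rings)
  allx <- unlist(lapply(rings, function(m) m[, 1]))
  ally <- unlist(lapply(rings, function(m) m[, 2]))
  bbox <- c(min(allx), min(ally), max(allx), max(ally))

  content_words <- 64L                    # fixed: 5-point single-ring polygon
  shp_len_words <- 50L + n * (4L + content_words)

  wshp <- file(paste0(base, ".shp"), "wb")
  wshx <- file(paste0(base, ".shx"), "wb")
  on.exit({ close(wshp); close(wshx) }, add = TRUE)
  header <- function(con, len_words) {
    writeBin(9994L, con, size = 4L, endian = "big")
    writeBin(integer(5L), con, size = 4L, endian = "big")
    writeBin(as.integer(len_words), con, size = 4L, endian = "big")
    writeBin(1000L, con, size = 4L, endian = "little")
    writeBin(5L, con, size = 4L, endian = "little")
    writeBin(c(bbox, 0, 0, 0, 0), con, size = 8L, endian = "little")
  }
  header(wshp, shp_len_words)
  header(wshx, 50L + n * 4L)

  offset_words <- 50L
  for (i in seq_len(n)) {
    m <- rings[[i]]
    writeBin(as.integer(offset_words), wshx, size = 4L, endian = "big")
    writeBin(content_words, wshx, size = 4L, endian = "big")
    writeBin(i, wshp, size = 4L, endian = "big")
    writeBin(content_words, wshp, size = 4L, endian = "big")
    writeBin(5L, wshp, size = 4L, endian = "little")
    writeBin(c(min(m[, 1]), min(m[, 2]), max(m[, 1]), max(m[, 2])),
             wshp, size = 8L, endian = "little")
    writeBin(c(1L, nrow(m)), wshp, size = 4L, endian = "little")
    writeBin(0L, wshp, size = 4L, endian = "little")
    writeBin(as.numeric(t(m)), wshp, size = 8L, endian = "little")
    offset_words <- offset_words + 4L + content_words
  }

  rows <- rep(seq_len(grid$P), each = grid$Q)
  cols <- rep(seq_len(grid$Q), times = grid$P)
  ids <- as.character(t(grid$plot_id))
  write_dbf(paste0(base, ".dbf"),
            data.frame(ROW = rows, COL = cols, PLOT_ID = ids,
                       stringsAsFactors = FALSE))
  invisible(path)
}

#' @rdname write_grid_shapefile
#' @export
read_grid_shapefile <- function(path, geotransform = NULL) {
  base <- sub("\\.shp$", "", path, ignore.case = TRUE)
  con <- file(paste0(base, ".shp"), "rb")
  on.exit(close(con), add = TRUE)
  if (readBin(con, "integer", 1L, 4L, endian = "big") != 9994L)
    stop("not a shapefile")
  seek(con, 24L)
  len_words <- readBin(con, "integer", 1L, 4L, endian = "big")
  seek(con, 100L)
  polys <- list()
  while (seek(con) < 2L * len_words) {
    readBin(con, "integer", 1L, 4L, endian = "big")            # record number
    readBin(con, "integer", 1L, 4L, endian = "big")            # content length
    type <- readBin(con, "integer", 1L, 4L, endian = "little")
    if (type != 5L) stop("only polygon shapefiles are supported")
    readBin(con, "numeric", 4L, 8L, endian = "little")         # box
    np <- readBin(con, "integer", 2L, 4L, endian = "little")   # parts, points
    readBin(con, "integer", np[1L], 4L, endian = "little")     # part offsets
    pts <- matrix(readBin(con, "numeric", 2L * np[2L], 8L, endian = "little"),
                  ncol = 2L, byrow = TRUE)
    polys[[length(polys) + 1L]] <- pts
  }
  attrs <- read_dbf(paste0(base, ".dbf"))
  if (nrow(attrs) != length(polys))
    stop("attribute table does not match shapefile records")

  if (!is.null(geotransform)) {
    a <- geotransform
    det <- a[2] * a[6] - a[3] * a[5]
    polys <- lapply(polys, function(m) {
      x <- m[, 1] - a[1]; y <- m[, 2] - a[4]
      cbind((a[6] * x - a[3] * y) / det, (-a[5] * x + a[2] * y) / det)
    })
  }

  P <- max(attrs$ROW); Q <- max(attrs$COL)
  u_img <- matrix(NA_real_, P, Q); v_img <- matrix(NA_real_, P, Q)
  W <- matrix(NA_real_, P, Q); H <- matrix(NA_real_, P, Q)
  ids <- matrix(NA_character_, P, Q)
  rot <- NA_real_
  for (i in seq_along(polys)) {
    m <- polys[[i]][1:4, , drop = FALSE]
    p <- attrs$ROW[i]; q <- attrs$COL[i]
    u_img[p, q] <- mean(m[, 1]); v_img[p, q] <- mean(m[, 2])
    W[p, q] <- sqrt(sum((m[2L, ] - m[1L, ])^2))
    H[p, q] <- sqrt(sum((m[3L, ] - m[2L, ])^2))
    if (is.na(rot))
      rot <- atan2(m[2L, 2] - m[1L, 2], m[2L, 1] - m[1L, 1]) * 180 / pi
  }
  # undo the grid rotation about the centroid to recover grid-frame centers
  if (abs(rot) > 1e-12) {
    th <- -rot * pi / 180
    cx <- mean(u_img); cy <- mean(v_img)
    u_g <- cx + cos(th) * (u_img - cx) - sin(th) * (v_img - cy)
    v_g <- cy + sin(th) * (u_img - cx) + cos(th) * (v_img - cy)
  } else {
    u_g <- u_img; v_g <- v_img
  }
  pitch_u <- if (Q > 1) mean(diff(t(u_g)[, 1])) else 0
  pitch_v <- if (P > 1) mean(diff(v_g[, 1])) else 0
  g <- field_grid(P, Q, cell_w = mean(W), cell_h = mean(H),
                  pitch_u = abs(pitch_u), pitch_v = abs(pitch_v),
                  rotation_deg = rot)
  g$u <- u_g; g$v <- v_g; g$W <- W; g$H <- H
  for (i in seq_along(polys)) ids[attrs$ROW[i], attrs$COL[i]] <- attrs$PLOT_ID[i]
  g$plot_id <- ids
  g
}

## ---- minimal dBase III codec ----------------------------------------------

write_dbf <- function(path, df) {
  con <- file(path, "wb")
  on.exit(close(con))
  n <- nrow(df)
  types <- vapply(df, function(col) if (is.numeric(col)) "N" else "C", "")
  widths <- ifelse(types == "N", 10L,
                   pmax(1L, vapply(df, function(col) max(nchar(as.character(col))), 1L)))
  header_size <- 32L + 32L * ncol(df) + 1L
  record_size <- 1L + sum(widths)
  writeBin(as.raw(c(0x03, 126, 1, 1)), con)             # version + date stamp
  writeBin(as.integer(n), con, size = 4L, endian = "little")
  writeBin(as.integer(c(header_size, record_size)), con, size = 2L,
           endian = "little")
  writeBin(raw(20L), con)
  for (j in seq_along(df)) {
    nm <- charToRaw(substr(names(df)[j], 1L, 10L))
    writeBin(c(nm, raw(11L - length(nm))), con)
    writeBin(charToRaw(types[j]), con)
    writeBin(raw(4L), con)
    writeBin(as.raw(c(widths[j], 0L)), con)
    writeBin(raw(14L), con)
  }
  writeBin(as.raw(0x0D), con)
  fmtd <- mapply(function(col, w, ty) {
    s <- as.character(col)
    if (ty == "N") formatC(s, width = w) else formatC(s, width = w, flag = "-")
  }, df, widths, types, SIMPLIFY = FALSE)
  for (i in seq_len(n)) {
    writeBin(charToRaw(" "), con)
    for (j in seq_along(df))
      writeBin(charToRaw(substr(fmtd[[j]][i], 1L, widths[j])), con)
  }
  writeBin(as.raw(0x1A), con)
  invisible(path)
}

read_dbf <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  readBin(con, "raw", 4L)
  n <- readBin(con, "integer", 1L, 4L, endian = "little")
  hs <- readBin(con, "integer", 1L, 2L, endian = "little")
  rs <- readBin(con, "integer", 1L, 2L, endian = "little")
  readBin(con, "raw", 20L)
  n_fields <- (hs - 33L) %/% 32L
  names <- character(n_fields); types <- character(n_fields)
  widths <- integer(n_fields)
  for (j in seq_len(n_fields)) {
    nm <- readBin(con, "raw", 11L)
    names[j] <- rawToChar(nm[nm != as.raw(0)])
    types[j] <- rawToChar(readBin(con, "raw", 1L))
    readBin(con, "raw", 4L)
    widths[j] <- as.integer(readBin(con, "raw", 1L))
    readBin(con, "raw", 15L)
  }
  seek(con, hs)
  out <- vector("list", n_fields)
  for (j in seq_len(n_fields)) out[[j]] <- character(n)
  for (i in seq_len(n)) {
    readBin(con, "raw", 1L)                 # deletion flag
    for (j in seq_len(n_fields))
      out[[j]][i] <- rawToChar(readBin(con, "raw", widths[j]))
  }
  for (j in seq_len(n_fields)) {
    out[[j]] <- trimws(out[[j]])
    if (types[j] == "N") out[[j]] <- as.numeric(out[[j]])
  }
  names(out) <- names
  as.data.frame(out, stringsAsFactors = FALSE)
}
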