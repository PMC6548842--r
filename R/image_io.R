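#' RGB orthomosaic images
#'
#' In-memory container for an orthomosaic: a V x U x 3 array of
#' non-negative channel intensities (8- or 16-bit scale), the ground
#' resolution, an optional affine geotransform and an optional nodata mask
#' (from the alpha band of a GeoTIFF).
#'
#' @param pixels numeric V x U x 3 array (rows = image rows).
#' @param resolution_cm_per_px positive scalar, centimetres per pixel.
#' @param geotransform optional length-6 affine vector
#'   \code{c(x0, dx, rx, y0, ry, dy)}; see \code{\link{scalar_field}}.
#' @param nodata_mask optional logical matrix, \code{TRUE} where the mosaic
#'   has no data.
#' @return An object of class \code{rgb_image}.
#' @export
rgb_image <- function(pixels, resolution_cm_per_px = 1, geotransform = NULL,
                      nodata_mask = NULL) {
  d <- dim(pixels)
  if (length(d) != 3L || d[3L] < 3L)
    stop("pixels must be a V x U x 3 array")
  if (d[1L] < 1L || d[2L] < 1L) stop("image must be non-empty")
  if (min(pixels) < 0) stop("channel intensities must be non-negative")
  if (resolution_cm_per_px <= 0) stop("resolution_cm_per_px must be positive")
  structure(list(pixels = pixels,
                 resolution_cm_per_px = resolution_cm_per_px,
                 geotransform = geotransform,
                 nodata_mask = nodata_mask),
            class = "rgb_image")
}

#' @export
print.rgb_image <- function(x, ...) {
  d <- dim(x$pixels)
  cat(sprintf("<rgb_image> %d x %d px, %d channels (%.3g cm/px)%s\n",
              d[2], d[1], d[3], x$resolution_cm_per_px,
              if (!is.null(x$geotransform)) ", georeferenced" else ""))
  invisible(x)
}

#' @export
dim.rgb_image <- function(x) dim(x$pixels)

#' Read an orthomosaic image
#'
#' Reads a TIFF/GeoTIFF (uncompressed baseline; geotransform and alpha
#' nodata honored when present), PNG or JPEG into an
#' \code{\link{rgb_image}}. PNG/JPEG values are rescaled to the 8-bit
#' range. For GeoTIFFs with a pixel-scale tag in metres the resolution is
#' derived from the geotransform.
#'
#' @param path file path; format chosen by extension.
#' @param resolution_cm_per_px ground resolution; overrides/replaces any
#'   value derived from the file.
#' @return An \code{\link{rgb_image}}.
#' @export
read_orthomosaic <- function(path, resolution_cm_per_px = NULL) {
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("tif", "tiff")) {
    t <- read_tiff(path)
    if (length(dim(t$data)) == 2L)
      stop("single-band TIFF: use read_field_tiff() for precomputed index fields")
    px <- t$data[, , 1:3, drop = FALSE]
    nodata <- NULL
    if (dim(t$data)[3L] >= 4L) nodata <- t$data[, , 4L] == 0
    res <- resolution_cm_per_px
    if (is.null(res)) {
      res <- if (!is.null(t$geotransform)) abs(t$geotransform[2]) * 100 else 1
    }
    rgb_image(px, resolution_cm_per_px = res, geotransform = t$geotransform,
              nodata_mask = nodata)
  } else if (ext == "png" || ext %in% c("jpg", "jpeg")) {
    arr <- if (ext == "png") png::readPNG(path) else jpeg::readJPEG(path)
    if (length(dim(arr)) == 2L) stop("grayscale image: 3 channels required")
    nodata <- NULL
    if (dim(arr)[3L] >= 4L) nodata <- arr[, , 4L] == 0
    rgb_image(arr[, , 1:3, drop = FALSE] * 255,
              resolution_cm_per_px = resolution_cm_per_px %||% 1,
              nodata_mask = nodata)
  } else {
    stop("unsupported image format: ", ext)
  }
}

#' Read and write single-band index fields as TIFF
#'
#' A \code{\link{scalar_field}} can be written as a 32-bit float single-band
#' (Geo)TIFF for inspection in GIS software, and any externally computed
#' single-band vegetation index (e.g. an NDVI raster) can be read back in
#' its place.
#'
#' @param path file path.
#' @param field a \code{scalar_field}.
#' @param resolution_cm_per_px resolution override when reading.
#' @return \code{read_field_tiff} returns a \code{scalar_field};
#'   \code{write_field_tiff} returns \code{path} invisibly.
#' @export
read_field_tiff <- function(path, resolution_cm_per_px = NULL) {
  t <- read_tiff(path)
  vals <- if (length(dim(t$data)) == 3L) t$data[, , 1L] else t$data
  res <- resolution_cm_per_px
  if (is.null(res))
    res <- if (!is.null(t$geotransform)) abs(t$geotransform[2]) * 100 else 1
  scalar_field(vals, resolution_cm_per_px = res, geotransform = t$geotransform)
}

#' @rdname read_field_tiff
#' @export
write_field_tiff <- function(field, path) {
  stopifnot(inherits(field, "scalar_field"))
  write_tiff(path, field$values, sample_format = "float",
             geotransform = field$geotransform)
  invisible(path)
}

#' @rdname read_field_tiff
#' @param image an \code{\link{rgb_image}} to write as an 8-bit RGB TIFF.
#' @export
write_image_tiff <- function(image, path) {
  stopifnot(inherits(image, "rgb_image"))
  write_tiff(path, image$pixels, sample_format = "uint8",
             geotransform = image$geotransform)
  invisible(path)
}

## ---- minimal baseline TIFF codec -------------------------------------------
## Uncompressed, contiguous-planar TIFF only; 8/16-bit unsigned and 32-bit
## float samples; strips; II and MM byte orders on read (II on write);
## GeoTIFF ModelPixelScale/ModelTiepoint tags for the affine transform.
## No compiled TIFF library ships with this R installation, so the codec is
## intentionally tiny rather than general.

tiff_type_size <- c(`1` = 1L, `2` = 1L, `3` = 2L, `4` = 4L, `5` = 8L,
                    `6` = 1L, `7` = 1L, `8` = 2L, `9` = 4L, `10` = 8L,
                    `11` = 4L, `12` = 8L)

read_tiff <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readBin(con, "raw", 2L)
  endian <- if (identical(as.integer(magic), c(0x49L, 0x49L))) "little"
            else if (identical(as.integer(magic), c(0x4dL, 0x4dL))) "big"
            else stop("not a TIFF file")
  rd <- function(what, n, size) readBin(con, what, n = n, size = size,
                                        endian = endian, signed = size >= 4L)
  if (rd("integer", 1L, 2L) != 42L) stop("not a TIFF file")
  ifd_off <- rd("integer", 1L, 4L)
  seek(con, ifd_off)
  n_entries <- rd("integer", 1L, 2L)
  tags <- list()
  for (i in seq_len(n_entries)) {
    tag <- rd("integer", 1L, 2L)
    type <- rd("integer", 1L, 2L)
    count <- rd("integer", 1L, 4L)
    size <- tiff_type_size[[as.character(type)]] * count
    val_raw_pos <- seek(con)
    if (size > 4L) {
      off <- rd("integer", 1L, 4L)
      here <- seek(con)
      seek(con, off)
    }
    vals <- switch(as.character(type),
      `3` = rd("integer", count, 2L),
      `4` = rd("integer", count, 4L),
      `11` = readBin(con, "numeric", count, size = 4L, endian = endian),
      `12` = readBin(con, "numeric", count, size = 8L, endian = endian),
      { seek(con, val_raw_pos); readBin(con, "raw", 4L); NULL })
    if (size > 4L) seek(con, here) else seek(con, val_raw_pos + 4L)
    tags[[as.character(tag)]] <- vals
  }
  need <- function(tag, default = NULL) {
    v <- tags[[as.character(tag)]]
    if (is.null(v)) {
      if (is.null(default)) stop("TIFF tag ", tag, " missing")
      default
    } else v
  }
  width <- need(256); height <- need(257)
  bits <- need(258, 1L)[1L]
  if (need(259, 1L) != 1L) stop("compressed TIFF not supported")
  spp <- need(277, 1L)
  if (!is.null(tags[["284"]]) && tags[["284"]] != 1L)
    stop("planar (non-contiguous) TIFF not supported")
  sample_fmt <- need(339, 1L)[1L]
  offsets <- need(273)
  counts <- need(279)
  rows_per_strip <- need(278, height)

  n_px <- as.numeric(width) * height * spp
  buf <- if (sample_fmt == 3L) numeric(n_px) else integer(n_px)
  pos <- 1L
  for (s in seq_along(offsets)) {
    seek(con, offsets[s])
    n_here <- counts[s] / (bits / 8L)
    v <- if (sample_fmt == 3L) {
      readBin(con, "numeric", n_here, size = 4L, endian = endian)
    } else {
      readBin(con, "integer", n_here, size = bits / 8L, endian = endian,
              signed = FALSE)
    }
    buf[pos:(pos + n_here - 1L)] <- v
    pos <- pos + n_here
  }
  # row-major, interleaved samples -> V x U x spp array
  data <- if (spp == 1L) {
    matrix(buf, nrow = height, ncol = width, byrow = TRUE)
  } else {
    a <- array(buf, dim = c(spp, width, height))
    aperm(a, c(3L, 2L, 1L))
  }
  geotransform <- NULL
  scale <- tags[["33550"]]; tie <- tags[["33922"]]
  if (!is.null(scale) && !is.null(tie)) {
    geotransform <- c(tie[4] - tie[1] * scale[1], scale[1], 0,
                      tie[5] + tie[2] * scale[2], 0, -scale[2])
  }
  list(data = data, geotransform = geotransform)
}

write_tiff <- function(path, data, sample_format = c("uint8", "float"),
                       geotransform = NULL) {
  sample_format <- match.arg(sample_format)
  d <- dim(data)
  spp <- if (length(d) == 3L) d[3L] else 1L
  height <- d[1L]; width <- d[2L]
  con <- file(path, "wb")
  on.exit(close(con))
  w2 <- function(x) writeBin(as.integer(x), con, size = 2L, endian = "little")
  w4 <- function(x) writeBin(as.integer(x), con, size = 4L, endian = "little")

  # interleave samples row-major
  flat <- if (spp == 1L) as.numeric(t(data)) else as.numeric(aperm(data, c(3L, 2L, 1L)))
  bytes_per_sample <- if (sample_format == "float") 4L else 1L
  data_bytes <- length(flat) * bytes_per_sample
  data_off <- 8L

  writeBin(charToRaw("II"), con); w2(42L); w4(data_off + data_bytes)
  if (sample_format == "float") {
    writeBin(flat, con, size = 4L, endian = "little")
  } else {
    writeBin(as.raw(pmin(pmax(round(flat), 0), 255)), con)
  }

  entries <- list(
    list(256, 4, 1, width), list(257, 4, 1, height),
    list(258, 3, spp, rep(bytes_per_sample * 8L, spp)),
    list(259, 3, 1, 1),
    list(262, 3, 1, if (spp >= 3L) 2L else 1L),
    list(273, 4, 1, data_off), list(277, 3, 1, spp),
    list(278, 4, 1, height), list(279, 4, 1, data_bytes),
    list(284, 3, 1, 1),
    list(339, 3, 1, if (sample_format == "float") 3L else 1L))
  extra <- list()
  if (!is.null(geotransform)) {
    entries <- c(entries, list(list(33550, 12, 3, "scale"),
                               list(33922, 12, 6, "tie")))
    extra$scale <- c(abs(geotransform[2]), abs(geotransform[6]), 0)
    extra$tie <- c(0, 0, 0, geotransform[1], geotransform[4], 0)
  }
  entries <- entries[order(vapply(entries, function(e) e[[1]], numeric(1)))]

  ifd_off <- data_off + data_bytes
  n <- length(entries)
  # values larger than 4 bytes go after the IFD
  overflow_off <- ifd_off + 2L + n * 12L + 4L
  w2(n)
  deferred <- list()
  for (e in entries) {
    w2(e[[1]]); w2(e[[2]]); w4(e[[3]])
    val <- e[[4]]
    type_size <- tiff_type_size[[as.character(e[[2]])]]
    nbytes <- type_size * e[[3]]
    if (is.character(val)) val <- extra[[val]]
    if (nbytes > 4L) {
      w4(overflow_off)
      deferred <- c(deferred, list(list(val = val, type = e[[2]])))
      overflow_off <- overflow_off + nbytes
    } else if (e[[2]] == 3 && e[[3]] <= 2L) {
      w2(val); if (e[[3]] == 1L) w2(0L)
    } else {
      w4(val)
    }
  }
  w4(0L)  # no further IFD
  for (dfr in deferred) {
    if (dfr$type == 12) writeBin(as.numeric(dfr$val), con, size = 8L, endian = "little")
    else if (dfr$type == 3) w2(dfr$val) else w4(dfr$val)
  }
  invisible(path)
}
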