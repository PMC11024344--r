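#' Calibrated multichannel image
#'
#' The common currency of all imaging operations: a channel-named stack of
#' 2D intensity rasters with a physical pixel size. Coordinates follow the
#' raster convention used throughout the package: 0-based physical origin at
#' the top-left pixel corner, x along columns, y along rows, so the centre of
#' pixel `[r, c]` sits at `((c - 0.5) * pixel_size_um, (r - 0.5) *
#' pixel_size_um)`.
#'
#' Intensities are held in single precision (the storage format of the
#' 32-bit float TIFFs written by [write_image()]), so a write/read round-trip
#' reproduces the pixels exactly.
#'
#' @param pixels Numeric array `rows x cols x channels` (a plain matrix is
#'   promoted to one channel), all values finite and non-negative.
#' @param channel_names Character vector naming the channels.
#' @param pixel_size_um Positive pixel size in micrometres.
#' @return An `ImageStack` object.
#' @export
image_stack <- function(pixels, channel_names, pixel_size_um) {
  if (is.matrix(pixels)) pixels <- array(pixels, c(dim(pixels), 1L))
  stopifnot(is.array(pixels), length(dim(pixels)) == 3L)
  stopifnot(length(channel_names) == dim(pixels)[3],
            !anyDuplicated(channel_names))
  stopifnot(is.numeric(pixel_size_um), length(pixel_size_um) == 1,
            pixel_size_um > 0)
  if (any(!is.finite(pixels)) || any(pixels < 0))
    stop("ImageStack intensities must be finite and non-negative")
  pixels <- float32(pixels)
  dimnames(pixels) <- list(NULL, NULL, channel_names)
  structure(list(pixels = pixels,
                 channel_names = as.character(channel_names),
                 pixel_size_um = as.numeric(pixel_size_um)),
            class = "ImageStack")
}

#' @export
print.ImageStack <- function(x, ...) {
  d <- dim(x$pixels)
  cat(sprintf("ImageStack: %d x %d px (%.3g x %.3g um), %d channel(s): %s\n",
              d[1], d[2], d[2] * x$pixel_size_um, d[1] * x$pixel_size_um,
              d[3], paste(x$channel_names, collapse = ", ")))
  invisible(x)
}

#' Extract one channel of an ImageStack as a matrix
#'
#' @param img An [image_stack()].
#' @param channel Channel name or index.
#' @return Numeric matrix.
#' @export
get_channel <- function(img, channel) {
  stopifnot(inherits(img, "ImageStack"))
  if (is.character(channel)) {
    if (!channel %in% img$channel_names)
      stop("channel '", channel, "' not found; available: ",
           paste(img$channel_names, collapse = ", "))
  } else {
    stopifnot(channel >= 1, channel <= dim(img$pixels)[3])
  }
  img$pixels[, , channel]
}

#' Read a calibrated multichannel TIFF
#'
#' Reads a multi-page TIFF as an [image_stack()]. Channel names and pixel
#' size come from the JSON sidecar written by [write_image()]
#' (`<path>.json`); for foreign TIFFs without a sidecar the pixel size must
#' be supplied explicitly (distances in this package are physical) and
#' channels get positional names.
#'
#' @param path TIFF file path.
#' @param pixel_size_um Optional calibration override in µm/pixel.
#' @param channel_names Optional channel-name override.
#' @return An `ImageStack`.
#' @export
read_image <- function(path, pixel_size_um = NULL, channel_names = NULL) {
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  pages <- lapply(pages, function(p) {
    if (length(dim(p)) == 3L) p[, , 1] else p  # tolerate grey-stored-as-RGB
  })
  meta <- list()
  sidecar <- paste0(path, ".json")
  if (file.exists(sidecar))
    meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  psz <- pixel_size_um %||% meta$pixel_size_um
  if (is.null(psz))
    stop("no pixel size: '", path, "' has no calibration sidecar and no ",
         "pixel_size_um override was given")
  cn <- channel_names %||% meta$channel_names %||%
    paste0("ch", seq_along(pages))
  image_stack(array(unlist(pages), c(dim(pages[[1]]), length(pages))),
              cn, psz)
}

#' Write an ImageStack as a calibrated multichannel TIFF
#'
#' One 32-bit float page per channel, plus a JSON sidecar (`<path>.json`)
#' carrying the channel names and pixel size. Values outside `[0, 1]` cannot
#' be represented by the writer and are clipped with a warning.
#'
#' @param img An [image_stack()].
#' @param path Output TIFF path.
#' @return `path`, invisibly.
#' @export
write_image <- function(img, path) {
  stopifnot(inherits(img, "ImageStack"))
  px <- img$pixels
  if (any(px < 0) || any(px > 1)) {
    warning("intensities outside [0, 1] clipped for TIFF storage")
    px <- pmin(pmax(px, 0), 1)
  }
  pages <- lapply(seq_len(dim(px)[3]), function(k) px[, , k])
  tiff::writeTIFF(pages, path, bits.per.sample = 32L)
  jsonlite::write_json(list(schema = "nichescape-image/1",
                            channel_names = img$channel_names,
                            pixel_size_um = img$pixel_size_um),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

# Map physical coordinates (um) to pixel indices, clamped to the raster.
coords_to_pixels <- function(x_um, y_um, dim_px, pixel_size_um) {
  r <- pmin(pmax(ceiling(y_um / pixel_size_um), 1L), dim_px[1])
  c <- pmin(pmax(ceiling(x_um / pixel_size_um), 1L), dim_px[2])
  cbind(row = as.integer(r), col = as.integer(c))
}

# Physical centre coordinates of pixel indices.
pixel_centers_um <- function(rows, cols, pixel_size_um) {
  cbind(x_um = (cols - 0.5) * pixel_size_um,
        y_um = (rows - 0.5) * pixel_size_um)
}
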