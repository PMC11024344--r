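#' Segment vessels from an endothelial marker channel
#'
#' Endothelia are identified from a CD31-like channel by intensity
#' thresholding followed by a shape filter that keeps elongated structures
#' and discards punctate background: each connected component must reach a
#' minimum area and a minimum elongation (major/minor axis ratio of its
#' second-moment ellipse).
#'
#' @param img An [image_stack()].
#' @param channel Channel name or index of the endothelial marker.
#' @param threshold `"otsu"` (default) for Otsu's method on the channel's own
#'   intensity range, or a fixed numeric threshold for reproducible reruns.
#' @param min_area_um2 Minimum component area in µm² (default 20).
#' @param min_elongation Minimum major/minor axis ratio (default 2.5);
#'   components rounder than this are treated as punctate background.
#' @return A `VesselMask`: logical raster `mask`, the `pixel_size_um`, and
#'   the resolved parameters under `params`.
#' @export
segment_vessels <- function(img, channel = "CD31", threshold = "otsu",
                            min_area_um2 = 20, min_elongation = 2.5) {
  stopifnot(inherits(img, "ImageStack"),
            min_area_um2 >= 0, min_elongation >= 1)
  x <- get_channel(img, channel)
  psz <- img$pixel_size_um
  if (all(x == 0)) {
    warning("channel is identically zero; returning empty vessel mask")
    return(vessel_mask(matrix(FALSE, nrow(x), ncol(x)), psz,
                       params = list(threshold = NA_real_,
                                     min_area_um2 = min_area_um2,
                                     min_elongation = min_elongation,
                                     channel = channel)))
  }
  thr <- resolve_threshold(threshold, x)
  bin <- x > thr
  lab <- EBImage::imageData(EBImage::bwlabel(bin * 1))
  nlab <- max(lab)
  keep <- logical(nlab)
  if (nlab > 0) {
    areas <- tabulate(lab[lab > 0], nbins = nlab) * psz^2
    mom <- EBImage::computeFeatures.moment(lab)
    # minor axis from major axis and eccentricity of the moment ellipse
    minor <- mom[, "m.majoraxis"] * sqrt(1 - mom[, "m.eccentricity"]^2)
    ratio <- ifelse(minor > 0, mom[, "m.majoraxis"] / minor, Inf)
    keep <- areas >= min_area_um2 & ratio >= min_elongation
  }
  mask <- matrix(FALSE, nrow(x), ncol(x))
  if (any(keep)) mask <- matrix(lab %in% which(keep), nrow(x), ncol(x))
  if (!any(mask)) warning("no component passed the vessel filters; empty mask")
  vessel_mask(mask, psz,
              params = list(threshold = thr, min_area_um2 = min_area_um2,
                            min_elongation = min_elongation,
                            channel = channel))
}

#' Construct a VesselMask from a logical raster
#'
#' @param mask Logical matrix (TRUE on vessels).
#' @param pixel_size_um Positive pixel size in µm.
#' @param params Optional provenance list (threshold, filters, channel).
#' @return A `VesselMask` object.
#' @export
vessel_mask <- function(mask, pixel_size_um, params = list()) {
  stopifnot(is.matrix(mask), is.logical(mask) || all(mask %in% c(0, 1)),
            pixel_size_um > 0)
  structure(list(mask = matrix(as.logical(mask), nrow(mask), ncol(mask)),
                 pixel_size_um = as.numeric(pixel_size_um),
                 params = params),
            class = "VesselMask")
}

#' Exact Euclidean distance field to the nearest vessel pixel
#'
#' For every pixel, the exact Euclidean distance (pixel centre to pixel
#' centre) to the nearest vessel pixel, scaled to µm. Operationalizes
#' "distance to the nearest vessel": zero on vessels, positive elsewhere.
#'
#' @param vmask A [vessel_mask()].
#' @return A `DistanceField`: `dist` raster in µm (all `Inf` with
#'   `empty = TRUE` when the mask has no vessel pixel), `pixel_size_um`.
#' @export
distance_field <- function(vmask) {
  stopifnot(inherits(vmask, "VesselMask"))
  m <- vmask$mask
  if (!any(m)) {
    warning("empty vessel mask: distances undefined (all Inf)")
    return(structure(list(dist = matrix(Inf, nrow(m), ncol(m)),
                          pixel_size_um = vmask$pixel_size_um, empty = TRUE),
                     class = "DistanceField"))
  }
  # distance of each non-vessel pixel to the nearest vessel pixel; EBImage's
  # distmap measures each non-zero pixel's distance to the nearest zero.
  d <- EBImage::imageData(EBImage::distmap(1 - m, metric = "euclidean"))
  structure(list(dist = d * vmask$pixel_size_um,
                 pixel_size_um = vmask$pixel_size_um, empty = FALSE),
            class = "DistanceField")
}

#' Percent area of a mask inside each subregion
#'
#' `100 * (mask pixels inside the region polygon) / (pixels inside the
#' polygon)`, the thresholded-area density readout (e.g., CD31 percent area
#' per DG subregion). Pixels are assigned by their centre's point-in-polygon
#' test.
#'
#' @param vmask A [vessel_mask()].
#' @param regions A [region_map()].
#' @return Data frame `(region, percent, n_pixels)`; `percent` is `NA` for a
#'   region containing no pixel centre.
#' @export
percent_area <- function(vmask, regions) {
  stopifnot(inherits(vmask, "VesselMask"), inherits(regions, "RegionMap"))
  m <- vmask$mask
  ctr <- pixel_grid_centers(dim(m), vmask$pixel_size_um)
  out <- lapply(names(regions$polygons), function(lbl) {
    inside <- points_in_polygon(ctr$x, ctr$y, regions$polygons[[lbl]])
    n <- sum(inside)
    data.frame(region = lbl,
               percent = if (n == 0) NA_real_ else 100 * sum(m[inside]) / n,
               n_pixels = n)
  })
  do.call(rbind, out)
}

#' Percent of one mask covered by another, per subregion
#'
#' `100 * |num & den & region| / |den & region|` — e.g., the percent of
#' CD31+ area occupied by occludin labelling in each subregion. Undefined
#' (`NA`) where the denominator mask is empty within the region.
#'
#' @param mask_num Numerator [vessel_mask()] (e.g., occludin & CD31).
#' @param mask_den Denominator [vessel_mask()] (e.g., CD31).
#' @param regions A [region_map()], or `NULL` for the whole image.
#' @return Data frame `(region, percent, n_den_pixels)`.
#' @export
overlap_fraction <- function(mask_num, mask_den, regions = NULL) {
  stopifnot(inherits(mask_num, "VesselMask"), inherits(mask_den, "VesselMask"),
            identical(dim(mask_num$mask), dim(mask_den$mask)))
  num <- mask_num$mask; den <- mask_den$mask
  if (is.null(regions)) {
    nden <- sum(den)
    return(data.frame(region = "all",
                      percent = if (nden == 0) NA_real_
                                else 100 * sum(num & den) / nden,
                      n_den_pixels = nden))
  }
  stopifnot(inherits(regions, "RegionMap"))
  ctr <- pixel_grid_centers(dim(den), mask_den$pixel_size_um)
  out <- lapply(names(regions$polygons), function(lbl) {
    inside <- points_in_polygon(ctr$x, ctr$y, regions$polygons[[lbl]])
    nden <- sum(den[inside])
    data.frame(region = lbl,
               percent = if (nden == 0) NA_real_
                         else 100 * sum(num[inside] & den[inside]) / nden,
               n_den_pixels = nden)
  })
  do.call(rbind, out)
}

# All pixel-centre coordinates of a raster, in µm.
pixel_grid_centers <- function(dim_px, pixel_size_um) {
  rows <- rep(seq_len(dim_px[1]), times = dim_px[2])
  cols <- rep(seq_len(dim_px[2]), each = dim_px[1])
  list(x = (cols - 0.5) * pixel_size_um, y = (rows - 0.5) * pixel_size_um,
       row = rows, col = cols)
}

#' Write a VesselMask as a single-channel TIFF
#' @param vmask A [vessel_mask()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_mask <- function(vmask, path) {
  img <- image_stack(vmask$mask * 1, "mask", vmask$pixel_size_um)
  write_image(img, path)
}

#' Read a single-channel TIFF as a VesselMask
#' @param path TIFF path (mask pixels > 0.5 are TRUE).
#' @param pixel_size_um Optional calibration override.
#' @return A `VesselMask`.
#' @export
read_mask <- function(path, pixel_size_um = NULL) {
  img <- read_image(path, pixel_size_um = pixel_size_um)
  vessel_mask(get_channel(img, 1) > 0.5, img$pixel_size_um)
}
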