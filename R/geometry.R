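#' SGZ midline polyline
#'
#' The subgranular zone (SGZ) is modelled as a narrow band — about two cell
#' body widths — around a reference centerline between the granule cell layer
#' and the hilus. The midline anchors the systematic random null
#' ([sample_random_null()]) and the synthetic generator's band geometry.
#'
#' @param vertices Two-column matrix of ordered `(x_um, y_um)` vertices
#'   (at least two, positive arc length).
#' @param band_halfwidth_um Half-width of the SGZ band in µm.
#' @return A `MidlinePolyline` object.
#' @export
midline_polyline <- function(vertices, band_halfwidth_um) {
  vertices <- as.matrix(vertices)
  stopifnot(ncol(vertices) == 2, nrow(vertices) >= 2,
            all(is.finite(vertices)),
            band_halfwidth_um > 0)
  colnames(vertices) <- c("x_um", "y_um")
  if (polyline_length(vertices) <= 0) stop("midline has zero arc length")
  structure(list(vertices = vertices,
                 band_halfwidth_um = as.numeric(band_halfwidth_um)),
            class = "MidlinePolyline")
}

#' Arc length of a polyline
#' @param vertices Two-column coordinate matrix.
#' @return Total arc length (same units as the coordinates).
#' @export
polyline_length <- function(vertices) {
  d <- diff(vertices)
  sum(sqrt(rowSums(d^2)))
}

# Point at arc-length positions s along the polyline, plus the local unit
# normal (left of travel). s is clamped to [0, L].
polyline_point_at <- function(vertices, s) {
  seg <- diff(vertices)
  len <- sqrt(rowSums(seg^2))
  cum <- c(0, cumsum(len))
  L <- cum[length(cum)]
  s <- pmin(pmax(s, 0), L)
  i <- pmin(findInterval(s, cum, rightmost.closed = TRUE), length(len))
  frac <- (s - cum[i]) / len[i]
  p <- vertices[i, , drop = FALSE] + seg[i, , drop = FALSE] * frac
  tang <- seg[i, , drop = FALSE] / len[i]
  normal <- cbind(-tang[, 2], tang[, 1])
  list(point = p, normal = normal)
}

# Minimum distance from each point to a polyline (vectorized over points).
dist_to_polyline <- function(px, py, vertices) {
  n <- nrow(vertices)
  best <- rep(Inf, length(px))
  for (i in seq_len(n - 1)) {
    ax <- vertices[i, 1]; ay <- vertices[i, 2]
    bx <- vertices[i + 1, 1]; by <- vertices[i + 1, 2]
    dx <- bx - ax; dy <- by - ay
    L2 <- dx^2 + dy^2
    t <- if (L2 == 0) 0 else pmin(pmax(((px - ax) * dx + (py - ay) * dy) / L2, 0), 1)
    d2 <- (px - (ax + t * dx))^2 + (py - (ay + t * dy))^2
    best <- pmin(best, d2)
  }
  sqrt(best)
}

# Resample a polyline at (at most) `step` spacing, endpoints included.
densify_polyline <- function(vertices, step) {
  L <- polyline_length(vertices)
  s <- seq(0, L, length.out = max(2L, ceiling(L / step) + 1L))
  polyline_point_at(vertices, s)$point
}

#' Labeled subregion polygons
#'
#' Holds the dentate-gyrus subregion polygons ({ML, GCL, SGZ, HL} or any
#' user-defined set) in physical µm coordinates, used by [percent_area()] and
#' [overlap_fraction()].
#'
#' @param polygons Named list of two-column `(x_um, y_um)` vertex matrices,
#'   one simple polygon per region; labels must be unique.
#' @return A `RegionMap` object.
#' @export
region_map <- function(polygons) {
  stopifnot(is.list(polygons), length(polygons) >= 1,
            !is.null(names(polygons)), !anyDuplicated(names(polygons)),
            all(nzchar(names(polygons))))
  polygons <- lapply(polygons, function(p) {
    p <- as.matrix(p)
    stopifnot(ncol(p) == 2, nrow(p) >= 3, all(is.finite(p)))
    colnames(p) <- c("x_um", "y_um")
    p
  })
  structure(list(polygons = polygons), class = "RegionMap")
}

# Logical: which of the points fall inside the polygon (pixel-centre test).
points_in_polygon <- function(px, py, polygon) {
  bnd <- rbind(polygon, polygon[1, ])
  mgcv::in.out(bnd, cbind(px, py))
}

#' Write / read midline and region geometry as JSON
#'
#' Plain-text interchange for the geometry objects: vertex lists in µm.
#'
#' @param x A `MidlinePolyline` or `RegionMap`.
#' @param path Output JSON path.
#' @return `path` invisibly (writer); the reconstructed object (reader).
#' @export
write_geometry <- function(x, path) {
  strip <- function(m) {m <- as.matrix(m); dimnames(m) <- NULL; m}
  if (inherits(x, "MidlinePolyline")) {
    obj <- list(schema = "nichescape-midline/1",
                vertices = strip(x$vertices),
                band_halfwidth_um = x$band_halfwidth_um)
  } else if (inherits(x, "RegionMap")) {
    obj <- list(schema = "nichescape-regions/1",
                regions = lapply(x$polygons, strip))
  } else stop("write_geometry handles MidlinePolyline or RegionMap")
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_geometry
#' @export
read_geometry <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  to_mat <- function(v) {
    m <- as.matrix(v)
    storage.mode(m) <- "double"
    colnames(m) <- c("x_um", "y_um")
    m
  }
  if (identical(obj$schema, "nichescape-midline/1")) {
    midline_polyline(to_mat(obj$vertices), obj$band_halfwidth_um)
  } else if (identical(obj$schema, "nichescape-regions/1")) {
    region_map(lapply(obj$regions, to_mat))
  } else stop("unrecognized geometry schema in ", path)
}
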