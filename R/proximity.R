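#' Per-cell nearest-vessel distance
#'
#' Distance from the middle of each cell body (its Hoechst+ nucleus
#' centroid) to the nearest vessel pixel, read from the Euclidean distance
#' field at the pixel containing the centroid (no subpixel interpolation;
#' the quantization bias is below half a pixel). Cells on vessels get 0.
#'
#' @param cells Cell table with `x_um`, `y_um`.
#' @param field A [distance_field()].
#' @return Numeric vector of distances in µm, one per row of `cells`.
#' @export
nearest_vessel_distance <- function(cells, field) {
  stopifnot(inherits(field, "DistanceField"))
  if (isTRUE(field$empty))
    stop("empty vessel mask: no distances can be measured; ",
         "review the upstream segmentation")
  d <- dim(field$dist)
  pix <- coords_to_pixels(cells$x_um, cells$y_um, d, field$pixel_size_um)
  field$dist[cbind(pix[, 1], pix[, 2])]
}

#' Systematic random-cell null along the SGZ midline
#'
#' The random baseline against which phenotype proximity is judged: sample
#' points are placed at a fixed arc-length spacing (default ~100 µm) along
#' the SGZ midline, starting from a seeded uniform offset in `[0, spacing)`
#' so the phase carries no information; each point is mapped to the nearest
#' Hoechst+ nucleus within the SGZ band, and duplicate nuclei are collapsed.
#'
#' @param midline A [midline_polyline()].
#' @param nuclei Data frame of candidate nuclei (`x_um`, `y_um`); typically
#'   all Hoechst+ cells of the section/animal.
#' @param spacing_um Arc-length spacing between sample points (default 100).
#' @param seed Integer seed for the phase offset.
#' @return Subset of `nuclei` rows chosen as the null set, with an
#'   `arc_s_um` column giving the generating sample position.
#' @export
sample_random_null <- function(midline, nuclei, spacing_um = 100, seed = NULL) {
  stopifnot(inherits(midline, "MidlinePolyline"), spacing_um > 0)
  L <- polyline_length(midline$vertices)
  if (L < spacing_um)
    stop("midline arc length (", round(L, 1), " um) is shorter than the ",
         "sampling spacing (", spacing_um, " um)")
  if (nrow(nuclei) == 0) stop("no candidate nuclei supplied")
  in_band <- dist_to_polyline(nuclei$x_um, nuclei$y_um, midline$vertices) <=
    midline$band_halfwidth_um
  if (!any(in_band)) stop("no candidate nucleus lies within the SGZ band")
  cand <- nuclei[in_band, , drop = FALSE]
  if (!is.null(seed)) set.seed(as.integer(seed))
  offset <- runif(1, 0, spacing_um)
  s <- seq(offset, L, by = spacing_um)
  pts <- polyline_point_at(midline$vertices, s)$point
  picked <- integer(0); arc <- numeric(0)
  for (i in seq_len(nrow(pts))) {
    d2 <- (cand$x_um - pts[i, 1])^2 + (cand$y_um - pts[i, 2])^2
    j <- which.min(d2)
    if (sqrt(d2[j]) > spacing_um / 2) {
      warning("no nucleus within ", spacing_um / 2, " um of the sample point ",
              "at arc length ", round(s[i], 1), " um; point skipped")
      next
    }
    picked <- c(picked, j); arc <- c(arc, s[i])
  }
  dup <- duplicated(picked)
  out <- cand[picked[!dup], , drop = FALSE]
  out$arc_s_um <- arc[!dup]
  rownames(out) <- NULL
  out
}

#' Per-animal vessel association index
#'
#' For one animal (one distance field): the mean nearest-vessel distance of
#' each phenotype, the mean distance of the systematic random null set, and
#' their signed difference, the association index. Negative = the phenotype
#' sits closer to vessels than random nuclei (preferential association);
#' positive = farther (dissociation).
#'
#' @param cells Classified cell table for one animal (`phenotype`, `x_um`,
#'   `y_um`; `animal_id`/`group` propagated if present).
#' @param null_set Null nuclei from [sample_random_null()].
#' @param field The animal's [distance_field()].
#' @param phenotypes Phenotypes to summarize (default: all present).
#' @return Data frame `(animal_id, group, phenotype, n_cells, mean_dist_um,
#'   null_mean_um, n_null, association_index_um)`. The index is `NA` unless
#'   the animal has at least 1 cell of the phenotype and at least 2 null
#'   samples.
#' @export
association_index <- function(cells, null_set, field, phenotypes = NULL) {
  stopifnot(inherits(field, "DistanceField"))
  if (length(unique(cells$animal_id)) > 1)
    stop("association_index() works on one animal at a time")
  cell_d <- nearest_vessel_distance(cells, field)
  null_d <- nearest_vessel_distance(null_set, field)
  null_ok <- length(null_d) >= 2
  if (!null_ok)
    warning("fewer than 2 null samples: association index undefined")
  phenotypes <- phenotypes %||% unique(as.character(cells$phenotype))
  aid <- if ("animal_id" %in% names(cells)) cells$animal_id[1] else NA
  grp <- if ("group" %in% names(cells)) as.character(cells$group[1]) else NA
  out <- do.call(rbind, lapply(phenotypes, function(p) {
    idx <- which(as.character(cells$phenotype) == p)
    m <- if (length(idx) >= 1) mean(cell_d[idx]) else NA_real_
    nm <- if (null_ok) mean(null_d) else NA_real_
    data.frame(animal_id = aid, group = grp, phenotype = p,
               n_cells = length(idx), mean_dist_um = m,
               null_mean_um = nm, n_null = length(null_d),
               association_index_um = if (length(idx) >= 1 && null_ok)
                 m - nm else NA_real_)
  }))
  rownames(out) <- NULL
  out
}

#' Radial-process contact with the vasculature
#'
#' A process contacts the vasculature if any point of its (densified)
#' polyline lies within `tol_um` of a vessel pixel; the default tolerance is
#' one pixel diagonal. Also returns the per-animal percent of cells with a
#' contacting process.
#'
#' @param processes Named list of per-cell polylines (two-column µm
#'   matrices, ≥ 2 vertices each); names are cell ids.
#' @param vmask A [vessel_mask()].
#' @param tol_um Contact tolerance in µm (default `pixel_size * sqrt(2)`).
#' @param animal_id Optional vector mapping each process to an animal (for
#'   the percent summary); a single value recycles.
#' @return List with `contact` (named logical vector) and `percent`
#'   (data frame `animal_id, n, n_contact, percent`).
#' @export
process_contact <- function(processes, vmask, tol_um = NULL, animal_id = NA) {
  stopifnot(inherits(vmask, "VesselMask"), length(processes) >= 1)
  psz <- vmask$pixel_size_um
  tol_um <- tol_um %||% (psz * sqrt(2))
  fld <- if (any(vmask$mask)) distance_field(vmask) else NULL
  contact <- vapply(processes, function(poly) {
    poly <- as.matrix(poly)
    stopifnot(ncol(poly) == 2, nrow(poly) >= 2)
    if (is.null(fld)) return(FALSE)
    pts <- densify_polyline(poly, psz / 2)
    d <- nearest_vessel_distance(
      data.frame(x_um = pts[, 1], y_um = pts[, 2]), fld)
    any(d <= tol_um)
  }, logical(1))
  names(contact) <- names(processes) %||% seq_along(processes)
  animal_id <- rep_len(animal_id, length(contact))
  pct <- do.call(rbind, lapply(unique(animal_id), function(a) {
    i <- which(animal_id %in% a | (is.na(a) & is.na(animal_id)))
    data.frame(animal_id = a, n = length(i), n_contact = sum(contact[i]),
               percent = 100 * mean(contact[i]))
  }))
  list(contact = contact, percent = pct)
}
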