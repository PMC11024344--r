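#' Configuration for the synthetic niche generator
#'
#' Defines one synthetic dentate-gyrus niche section: a curvilinear SGZ
#' midline with a nucleus-dense band, a planar curvilinear capillary network
#' concentrated around the band, and cell populations whose nearest-vessel
#' distance distributions are shifted by configurable offsets relative to
#' the random-nucleus baseline (the mean distance of a random SGZ cell).
#'
#' Default physical scale: a 4096 x 256 µm field at 1 µm/px — the SGZ
#' ribbon of one animal collected across sections into a single montage —
#' with SGZ band half-width 7.5 µm (a ~15 µm band, about two cell-body
#' widths), capillary radius 2.5 µm, and vessel density 0.018 µm of vessel
#' centreline per µm² of field (≈ 8% CD31 area near the band).
#'
#' @param image_size_px Integer `(rows, cols)` raster size.
#' @param pixel_size_um µm per pixel.
#' @param midline Optional [midline_polyline()]; default: a gentle sine
#'   centreline across the full width at mid-height.
#' @param band_halfwidth_um SGZ band half-width (µm); must be below a
#'   quarter of the smaller image extent.
#' @param vessel_density Expected vessel centreline length per field area
#'   (µm/µm²).
#' @param vessel_radius_um Capillary tube radius (µm).
#' @param vessel_spread_um SD of the vessel offsets from the midline (µm);
#'   controls how tightly the capillary bed hugs the band.
#' @param n_cells_per_type Named integer vector of cells per phenotype
#'   (names from [NICHE_PHENOTYPES]).
#' @param distance_offset_um Data frame `(phenotype, group, offset_um)`:
#'   ground-truth shift of each phenotype's mean nearest-vessel distance
#'   relative to the random-nucleus baseline, per experimental group.
#' @param placement_sd_um Spread (µm) of each phenotype's distance
#'   preference around its target distance (default 4): cells of a
#'   phenotype occupy a characteristic distance band rather than an
#'   arbitrary reweighting of all band positions.
#' @param hoechst_density Plain (unlabelled) Hoechst+ nuclei per 100 µm of
#'   midline arc length.
#' @param noise List of intensity model parameters: `background`,
#'   `vessel_intensity`, `nucleus_intensity`, `read_sd` (Gaussian read
#'   noise), `shot_scale` (Poisson-like variance scaling on signal).
#' @param seed Integer seed; all generator randomness derives from it.
#' @return A validated `NicheConfig` list.
#' @export
niche_config <- function(image_size_px = c(256L, 4096L),
                         pixel_size_um = 1,
                         midline = NULL,
                         band_halfwidth_um = 7.5,
                         vessel_density = 0.018,
                         vessel_radius_um = 2.5,
                         vessel_spread_um = 30,
                         n_cells_per_type = c("RGL-NSC" = 40L, IPC = 60L,
                                              NB = 30L, IN = 25L,
                                              astrocyte = 30L, other = 25L),
                         distance_offset_um = NULL,
                         placement_sd_um = 4,
                         hoechst_density = 40,
                         noise = list(background = 0.05,
                                      vessel_intensity = 0.6,
                                      nucleus_intensity = 0.5,
                                      read_sd = 0.02, shot_scale = 0.03),
                         seed = 1L) {
  stopifnot(length(image_size_px) == 2, all(image_size_px >= 32),
            pixel_size_um > 0, band_halfwidth_um > 0,
            vessel_density > 0, vessel_radius_um > 0, vessel_spread_um > 0,
            hoechst_density > 0)
  extent_um <- rev(image_size_px) * pixel_size_um  # (x, y)
  if (band_halfwidth_um >= min(extent_um) / 4)
    stop("band_halfwidth_um must be < min(image extent)/4")
  stopifnot(!is.null(names(n_cells_per_type)),
            all(names(n_cells_per_type) %in% NICHE_PHENOTYPES))
  if (is.null(midline)) {
    xs <- seq(0, extent_um[1], length.out = 9)
    ys <- extent_um[2] / 2 + 0.08 * extent_um[2] * sin(xs / extent_um[1] * 2 * pi)
    midline <- midline_polyline(cbind(xs, ys), band_halfwidth_um)
  }
  if (is.null(distance_offset_um))
    distance_offset_um <- data.frame(phenotype = character(0),
                                     group = character(0),
                                     offset_um = numeric(0))
  stopifnot(is.data.frame(distance_offset_um),
            all(c("phenotype", "group", "offset_um") %in%
                  names(distance_offset_um)))
  noise <- modifyList(list(background = 0.05, vessel_intensity = 0.6,
                           nucleus_intensity = 0.5, read_sd = 0.02,
                           shot_scale = 0.03), noise)
  structure(list(image_size_px = as.integer(image_size_px),
                 pixel_size_um = pixel_size_um, midline = midline,
                 band_halfwidth_um = band_halfwidth_um,
                 vessel_density = vessel_density,
                 vessel_radius_um = vessel_radius_um,
                 vessel_spread_um = vessel_spread_um,
                 n_cells_per_type = n_cells_per_type,
                 distance_offset_um = distance_offset_um,
                 placement_sd_um = placement_sd_um,
                 hoechst_density = hoechst_density,
                 noise = noise, seed = as.integer(seed)),
            class = "NicheConfig")
}

# Cells of a phenotype occupy a characteristic distance band around the
# vasculature: placement weights are a Gaussian kernel in distance,
# w(d) = exp(-(d - mu)^2 / (2 sd^2)), with the kernel centre mu solved so
# that the weighted mean over the achievable band-pixel distances equals
# the target (the weighted mean is monotone increasing in mu, so a single
# root bracketed by the distance range exists iff the target is inside
# that range).
solve_kernel_center <- function(d, target, sd_um) {
  dmin <- min(d); dmax <- max(d)
  if (target <= dmin || target >= dmax) return(NULL)
  wmean <- function(mu) {
    e <- -(d - mu)^2 / (2 * sd_um^2)
    w <- exp(e - max(e))
    sum(d * w) / sum(w) - target
  }
  lo <- dmin - 6 * sd_um; hi <- dmax + 6 * sd_um
  if (!(wmean(lo) < 0 && wmean(hi) > 0)) return(NULL)
  uniroot(wmean, c(lo, hi), tol = 1e-9)$root
}

# Sample n band-pixel indices so the expected distance equals `target`.
sample_at_target_mean <- function(d, n, target, sd_um = 4, what = "cells") {
  mu <- solve_kernel_center(d, target, sd_um)
  if (is.null(mu))
    stop("infeasible placement for ", what, ": target mean distance ",
         round(target, 2), " um is outside the achievable range [",
         round(min(d), 2), ", ", round(max(d), 2), "] um in the band")
  e <- -(d - mu)^2 / (2 * sd_um^2)
  w <- exp(e - max(e))
  sample.int(length(d), n, replace = TRUE, prob = w)
}

# Random smooth capillary segments concentrated around the midline band: a
# planar Boolean segment process with random orientations, centre offsets
# normal around the midline (sd = vessel_spread_um) and mild curvature.
# Returns a list of densified curves (two-column um matrices).
draw_vessel_curves <- function(cfg, segment_length_um = 120) {
  extent <- rev(cfg$image_size_px) * cfg$pixel_size_um
  target_len <- cfg$vessel_density * prod(extent)
  n_seg <- max(1L, rpois(1, target_len / segment_length_um))
  L <- polyline_length(cfg$midline$vertices)
  lapply(seq_len(n_seg), function(i) {
    cx <- runif(1, 0, extent[1])
    pa <- polyline_point_at(cfg$midline$vertices, cx / extent[1] * L)
    cy <- pa$point[1, 2] + rnorm(1, 0, cfg$vessel_spread_um)
    # capillaries roughly follow the plane of the band: orientation is the
    # local midline direction plus moderate jitter, so thresholded
    # components stay individually elongated rather than meshing
    th <- atan2(-pa$normal[1, 1], pa$normal[1, 2]) + rnorm(1, 0, 0.25)
    s <- seq(-segment_length_um / 2, segment_length_um / 2, length.out = 5)
    wig <- cumsum(rnorm(5, 0, 3)); wig <- wig - mean(wig)
    xs <- cx + s * cos(th) - wig * sin(th)
    ys <- cy + s * sin(th) + wig * cos(th)
    sp <- spline(seq_along(xs), xs, n = 60)
    spy <- spline(seq_along(ys), ys, n = 60)
    densify_polyline(cbind(sp$y, spy$y), cfg$pixel_size_um / 2)
  })
}

# Rasterize curve points into a logical tube mask of the configured radius.
rasterize_tubes <- function(curves, cfg) {
  d <- cfg$image_size_px
  raster <- matrix(0, d[1], d[2])
  for (cv in curves) {
    pix <- coords_to_pixels(cv[, 1], cv[, 2], d, cfg$pixel_size_um)
    ok <- cv[, 1] >= 0 & cv[, 1] <= d[2] * cfg$pixel_size_um &
          cv[, 2] >= 0 & cv[, 2] <= d[1] * cfg$pixel_size_um
    raster[pix[ok, , drop = FALSE]] <- 1
  }
  if (!any(raster > 0)) return(matrix(FALSE, d[1], d[2]))
  dt <- EBImage::imageData(EBImage::distmap(1 - raster, metric = "euclidean"))
  dt * cfg$pixel_size_um <= cfg$vessel_radius_um
}

render_noise <- function(signal, noise) {
  x <- noise$background + signal +
    rnorm(length(signal), 0, noise$read_sd) +
    rnorm(length(signal), 0, sqrt(pmax(signal, 0) * noise$shot_scale))
  matrix(pmin(pmax(x, 0), 1), nrow(signal), ncol(signal))
}

# Marker template per phenotype (reporter + antigen markers in one table).
phenotype_markers <- function(phen) {
  tmpl <- list(
    "RGL-NSC"  = list(EYFP = TRUE,  GFP = TRUE,  GFAP = TRUE,  SOX2 = TRUE,
                      MCM2 = FALSE, DCX = FALSE, radial_process = TRUE,
                      bipolar = FALSE, primary_dendrite = FALSE),
    "IPC"      = list(EYFP = TRUE,  GFP = TRUE,  GFAP = FALSE, SOX2 = TRUE,
                      MCM2 = TRUE,  DCX = FALSE, radial_process = FALSE,
                      bipolar = FALSE, primary_dendrite = FALSE),
    "NB"       = list(EYFP = TRUE,  GFP = TRUE,  GFAP = FALSE, SOX2 = FALSE,
                      MCM2 = FALSE, DCX = TRUE,  radial_process = FALSE,
                      bipolar = TRUE, primary_dendrite = FALSE),
    "IN"       = list(EYFP = TRUE,  GFP = TRUE,  GFAP = FALSE, SOX2 = FALSE,
                      MCM2 = FALSE, DCX = TRUE,  radial_process = FALSE,
                      bipolar = FALSE, primary_dendrite = TRUE),
    "astrocyte" = list(EYFP = FALSE, GFP = FALSE, GFAP = TRUE, SOX2 = TRUE,
                      MCM2 = FALSE, DCX = FALSE, radial_process = FALSE,
                      bipolar = FALSE, primary_dendrite = FALSE),
    "other"    = list(EYFP = FALSE, GFP = FALSE, GFAP = FALSE, SOX2 = FALSE,
                      MCM2 = FALSE, DCX = FALSE, radial_process = FALSE,
                      bipolar = FALSE, primary_dendrite = FALSE))
  tmpl[[phen]]
}

#' Generate one synthetic niche section with ground truth
#'
#' Renders a calibrated two-channel image (CD31-like vessel tubes, Hoechst
#' nuclei), a cell table whose phenotype populations realize the configured
#' nearest-vessel distance offsets relative to the random-nucleus baseline,
#' the SGZ midline and subregion polygons, and a `NicheTruth` record of
#' every placement. Deterministic given `config$seed`.
#'
#' Placement: band pixels are sampled from an exponentially tilted version
#' of the band's distance distribution whose mean equals
#' `baseline + offset`, where `baseline` is the mean distance of band pixel
#' centres to the nearest vessel (the expected distance of a random SGZ
#' nucleus). An offset pushing the target outside the achievable range
#' raises an error naming the phenotype and offset.
#'
#' @param config A [niche_config()].
#' @param group Experimental group label used to look up offsets (default
#'   `"WT"`).
#' @param animal_id Animal identifier stamped into the cell table.
#' @param offset_shift_um Extra animal-level shift added to every configured
#'   offset (used by [generate_cohort()] for between-animal variation).
#' @return List with `image` ([image_stack()]), `cells` (cell table),
#'   `midline`, `regions` ([region_map()] with ML/GCL/SGZ/HL), and `truth`
#'   (vessel mask, per-cell true distances, baseline mean, realized and
#'   configured offsets).
#' @export
generate_niche <- function(config, group = "WT", animal_id = "a1",
                           offset_shift_um = 0) {
  stopifnot(inherits(config, "NicheConfig"))
  set.seed(config$seed)
  d <- config$image_size_px
  psz <- config$pixel_size_um

  curves <- draw_vessel_curves(config)
  vmask_truth <- rasterize_tubes(curves, config)
  vm <- vessel_mask(vmask_truth, psz, params = list(source = "truth"))
  fld <- distance_field(vm)

  grid <- pixel_grid_centers(d, psz)
  band <- dist_to_polyline(grid$x, grid$y, config$midline$vertices) <=
    config$band_halfwidth_um
  band_idx <- which(band)
  band_d <- fld$dist[band_idx]
  baseline_mean <- mean(band_d)

  offsets <- config$distance_offset_um
  get_offset <- function(phen) {
    row <- offsets$phenotype == phen & offsets$group == group
    if (any(row)) offsets$offset_um[which(row)[1]] else 0
  }

  arc_L <- polyline_length(config$midline$vertices)
  cells_list <- list()

  # Phenotype populations in the band, tilted to their target offsets.
  band_phens <- intersect(names(config$n_cells_per_type),
                          c("RGL-NSC", "IPC", "NB", "IN"))
  for (phen in band_phens) {
    n <- config$n_cells_per_type[[phen]]
    if (n == 0) next
    off <- get_offset(phen) + offset_shift_um
    target <- baseline_mean + off
    pick <- tryCatch(
      sample_at_target_mean(band_d, n, target,
                            sd_um = config$placement_sd_um,
                            what = paste0("phenotype ", phen,
                                          " (offset ", round(off, 3), " um)")),
      error = function(e) stop(conditionMessage(e), call. = FALSE))
    idx <- band_idx[pick]
    cells_list[[phen]] <- data.frame(
      x_um = grid$x[idx], y_um = grid$y[idx],
      phenotype_true = phen, in_sgz = TRUE, true_dist_um = fld$dist[idx])
  }

  # Astrocytes and unlabelled cells outside the band (hilus/GCL side).
  out_phens <- intersect(names(config$n_cells_per_type),
                         c("astrocyte", "other"))
  out_idx_pool <- which(!band)
  for (phen in out_phens) {
    n <- config$n_cells_per_type[[phen]]
    if (n == 0) next
    idx <- sample(out_idx_pool, n)
    cells_list[[phen]] <- data.frame(
      x_um = grid$x[idx], y_um = grid$y[idx],
      phenotype_true = phen, in_sgz = FALSE, true_dist_um = fld$dist[idx])
  }

  # Plain Hoechst+ nuclei along the band: uniform in arc length and lateral
  # offset; these carry the random-cell baseline.
  n_fill <- round(config$hoechst_density * arc_L / 100)
  s <- runif(n_fill, 0, arc_L)
  lat <- runif(n_fill, -config$band_halfwidth_um, config$band_halfwidth_um)
  pa <- polyline_point_at(config$midline$vertices, s)
  fx <- pa$point[, 1] + pa$normal[, 1] * lat
  fy <- pa$point[, 2] + pa$normal[, 2] * lat
  ok <- fx >= 0 & fx <= d[2] * psz & fy >= 0 & fy <= d[1] * psz
  fill_pix <- coords_to_pixels(fx[ok], fy[ok], d, psz)
  cells_list[["hoechst"]] <- data.frame(
    x_um = fx[ok], y_um = fy[ok], phenotype_true = "other", in_sgz = TRUE,
    true_dist_um = fld$dist[fill_pix])

  raw <- do.call(rbind, cells_list)
  rownames(raw) <- NULL
  n_cells <- nrow(raw)

  marker_cols <- c("EYFP", "GFP", "GFAP", "SOX2", "MCM2", "DCX",
                   "radial_process", "bipolar", "primary_dendrite")
  mk <- do.call(rbind, lapply(raw$phenotype_true, function(p)
    as.data.frame(phenotype_markers(p))))
  cells <- cbind(
    data.frame(cell_id = sprintf("%s_c%04d", animal_id, seq_len(n_cells)),
               animal_id = animal_id, group = group),
    raw[c("x_um", "y_um")], mk[marker_cols],
    data.frame(BrdU = FALSE, CD31 = FALSE, aCas3 = FALSE, Hoechst = TRUE,
               in_sgz = raw$in_sgz, phenotype = NA_character_))

  # Channels: CD31 tubes + Hoechst nuclei (small Gaussian somata).
  sig_cd31 <- vmask_truth * config$noise$vessel_intensity
  nuc_kernel <- gaussian_kernel(sd_px = max(1, 1.5 / psz))
  pix <- coords_to_pixels(cells$x_um, cells$y_um, d, psz)
  sig_hoechst <- stamp_kernel(matrix(0, d[1], d[2]), pix[, 1], pix[, 2],
                              nuc_kernel, config$noise$nucleus_intensity)
  img <- image_stack(array(c(render_noise(sig_cd31, config$noise),
                             render_noise(pmin(sig_hoechst, 0.9),
                                          config$noise)),
                           c(d, 2L)),
                     c("CD31", "Hoechst"), psz)

  regions <- niche_regions(config)

  realized <- do.call(rbind, lapply(band_phens, function(p) {
    i <- cells_list[[p]]
    if (is.null(i)) return(NULL)
    data.frame(phenotype = p, group = group,
               offset_configured_um = get_offset(p) + offset_shift_um,
               offset_realized_um = mean(i$true_dist_um) - baseline_mean)
  }))

  truth <- list(vessel_mask = vmask_truth,
                baseline_mean_um = baseline_mean,
                cells = data.frame(cell_id = cells$cell_id,
                                   phenotype = raw$phenotype_true,
                                   true_dist_um = raw$true_dist_um),
                offsets = realized,
                seed = config$seed, group = group, animal_id = animal_id)

  list(image = img, cells = cells, midline = config$midline,
       regions = regions, truth = truth)
}

# ML / GCL / SGZ / HL polygons as bands parallel to the midline (offsets in
# the midline's normal direction, clipped to the field).
niche_regions <- function(config) {
  extent <- rev(config$image_size_px) * config$pixel_size_um
  hw <- config$band_halfwidth_um
  gcl_th <- 8 * hw          # granule cell layer thickness
  L <- polyline_length(config$midline$vertices)
  pa <- polyline_point_at(config$midline$vertices,
                          seq(0, L, length.out = max(2L, ceiling(L / 4))))
  offset_curve <- function(k) cbind(pa$point[, 1] + pa$normal[, 1] * k,
                                    pa$point[, 2] + pa$normal[, 2] * k)
  strip <- function(k1, k2) {
    a <- offset_curve(k1); b <- offset_curve(k2)
    rbind(a, b[rev(seq_len(nrow(b))), , drop = FALSE])
  }
  # normal points toward negative y (up) for a left-to-right midline; GCL
  # and ML sit on the normal side, hilus opposite.
  top <- extent[2]
  region_map(list(
    SGZ = strip(-hw, hw),
    GCL = strip(hw, hw + gcl_th),
    ML  = strip(hw + gcl_th, hw + gcl_th + 0.45 * extent[2]),
    HL  = strip(-hw - 0.45 * extent[2], -hw)))
}

#' Generate a per-animal cohort of synthetic niches
#'
#' Emulates the per-mouse design: each animal is an independent niche whose
#' offsets are the group's configured offsets plus one animal-level normal
#' deviate (SD `between_animal_sd_um`), with per-animal seeds derived
#' deterministically from the master seed via [seed_stream()].
#'
#' @param config A [niche_config()] (its `seed` is the master seed unless
#'   `seed` is given).
#' @param groups Character vector of group labels (≥ 1).
#' @param n_animals_per_group Animals per group, scalar or one per group
#'   (each ≥ 2).
#' @param between_animal_sd_um SD of the animal-level offset deviate (µm).
#' @param seed Optional master seed override.
#' @return List of per-animal niches (as from [generate_niche()]), with an
#'   `animals` attribute table `(animal_id, group, seed, offset_shift_um)`.
#' @export
generate_cohort <- function(config, groups = c("WT", "iKD"),
                            n_animals_per_group = 8,
                            between_animal_sd_um = 0.8, seed = NULL) {
  stopifnot(inherits(config, "NicheConfig"),
            all(n_animals_per_group >= 2))
  n_per <- rep_len(n_animals_per_group, length(groups))
  master <- seed %||% config$seed
  n_total <- sum(n_per)
  seeds <- seed_stream(master, n_total + 1L)
  set.seed(seeds[n_total + 1L])
  shifts <- rnorm(n_total, 0, between_animal_sd_um)
  plan <- data.frame(
    animal_id = sprintf("%s_m%02d", rep(groups, n_per),
                        unlist(lapply(n_per, seq_len))),
    group = rep(groups, n_per),
    seed = seeds[seq_len(n_total)],
    offset_shift_um = shifts)
  out <- lapply(seq_len(n_total), function(i) {
    cfg_i <- config
    cfg_i$seed <- plan$seed[i]
    generate_niche(cfg_i, group = plan$group[i],
                   animal_id = plan$animal_id[i],
                   offset_shift_um = plan$offset_shift_um[i])
  })
  names(out) <- plan$animal_id
  attr(out, "animals") <- plan
  out
}
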