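#' Generate a synthetic RNAscope-style puncta image with ground truth
#'
#' Nuclei are laid out as non-overlapping disks on a jittered grid, each
#' labelled with a phenotype; per-nucleus puncta counts are Poisson with the
#' phenotype's rate, and puncta are rendered as small Gaussian spots at
#' integer pixel positions inside the nucleus, separated by at least
#' `min_separation_px` (Chebyshev) where feasible. When a nucleus cannot
#' hold its drawn count at that separation, the remaining spots are allowed
#' to merge and the nucleus is flagged in the truth (a documented
#' undercount for detection).
#'
#' @param n_cells_per_type Named integer vector: nuclei per phenotype.
#' @param mean_puncta Named numeric vector: Poisson puncta rate per
#'   phenotype (≥ 0).
#' @param nucleus_radius_um Nucleus disk radius (default 4 µm).
#' @param pixel_size_um µm per pixel (default 0.25).
#' @param min_separation_px Minimum Chebyshev separation between spot
#'   centres (default 3).
#' @param seed Integer seed.
#' @return List: `image` (channels `Vegfa`, `Hoechst`), `nucleus_masks`
#'   (labelled integer matrix), `nuclei` (nucleus_id, phenotype, centre),
#'   `truth` (per-nucleus true counts, merged flags, rates).
#' @export
generate_puncta_image <- function(n_cells_per_type, mean_puncta,
                                  nucleus_radius_um = 4,
                                  pixel_size_um = 0.25,
                                  min_separation_px = 3L,
                                  seed = 1L) {
  stopifnot(!is.null(names(n_cells_per_type)),
            all(names(n_cells_per_type) %in% names(mean_puncta)),
            all(mean_puncta >= 0))
  set.seed(as.integer(seed))
  n_total <- sum(n_cells_per_type)
  r_px <- nucleus_radius_um / pixel_size_um
  pitch <- ceiling(2.6 * r_px)
  ncol_grid <- ceiling(sqrt(n_total))
  nrow_grid <- ceiling(n_total / ncol_grid)
  d <- c(nrow_grid * pitch + pitch, ncol_grid * pitch + pitch)

  phen <- sample(rep(names(n_cells_per_type), n_cells_per_type))
  slots <- sample(nrow_grid * ncol_grid, n_total)
  gr <- (slots - 1) %/% ncol_grid + 1
  gc <- (slots - 1) %% ncol_grid + 1
  jit <- max(0, floor((pitch - 2 * r_px - 2) / 2))
  cr <- gr * pitch + sample(-jit:jit, n_total, replace = TRUE)
  cc <- gc * pitch + sample(-jit:jit, n_total, replace = TRUE)

  masks <- matrix(0L, d[1], d[2])
  dk <- disk_kernel(r_px)
  k <- (nrow(dk) - 1L) %/% 2L
  for (i in seq_len(n_total)) {
    rr <- (cr[i] - k):(cr[i] + k); cc2 <- (cc[i] - k):(cc[i] + k)
    sel <- dk > 0
    masks[rr, cc2][sel] <- i
  }

  counts <- rpois(n_total, mean_puncta[phen])
  spot_rows <- integer(0); spot_cols <- integer(0)
  merged <- logical(n_total)
  ik <- disk_kernel(max(r_px - 2, 2))
  inner_c <- (nrow(ik) - 1L) %/% 2L + 1L
  inner <- which(ik > 0, arr.ind = TRUE) - inner_c  # offsets from centre
  for (i in seq_len(n_total)) {
    if (counts[i] == 0) next
    placed <- matrix(numeric(0), 0, 2)
    tries <- 0
    while (nrow(placed) < counts[i] && tries < 200 * counts[i]) {
      j <- sample(nrow(inner), 1)
      cand <- c(cr[i] + inner[j, 1], cc[i] + inner[j, 2])
      ok <- nrow(placed) == 0 ||
        all(pmax(abs(placed[, 1] - cand[1]),
                 abs(placed[, 2] - cand[2])) >= min_separation_px)
      if (ok) placed <- rbind(placed, cand)
      tries <- tries + 1
    }
    if (nrow(placed) < counts[i]) {
      merged[i] <- TRUE
      warning("nucleus ", i, " cannot hold ", counts[i], " puncta at ",
              "separation ", min_separation_px, " px; remaining spots merge")
      while (nrow(placed) < counts[i]) {   # place without separation
        j <- sample(nrow(inner), 1)
        placed <- rbind(placed, c(cr[i] + inner[j, 1],
                                  cc[i] + inner[j, 2]))
      }
    }
    spot_rows <- c(spot_rows, placed[, 1]); spot_cols <- c(spot_cols, placed[, 2])
  }

  spot_kernel <- gaussian_kernel(sd_px = 0.7, radius = 3L)
  sig_spots <- stamp_kernel(matrix(0, d[1], d[2]), spot_rows, spot_cols,
                            spot_kernel, 0.8)
  noise <- list(background = 0.05, read_sd = 0.015, shot_scale = 0.01)
  vegfa <- render_noise(pmin(sig_spots, 0.93), noise)
  hoechst <- render_noise((masks > 0) * 0.5, noise)
  img <- image_stack(array(c(vegfa, hoechst), c(d, 2L)),
                     c("Vegfa", "Hoechst"), pixel_size_um)

  nuclei <- data.frame(nucleus_id = seq_len(n_total), phenotype = phen,
                       row = cr, col = cc,
                       x_um = (cc - 0.5) * pixel_size_um,
                       y_um = (cr - 0.5) * pixel_size_um)
  truth <- data.frame(nucleus_id = seq_len(n_total), phenotype = phen,
                      true_count = counts, merged = merged,
                      rate = unname(mean_puncta[phen]))
  list(image = img, nucleus_masks = masks, nuclei = nuclei, truth = truth)
}

#' Generate a synthetic scratch-wound time series with ground truth
#'
#' The true cell-free area follows a linear closure trajectory,
#' `area(t) = area(0) * max(0, 1 - rate * t)` for each condition; observed
#' areas add multiplicative log-normal noise. Optionally renders each
#' timepoint as a bright-confluent-field image with a dark vertical
#' cell-free stripe of matching area.
#'
#' @param initial_area_um2 Scratch area at t = 0 (> 0).
#' @param closure_fraction_per_h Named numeric vector: fraction of the
#'   initial area closed per hour, per condition (0 = non-motile).
#' @param timepoints_h Numeric vector of imaging times; must include 0.
#' @param noise_cv Coefficient of variation of the multiplicative
#'   measurement noise (default 0.03); truth stores noiseless areas.
#' @param render Render images per timepoint (default TRUE).
#' @param image_size_px,pixel_size_um Rendered field geometry; defaults
#'   give a ~1 x 0.5 mm field at 2 µm/px.
#' @param seed Integer seed.
#' @return List: `areas` (condition, t_h, area_true_um2, area_um2),
#'   `images` (named list of [image_stack()] or NULL), `truth` (noiseless
#'   areas and configured rates).
#' @export
generate_scratch_series <- function(initial_area_um2,
                                    closure_fraction_per_h,
                                    timepoints_h = c(0, 1, 4, 8),
                                    noise_cv = 0.03,
                                    render = TRUE,
                                    image_size_px = c(256L, 512L),
                                    pixel_size_um = 2,
                                    seed = 1L) {
  stopifnot(initial_area_um2 > 0, 0 %in% timepoints_h,
            !is.null(names(closure_fraction_per_h)),
            all(closure_fraction_per_h >= 0))
  set.seed(as.integer(seed))
  conds <- names(closure_fraction_per_h)
  grid_df <- expand.grid(condition = conds, t_h = sort(timepoints_h),
                         stringsAsFactors = FALSE)
  grid_df$area_true_um2 <- initial_area_um2 *
    pmax(0, 1 - closure_fraction_per_h[grid_df$condition] * grid_df$t_h)
  noise_mult <- exp(rnorm(nrow(grid_df), 0, noise_cv))
  noise_mult[grid_df$t_h == 0] <- 1      # areas are normalized to t = 0
  grid_df$area_um2 <- grid_df$area_true_um2 * noise_mult

  images <- NULL
  if (render) {
    d <- image_size_px
    field_h_um <- d[1] * pixel_size_um
    images <- list()
    for (i in seq_len(nrow(grid_df))) {
      w_um <- grid_df$area_um2[i] / field_h_um
      w_px <- round(w_um / pixel_size_um)
      sig <- matrix(0.55, d[1], d[2])
      if (w_px > 0) {
        c0 <- round(d[2] / 2 - w_px / 2) + 1
        sig[, c0:(c0 + w_px - 1)] <- 0
      }
      img <- render_noise(sig, list(background = 0.05, read_sd = 0.02,
                                    shot_scale = 0.005))
      images[[paste0(grid_df$condition[i], "_t", grid_df$t_h[i])]] <-
        image_stack(img, "phase", pixel_size_um)
      # rendered stripe is quantized to whole pixel columns
      grid_df$area_um2[i] <- w_px * pixel_size_um * field_h_um
    }
  }
  list(areas = grid_df, images = images,
       truth = list(initial_area_um2 = initial_area_um2,
                    closure_fraction_per_h = closure_fraction_per_h,
                    areas_noiseless = grid_df[c("condition", "t_h",
                                                "area_true_um2")]))
}

#' Generate a synthetic attachment-assay plate with ground truth
#'
#' Wells come in adjacent vehicle/treated pairs (matching the paired-well
#' design that controls for plate-position handling forces). Each well gets
#' a pre-detachment nuclei image; the post-detachment image retains a
#' binomial draw of the same nuclei at the treatment's retention fraction,
#' in place (acquisition positions are registered by construction).
#'
#' @param n_pairs Number of adjacent well pairs (≥ 1).
#' @param cells_per_well Expected nuclei per well (Poisson).
#' @param retention Named fractions in `[0, 1]`: `c(vehicle = ...,
#'   treated = ...)`.
#' @param plate_id Plate/experiment label.
#' @param image_size_px,pixel_size_um Field geometry (default 384 px at
#'   2 µm/px ≈ 0.77 mm square).
#' @param nucleus_radius_um Rendered nucleus radius (default 5 µm).
#' @param seed Integer seed.
#' @return List: `wells` (list with `pre`/`post` [image_stack()]s per
#'   well), `table` (plate_id, pair_id, condition, true pre/post counts,
#'   true retention), `truth` (retention fractions).
#' @export
generate_attachment_plate <- function(n_pairs, cells_per_well = 1000,
                                      retention = c(vehicle = 0.8,
                                                    treated = 0.55),
                                      plate_id = "plate1",
                                      image_size_px = c(384L, 384L),
                                      pixel_size_um = 2,
                                      nucleus_radius_um = 5,
                                      seed = 1L) {
  stopifnot(n_pairs >= 1, all(retention >= 0 & retention <= 1),
            all(c("vehicle", "treated") %in% names(retention)))
  set.seed(as.integer(seed))
  d <- image_size_px
  r_px <- nucleus_radius_um / pixel_size_um
  pitch <- ceiling(2 * r_px + 4)
  nr_g <- (d[1] - pitch) %/% pitch
  nc_g <- (d[2] - pitch) %/% pitch
  n_sites <- nr_g * nc_g
  jit <- max(0L, (pitch - 2 * ceiling(r_px) - 2) %/% 2)
  dk <- disk_kernel(r_px)
  k <- (nrow(dk) - 1L) %/% 2L
  noise <- list(background = 0.05, read_sd = 0.02, shot_scale = 0.02)

  render_well <- function(rows, cols) {
    sig <- stamp_kernel(matrix(0, d[1], d[2]), rows, cols, dk, 0.6)
    image_stack(render_noise(pmin(sig, 0.9), noise), "Hoechst",
                pixel_size_um)
  }

  wells <- list(); tab <- list()
  for (p in seq_len(n_pairs)) {
    for (cond in c("vehicle", "treated")) {
      n_pre <- min(rpois(1, cells_per_well), n_sites)
      slots <- sample(n_sites, n_pre)
      gr <- (slots - 1) %/% nc_g + 1
      gc <- (slots - 1) %% nc_g + 1
      rows <- gr * pitch + sample(-jit:jit, n_pre, replace = TRUE)
      cols <- gc * pitch + sample(-jit:jit, n_pre, replace = TRUE)
      keep <- runif(n_pre) < retention[[cond]]
      wid <- sprintf("%s_p%02d_%s", plate_id, p, cond)
      wells[[wid]] <- list(pre = render_well(rows, cols),
                           post = render_well(rows[keep], cols[keep]),
                           pair_id = p, condition = cond)
      tab[[wid]] <- data.frame(plate_id = plate_id, pair_id = p,
                               well_id = wid, condition = cond,
                               true_pre = n_pre, true_post = sum(keep),
                               true_retention = retention[[cond]])
    }
  }
  list(wells = wells, table = do.call(rbind, c(tab, make.row.names = FALSE)),
       truth = list(retention = retention,
                    cells_per_well = cells_per_well))
}
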