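#' Scratch (cell-free) area of a wound-healing image
#'
#' Automated surrogate for manual outlining: pixels below an intensity
#' threshold are candidate cell-free space, and the scratch is the largest
#' connected background component; its area is returned in µm².
#'
#' On a fully confluent field any threshold merely splits the noise, so the
#' split is accepted only when the intensity contrast between the two
#' classes exceeds `min_contrast`; otherwise the image is called confluent
#' (area 0).
#'
#' @param img An [image_stack()].
#' @param channel Channel to analyse (default the first).
#' @param threshold `"otsu"` (default) or fixed numeric.
#' @param min_contrast Minimum between-class intensity contrast for a
#'   credible cell-free region (default 0.25, intensity units): an Otsu
#'   split of pure shot/read noise separates the class means by roughly
#'   1.6 noise SDs, well below this, while a genuine scratch separates by
#'   the full cell-to-substrate contrast.
#' @return List: `area_um2`, `params` (resolved threshold, component id).
#' @export
scratch_area <- function(img, channel = 1, threshold = "otsu",
                         min_contrast = 0.25) {
  stopifnot(inherits(img, "ImageStack"))
  x <- get_channel(img, channel)
  thr <- resolve_threshold(threshold, x)
  bg <- x < thr
  if (!any(bg) ||
      (any(bg) && any(!bg) && mean(x[!bg]) - mean(x[bg]) < min_contrast)) {
    warning("no credible cell-free region found; area 0")
    return(list(area_um2 = 0, params = list(threshold = thr)))
  }
  lab <- EBImage::imageData(EBImage::bwlabel(bg * 1))
  sizes <- tabulate(lab[lab > 0], nbins = max(lab))
  big <- which.max(sizes)
  list(area_um2 = sizes[big] * img$pixel_size_um^2,
       params = list(threshold = thr, component = big))
}

#' Scratch ingression per timepoint
#'
#' `ingression(t) = 1 - area(t) / area(0)`: 0 is no ingression, 1 is
#' complete closure. Values are not clamped; a widening scratch yields a
#' negative ingression, reported with a warning.
#'
#' @param series Data frame with columns `t_h` and `area_um2` (one well /
#'   condition), or additionally `condition` and/or `well_id` to stratify.
#' @return `series` with an `ingression` column.
#' @export
ingression <- function(series) {
  stopifnot(all(c("t_h", "area_um2") %in% names(series)),
            0 %in% series$t_h)
  key_cols <- intersect(c("condition", "well_id"), names(series))
  key <- if (length(key_cols) == 0) rep("all", nrow(series))
         else do.call(paste, c(series[key_cols], sep = "\r"))
  out <- series
  out$ingression <- NA_real_
  for (k in unique(key)) {
    i <- key == k
    a0 <- series$area_um2[i & series$t_h == 0]
    if (length(a0) != 1 || a0 <= 0)
      stop("each series needs exactly one positive area at t = 0")
    out$ingression[i] <- 1 - series$area_um2[i] / a0
  }
  if (any(out$ingression < 0))
    warning("negative ingression (scratch widened) at ",
            sum(out$ingression < 0), " timepoint(s)")
  out
}

#' Count nuclei in a thresholded image
#'
#' Threshold, connected components, size filter — the automated
#' particle-counting readout used for attachment assays.
#'
#' With an automatic threshold, an empty (nucleus-free) field would be
#' split along its own noise; the split is accepted only when the
#' between-class intensity contrast exceeds `min_contrast`, otherwise the
#' count is 0. A fixed numeric threshold is applied as given.
#'
#' @param img An [image_stack()].
#' @param channel Channel to count (default the first, e.g., `"Hoechst"`).
#' @param threshold `"otsu"` (default) or fixed numeric.
#' @param min_area_um2 Minimum particle area in µm² (default 20).
#' @param min_contrast Minimum between-class contrast for an automatic
#'   threshold to be credible (default 0.25, intensity units).
#' @return Integer count of components with area ≥ `min_area_um2`.
#' @export
count_nuclei <- function(img, channel = 1, threshold = "otsu",
                         min_area_um2 = 20, min_contrast = 0.25) {
  stopifnot(inherits(img, "ImageStack"), min_area_um2 >= 0)
  x <- get_channel(img, channel)
  thr <- resolve_threshold(threshold, x)
  bin <- x > thr
  if (!any(bin)) return(0L)
  if (!is.numeric(threshold) && any(!bin) &&
      mean(x[bin]) - mean(x[!bin]) < min_contrast)
    return(0L)
  lab <- EBImage::imageData(EBImage::bwlabel(bin * 1))
  sizes <- tabulate(lab[lab > 0], nbins = max(lab))
  sum(sizes * img$pixel_size_um^2 >= min_area_um2)
}

#' Percent of cells retained after detachment
#'
#' `100 * post / pre` for a well. Values above 100% are possible under
#' counting noise and are reported with a warning rather than clamped.
#'
#' @param pre_count,post_count Non-negative counts; `pre_count` must be
#'   positive (vectorized).
#' @return Percent retained.
#' @export
retention <- function(pre_count, post_count) {
  stopifnot(all(pre_count > 0), all(post_count >= 0))
  r <- 100 * post_count / pre_count
  if (any(r > 100))
    warning(sum(r > 100), " well(s) exceed 100% retention (counting noise)")
  r
}

#' Paired-well attachment effect with block statistics
#'
#' Wells are analysed in adjacent vehicle/treated pairs. Per pair the
#' treatment effect is `100 * (1 - treated_retention / vehicle_retention)`;
#' the summary is the mean ± SEM across pairs. The main effect of treatment
#' is tested across experiment blocks with a two-way ANOVA
#' (treatment x experiment) on well-level retention via [compare_groups()].
#'
#' @param wells Data frame with columns `experiment` (block), `pair_id`,
#'   `condition` (`"vehicle"`/`"treated"`), and either `retention_pct` or
#'   both `pre_count` and `post_count`.
#' @return List: `per_pair` (experiment, pair_id, vehicle/treated retention,
#'   percent_reduction), `mean_reduction`, `sem`, `n_pairs`, `stats`
#'   (a `StatsResult`, when ≥ 2 experiments or ≥ 2 pairs).
#' @export
paired_effect <- function(wells) {
  need <- c("experiment", "pair_id", "condition")
  stopifnot(all(need %in% names(wells)),
            all(wells$condition %in% c("vehicle", "treated")))
  if (!"retention_pct" %in% names(wells)) {
    stopifnot(all(c("pre_count", "post_count") %in% names(wells)))
    wells$retention_pct <- retention(wells$pre_count, wells$post_count)
  }
  keys <- unique(wells[c("experiment", "pair_id")])
  if (nrow(keys) < 2) stop("need at least 2 well pairs")
  per_pair <- do.call(rbind, lapply(seq_len(nrow(keys)), function(i) {
    sub <- wells[wells$experiment == keys$experiment[i] &
                   wells$pair_id == keys$pair_id[i], ]
    v <- sub$retention_pct[sub$condition == "vehicle"]
    t <- sub$retention_pct[sub$condition == "treated"]
    stopifnot(length(v) == 1, length(t) == 1)
    data.frame(experiment = keys$experiment[i], pair_id = keys$pair_id[i],
               vehicle_retention = v, treated_retention = t,
               percent_reduction = 100 * (1 - t / v))
  }))
  stats <- NULL
  if (length(unique(wells$experiment)) >= 2) {
    stats <- compare_groups(wells, "retention_pct", "condition",
                            factor2 = "experiment")
  } else {
    stats <- compare_groups(wells, "retention_pct", "condition")
  }
  list(per_pair = per_pair,
       mean_reduction = mean(per_pair$percent_reduction),
       sem = sd(per_pair$percent_reduction) / sqrt(nrow(per_pair)),
       n_pairs = nrow(per_pair),
       stats = stats)
}
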