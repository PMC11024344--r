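#' Detect puncta and count them per nucleus
#'
#' Automated surrogate for manual transcript-dot counting: puncta are local
#' intensity maxima above a threshold, with a minimum peak separation, each
#' assigned to the labelled nucleus containing it. Counting works on the 2D
#' (projected) image; spots merged below the minimum separation count once,
#' a documented undercount.
#'
#' @param img An [image_stack()].
#' @param puncta_channel Channel carrying the in situ signal (e.g.,
#'   `"Vegfa"`).
#' @param nucleus_masks Labelled integer matrix (0 = background, k = nucleus
#'   k); labels non-overlapping.
#' @param threshold `"otsu"` (default, on the channel's own range) or a
#'   fixed numeric value.
#' @param min_separation_px Minimum Chebyshev distance between detected
#'   peaks (default 2).
#' @return A `PunctaResult` list: `per_nucleus` data frame
#'   `(nucleus_id, puncta_count)` covering every label (zeros included),
#'   `n_outside` (peaks in no nucleus), `params`.
#' @export
detect_puncta <- function(img, puncta_channel, nucleus_masks,
                          threshold = "otsu", min_separation_px = 2L) {
  stopifnot(inherits(img, "ImageStack"),
            identical(dim(nucleus_masks), dim(img$pixels)[1:2]))
  x <- get_channel(img, puncta_channel)
  if (max(x) == min(x)) {
    warning("uniform puncta channel: no peaks detectable")
    n <- max(nucleus_masks)
    return(structure(list(per_nucleus = data.frame(
      nucleus_id = seq_len(n), puncta_count = integer(n)),
      n_outside = 0L, params = list(threshold = NA_real_,
                                    min_separation_px = min_separation_px)),
      class = "PunctaResult"))
  }
  thr <- resolve_threshold(threshold, x)
  peaks <- local_maxima(x, radius = as.integer(min_separation_px),
                        threshold = thr)
  lab <- nucleus_masks[peaks]
  n <- max(nucleus_masks)
  counts <- tabulate(lab[lab > 0], nbins = n)
  structure(list(per_nucleus = data.frame(nucleus_id = seq_len(n),
                                          puncta_count = counts),
                 n_outside = sum(lab == 0),
                 params = list(threshold = thr,
                               min_separation_px = min_separation_px)),
            class = "PunctaResult")
}

#' Percent difference in per-cell puncta between two phenotypes
#'
#' Per animal: `100 * (mean_b - mean_a) / mean_b`, where `b` is the explicit
#' reference phenotype (e.g., astrocytes) — the percent by which phenotype
#' `a` expresses fewer puncta per cell than the reference. The group value
#' is the mean ± SEM over animals.
#'
#' @param counts Data frame with columns `animal_id`, `phenotype`,
#'   `puncta_count` (one row per nucleus).
#' @param phenotype_a Phenotype being compared (e.g., `"RGL-NSC"`).
#' @param reference Reference phenotype `b` (e.g., `"astrocyte"`).
#' @return List: `per_animal` data frame `(animal_id, mean_a, mean_b,
#'   percent_difference)`, `mean`, `sem`, `n_animals`.
#' @export
percent_difference <- function(counts, phenotype_a, reference) {
  stopifnot(all(c("animal_id", "phenotype", "puncta_count") %in%
                  names(counts)))
  have <- unique(counts$phenotype)
  if (!phenotype_a %in% have || !reference %in% have)
    stop("both phenotypes must be present: missing ",
         paste(setdiff(c(phenotype_a, reference), have), collapse = ", "))
  per <- do.call(rbind, lapply(unique(counts$animal_id), function(aid) {
    sub <- counts[counts$animal_id == aid, ]
    ma <- mean(sub$puncta_count[sub$phenotype == phenotype_a])
    mb <- mean(sub$puncta_count[sub$phenotype == reference])
    data.frame(animal_id = aid, mean_a = ma, mean_b = mb,
               percent_difference = if (is.finite(mb) && mb > 0)
                 100 * (mb - ma) / mb else NA_real_)
  }))
  pd <- per$percent_difference[!is.na(per$percent_difference)]
  list(per_animal = per, mean = mean(pd),
       sem = if (length(pd) > 1) sd(pd) / sqrt(length(pd)) else NA_real_,
       n_animals = length(pd))
}
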