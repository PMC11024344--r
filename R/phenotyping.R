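#' Controlled phenotype vocabulary
#'
#' The niche phenotypes used throughout the package: radial glia-like neural
#' stem cells (RGL-NSC), intermediate progenitor cells (IPC), astrocytes,
#' neuroblasts (NB), immature neurons (IN), and a fall-through class (other).
#' @export
NICHE_PHENOTYPES <- c("RGL-NSC", "IPC", "astrocyte", "NB", "IN", "other")

# Column requirements per rule set.
.rule_columns <- list(
  reporter = c("EYFP", "GFAP", "MCM2", "DCX",
               "radial_process", "bipolar", "primary_dendrite", "in_sgz"),
  antigen  = c("GFAP", "SOX2", "DCX",
               "radial_process", "bipolar", "primary_dendrite", "in_sgz")
)

#' Assign niche phenotypes from marker calls and morphology flags
#'
#' Classifies every cell into exactly one label from [NICHE_PHENOTYPES],
#' applying the rules in a fixed priority order (RGL-NSC > IPC > NB > IN >
#' astrocyte > other) so that multi-positive cells resolve deterministically.
#'
#' Two rule sets ship:
#' \describe{
#'   \item{`reporter`}{lineage-reporter experiments: RGL-NSC = EYFP+/GFAP+
#'     with a radial process; IPC = EYFP+/MCM2+ in the SGZ; NB = DCX+ with
#'     bipolar morphology; IN = DCX+ with a primary dendrite; astrocyte =
#'     GFAP+ stellate (no radial process) outside the SGZ.}
#'   \item{`antigen`}{antigen-only labelling: RGL-NSC = GFAP+/SOX2+ with a
#'     radial process; IPC = GFAP-/SOX2+ in the SGZ; NB/IN as above;
#'     astrocyte = GFAP+/SOX2+ stellate outside the SGZ.}
#' }
#'
#' Marker columns are logical calls (manual annotation or [call_markers()]);
#' morphology arrives as flags (`radial_process`, `bipolar`,
#' `primary_dendrite`) — morphology inference from pixels is out of scope.
#'
#' @param cells Cell table (data frame) with the marker/morphology columns
#'   required by the rule set, plus `in_sgz`.
#' @param rules `"reporter"` or `"antigen"`.
#' @return `cells` with a `phenotype` factor column (levels
#'   [NICHE_PHENOTYPES]).
#' @export
classify_cells <- function(cells, rules = c("reporter", "antigen")) {
  rules <- match.arg(rules)
  need <- .rule_columns[[rules]]
  missing_cols <- setdiff(need, names(cells))
  if (length(missing_cols) > 0)
    stop("rule set '", rules, "' requires missing column(s): ",
         paste(missing_cols, collapse = ", "))
  b <- function(col) as.logical(cells[[col]]) %in% TRUE
  if (rules == "reporter") {
    is_rgl <- b("EYFP") & b("GFAP") & b("radial_process")
    is_ipc <- b("EYFP") & b("MCM2") & b("in_sgz")
    is_ast <- b("GFAP") & !b("radial_process") & !b("in_sgz")
  } else {
    is_rgl <- b("GFAP") & b("SOX2") & b("radial_process")
    is_ipc <- !b("GFAP") & b("SOX2") & b("in_sgz")
    is_ast <- b("GFAP") & b("SOX2") & !b("radial_process") & !b("in_sgz")
  }
  is_nb <- b("DCX") & b("bipolar")
  is_in <- b("DCX") & b("primary_dendrite")
  phen <- rep("other", nrow(cells))
  phen[is_ast] <- "astrocyte"
  phen[is_in]  <- "IN"
  phen[is_nb]  <- "NB"
  phen[is_ipc] <- "IPC"
  phen[is_rgl] <- "RGL-NSC"   # assigned last = highest priority
  cells$phenotype <- factor(phen, levels = NICHE_PHENOTYPES)
  cells
}

#' Call boolean markers from channel intensities at cell centroids
#'
#' Helper for tables that carry centroid coordinates but no manual marker
#' calls: for each requested channel, the mean intensity in a small square
#' neighbourhood around each centroid is compared against an Otsu threshold
#' over all cells' neighbourhood means.
#'
#' @param cells Cell table with `x_um`, `y_um`.
#' @param img An [image_stack()].
#' @param channels Channels to call (default: all in `img`).
#' @param radius_px Neighbourhood half-width in pixels (default 2).
#' @return `cells` with one logical column per called channel.
#' @export
call_markers <- function(cells, img, channels = NULL, radius_px = 2L) {
  stopifnot(inherits(img, "ImageStack"))
  channels <- channels %||% img$channel_names
  d <- dim(img$pixels)
  pix <- coords_to_pixels(cells$x_um, cells$y_um, d, img$pixel_size_um)
  for (ch in channels) {
    x <- get_channel(img, ch)
    vals <- vapply(seq_len(nrow(pix)), function(i) {
      rr <- max(1, pix[i, 1] - radius_px):min(d[1], pix[i, 1] + radius_px)
      cc <- max(1, pix[i, 2] - radius_px):min(d[2], pix[i, 2] + radius_px)
      mean(x[rr, cc])
    }, numeric(1))
    cells[[ch]] <- vals > otsu_threshold(matrix(vals))
  }
  cells
}

#' Per-animal phenotype composition
#'
#' Percent of cells of each phenotype within a denominator selection, per
#' animal — e.g., "percent of GFP+ cells of each phenotype". Over an
#' exhaustive phenotype partition the percentages sum to 100 per animal.
#'
#' @param cells Classified cell table (needs `animal_id`, `phenotype`).
#' @param phenotypes Phenotypes to report (default: all levels present).
#' @param denominator `NULL` for all cells, the name of a logical column
#'   (e.g., `"GFP"`), or a logical vector over rows.
#' @return Data frame `(animal_id, group, phenotype, n, n_denominator,
#'   percent)`; `percent` is `NA` for an animal with an empty denominator.
#' @export
composition <- function(cells, phenotypes = NULL, denominator = NULL) {
  stopifnot("phenotype" %in% names(cells), "animal_id" %in% names(cells))
  sel <- if (is.null(denominator)) rep(TRUE, nrow(cells))
         else if (is.character(denominator)) {
           stopifnot(denominator %in% names(cells))
           as.logical(cells[[denominator]]) %in% TRUE
         } else as.logical(denominator) %in% TRUE
  phenotypes <- phenotypes %||% unique(as.character(cells$phenotype))
  animals <- unique(cells$animal_id)
  grp <- if ("group" %in% names(cells))
    setNames(as.character(cells$group), cells$animal_id)[as.character(animals)]
    else rep(NA_character_, length(animals))
  out <- do.call(rbind, lapply(seq_along(animals), function(i) {
    a <- animals[i]
    rows <- cells$animal_id == a & sel
    nd <- sum(rows)
    if (nd == 0)
      warning("animal ", a, ": empty denominator; composition undefined")
    data.frame(animal_id = a, group = unname(grp[i]), phenotype = phenotypes,
               n = unname(vapply(phenotypes,
                                 function(p) sum(rows & cells$phenotype == p),
                                 numeric(1))),
               n_denominator = nd)
  }))
  out$percent <- ifelse(out$n_denominator > 0,
                        100 * out$n / out$n_denominator, NA_real_)
  rownames(out) <- NULL
  out
}

#' Count cells positive for two markers, per animal
#'
#' Co-labelling count (symmetric in its two arguments); zero is a valid and
#' often expected result (e.g., no CD31+/MCM2+ endothelia = no angiogenesis).
#'
#' @param cells Cell table with logical marker columns and `animal_id`.
#' @param marker_a,marker_b Marker column names.
#' @return Data frame `(animal_id, group, n_double_positive)`.
#' @export
count_colabeled <- function(cells, marker_a, marker_b) {
  stopifnot(marker_a %in% names(cells), marker_b %in% names(cells),
            "animal_id" %in% names(cells))
  pos <- (as.logical(cells[[marker_a]]) %in% TRUE) &
         (as.logical(cells[[marker_b]]) %in% TRUE)
  animals <- unique(cells$animal_id)
  grp <- if ("group" %in% names(cells))
    setNames(as.character(cells$group), cells$animal_id)[as.character(animals)]
    else rep(NA_character_, length(animals))
  data.frame(animal_id = animals, group = grp,
             n_double_positive = unname(vapply(animals,
               function(a) sum(pos & cells$animal_id == a), numeric(1))),
             row.names = NULL)
}

#' Read / write the cell-table CSV
#'
#' UTF-8 comma-separated schema: `cell_id, animal_id, group, x_um, y_um`,
#' logical marker columns, morphology flags, `in_sgz`, optional `phenotype`.
#'
#' @param cells Cell table.
#' @param path CSV path.
#' @return `path` invisibly (writer); the cell table (reader).
#' @export
write_cell_table <- function(cells, path) {
  write.csv(cells, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_cell_table
#' @export
read_cell_table <- function(path) {
  cells <- read.csv(path, stringsAsFactors = FALSE)
  if ("phenotype" %in% names(cells))
    cells$phenotype <- factor(cells$phenotype, levels = NICHE_PHENOTYPES)
  cells
}
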