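test_that("nearest-vessel distances follow closed forms and brute force", {
  m <- matrix(FALSE, 40, 40); m[20, 10] <- TRUE
  fld <- distance_field(vessel_mask(m, 0.5))
  cells <- data.frame(x_um = c(4.75, 4.75 + 10 * 0.5),
                      y_um = c(9.75, 9.75))
  d <- nearest_vessel_distance(cells, fld)
  expect_equal(d, c(0, 5))   # on the vessel; 10 px away at 0.5 um/px
  # 100 random cells on a random mask vs exhaustive search
  set.seed(19)
  m2 <- matrix(runif(1600) < 0.04, 40, 40)
  fld2 <- distance_field(vessel_mask(m2, 0.8))
  bf <- bf_distance_field(m2, 0.8)
  cells2 <- data.frame(x_um = runif(100, 0, 40 * 0.8),
                       y_um = runif(100, 0, 40 * 0.8))
  pix <- nichescape:::coords_to_pixels(cells2$x_um, cells2$y_um,
                                       c(40, 40), 0.8)
  expect_equal(nearest_vessel_distance(cells2, fld2), bf[pix])
})

test_that("empty vessel mask is a hard error for distance measurement", {
  suppressWarnings(fld <- distance_field(vessel_mask(matrix(FALSE, 5, 5), 1)))
  expect_error(nearest_vessel_distance(data.frame(x_um = 1, y_um = 1), fld),
               "segmentation")
})

test_that("systematic null sampling spaces points and maps to nuclei", {
  mid <- midline_polyline(cbind(c(0, 1000), c(50, 50)), 10)
  # nuclei exactly at every possible sample position on the midline
  nuclei <- data.frame(x_um = seq(0.5, 999.5, by = 0.5), y_um = 50)
  null1 <- sample_random_null(mid, nuclei, spacing_um = 100, seed = 1)
  expect_gte(nrow(null1), floor(1000 / 100) - 1)
  expect_lte(nrow(null1), 10)
  # consecutive picked nuclei sit ~100 um apart along the line
  expect_equal(diff(null1$arc_s_um), rep(100, nrow(null1) - 1))
  # identity: nuclei placed exactly at the sample points are returned
  expect_lt(max(abs(null1$x_um - null1$arc_s_um)), 0.5)
  # determinism
  null2 <- sample_random_null(mid, nuclei, spacing_um = 100, seed = 1)
  expect_identical(null1, null2)
  # a different seed moves the phase
  null3 <- sample_random_null(mid, nuclei, spacing_um = 100, seed = 2)
  expect_false(isTRUE(all.equal(null1$arc_s_um[1], null3$arc_s_um[1])))
})

test_that("null sampling skips gaps and rejects short midlines", {
  mid <- midline_polyline(cbind(c(0, 300), c(0, 0)), 10)
  nuclei <- data.frame(x_um = c(5, 8, 290), y_um = c(0, 2, 0))
  expect_warning(nullset <- sample_random_null(mid, nuclei, 100, seed = 3),
                 "skipped")
  expect_lte(nrow(nullset), 2)
  expect_error(sample_random_null(
    midline_polyline(cbind(c(0, 50), c(0, 0)), 10), nuclei, 100),
    "arc length")
  far <- data.frame(x_um = 150, y_um = 500)  # outside the band
  expect_error(sample_random_null(mid, far, 100, seed = 1), "band")
})

test_that("association index is zero against itself and recovers offsets", {
  m <- matrix(FALSE, 60, 60); m[30, ] <- TRUE
  fld <- distance_field(vessel_mask(m, 1))
  pts <- data.frame(animal_id = "m1", group = "WT",
                    x_um = seq(5, 50, by = 5), y_um = c(12, 18, 40, 33, 27,
                                                        9, 41, 22, 35, 14),
                    phenotype = "IPC")
  ai <- association_index(pts, pts, fld, "IPC")
  expect_equal(ai$association_index_um, 0)
  expect_equal(ai$n_cells, 10)
})

test_that("association index is invariant under rigid translation", {
  set.seed(33)
  m <- matrix(FALSE, 50, 80); m[matrix(c(sample(20, 30, TRUE) + 10,
                                         sample(60, 30, TRUE)), 30)] <- TRUE
  cells <- data.frame(animal_id = "m1", group = "WT",
                      x_um = runif(20, 5, 50), y_um = runif(20, 5, 40),
                      phenotype = "RGL-NSC")
  nullset <- data.frame(x_um = runif(8, 5, 50), y_um = runif(8, 5, 40))
  ai1 <- association_index(cells, nullset, distance_field(vessel_mask(m, 1)),
                           "RGL-NSC")
  # translate mask by (+5 px right, +3 px down) and all coordinates with it
  m2 <- matrix(FALSE, 50, 80)
  m2[(1:50) > 3, (1:80) > 5] <- m[1:47, 1:75]
  shift <- function(df) transform(df, x_um = x_um + 5, y_um = y_um + 3)
  ai2 <- association_index(shift(cells), shift(nullset),
                           distance_field(vessel_mask(m2, 1)), "RGL-NSC")
  expect_equal(ai2$association_index_um, ai1$association_index_um)
})

test_that("null mean is robust to nucleus density (systematic sampling)", {
  cfg <- niche_config(image_size_px = c(192L, 1024L),
                      n_cells_per_type = c("RGL-NSC" = 2L),
                      hoechst_density = 30, seed = 55)
  n <- generate_niche(cfg)
  fld <- distance_field(vessel_mask(n$truth$vessel_mask, cfg$pixel_size_um))
  # halve the nucleus density on the same vessel field by subsampling
  nuc_dense <- n$cells[n$cells$in_sgz, c("x_um", "y_um")]
  nuc_sparse <- nuc_dense[seq(1, nrow(nuc_dense), by = 2), ]
  d_dense <- nearest_vessel_distance(
    sample_random_null(n$midline, nuc_dense, 100, seed = 5), fld)
  d_sparse <- nearest_vessel_distance(
    sample_random_null(n$midline, nuc_sparse, 100, seed = 5), fld)
  null_se <- sd(d_dense) / sqrt(length(d_dense))
  expect_lt(abs(mean(d_dense) - mean(d_sparse)), null_se)
})

test_that("process contact detects touching and clear-by-construction cases", {
  m <- matrix(FALSE, 40, 40); m[20, 20] <- TRUE
  vm <- vessel_mask(m, 1)
  touching <- cbind(c(5, 19.5), c(5, 19.5))      # ends on the vessel pixel
  clear <- cbind(c(1, 10), c(1, 1))              # stays >= 18 px away
  res <- process_contact(list(a = touching, b = clear), vm)
  expect_true(res$contact[["a"]])
  expect_false(res$contact[["b"]])
  expect_equal(res$percent$percent, 50)
  # empty mask: no contact anywhere
  res0 <- suppressWarnings(
    process_contact(list(a = touching), vessel_mask(matrix(FALSE, 4, 4), 1)))
  expect_false(any(res0$contact))
  expect_equal(res0$percent$percent, 0)
})
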