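# Small, fast generator configuration used throughout: a 512 x 192 um
# field keeps single-niche tests quick while preserving the geometry.
small_cfg <- function(seed, offsets = NULL, n_cells = NULL, ...) {
  niche_config(image_size_px = c(192L, 512L),
               n_cells_per_type = n_cells %||%
                 c("RGL-NSC" = 25L, IPC = 30L, astrocyte = 10L, other = 5L),
               distance_offset_um = offsets,
               hoechst_density = 30, seed = seed, ...)
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("identical config and seed give bit-identical outputs", {
  cfg <- small_cfg(42)
  a <- generate_niche(cfg, group = "WT", animal_id = "m1")
  b <- generate_niche(cfg, group = "WT", animal_id = "m1")
  expect_identical(a$image$pixels, b$image$pixels)
  expect_identical(a$cells, b$cells)
  expect_identical(a$truth$vessel_mask, b$truth$vessel_mask)
})

test_that("truth distances equal brute force from the truth mask", {
  cfg <- niche_config(image_size_px = c(64L, 64L), pixel_size_um = 1,
                      band_halfwidth_um = 7.5, vessel_density = 0.03,
                      n_cells_per_type = c("RGL-NSC" = 10L, IPC = 10L),
                      hoechst_density = 20, seed = 9)
  n <- generate_niche(cfg)
  bf <- bf_distance_field(n$truth$vessel_mask, cfg$pixel_size_um)
  pix <- nichescape:::coords_to_pixels(n$cells$x_um, n$cells$y_um,
                                       dim(n$truth$vessel_mask),
                                       cfg$pixel_size_um)
  expect_lt(max(abs(n$truth$cells$true_dist_um - bf[pix])),
            cfg$pixel_size_um / 2)
})

test_that("zero offsets introduce no phenotype-vessel association", {
  # calibration invariant: across 20 seeds, realized offsets centre on 0
  real <- sapply(1:20, function(s) {
    n <- generate_niche(small_cfg(s))
    n$truth$offsets$offset_realized_um[n$truth$offsets$phenotype == "RGL-NSC"]
  })
  expect_lt(abs(mean(real)), 2 * sd(real) / sqrt(length(real)))
})

test_that("a configured IPC offset is realized in the truth records", {
  offs <- data.frame(phenotype = "IPC", group = "WT", offset_um = -3)
  cfg <- niche_config(distance_offset_um = offs,
                      n_cells_per_type = c(IPC = 500L),
                      hoechst_density = 30, seed = 77)
  n <- generate_niche(cfg, group = "WT")
  ipc_mean <- mean(n$truth$cells$true_dist_um[n$truth$cells$phenotype == "IPC"])
  baseline <- n$truth$baseline_mean_um
  expect_gt(ipc_mean - baseline, -3.5)
  expect_lt(ipc_mean - baseline, -2.5)
})

test_that("infeasible offsets fail with an informative error", {
  offs <- data.frame(phenotype = "RGL-NSC", group = "WT", offset_um = 500)
  cfg <- small_cfg(5, offsets = offs)
  expect_error(generate_niche(cfg, group = "WT"),
               "RGL-NSC.*outside the achievable range")
})

test_that("cohorts derive per-animal seeds and offsets deterministically", {
  cfg <- small_cfg(13)
  coh1 <- generate_cohort(cfg, groups = c("WT", "KD"),
                          n_animals_per_group = 2,
                          between_animal_sd_um = 0.5, seed = 13)
  coh2 <- generate_cohort(cfg, groups = c("WT", "KD"),
                          n_animals_per_group = 2,
                          between_animal_sd_um = 0.5, seed = 13)
  expect_identical(attr(coh1, "animals"), attr(coh2, "animals"))
  expect_identical(coh1[[3]]$image$pixels, coh2[[3]]$image$pixels)
  # zero between-animal SD: every animal carries the group offset exactly
  coh0 <- generate_cohort(cfg, groups = "WT", n_animals_per_group = 3,
                          between_animal_sd_um = 0, seed = 2)
  expect_equal(attr(coh0, "animals")$offset_shift_um, rep(0, 3))
})

test_that("cohort truth reproduces a configured group offset difference", {
  offs <- offsets_table(rgl_kd = 0, ipc_kd = 3.565)
  cfg <- small_cfg(31, offsets = offs)
  coh <- generate_cohort(cfg, groups = c("WT", "KD"),
                         n_animals_per_group = 8,
                         between_animal_sd_um = 0.8, seed = 31)
  plan <- attr(coh, "animals")
  per_animal <- sapply(coh, function(n) {
    i <- n$truth$cells$phenotype == "IPC"
    mean(n$truth$cells$true_dist_um[i]) - n$truth$baseline_mean_um
  })
  diff <- mean(per_animal[plan$group == "KD"]) -
    mean(per_animal[plan$group == "WT"])
  sem <- sqrt(var(per_animal[plan$group == "KD"]) / 8 +
                var(per_animal[plan$group == "WT"]) / 8)
  expect_lt(abs(diff - 3.565), 2 * sem)
})

test_that("generated cells appear exactly once with non-negative distances", {
  n <- generate_niche(small_cfg(3))
  expect_false(anyDuplicated(n$cells$cell_id) > 0)
  expect_identical(nrow(n$cells), nrow(n$truth$cells))
  expect_true(all(n$truth$cells$true_dist_um >= 0))
  expect_true(all(n$cells$Hoechst))
})
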