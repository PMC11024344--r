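test_that("elongation filter keeps tubes and rejects punctate dots", {
  img <- tube_and_dots_image()
  vm <- segment_vessels(img, "CD31", threshold = 0.5, min_area_um2 = 0,
                        min_elongation = 2.5)
  truth_tube <- matrix(FALSE, 60, 120); truth_tube[28:32, 10:110] <- TRUE
  expect_identical(vm$mask, truth_tube)
  # with the elongation filter relaxed, the dots come back
  vm2 <- segment_vessels(img, "CD31", threshold = 0.5, min_area_um2 = 0,
                         min_elongation = 1)
  expect_gt(sum(vm2$mask), sum(vm$mask))
})

test_that("blank and identity segmentation edge cases", {
  blank <- mat_image(matrix(0, 30, 30), channel = "CD31")
  expect_warning(vm <- segment_vessels(blank, "CD31"), "empty")
  expect_false(any(vm$mask))
  # truth raster fed back as intensity with a fixed threshold is recovered
  set.seed(4)
  cfg <- niche_config(image_size_px = c(96L, 256L),
                      n_cells_per_type = c("RGL-NSC" = 2L),
                      hoechst_density = 5, seed = 4)
  truth <- generate_niche(cfg)$truth$vessel_mask
  img <- mat_image(truth * 1, cfg$pixel_size_um, "CD31")
  vm <- segment_vessels(img, "CD31", threshold = 0.5, min_area_um2 = 0,
                        min_elongation = 1)
  expect_identical(vm$mask, truth)
  expect_equal(vm$params$threshold, 0.5)
})

test_that("distance field is exact: closed forms and brute force", {
  m <- matrix(FALSE, 9, 15); m[5, 3] <- TRUE
  fld <- distance_field(vessel_mask(m, 0.5))
  expect_equal(fld$dist[5, 3], 0)
  expect_equal(fld$dist[5, 3 + 7], 7 * 0.5)
  expect_equal(fld$dist[5 + 3, 3 + 4], 5 * 0.5)
  # all-true mask: identically zero
  expect_true(all(distance_field(vessel_mask(matrix(TRUE, 6, 6), 1))$dist == 0))
  # random mask vs exhaustive search
  set.seed(11)
  m2 <- matrix(runif(30 * 30) < 0.05, 30, 30)
  fld2 <- distance_field(vessel_mask(m2, 0.7))
  expect_equal(fld2$dist, bf_distance_field(m2, 0.7))
})

test_that("empty mask distances are flagged undefined", {
  expect_warning(fld <- distance_field(vessel_mask(matrix(FALSE, 5, 5), 1)),
                 "empty")
  expect_true(fld$empty)
  expect_true(all(is.infinite(fld$dist)))
})

test_that("adding vessel pixels never increases any distance", {
  set.seed(21)
  for (i in 1:10) {
    m <- matrix(runif(40 * 40) < 0.02, 40, 40)
    if (!any(m)) m[20, 20] <- TRUE
    extra <- m | (matrix(runif(40 * 40) < 0.02, 40, 40))
    d1 <- distance_field(vessel_mask(m, 1))$dist
    d2 <- distance_field(vessel_mask(extra, 1))$dist
    expect_true(all(d2 <= d1 + 1e-12))
  }
})

test_that("percent area: half-covered rectangle, empty mask, bounds", {
  regions <- region_map(list(box = cbind(c(0, 10, 10, 0), c(0, 0, 10, 10))))
  m <- matrix(FALSE, 12, 12); m[1:5, 1:10] <- TRUE  # top half of the box
  pa <- percent_area(vessel_mask(m, 1), regions)
  expect_equal(pa$percent, 50)
  pa0 <- percent_area(vessel_mask(matrix(FALSE, 12, 12), 1), regions)
  expect_equal(pa0$percent, 0)
  # percent stays in [0, 100] for arbitrary masks
  set.seed(3)
  for (i in 1:5) {
    mr <- matrix(runif(144) < runif(1), 12, 12)
    p <- percent_area(vessel_mask(mr, 1), regions)$percent
    expect_gte(p, 0); expect_lte(p, 100)
  }
})

test_that("rendered tube area matches its analytic area within a boundary band", {
  # vertical tube of radius r centred at column c0: analytic area 2r * height
  nr <- 80; nc <- 80; psz <- 0.5
  centre_x <- 20.25; r_um <- 3
  ctr <- nichescape:::pixel_grid_centers(c(nr, nc), psz)
  m <- matrix(abs(ctr$x - centre_x) <= r_um, nr, nc)
  regions <- region_map(list(all = cbind(c(0, 40, 40, 0), c(0, 0, 40, 40))))
  pa <- percent_area(vessel_mask(m, psz), regions)
  analytic_pct <- 100 * (2 * r_um * 40) / (40 * 40)
  # one pixel-boundary band of error on each tube edge
  band_pct <- 100 * (2 * psz * 40) / (40 * 40)
  expect_lt(abs(pa$percent - analytic_pct), band_pct)
})

test_that("overlap fraction: identity, disjoint, brute force", {
  set.seed(8)
  den <- matrix(runif(2500) < 0.3, 50, 50)
  num <- matrix(runif(2500) < 0.3, 50, 50)
  vm_d <- vessel_mask(den, 1); vm_n <- vessel_mask(num, 1)
  expect_equal(overlap_fraction(vm_d, vm_d)$percent, 100)
  disjoint <- vessel_mask(!den, 1)
  expect_equal(overlap_fraction(disjoint, vm_d)$percent, 0)
  expect_equal(overlap_fraction(vm_n, vm_d)$percent,
               100 * sum(num & den) / sum(den))
  # undefined where the denominator is empty
  empty <- vessel_mask(matrix(FALSE, 50, 50), 1)
  expect_true(is.na(overlap_fraction(vm_n, empty)$percent))
})
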