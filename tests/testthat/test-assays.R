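test_that("scratch area matches the analytic stripe area", {
  # 60-px-wide dark stripe in a 200x150 px field at 2 um/px
  x <- matrix(0.6, 150, 200); x[, 71:130] <- 0.05
  img <- mat_image(x, 2, "phase")
  res <- scratch_area(img, threshold = 0.3)
  expect_equal(res$area_um2, 60 * 150 * 4)
  # determinism: same image, same area
  expect_equal(scratch_area(img, threshold = 0.3)$area_um2, res$area_um2)
})

test_that("a confluent field has no credible scratch", {
  set.seed(17)
  x <- matrix(0.55 + rnorm(150 * 200, 0, 0.05), 150, 200)
  img <- mat_image(pmax(x, 0), 2, "phase")
  expect_warning(res <- scratch_area(img), "no credible")
  expect_equal(res$area_um2, 0)
})

test_that("rendered scratch series areas are recovered across timepoints", {
  s <- generate_scratch_series(1e5, c(vehicle = 1 / 8, SU5416 = 0.05),
                               c(0, 1, 4, 8), seed = 2)
  measured <- vapply(seq_len(nrow(s$areas)), function(i) {
    key <- paste0(s$areas$condition[i], "_t", s$areas$t_h[i])
    suppressWarnings(scratch_area(s$images[[key]])$area_um2)
  }, numeric(1))
  expect_equal(measured, s$areas$area_um2)
})

test_that("ingression follows the normalization formula exactly", {
  ser <- data.frame(t_h = c(0, 1, 4, 8),
                    area_um2 = c(1000, 1000, 250, 0))
  out <- ingression(ser)
  expect_equal(out$ingression, c(0, 0, 0.75, 1))
  # a widening scratch is reported, flagged, not clamped
  wid <- data.frame(t_h = c(0, 2), area_um2 = c(1000, 1200))
  expect_warning(out2 <- ingression(wid), "widened")
  expect_equal(out2$ingression, c(0, -0.2))
  expect_true(all(out$ingression <= 1))
  # quiescent-style series: zero closure at every timepoint out to 30 h
  q <- generate_scratch_series(1e5, c(quiescent = 0), c(0, 1, 4, 8, 30),
                               render = FALSE, seed = 4)
  expect_true(all(q$truth$areas_noiseless$area_true_um2 == 1e5))
})

test_that("nuclei counting matches truth and brute-force enumeration", {
  blank <- mat_image(matrix(0, 40, 40), 2, "Hoechst")
  expect_equal(count_nuclei(blank, threshold = 0.3), 0L)
  # 200 non-touching nuclei from the generator are counted exactly
  p <- generate_attachment_plate(1, 200, c(vehicle = 1, treated = 1),
                                 seed = 12)
  w <- p$wells[[1]]
  expect_equal(count_nuclei(w$pre), p$table$true_pre[1])
  # two merged nuclei resolve as one component (documented undercount)
  x <- matrix(0.02, 30, 30)
  dk <- nichescape:::disk_kernel(3)
  x <- nichescape:::stamp_kernel(x, c(15, 15), c(12, 17), dk, 0.8)
  expect_equal(count_nuclei(mat_image(pmin(x, 1), 1, "Hoechst"),
                            threshold = 0.4, min_area_um2 = 5), 1L)
  # random binary fields: component count equals exhaustive flood fill
  set.seed(26)
  for (i in 1:6) {
    b <- matrix(runif(32 * 32) < 0.2, 32, 32)
    img <- mat_image(b * 0.9, 1, "Hoechst")
    expect_equal(count_nuclei(img, threshold = 0.5, min_area_um2 = 0),
                 bf_count_components(b))
  }
})

test_that("retention arithmetic, warnings and guards", {
  expect_equal(retention(1000, 1000), 100)
  expect_equal(retention(1000, 0), 0)
  expect_equal(retention(1000, 690), 69)
  expect_warning(r <- retention(100, 104), "100%")
  expect_equal(r, 104)
  expect_error(retention(0, 5))
})

test_that("retention recovery from binomial draws is unbiased", {
  set.seed(61)
  for (p in c(0.1, 0.3, 0.5, 0.7, 0.9)) {
    pre <- rpois(200, 1000)
    post <- rbinom(200, pre, p)
    est <- mean(retention(pre, post))
    expect_lt(abs(est - 100 * p), 1)   # within one percentage point
  }
})

test_that("paired-well effect recovers a configured reduction", {
  # zero effect: identical retention in both wells of every pair
  wells0 <- data.frame(experiment = rep(1:2, each = 4),
                       pair_id = rep(1:2, 2, each = 2),
                       condition = rep(c("vehicle", "treated"), 4),
                       retention_pct = 80)
  pe0 <- paired_effect(wells0)
  expect_equal(pe0$mean_reduction, 0)
  # images end to end: one plate, known truth
  p <- generate_attachment_plate(3, 400,
                                 c(vehicle = 0.8, treated = 0.8 * 0.69),
                                 seed = 21)
  wells <- do.call(rbind, lapply(names(p$wells), function(wid) {
    w <- p$wells[[wid]]
    data.frame(experiment = "e1", pair_id = w$pair_id,
               condition = w$condition,
               pre_count = count_nuclei(w$pre),
               post_count = count_nuclei(w$post))
  }))
  pe <- paired_effect(wells)
  expect_equal(pe$n_pairs, 3)
  sem <- sd(pe$per_pair$percent_reduction) / sqrt(3)
  expect_lt(abs(pe$mean_reduction - 31), max(3 * sem, 5))
})

test_that("full retention keeps every nucleus and zero retention none", {
  p <- generate_attachment_plate(1, 150, c(vehicle = 1, treated = 0),
                                 seed = 33)
  veh <- p$wells[[grep("vehicle", names(p$wells))]]
  tr <- p$wells[[grep("treated", names(p$wells))]]
  expect_equal(count_nuclei(veh$post), count_nuclei(veh$pre))
  expect_equal(count_nuclei(tr$post), 0L)
  expect_equal(p$table$true_post[p$table$condition == "treated"], 0L)
})
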