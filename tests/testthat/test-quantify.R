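test_that("cylindrical ROI volume matches the analytic cylinder", {
  grid <- make_vol(c(40, 40, 120), spacing = rep(0.5, 3), constant = 0)
  roi <- build_segment_roi(grid, landmark = c(10, 10, 2), direction = c(0, 0, 1),
                           length_mm = 50, radius_mm = 5,
                           label = "distal_aorta", region = "aorto_iliac")
  vol <- measure_volume(roi$mask, grid$spacing)
  expect_lt(abs(vol - pi * 25 * 50) / (pi * 25 * 50), 0.03)
})

test_that("ROI construction validates geometry", {
  grid <- make_vol(c(20, 20, 20), spacing = rep(0.5, 3), constant = 0)
  expect_error(build_segment_roi(grid, c(5, 5, 1), c(0, 0, 1), 0, 2,
                                 "distal_aorta", "aorto_iliac"), "positive")
  expect_error(build_segment_roi(grid, c(5, 5, 1), c(0, 0, 0), 10, 2,
                                 "distal_aorta", "aorto_iliac"), "nonzero")
  expect_error(build_segment_roi(grid, c(100, 100, 100), c(0, 0, 1), 5, 1,
                                 "distal_aorta", "aorto_iliac"), "outside")
  # opposite directions from one landmark give disjoint proximal/distal masks
  up <- build_segment_roi(grid, c(5, 5, 5), c(0, 0, 1), 4, 2,
                          "common_femoral_proximal_L", "ilio_femoral")
  dn <- build_segment_roi(grid, c(5, 5, 4.9), c(0, 0, -1), 4, 2,
                          "superficial_femoral_distal_L", "ilio_femoral")
  expect_false(any(up$mask & dn$mask))
})

test_that("CT segmentation applies a strict 560 HU threshold", {
  dims <- c(20, 20, 20)
  grid <- make_vol(dims, spacing = rep(0.5, 3), constant = 300, modality = "CT")
  roi <- build_segment_roi(grid, c(5, 5, 1), c(0, 0, 1), 8, 4,
                           "distal_aorta", "aorto_iliac")
  expect_equal(measure_volume(segment_ct(grid, roi), grid$spacing), 0)

  # exactly 80 ROI voxels at 900 HU -> 80 * 0.125 = 10 mm^3
  idx <- which(roi$mask)[1:80]
  grid$data[idx] <- 900
  mask <- segment_ct(grid, roi)
  expect_equal(sum(mask), 80L)
  expect_equal(measure_volume(mask, grid$spacing), 10)

  # boundary value 560 is excluded (strict inequality)
  grid$data[idx] <- 560
  expect_equal(sum(segment_ct(grid, roi)), 0L)

  mr <- make_vol(dims, spacing = rep(0.5, 3), constant = 100, modality = "MR")
  expect_error(segment_ct(mr, roi), "CT")
})

test_that("MR two-pass rule classifies dark voxels against a constant background", {
  dims <- c(20, 20, 20)
  vol <- make_vol(dims, spacing = rep(0.5, 3), constant = 100, modality = "MR")
  roi <- build_segment_roi(vol, c(5, 5, 1), c(0, 0, 1), 8, 4,
                           "common_femoral_proximal_L", "ilio_femoral")
  # 50 dark voxels: pass 1 classifies them, pass 2 background is constant
  # (sigma = 0) so the final threshold is the background mean itself
  idx <- which(roi$mask)[seq(1, 300, by = 6)[1:50]]
  vol$data[idx] <- 0
  res <- segment_mr(vol, roi)
  expect_equal(sum(res$mask), 50L)
  expect_equal(measure_volume(res$mask, vol$spacing), 6.25)
  expect_equal(res$sigma, 0)
  expect_equal(res$mu, 100)

  # fully constant ROI is degenerate: empty mask with a warning
  vol$data[idx] <- 100
  expect_warning(res0 <- segment_mr(vol, roi), "degenerate")
  expect_equal(sum(res0$mask), 0L)
})

test_that("MR pass-1 false-positive fraction matches the normal tail", {
  dims <- c(50, 50, 80)
  vol <- scalar_volume(
    withr::with_seed(9, array(stats::rnorm(prod(dims), 100, 10), dims)),
    rep(0.5, 3), modality = "MR")
  roi <- build_segment_roi(vol, c(12.5, 12.5, 1), c(0, 0, 1), 36, 11,
                           "common_femoral_proximal_L", "ilio_femoral")
  expect_gt(sum(roi$mask), 1e5)
  res <- segment_mr(vol, roi)
  frac1 <- res$pass1$n_classified / sum(roi$mask)
  expect_gt(frac1, stats::pnorm(-3) / 2)
  expect_lt(frac1, stats::pnorm(-3) * 2)
})

test_that("k = 2 masks contain k = 3 masks", {
  dims <- c(24, 24, 24)
  vol <- scalar_volume(
    withr::with_seed(4, array(stats::rnorm(prod(dims), 100, 10), dims)),
    rep(0.5, 3), modality = "MR")
  roi <- build_segment_roi(vol, c(6, 6, 1), c(0, 0, 1), 10, 5,
                           "distal_aorta", "aorto_iliac")
  m2 <- segment_mr(vol, roi, threshold_policy(k_aorto_iliac = 2))$mask
  m3 <- segment_mr(vol, roi, threshold_policy(k_aorto_iliac = 3))$mask
  expect_true(all(m3[m2 == FALSE] == FALSE))
  expect_true(all(m2[m3] == TRUE))
})

test_that("threshold monotonicity: stricter thresholds never grow the volume", {
  ex <- make_tiny_exam(seed = 21)
  ex$ct$data[which(ex$rois[[1]]$mask)[1:40]] <- 800
  ex$mr$data[which(ex$rois[[2]]$mask)[1:40]] <- 10
  ct_vols <- sapply(c(400, 560, 700, 900),
                    function(cut) sum(segment_ct(ex$ct, ex$rois[[1]],
                                                 threshold_policy(ct_hu_cutoff = cut))))
  expect_true(all(diff(ct_vols) <= 0))
  mr_vols <- sapply(c(1.5, 2, 3, 4),
                    function(k) sum(segment_mr(ex$mr, ex$rois[[2]],
                                               threshold_policy(k_ilio_femoral = k))$mask))
  expect_true(all(diff(mr_vols) <= 0))
})

test_that("volume measurement enforces the isotropic-grid precondition", {
  m <- array(FALSE, c(3, 3, 3)); m[1:8] <- TRUE
  expect_equal(measure_volume(m, rep(0.5, 3)), 1)
  expect_equal(measure_volume(array(FALSE, c(3, 3, 3)), rep(0.5, 3)), 0)
  m1000 <- array(TRUE, c(10, 10, 10))
  expect_equal(measure_volume(m1000, rep(0.5, 3)), 125)
  expect_error(measure_volume(m, c(1, 1, 1.3)), "isotropic")
})

test_that("severity classification follows the CTA volume bands", {
  expect_identical(classify_severity(c(0, 99, 99.9)), rep(1L, 3))
  expect_identical(classify_severity(c(100, 150, 299.9)), rep(2L, 3))
  expect_identical(classify_severity(c(300, 1000)), rep(3L, 2))
  expect_error(classify_severity(-1), "non-negative")
})

test_that("exam quantification books segments, severity and exclusions", {
  ex <- make_tiny_exam(seed = 2)
  tab <- quantify_exam(ex$ct, ex$mr, ex$rois, exam_id = "e1")
  expect_equal(nrow(tab), 2L * length(ex$rois))
  expect_setequal(unique(tab$segment), ex$labels)
  expect_true(all(!tab$excluded))
  # severity group equals the classification of the CT row's volume
  ct_rows <- tab[tab$modality == "CT", ]
  expect_identical(ct_rows$group, classify_severity(ct_rows$volume_mm3))

  excl <- data.frame(segment = ex$labels[2], reason = "susceptibility artifact")
  tab2 <- quantify_exam(ex$ct, ex$mr, ex$rois, exclusions = excl, exam_id = "e1")
  ex_rows <- tab2[tab2$segment == ex$labels[2], ]
  expect_true(all(ex_rows$excluded))
  expect_true(all(is.na(ex_rows$volume_mm3)))
  # analyzed + excluded = available
  expect_equal(sum(!tab2$excluded) / 2 + sum(tab2$excluded) / 2, length(ex$rois))

  expect_equal(nrow(quantify_exam(ex$ct, ex$mr, list(), exam_id = "e")), 0L)
  expect_error(quantify_exam(ex$ct, ex$mr, ex$rois[c(1, 1)]), "repeated")
  expect_error(quantify_exam(ex$ct, ex$mr, ex$rois,
                             exclusions = data.frame(segment = "nope",
                                                     reason = "x")), "not among")
})

test_that("noise-free recovery is exact at analysis resolution and improves with refinement", {
  coh <- phantom_cohort(2, spacing = rep(0.5, 3), psf_fwhm_mm = 0,
                        surface_layer_mm = 0, ct_noise_sd = 0,
                        mr_noise_sd = 0, seed = 31)
  tab <- suppressWarnings(quantify_cohort(coh))
  mr <- tab[tab$modality == "MR" & tab$true_voxel_mm3 >= 30, ]
  expect_gt(nrow(mr), 0)
  expect_lt(max(abs(mr$volume_mm3 - mr$true_voxel_mm3) / mr$true_voxel_mm3), 0.05)

  # native anisotropic rendering (interpolated) has larger error
  coh_n <- phantom_cohort(2, psf_fwhm_mm = 0, surface_layer_mm = 0,
                          ct_noise_sd = 0, mr_noise_sd = 0, seed = 31)
  tab_n <- suppressWarnings(quantify_cohort(coh_n))
  mr_n <- tab_n[tab_n$modality == "MR" & tab_n$true_voxel_mm3 >= 30, ]
  err_fine <- max(abs(mr$volume_mm3 - mr$true_voxel_mm3) / mr$true_voxel_mm3)
  err_coarse <- max(abs(mr_n$volume_mm3 - mr_n$true_voxel_mm3) / mr_n$true_voxel_mm3)
  expect_gte(err_coarse, err_fine)
})

test_that("paired_volumes pivots to one row per analyzed segment", {
  ex <- make_tiny_exam(seed = 6)
  tab <- quantify_exam(ex$ct, ex$mr, ex$rois, exam_id = "e1")
  pv <- paired_volumes(tab, field_strength = "3T")
  expect_equal(nrow(pv), length(ex$rois))
  expect_true(all(c("cta_mm3", "mr_mm3", "group", "field_strength") %in% names(pv)))
})
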