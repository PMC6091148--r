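test_that("voxelized truth converges to the analytic ellipsoid volume", {
  # sphere r = 3 mm: analytic 4/3*pi*27 = 113.097 mm^3
  spec <- make_sphere_spec(r_mm = 3, spacing = rep(0.25, 3))
  tr <- voxelize_truth(spec)
  expect_equal(tr$deposits$analytic_mm3, 4 / 3 * pi * 27, tolerance = 1e-12)
  expect_lt(abs(tr$deposits$voxel_mm3 - 113.097) / 113.097, 0.02)

  # refinement: coarser grid has larger (or equal) voxelization error
  err <- sapply(c(1.0, 0.5, 0.25), function(sp) {
    t2 <- voxelize_truth(make_sphere_spec(r_mm = 3, spacing = rep(sp, 3)))
    abs(t2$deposits$voxel_mm3 - 4 / 3 * pi * 27)
  })
  expect_true(all(diff(err) <= 0))
})

test_that("ground truth is additive over disjoint deposits and empty for none", {
  spec <- make_sphere_spec()
  spec$deposits <- tibble::tibble(
    deposit_id = 1:2, segment = c("s1", "s1"),
    cx = c(7, 17), cy = c(12, 12), cz = c(12, 12),
    a = c(2, 2.5), b = c(2, 2), c = c(2, 2))
  tr <- voxelize_truth(spec)
  expect_equal(tr$segments$voxel_mm3, sum(tr$deposits$voxel_mm3))

  spec$deposits <- spec$deposits[0, ]
  tr0 <- voxelize_truth(spec)
  expect_equal(nrow(tr0$deposits), 0L)
  expect_true(all(tr0$label == 0L))
})

test_that("phantom_spec enforces contrast and containment invariants", {
  spec <- make_sphere_spec()
  expect_s3_class(spec, "phantom_spec")
  expect_error(phantom_spec(spec$shape, spec$spacing, spec$vessels,
                            spec$deposits,
                            ct_model = list(soft_hu = 50, lumen_hu = 600,
                                            calcium_hu = 1200,
                                            psf_fwhm_mm = 0, noise_sd = 0),
                            mr_model = spec$mr_model), "560")
  dep_out <- spec$deposits
  dep_out$cx <- 100
  expect_error(phantom_spec(spec$shape, spec$spacing, spec$vessels, dep_out,
                            spec$ct_model, spec$mr_model), "outside")
})

test_that("noise-free CT render is piecewise constant and matches truth", {
  spec <- make_sphere_spec(fwhm = 0, ct_noise = 0)
  ct <- render_ct(spec)
  tr <- voxelize_truth(spec)
  expect_identical(ct$modality, "CT")
  expect_true(all(ct$data[tr$label == 1L] == 1200))
  expect_setequal(unique(as.vector(ct$data)), c(50, 300, 1200))
  expect_equal(sum(ct$data > 560), tr$deposits$voxel_count)
})

test_that("CT blooming enlarges the suprathreshold region monotonically", {
  truth_n <- voxelize_truth(make_sphere_spec())$deposits$voxel_count
  counts <- sapply(c(0, 0.5, 1.0, 1.5), function(fw) {
    sum(render_ct(make_sphere_spec(fwhm = fw, ct_noise = 0))$data > 560)
  })
  expect_gt(counts[3], truth_n)          # FWHM 1.0 blooms beyond the truth
  expect_true(all(diff(counts) >= 0))    # never shrinks as the PSF widens
})

test_that("MR render darkens the eroded deposit core", {
  spec <- make_sphere_spec(r_mm = 4, layer = 0, mr_noise = 0)
  mr <- render_mr(spec)
  tr <- voxelize_truth(spec)
  expect_identical(mr$modality, "MR")
  expect_true(all(mr$data[tr$label == 1L] == 0))

  # 0.5 mm layer on a 4 mm sphere: dark core ~ 4/3*pi*3.5^3 = 179.6 mm^3
  spec05 <- make_sphere_spec(r_mm = 4, layer = 0.5, mr_noise = 0)
  dark <- sum(render_mr(spec05)$data < 50) * prod(spec05$spacing)
  expect_lt(dark, tr$deposits$voxel_mm3)
  expect_lt(abs(dark - 4 / 3 * pi * 3.5^3) / (4 / 3 * pi * 3.5^3), 0.05)

  # increasing layer never grows the dark core
  darks <- sapply(c(0, 0.4, 0.8, 1.2), function(l) {
    sum(render_mr(make_sphere_spec(r_mm = 4, layer = l, mr_noise = 0))$data < 50)
  })
  expect_true(all(diff(darks) <= 0))

  # layer at least the smallest semi-axis: deposit vanishes with a warning
  expect_warning(big <- render_mr(make_sphere_spec(r_mm = 1.5, layer = 1.5)),
                 "rendered empty")
  expect_true(all(big$data == 100))
})

test_that("renders are seed-reproducible and noise is separable", {
  s1 <- make_sphere_spec(ct_noise = 10, mr_noise = 10, seed = 7)
  s2 <- make_sphere_spec(ct_noise = 10, mr_noise = 10, seed = 8)
  expect_identical(render_ct(s1)$data, render_ct(s1)$data)
  expect_false(identical(render_ct(s1)$data, render_ct(s2)$data))
  # deterministic part is independent of the seed
  expect_identical(render_ct(s1, add_noise = FALSE)$data,
                   render_ct(s2, add_noise = FALSE)$data)
  expect_identical(render_mr(s1, add_noise = FALSE)$data,
                   render_mr(s2, add_noise = FALSE)$data)
})

test_that("rendered MR noise has the stated SD over the background", {
  spec <- make_sphere_spec(mr_noise = 10, extent = c(16, 16, 16),
                           spacing = rep(0.5, 3))
  spec$deposits <- spec$deposits[0, ]
  mr <- render_mr(spec)
  expect_gt(length(mr$data), 1e4)
  expect_lt(abs(stats::sd(mr$data) - 10) / 10, 0.05)
})

test_that("simulated ratings follow the stated agreement structure", {
  r1 <- simulate_ratings(50, agreement = 1, seed = 3)
  expect_identical(r1$reader1, r1$reader2)
  expect_equal(weighted_kappa(r1$reader1, r1$reader2)$kappa, 1)

  r0 <- simulate_ratings(1, agreement = 0.5, seed = 1)
  expect_true(all(unlist(r0) %in% 1:5))

  # agreement 0: kappa approaches the closed-form value of the generator
  p <- c(0, 0, 0.2, 0.5, 0.3)
  A <- matrix(0, 5, 5)
  for (i in 1:5) {
    if (i == 1) A[i, 2] <- 1
    else if (i == 5) A[i, 4] <- 1
    else A[i, c(i - 1, i + 1)] <- 0.5
  }
  O <- diag(p) %*% A
  w <- abs(outer(1:5, 1:5, "-")) / 4
  kappa_cf <- 1 - sum(w * O) / sum(w * outer(p, colSums(O)))
  mc <- simulate_ratings(1e5, agreement = 0, seed = 11)
  expect_lt(abs(weighted_kappa(mc$reader1, mc$reader2)$kappa - kappa_cf), 0.02)
})
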