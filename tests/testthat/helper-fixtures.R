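# Shared fixture builders; everything is generated in code at test time.

# Small scalar volume with reproducible content.
make_vol <- function(dims = c(10, 10, 8), spacing = c(1, 1, 1.3),
                     modality = "CT", seed = 1, constant = NULL) {
  data <- if (is.null(constant)) {
    withr::with_seed(seed, array(stats::rnorm(prod(dims)), dims))
  } else {
    array(constant, dims)
  }
  scalar_volume(data, spacing = spacing, modality = modality)
}

# One-vessel phantom spec with a single spherical deposit of radius r_mm.
make_sphere_spec <- function(r_mm = 3, spacing = c(0.5, 0.5, 0.5),
                             extent = c(24, 24, 24), fwhm = 0, layer = 0,
                             ct_noise = 0, mr_noise = 0, seed = 1) {
  shape <- as.integer(floor(extent / spacing)) + 1L
  ctr <- extent / 2
  phantom_spec(
    shape = shape, spacing = spacing,
    vessels = tibble::tibble(x0 = ctr[1], y0 = ctr[2], z0 = 2,
                             x1 = ctr[1], y1 = ctr[2], z1 = extent[3] - 2,
                             lumen_radius_mm = 3, wall_mm = 0),
    deposits = tibble::tibble(deposit_id = 1L, segment = "seg1",
                              cx = ctr[1], cy = ctr[2], cz = ctr[3],
                              a = r_mm, b = r_mm, c = r_mm),
    ct_model = list(soft_hu = 50, lumen_hu = 300, calcium_hu = 1200,
                    psf_fwhm_mm = fwhm, noise_sd = ct_noise),
    mr_model = list(background_mean = 100, calcium_fraction = 0,
                    surface_layer_mm = layer, noise_sd = mr_noise),
    seed = seed)
}

# Tiny paired CT/MR exam plus 0.5 mm segment ROIs for bookkeeping tests:
# the geometry is miniature but the segment labels are the standard sets.
make_tiny_exam <- function(region = "ilio_femoral", seed = 1) {
  dims <- c(24L, 24L, 26L)
  sp <- rep(0.5, 3)
  labels <- calcquant:::segment_labels(region)
  ct <- scalar_volume(
    withr::with_seed(seed, array(stats::rnorm(prod(dims), 300, 10), dims)),
    sp, modality = "CT")
  mr <- scalar_volume(
    withr::with_seed(seed + 1, array(stats::rnorm(prod(dims), 100, 5), dims)),
    sp, modality = "MR")
  pos <- list(c(3, 3), c(3, 8), c(8, 3), c(8, 8), c(5.5, 5.5))
  rois <- lapply(seq_along(labels), function(i) {
    build_segment_roi(ct, landmark = c(pos[[i]][1], pos[[i]][2], 1.5),
                      direction = c(0, 0, 1), length_mm = 10,
                      radius_mm = 1.6, label = labels[i], region = region)
  })
  list(ct = ct, mr = mr, rois = rois, labels = labels)
}

# Brute-force oracles for the agreement estimators --------------------------

oracle_pearson <- function(x, y) {
  n <- length(x)
  sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
}

# ICC(A,1) from an explicit two-way ANOVA fitted with aov()
oracle_icc <- function(x, y) {
  n <- length(x)
  df <- data.frame(v = c(x, y), subj = factor(rep(seq_len(n), 2)),
                   rater = factor(rep(1:2, each = n)))
  ms <- summary(stats::aov(v ~ subj + rater, data = df))[[1]]$"Mean Sq"
  MSR <- ms[1]; MSC <- ms[2]; MSE <- ms[3]; k <- 2
  (MSR - MSE) / (MSR + (k - 1) * MSE + k * (MSC - MSE) / n)
}

oracle_weighted_kappa <- function(r1, r2, n_cat = 5) {
  n <- length(r1)
  O <- matrix(0, n_cat, n_cat)
  for (i in seq_len(n)) O[r1[i], r2[i]] <- O[r1[i], r2[i]] + 1 / n
  w <- abs(outer(seq_len(n_cat), seq_len(n_cat), "-")) / (n_cat - 1)
  E <- outer(rowSums(O), colSums(O))
  1 - sum(w * O) / sum(w * E)
}
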