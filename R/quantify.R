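#' Threshold policy for calcium segmentation
#'
#' Bundles the modality-specific segmentation thresholds. On CT, voxels
#' strictly above a fixed Hounsfield cutoff (default 560 HU, which separates
#' dense calcium from contrast-enhanced lumen) are calcium. On MR, voxels
#' more than `k` standard deviations below the ROI background mean are
#' calcium; `k = 3` in the ilio-femoral region and `k = 2` in the aorto-iliac
#' region, where background signal is more variable.
#'
#' @param ct_hu_cutoff CT cutoff in HU (> 0), default 560.
#' @param k_ilio_femoral MR SD multiplier for ilio-femoral ROIs, default 3.
#' @param k_aorto_iliac MR SD multiplier for aorto-iliac ROIs, default 2.
#' @return An object of class `threshold_policy`.
#' @export
threshold_policy <- function(ct_hu_cutoff = 560, k_ilio_femoral = 3,
                             k_aorto_iliac = 2) {
  stopifnot(ct_hu_cutoff > 0, k_ilio_femoral > 0, k_aorto_iliac > 0)
  structure(list(ct_hu_cutoff = ct_hu_cutoff,
                 k_ilio_femoral = k_ilio_femoral,
                 k_aorto_iliac = k_aorto_iliac),
            class = "threshold_policy")
}

mr_k_for <- function(policy, region) {
  switch(region,
         ilio_femoral = policy$k_ilio_femoral,
         aorto_iliac = policy$k_aorto_iliac,
         stop("unknown region: ", region))
}

#' Build a cylindrical vessel-segment ROI
#'
#' Rasterizes a cylinder of the given length and radius, starting at an
#' anatomical landmark (e.g. the femoral bifurcation) and extending along a
#' direction, onto the grid of an analysis volume. This mirrors how vessel
#' segments are localized in practice: a landmark plus a fixed 5-cm extent,
#' not a traced lumen.
#'
#' @param grid a [scalar_volume()] defining the analysis grid.
#' @param landmark numeric length-3 physical point in mm.
#' @param direction numeric length-3, need not be normalized.
#' @param length_mm cylinder length in mm (default 50, i.e. 5 cm).
#' @param radius_mm cylinder radius in mm.
#' @param label segment label.
#' @param region `"ilio_femoral"` or `"aorto_iliac"`.
#' @return An object of class `segment_roi`: label, region, logical `mask`
#'   on the grid, and the grid spacing.
#' @export
build_segment_roi <- function(grid, landmark, direction, length_mm = 50,
                              radius_mm, label,
                              region = c("ilio_femoral", "aorto_iliac")) {
  stopifnot(is_scalar_volume(grid))
  region <- match.arg(region)
  direction <- as.numeric(direction)
  if (sqrt(sum(direction^2)) <= 0) stop("`direction` must be nonzero")
  if (length_mm <= 0) stop("`length_mm` must be positive")
  if (radius_mm <= 0) stop("`radius_mm` must be positive")
  u <- direction / sqrt(sum(direction^2))
  co <- grid_coords(dim(grid$data), grid$spacing, grid$origin)
  mask <- cylinder_mask(co, landmark, landmark + u * length_mm, radius_mm)
  if (!any(mask)) stop("ROI cylinder '", label, "' lies entirely outside the grid")
  structure(list(label = label, region = region, mask = mask,
                 spacing = grid$spacing),
            class = "segment_roi")
}

check_roi_grid <- function(vol, roi) {
  if (!identical(dim(vol$data), dim(roi$mask)) ||
      max(abs(vol$spacing - roi$spacing)) > 1e-9) {
    stop("ROI grid does not match the analysis volume grid")
  }
}

#' Segment calcium on CT by fixed Hounsfield threshold
#'
#' Classifies as calcium every ROI voxel with intensity strictly above the
#' policy's HU cutoff. The volume must already be resampled to isotropic
#' resolution; thresholding is never applied on the native anisotropic grid.
#'
#' @param vol a CT [scalar_volume()], isotropic.
#' @param roi a [build_segment_roi()] result on the same grid.
#' @param policy a [threshold_policy()].
#' @return A logical mask array of the volume's shape.
#' @export
segment_ct <- function(vol, roi, policy = threshold_policy()) {
  stopifnot(is_scalar_volume(vol))
  if (vol$modality != "CT") stop("segment_ct requires a CT volume, got ", vol$modality)
  check_roi_grid(vol, roi)
  roi$mask & vol$data > policy$ct_hu_cutoff
}

#' Segment calcium on MR by the mean - k SD rule
#'
#' Two-pass background-relative thresholding within the ROI. Pass 1 computes
#' the mean and SD (n-1 denominator) over all ROI voxels and classifies
#' voxels strictly below mean - k SD. Pass 2 recomputes the background
#' statistics over the ROI voxels *excluding* those classified in pass 1 --
#' so dark calcium does not inflate the SD and suppress its own detection --
#' and re-classifies once. `k` is taken from the policy according to the
#' ROI's anatomical region (3 ilio-femoral, 2 aorto-iliac).
#'
#' @param vol an MR [scalar_volume()], isotropic.
#' @inheritParams segment_ct
#' @return A list: `mask` (final logical array), `mu`, `sigma` (final
#'   background statistics), `threshold` (final cutoff mu - k sigma), `k`,
#'   and `pass1` (list with the pass-1 mu, sigma, threshold and voxel count).
#' @export
segment_mr <- function(vol, roi, policy = threshold_policy()) {
  stopifnot(is_scalar_volume(vol))
  if (vol$modality != "MR") stop("segment_mr requires an MR volume, got ", vol$modality)
  check_roi_grid(vol, roi)
  k <- mr_k_for(policy, roi$region)
  vals <- vol$data[roi$mask]
  mu1 <- mean(vals)
  sd1 <- stats::sd(vals)
  if (!is.finite(sd1) || sd1 == 0) {
    warning("degenerate ROI '", roi$label, "': background SD is zero; empty mask")
    return(list(mask = array(FALSE, dim(vol$data)), mu = mu1, sigma = 0,
                threshold = mu1, k = k,
                pass1 = list(mu = mu1, sigma = 0, threshold = mu1, n_classified = 0L)))
  }
  thr1 <- mu1 - k * sd1
  cls1 <- vals < thr1
  rest <- vals[!cls1]
  mu2 <- mean(rest)
  sd2 <- if (length(rest) >= 2) stats::sd(rest) else 0
  if (!is.finite(sd2)) sd2 <- 0
  thr2 <- mu2 - k * sd2
  mask <- array(FALSE, dim(vol$data))
  mask[roi$mask] <- vals < thr2
  list(mask = mask, mu = mu2, sigma = sd2, threshold = thr2, k = k,
       pass1 = list(mu = mu1, sigma = sd1, threshold = thr1,
                    n_classified = sum(cls1)))
}

#' Measure the physical volume of a binary mask
#'
#' Volume in mm cubed as voxel count times voxel volume. The grid must be
#' isotropic: volumetry is only defined after resampling, enforcing the
#' resample-first measurement order.
#'
#' @param mask logical array.
#' @param spacing numeric length-3 voxel size in mm (isotropic).
#' @return Volume in mm cubed.
#' @examples
#' measure_volume(array(c(rep(TRUE, 8), rep(FALSE, 19)), c(3, 3, 3)),
#'                rep(0.5, 3))  # 8 * 0.125 = 1 mm^3
#' @export
measure_volume <- function(mask, spacing) {
  spacing <- as.numeric(spacing)
  stopifnot(length(spacing) == 3, all(spacing > 0))
  if (!is_isotropic(spacing)) {
    stop("volume measurement requires an isotropic grid; resample first ",
         sprintf("(spacing %.4g x %.4g x %.4g mm)", spacing[1], spacing[2], spacing[3]))
  }
  sum(mask) * prod(spacing)
}

#' Classify calcification severity from CTA volume
#'
#' Severity groups on the CTA calcification volume: group 1 (none or mild)
#' below 100 mm cubed, group 2 (moderate) 100 to below 300 mm cubed,
#' group 3 (severe) at or above 300 mm cubed.
#'
#' @param cta_volume numeric vector of CTA volumes in mm cubed (>= 0).
#' @return Integer vector of groups in 1..3.
#' @examples
#' classify_severity(c(0, 150, 300))  # 1 2 3
#' @export
classify_severity <- function(cta_volume) {
  if (any(!is.finite(cta_volume)) || any(cta_volume < 0)) {
    stop("CTA volumes must be finite and non-negative")
  }
  findInterval(cta_volume, c(100, 300)) + 1L
}

#' Quantify one paired CT/MR exam over a set of segment ROIs
#'
#' Runs the modality-specific segmentation in every ROI of both volumes and
#' assembles the per-segment bookkeeping table: one row per (segment,
#' modality) with volume, voxel count, the threshold actually applied,
#' background statistics (MR), severity group (always from the CTA volume),
#' and the exclusion flag. Excluded segments (e.g. susceptibility artifact
#' from a hip prosthesis) carry no volumes.
#'
#' @param ct,mr isotropic CT and MR [scalar_volume()]s on matching grids.
#' @param rois list of [build_segment_roi()] objects with distinct labels.
#' @param policy a [threshold_policy()].
#' @param exclusions optional data frame with columns `segment`, `reason`.
#' @param exam_id identifier copied into the table.
#' @return A tibble (the segment table) with columns `exam_id`, `segment`,
#'   `region`, `modality`, `volume_mm3`, `voxel_count`, `threshold`,
#'   `bg_mean`, `bg_sd`, `group`, `excluded`, `reason`.
#' @export
quantify_exam <- function(ct, mr, rois, policy = threshold_policy(),
                          exclusions = NULL, exam_id = "exam") {
  labels <- vapply(rois, function(r) r$label, character(1))
  if (anyDuplicated(labels)) stop("repeated ROI label: ",
                                  labels[duplicated(labels)][1])
  if (!is.null(exclusions)) {
    exclusions <- tibble::as_tibble(exclusions)
    bad <- setdiff(exclusions$segment, labels)
    if (length(bad)) stop("exclusion label not among ROIs: ", bad[1])
    if (any(!nzchar(exclusions$reason))) stop("exclusion reason must be nonempty")
  }
  if (length(rois) == 0) {
    return(tibble::tibble(exam_id = character(), segment = character(),
                          region = character(), modality = character(),
                          volume_mm3 = numeric(), voxel_count = integer(),
                          threshold = numeric(), bg_mean = numeric(),
                          bg_sd = numeric(), group = integer(),
                          excluded = logical(), reason = character()))
  }
  rows <- purrr::map(rois, function(roi) {
    excl <- !is.null(exclusions) && roi$label %in% exclusions$segment
    reason <- if (excl) exclusions$reason[match(roi$label, exclusions$segment)] else ""
    if (excl) {
      return(tibble::tibble(
        exam_id = exam_id, segment = roi$label, region = roi$region,
        modality = c("CT", "MR"), volume_mm3 = NA_real_,
        voxel_count = NA_integer_, threshold = NA_real_,
        bg_mean = NA_real_, bg_sd = NA_real_, group = NA_integer_,
        excluded = TRUE, reason = reason))
    }
    ct_mask <- segment_ct(ct, roi, policy)
    mr_seg <- segment_mr(mr, roi, policy)
    ct_vol <- measure_volume(ct_mask, ct$spacing)
    mr_vol <- measure_volume(mr_seg$mask, mr$spacing)
    tibble::tibble(
      exam_id = exam_id, segment = roi$label, region = roi$region,
      modality = c("CT", "MR"),
      volume_mm3 = c(ct_vol, mr_vol),
      voxel_count = c(sum(ct_mask), sum(mr_seg$mask)),
      threshold = c(policy$ct_hu_cutoff, mr_seg$threshold),
      bg_mean = c(NA_real_, mr_seg$mu),
      bg_sd = c(NA_real_, mr_seg$sigma),
      group = classify_severity(ct_vol),
      excluded = FALSE, reason = "")
  })
  dplyr::bind_rows(rows)
}

#' Quantify a phantom cohort end to end
#'
#' For every exam of a [phantom_cohort()]: resamples both volumes to the
#' isotropic analysis resolution, builds the segment ROIs on the resampled
#' grid from the stored landmark definitions, runs [quantify_exam()], and
#' joins the per-segment ground-truth volumes.
#'
#' @param cohort a [phantom_cohort()] tibble.
#' @param policy a [threshold_policy()].
#' @param target_mm isotropic analysis resolution in mm, default 0.5.
#' @return The combined segment table with additional columns
#'   `true_voxel_mm3` and `true_analytic_mm3`.
#' @export
quantify_cohort <- function(cohort, policy = threshold_policy(),
                            target_mm = 0.5) {
  tabs <- purrr::pmap(cohort, function(exam_id, spec, ct, mr, truth, roi_defs) {
    ct_iso <- resample_isotropic(ct, target_mm)
    mr_iso <- resample_isotropic(mr, target_mm)
    rois <- purrr::pmap(roi_defs, function(segment, region, lx, ly, lz,
                                           dx, dy, dz, length_mm, radius_mm) {
      build_segment_roi(ct_iso, c(lx, ly, lz), c(dx, dy, dz),
                        length_mm, radius_mm, segment, region)
    })
    tab <- quantify_exam(ct_iso, mr_iso, rois, policy, exam_id = exam_id)
    dplyr::left_join(tab,
                     dplyr::rename(truth$segments,
                                   true_analytic_mm3 = "analytic_mm3",
                                   true_voxel_mm3 = "voxel_mm3"),
                     by = "segment") |>
      tidyr::replace_na(list(true_analytic_mm3 = 0, true_voxel_mm3 = 0))
  })
  dplyr::bind_rows(tabs)
}

#' Pivot a segment table to paired per-segment volumes
#'
#' Reshapes the long (segment, modality) table into one row per analyzed
#' segment with `cta_mm3` and `mr_mm3` side by side, plus the severity group
#' (from CTA) and stratum labels -- the input expected by the agreement
#' statistics.
#'
#' @param segment_table output of [quantify_exam()] / [quantify_cohort()].
#' @param field_strength optional per-exam field label ("1.5T"/"3T"): either
#'   a single value or a data frame with columns `exam_id`, `field_strength`.
#' @return A tibble with columns `exam_id`, `segment`, `region`, `group`,
#'   `cta_mm3`, `mr_mm3` (and `field_strength` if given).
#' @export
paired_volumes <- function(segment_table, field_strength = NULL) {
  pv <- segment_table |>
    dplyr::filter(!.data$excluded) |>
    dplyr::select("exam_id", "segment", "region", "group", "modality",
                  "volume_mm3") |>
    tidyr::pivot_wider(names_from = "modality", values_from = "volume_mm3") |>
    dplyr::rename(cta_mm3 = "CT", mr_mm3 = "MR")
  if (!is.null(field_strength)) {
    if (is.data.frame(field_strength)) {
      pv <- dplyr::left_join(pv, tibble::as_tibble(field_strength), by = "exam_id")
    } else {
      pv$field_strength <- field_strength
    }
  }
  pv
}
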