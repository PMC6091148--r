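#' Specify a synthetic paired CT/MR vessel phantom
#'
#' A `phantom_spec` describes one synthetic exam: a voxel grid, one or more
#' straight vessel segments (cylinders), ellipsoidal calcium deposits with
#' analytically known volumes, and the modality models used to render the
#' paired CT and MR volumes. The CT model places contrast-enhanced lumen
#' (~300 HU) and dense calcium (>600 HU) in a soft-tissue background and
#' blurs the field with an isotropic Gaussian point-spread function whose
#' FWHM controls the blooming artifact. The MR model places near-zero calcium
#' signal in an intermediate-signal background; a surface-water layer of the
#' stated thickness erodes the dark core, shrinking the apparent deposit.
#'
#' @param shape integer length-3 grid dimensions.
#' @param spacing numeric length-3 voxel size in mm.
#' @param vessels data frame with columns `x0, y0, z0, x1, y1, z1` (axis
#'   endpoints, mm), `lumen_radius_mm`, `wall_mm`.
#' @param deposits data frame with columns `deposit_id`, `segment`,
#'   `cx, cy, cz` (centre, mm), `a, b, c` (semi-axes, mm).
#' @param ct_model list: `soft_hu`, `lumen_hu`, `calcium_hu`, `psf_fwhm_mm`,
#'   `noise_sd`.
#' @param mr_model list: `background_mean`, `calcium_fraction` (fraction of
#'   the background mean retained inside deposits, ~0), `surface_layer_mm`,
#'   `noise_sd`.
#' @param seed integer seed controlling the rendered noise.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(shape, spacing,
                         vessels, deposits,
                         ct_model = list(soft_hu = 50, lumen_hu = 300,
                                         calcium_hu = 1200, psf_fwhm_mm = 1.0,
                                         noise_sd = 10),
                         mr_model = list(background_mean = 100,
                                         calcium_fraction = 0,
                                         surface_layer_mm = 0.4,
                                         noise_sd = 10),
                         seed = 1L) {
  shape <- as.integer(shape)
  spacing <- as.numeric(spacing)
  stopifnot(length(shape) == 3L, all(shape >= 2L),
            length(spacing) == 3L, all(spacing > 0))
  vessels <- tibble::as_tibble(vessels)
  deposits <- tibble::as_tibble(deposits)
  if (nrow(vessels) > 0 && any(vessels$lumen_radius_mm <= 0)) {
    stop("vessel lumen radii must be positive")
  }
  if (nrow(deposits) > 0) {
    if (any(deposits$a <= 0 | deposits$b <= 0 | deposits$c <= 0)) {
      stop("deposit semi-axes must be positive")
    }
    ext <- (shape - 1) * spacing
    lo <- cbind(deposits$cx - deposits$a, deposits$cy - deposits$b,
                deposits$cz - deposits$c)
    hi <- cbind(deposits$cx + deposits$a, deposits$cy + deposits$b,
                deposits$cz + deposits$c)
    if (any(lo < 0) || any(t(t(hi) > ext))) {
      stop("at least one deposit extends outside the phantom grid")
    }
  }
  if (ct_model$psf_fwhm_mm < 0) stop("PSF FWHM must be >= 0")
  if (ct_model$calcium_hu <= 560 || ct_model$lumen_hu >= 560) {
    stop("CT model must satisfy calcium HU > 560 > lumen HU")
  }
  calc_sig <- mr_model$calcium_fraction * mr_model$background_mean
  if (calc_sig >= mr_model$background_mean - 3 * mr_model$noise_sd) {
    stop("MR calcium signal must lie below background mean - 3 SD")
  }
  structure(
    list(shape = shape, spacing = spacing, vessels = vessels,
         deposits = deposits, ct_model = ct_model, mr_model = mr_model,
         seed = as.integer(seed)),
    class = "phantom_spec")
}

#' @export
print.phantom_spec <- function(x, ...) {
  cat(sprintf("<phantom_spec> %d x %d x %d grid, %d vessel(s), %d deposit(s), seed %d\n",
              x$shape[1], x$shape[2], x$shape[3],
              nrow(x$vessels), nrow(x$deposits), x$seed))
  invisible(x)
}

#' Voxelize the ground-truth deposits of a phantom
#'
#' Rasterizes every deposit ellipsoid on the phantom grid by the
#' inside-ellipsoid test at voxel centres, and tabulates the analytic volume
#' (4/3 pi a b c) next to the voxelized volume (voxel count times voxel
#' volume). These are the reference values that threshold volumetry is judged
#' against.
#'
#' @param spec a [phantom_spec()].
#' @return A list with `label` (integer array: deposit id per voxel, 0 =
#'   background), `deposits` (tibble: deposit_id, segment, analytic_mm3,
#'   voxel_count, voxel_mm3) and `segments` (tibble of per-segment totals).
#' @export
voxelize_truth <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  label <- array(0L, dim = spec$shape)
  dep <- spec$deposits
  vox_mm3 <- prod(spec$spacing)
  counts <- integer(nrow(dep))
  if (nrow(dep) > 0) {
    co <- grid_coords(spec$shape, spec$spacing)
    for (i in seq_len(nrow(dep))) {
      m <- ellipsoid_mask(co, c(dep$cx[i], dep$cy[i], dep$cz[i]),
                          c(dep$a[i], dep$b[i], dep$c[i]))
      counts[i] <- sum(m)
      label[m] <- i
    }
  }
  deposits <- tibble::tibble(
    deposit_id = if (nrow(dep) > 0) dep$deposit_id else integer(),
    segment = if (nrow(dep) > 0) dep$segment else character(),
    analytic_mm3 = if (nrow(dep) > 0) 4 / 3 * pi * dep$a * dep$b * dep$c else numeric(),
    voxel_count = counts,
    voxel_mm3 = counts * vox_mm3)
  segments <- deposits |>
    dplyr::group_by(.data$segment) |>
    dplyr::summarise(analytic_mm3 = sum(.data$analytic_mm3),
                     voxel_mm3 = sum(.data$voxel_mm3), .groups = "drop")
  list(label = label, deposits = deposits, segments = segments)
}

# noise field shared by both renderers: zero-mean Gaussian, reproducible from
# the spec seed plus a per-modality offset so CT and MR noise are independent
render_noise <- function(shape, sd, seed, offset) {
  if (sd <= 0) return(0)
  old <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed + offset)
  array(stats::rnorm(prod(shape), 0, sd), dim = shape)
}

#' Render the CT volume of a phantom
#'
#' Builds the piecewise-constant Hounsfield field (soft tissue, vessel lumen,
#' calcium deposits), convolves it with an isotropic Gaussian PSF of the
#' stated FWHM -- the mechanism by which dense calcium blooms beyond its true
#' extent under a fixed threshold -- and adds seeded Gaussian noise.
#'
#' @param spec a [phantom_spec()].
#' @param add_noise add the seeded noise field (default TRUE). With
#'   `add_noise = FALSE` the render is fully deterministic regardless of seed.
#' @return A CT [scalar_volume()] in HU.
#' @export
render_ct <- function(spec, add_noise = TRUE) {
  stopifnot(inherits(spec, "phantom_spec"))
  cm <- spec$ct_model
  co <- grid_coords(spec$shape, spec$spacing)
  field <- array(cm$soft_hu, dim = spec$shape)
  for (i in seq_len(nrow(spec$vessels))) {
    v <- spec$vessels[i, ]
    m <- cylinder_mask(co, c(v$x0, v$y0, v$z0), c(v$x1, v$y1, v$z1),
                       v$lumen_radius_mm)
    field[m] <- cm$lumen_hu
  }
  for (i in seq_len(nrow(spec$deposits))) {
    d <- spec$deposits[i, ]
    m <- ellipsoid_mask(co, c(d$cx, d$cy, d$cz), c(d$a, d$b, d$c))
    field[m] <- cm$calcium_hu
  }
  if (cm$psf_fwhm_mm > 0) {
    field <- gaussian_blur(field, spec$spacing, cm$psf_fwhm_mm)
  }
  if (add_noise) {
    field <- field + render_noise(spec$shape, cm$noise_sd, spec$seed, 1L)
  }
  scalar_volume(field, spacing = spec$spacing, modality = "CT")
}

#' Render the MR volume of a phantom
#'
#' Proton-density in-phase contrast: uniform intermediate-signal background,
#' with deposit cores set to `calcium_fraction` of the background mean. The
#' surface-water layer is modelled by eroding each deposit: a deposit's dark
#' core is the ellipsoid with every semi-axis reduced by the layer thickness
#' (exact erosion for spherical deposits, a close approximation otherwise).
#' A deposit whose smallest semi-axis does not exceed the layer thickness
#' vanishes, with a warning.
#'
#' @inheritParams render_ct
#' @return An MR [scalar_volume()] in arbitrary signal units.
#' @export
render_mr <- function(spec, add_noise = TRUE) {
  stopifnot(inherits(spec, "phantom_spec"))
  mm <- spec$mr_model
  co <- grid_coords(spec$shape, spec$spacing)
  field <- array(mm$background_mean, dim = spec$shape)
  lay <- mm$surface_layer_mm
  for (i in seq_len(nrow(spec$deposits))) {
    d <- spec$deposits[i, ]
    semi <- c(d$a, d$b, d$c) - lay
    if (any(semi <= 0)) {
      warning(sprintf(
        "deposit %s: surface layer %.2g mm >= smallest semi-axis; rendered empty",
        d$deposit_id, lay))
      next
    }
    m <- ellipsoid_mask(co, c(d$cx, d$cy, d$cz), semi)
    field[m] <- mm$calcium_fraction * mm$background_mean
  }
  if (add_noise) {
    field <- field + render_noise(spec$shape, mm$noise_sd, spec$seed, 2L)
  }
  scalar_volume(field, spacing = spec$spacing, modality = "MR")
}

#' Simulate paired ordinal reader scores
#'
#' Draws reader-1 image-quality scores on the 1-5 Likert scale from a fixed
#' categorical distribution (default concentrated on 3-5, mean 4.1, matching
#' typical diagnostic-confidence ratings). Reader 2 repeats reader 1's score
#' with probability `agreement`, and otherwise moves to a uniformly chosen
#' adjacent category. Used to exercise the weighted-kappa estimator under a
#' known agreement structure.
#'
#' @param n number of rated cases.
#' @param agreement probability in [0, 1] that reader 2 matches reader 1.
#' @param seed integer seed.
#' @param probs length-5 category probabilities for reader 1.
#' @return A tibble with integer columns `reader1`, `reader2` in 1..5.
#' @export
simulate_ratings <- function(n, agreement, seed = 1L,
                             probs = c(0, 0, 0.2, 0.5, 0.3)) {
  stopifnot(n >= 1, agreement >= 0, agreement <= 1,
            length(probs) == 5, all(probs >= 0), sum(probs) > 0)
  old <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  r1 <- sample.int(5L, n, replace = TRUE, prob = probs)
  same <- stats::runif(n) < agreement
  step <- ifelse(r1 == 1L, 1L,
          ifelse(r1 == 5L, -1L,
                 sample(c(-1L, 1L), n, replace = TRUE)))
  r2 <- ifelse(same, r1, r1 + step)
  tibble::tibble(reader1 = as.integer(r1), reader2 = as.integer(r2))
}

# ---- cohort generator --------------------------------------------------------

# Standard segment label sets
segment_labels <- function(region = c("ilio_femoral", "aorto_iliac")) {
  region <- match.arg(region)
  if (region == "ilio_femoral") {
    c("common_femoral_proximal_L", "superficial_femoral_distal_L",
      "common_femoral_proximal_R", "superficial_femoral_distal_R")
  } else {
    c("distal_aorta", "common_iliac_L", "common_iliac_R",
      "external_iliac_L", "external_iliac_R")
  }
}

# Random deposits for one vessel segment: intimal ellipsoids seated at the
# lumen-wall interface (radial offset 2.3 mm from the axis), elongated along
# the vessel. Axial slots keep deposits disjoint and clear of the segment
# ends so the ROI cylinder fully contains them; the per-segment analytic
# total is capped so calcium stays a small fraction of the ROI, the regime
# in which the background-statistics MR rule is identifiable.
random_deposits <- function(segment, vx, vy, z_lo, z_hi,
                            n_dep, total_cap = 260) {
  if (n_dep == 0) return(NULL)
  ang <- stats::runif(n_dep, 0, 2 * pi)
  a <- stats::runif(n_dep, 2.05, 2.45)
  b <- stats::runif(n_dep, 2.05, 2.45)
  cc <- stats::runif(n_dep, 3.0, 5.0)
  # end margin = max axial semi-axis + jitter + resampling-kernel reach, so a
  # deposit's smoothed footprint stays inside its own segment
  slots <- seq(z_lo + 9, z_hi - 9, length.out = max(n_dep, 2))[seq_len(n_dep)]
  cz <- slots + stats::runif(n_dep, -1, 1)
  vol <- 4 / 3 * pi * a * b * cc
  keep <- cumsum(vol) <= total_cap
  if (!any(keep)) keep[1] <- TRUE
  tibble::tibble(
    segment = segment,
    cx = vx + 2.3 * cos(ang), cy = vy + 2.3 * sin(ang), cz = cz,
    a = a, b = b, c = cc)[keep, ]
}

#' Generate a cohort of paired CT/MR phantom exams
#'
#' Builds `n_exams` synthetic exams for one anatomical region with
#' randomized calcium burden, renders the paired CT and MR volumes, and
#' voxelizes the ground truth. Per-segment deposit counts and sizes are drawn
#' so that segment totals span the clinically used severity range (zero to
#' several hundred mm cubed). Vessels are vertical cylinders on a coarse
#' anisotropic grid (1 x 1 x 1.3 mm, the native MR resolution); the
#' ilio-femoral layout has two limbs each carrying a proximal and a distal
#' 5-cm femoral segment, the aorto-iliac layout five parallel 5-cm segments.
#'
#' @param n_exams number of exams.
#' @param region `"ilio_femoral"` or `"aorto_iliac"`.
#' @param spacing rendering-grid voxel size in mm. The default
#'   `c(1, 1, 1.3)` is the native MR grid (1 mm in-plane, 1.3 mm slices);
#'   pass `c(0.5, 0.5, 0.5)` to render directly at the analysis resolution,
#'   which isolates the threshold rule from interpolation effects.
#' @param psf_fwhm_mm CT blooming PSF FWHM in mm (default 1.0).
#' @param surface_layer_mm MR surface-water layer in mm (default 0.4).
#' @param ct_noise_sd CT noise SD in HU (default 10).
#' @param mr_noise_sd MR noise SD in signal units; background mean is 100, so
#'   the default 10 is 10 percent of background.
#' @param seed integer seed.
#' @return A tibble with one row per exam: `exam_id`, list-columns `spec`,
#'   `ct`, `mr`, `truth`, and `roi_defs` (tibble of ROI definitions:
#'   segment, region, landmark, direction, length, radius).
#' @export
phantom_cohort <- function(n_exams = 12, region = c("ilio_femoral", "aorto_iliac"),
                           spacing = c(1, 1, 1.3),
                           psf_fwhm_mm = 1.0, surface_layer_mm = 0.4,
                           ct_noise_sd = 10, mr_noise_sd = 10, seed = 1L) {
  region <- match.arg(region)
  old <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)

  # ROI = lumen radius 3 mm + 2 mm wall margin; deposits (radial extent
  # <= 2.3 + 2.45 mm) stay inside it
  roi_radius <- 5.05

  if (region == "ilio_femoral") {
    extent <- c(52, 26, 108)
    limbs <- tibble::tibble(x = c(14, 38), y = 13, side = c("L", "R"))
    z_bif <- 54; z_top <- 104; z_bot <- 4
  } else {
    extent <- c(84, 26, 60)
    xs <- c(10, 26, 42, 58, 74)
    labs <- segment_labels("aorto_iliac")
    z_lo <- 4; z_hi <- 54
  }
  shape <- as.integer(floor(extent / spacing)) + 1L

  exams <- vector("list", n_exams)
  for (e in seq_len(n_exams)) {
    exam_seed <- seed * 1000L + e
    if (region == "ilio_femoral") {
      vessels <- tibble::tibble(
        x0 = limbs$x, y0 = limbs$y, z0 = z_bot,
        x1 = limbs$x, y1 = limbs$y, z1 = z_top,
        lumen_radius_mm = 3, wall_mm = 0)
      segs <- tibble::tibble(
        segment = segment_labels("ilio_femoral"),
        vx = rep(limbs$x, each = 2), vy = rep(limbs$y, each = 2),
        z_lo = rep(c(z_bif, z_bot), 2), z_hi = rep(c(z_top, z_bif), 2))
      roi_defs <- tibble::tibble(
        segment = segs$segment, region = region,
        lx = segs$vx, ly = segs$vy, lz = z_bif,
        dx = 0, dy = 0, dz = ifelse(grepl("proximal", segs$segment), 1, -1),
        length_mm = 50, radius_mm = roi_radius)
    } else {
      vessels <- tibble::tibble(
        x0 = xs, y0 = 13, z0 = z_lo, x1 = xs, y1 = 13, z1 = z_hi,
        lumen_radius_mm = 3, wall_mm = 0)
      segs <- tibble::tibble(segment = labs, vx = xs, vy = 13,
                             z_lo = z_lo, z_hi = z_hi)
      roi_defs <- tibble::tibble(
        segment = segs$segment, region = region,
        lx = segs$vx, ly = segs$vy, lz = z_lo,
        dx = 0, dy = 0, dz = 1, length_mm = 50, radius_mm = roi_radius)
    }
    dep_list <- list()
    for (s in seq_len(nrow(segs))) {
      n_dep <- sample(0:3, 1, prob = c(0.3, 0.3, 0.25, 0.15))
      dep_list[[s]] <- random_deposits(segs$segment[s], segs$vx[s], segs$vy[s],
                                       segs$z_lo[s], segs$z_hi[s], n_dep)
    }
    deposits <- dplyr::bind_rows(dep_list)
    if (nrow(deposits) == 0) {
      deposits <- tibble::tibble(segment = character(), cx = numeric(),
                                 cy = numeric(), cz = numeric(),
                                 a = numeric(), b = numeric(), c = numeric())
    }
    deposits$deposit_id <- seq_len(nrow(deposits))
    spec <- phantom_spec(
      shape = shape, spacing = spacing,
      vessels = vessels, deposits = deposits,
      ct_model = list(soft_hu = 50, lumen_hu = 300, calcium_hu = 1200,
                      psf_fwhm_mm = psf_fwhm_mm, noise_sd = ct_noise_sd),
      mr_model = list(background_mean = 100, calcium_fraction = 0,
                      surface_layer_mm = surface_layer_mm,
                      noise_sd = mr_noise_sd),
      seed = exam_seed)
    ct <- render_ct(spec)
    mr <- render_mr(spec)
    truth <- voxelize_truth(spec)
    exams[[e]] <- tibble::tibble(
      exam_id = sprintf("exam%02d", e),
      spec = list(spec), ct = list(ct), mr = list(mr),
      truth = list(truth), roi_defs = list(roi_defs))
  }
  dplyr::bind_rows(exams)
}
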