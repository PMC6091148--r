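#' Thin-slab minimum / maximum intensity projection
#'
#' Collapses a slab of the volume onto a 2-D image by taking, per projected
#' pixel, the minimum (MinIP) or maximum (MIP) intensity across the slab.
#' Thin MinIP slabs (4-15 mm) are the standard qualitative display for dark
#' MR calcium; thin MIP slabs display bright CT calcium. Axis-aligned slabs
#' use the voxel values directly (bit-exact); oblique slab normals resample
#' the volume along the normal by trilinear interpolation first, which
#' requires an isotropic grid.
#'
#' @param vol a [scalar_volume()].
#' @param normal projection direction: `"x"`, `"y"`, `"z"`, or a numeric
#'   length-3 oblique normal (need not be normalized).
#' @param thickness_mm slab thickness in mm; below one voxel triggers a
#'   single-slice passthrough with a warning.
#' @param center_mm physical coordinate of the slab centre along the normal;
#'   defaults to the volume centre (or the centroid of `mask` if given).
#' @param mode `"min"` or `"max"`.
#' @param mask optional logical array (e.g. a segmented calcium mask) whose
#'   centroid places the slab.
#' @return A numeric matrix of class `slab_projection` with attributes
#'   `pixel_mm`, `mode`, `thickness_mm`.
#' @export
thin_slab_projection <- function(vol, normal = "y", thickness_mm = 8,
                                 center_mm = NULL, mode = c("min", "max"),
                                 mask = NULL) {
  stopifnot(is_scalar_volume(vol))
  mode <- match.arg(mode)
  if (thickness_mm <= 0) stop("slab thickness must be positive")
  d <- dim(vol$data)

  axis <- if (is.character(normal)) match(normal, c("x", "y", "z")) else NA
  if (is.character(normal) && is.na(axis)) stop("unknown axis: ", normal)

  if (!is.na(axis)) {
    coords <- axis_coords(vol, axis)
    if (is.null(center_mm)) {
      center_mm <- if (!is.null(mask) && any(mask)) {
        co <- grid_coords(d, vol$spacing, vol$origin)
        mean(switch(axis, co$X, co$Y, co$Z)[mask])
      } else mean(range(coords))
    }
    sel <- which(abs(coords - center_mm) <= thickness_mm / 2)
    if (length(sel) == 0) {
      if (center_mm < min(coords) - thickness_mm / 2 ||
          center_mm > max(coords) + thickness_mm / 2) {
        stop("slab lies outside the volume")
      }
      warning("slab thinner than one voxel; single-slice passthrough")
      sel <- which.min(abs(coords - center_mm))
    }
    sub <- switch(axis,
                  vol$data[sel, , , drop = FALSE],
                  vol$data[, sel, , drop = FALSE],
                  vol$data[, , sel, drop = FALSE])
    img <- apply(sub, setdiff(1:3, axis), if (mode == "min") min else max)
    px <- vol$spacing[setdiff(1:3, axis)]
  } else {
    # oblique: sample planes perpendicular to the normal
    if (!is_isotropic(vol$spacing)) {
      stop("oblique projections require an isotropic volume; resample first")
    }
    n <- as.numeric(normal)
    n <- n / sqrt(sum(n^2))
    # orthonormal in-plane basis
    ref <- if (abs(n[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    u <- ref - sum(ref * n) * n; u <- u / sqrt(sum(u^2))
    v <- c(n[2] * u[3] - n[3] * u[2], n[3] * u[1] - n[1] * u[3],
           n[1] * u[2] - n[2] * u[1])
    sp <- vol$spacing[1]
    ctr <- vol$origin + (d - 1) * vol$spacing / 2
    if (is.null(center_mm)) center_mm <- 0   # offset along normal from centre
    half_diag <- sqrt(sum(((d - 1) * vol$spacing / 2)^2))
    s_in <- seq(-half_diag, half_diag, by = sp)
    n_off <- max(1L, floor(thickness_mm / 2 / sp))
    offs <- seq(-n_off, n_off) * sp + center_mm
    img <- NULL
    for (o in offs) {
      P <- expand.grid(a = s_in, b = s_in)
      pts <- cbind(ctr[1] + P$a * u[1] + P$b * v[1] + o * n[1],
                   ctr[2] + P$a * u[2] + P$b * v[2] + o * n[2],
                   ctr[3] + P$a * u[3] + P$b * v[3] + o * n[3])
      vals <- matrix(trilinear_sample(vol, pts), length(s_in), length(s_in))
      img <- if (is.null(img)) vals
             else if (mode == "min") pmin(img, vals) else pmax(img, vals)
    }
    px <- c(sp, sp)
  }
  structure(img, class = c("slab_projection", "matrix"),
            pixel_mm = px, mode = mode, thickness_mm = thickness_mm)
}

# Trilinear interpolation of a volume at arbitrary physical points (rows of
# pts); points outside the extent take the nearest-edge value.
trilinear_sample <- function(vol, pts) {
  d <- dim(vol$data)
  u <- sweep(sweep(pts, 2, vol$origin), 2, vol$spacing, "/")   # 0-based index
  u <- pmax(pmin(u, matrix(d - 1, nrow(pts), 3, byrow = TRUE)), 0)
  i0 <- pmin(floor(u), matrix(d - 2, nrow(pts), 3, byrow = TRUE))
  f <- u - i0
  i0 <- i0 + 1   # 1-based lower corner
  val <- 0
  for (dx in 0:1) for (dy in 0:1) for (dz in 0:1) {
    w <- (if (dx) f[, 1] else 1 - f[, 1]) *
         (if (dy) f[, 2] else 1 - f[, 2]) *
         (if (dz) f[, 3] else 1 - f[, 3])
    idx <- cbind(i0[, 1] + dx, i0[, 2] + dy, i0[, 3] + dz)
    val <- val + w * vol$data[idx]
  }
  val
}

#' @export
print.slab_projection <- function(x, ...) {
  cat(sprintf("<slab_projection> %s over %.3g mm slab, %d x %d px\n",
              toupper(attr(x, "mode")), attr(x, "thickness_mm"),
              nrow(x), ncol(x)))
  invisible(x)
}

#' @export
autoplot.slab_projection <- function(object, ...) {
  px <- attr(object, "pixel_mm")
  df <- expand.grid(x = (seq_len(nrow(object)) - 1) * px[1],
                    y = (seq_len(ncol(object)) - 1) * px[2])
  df$intensity <- as.vector(unclass(object))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y,
                                   fill = .data$intensity)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_gradient(low = "black", high = "white") +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = "mm", y = "mm",
                  fill = NULL,
                  subtitle = sprintf("%s, %.3g mm slab",
                                     toupper(attr(object, "mode")),
                                     attr(object, "thickness_mm"))) +
    ggplot2::theme_minimal()
}
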