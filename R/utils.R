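# Internal geometry and filtering helpers shared by the phantom generator,
# ROI builder and artifact metrics.

# Physical coordinates of all voxel centres: three arrays of the grid shape.
grid_coords <- function(shape, spacing, origin = c(0, 0, 0)) {
  xc <- origin[1] + (seq_len(shape[1]) - 1) * spacing[1]
  yc <- origin[2] + (seq_len(shape[2]) - 1) * spacing[2]
  zc <- origin[3] + (seq_len(shape[3]) - 1) * spacing[3]
  list(X = array(xc, dim = shape),
       Y = array(rep(yc, each = shape[1]), dim = shape),
       Z = array(rep(zc, each = shape[1] * shape[2]), dim = shape))
}

# Voxel-centre rasterization of a finite cylinder from p0 to p1.
cylinder_mask <- function(co, p0, p1, radius) {
  axis <- p1 - p0
  len <- sqrt(sum(axis^2))
  if (len <= 0) stop("cylinder has zero length")
  u <- axis / len
  vx <- co$X - p0[1]; vy <- co$Y - p0[2]; vz <- co$Z - p0[3]
  t <- vx * u[1] + vy * u[2] + vz * u[3]
  d2 <- vx^2 + vy^2 + vz^2 - t^2
  t >= 0 & t <= len & d2 <= radius^2
}

# Voxel-centre rasterization of an axis-aligned ellipsoid.
ellipsoid_mask <- function(co, center, semi) {
  ((co$X - center[1]) / semi[1])^2 +
    ((co$Y - center[2]) / semi[2])^2 +
    ((co$Z - center[3]) / semi[3])^2 <= 1
}

# Separable Gaussian blur with replicate edges; FWHM in mm.
gaussian_blur <- function(arr, spacing, fwhm_mm) {
  sigma_mm <- fwhm_mm / (2 * sqrt(2 * log(2)))
  for (axis in 1:3) {
    sigma <- sigma_mm / spacing[axis]
    if (sigma < 1e-6) next
    R <- max(1L, ceiling(4 * sigma))
    k <- stats::dnorm(seq(-R, R), sd = sigma)
    k <- k / sum(k)
    n <- dim(arr)[axis]
    W <- matrix(0, n, n)
    for (o in seq(-R, R)) {
      j <- pmin(pmax(seq_len(n) + o, 1L), n)
      W[cbind(seq_len(n), j)] <- W[cbind(seq_len(n), j)] + k[o + R + 1]
    }
    arr <- apply_axis_matrix(arr, W, axis)
  }
  arr
}

# Binary dilation by a cubic structuring element of half-width r voxels,
# implemented as a separable running maximum.
dilate_mask <- function(mask, r = 1L) {
  if (r < 1) return(mask)
  d <- dim(mask)
  out <- mask
  for (axis in 1:3) {
    acc <- out
    for (o in seq_len(r)) {
      idx_fwd <- pmin(seq_len(d[axis]) + o, d[axis])
      idx_bwd <- pmax(seq_len(d[axis]) - o, 1L)
      sl <- function(i) switch(axis,
                               out[i, , , drop = FALSE],
                               out[, i, , drop = FALSE],
                               out[, , i, drop = FALSE])
      acc <- acc | switch(axis,
                          out[idx_fwd, , , drop = FALSE],
                          out[, idx_fwd, , drop = FALSE],
                          out[, , idx_fwd, drop = FALSE])
      acc <- acc | switch(axis,
                          out[idx_bwd, , , drop = FALSE],
                          out[, idx_bwd, , drop = FALSE],
                          out[, , idx_bwd, drop = FALSE])
    }
    out <- acc
  }
  out
}
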