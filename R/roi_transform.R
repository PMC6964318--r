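#' Region-of-interest mask
#'
#' A depot mask with voxel-volume metadata. Masks are binary when drawn;
#' after resampling through a deformation field they are kept as
#' floating-point weights in [0, 1] so that analyses can run on raw
#' (non-interpolated) data with fractional voxel contributions.
#'
#' @param values Array with values in [0, 1].
#' @param voxel_volume Voxel volume in microlitres.
#' @param label Depot name, e.g. "supraclavicular" or "deltoid SAT".
#' @return An object of class `bat_roi`.
#' @export
roi_mask <- function(values, voxel_volume, label = "supraclavicular") {
  values <- values * 1  # logical -> numeric
  if (any(values < 0 | values > 1)) stop("mask values must lie in [0, 1]")
  if (voxel_volume <= 0) stop("voxel_volume must be positive")
  structure(list(values = values, voxel_volume = voxel_volume, label = label),
            class = "bat_roi")
}

#' Dense deformation field
#'
#' Per-voxel displacements in millimetres, defined on the target-image grid
#' (pulling convention): the transformed image at grid point x samples the
#' source image at x + d(x).
#'
#' @param displacements 4-D array, last axis of length 3 (x, y, z
#'   displacement components in mm).
#' @param spacing Voxel spacing in mm along each axis.
#' @return An object of class `bat_defo`.
#' @export
deformation_field <- function(displacements, spacing = c(1.1, 1.1, 1.1)) {
  d <- dim(displacements)
  if (length(d) != 4 || d[4] != 3)
    stop("displacements must be a 4-D array with 3 components on the last axis")
  if (!all(is.finite(displacements)))
    stop("displacement field must be finite everywhere")
  structure(list(displacements = displacements, spacing = spacing,
                 shape = d[1:3]),
            class = "bat_defo")
}

#' Synthetic smooth deformation field
#'
#' Sum of seeded Gaussian bumps per component, scaled to a given maximum
#' displacement; used to exercise the transform interface in the absence of
#' a registration run.
#'
#' @param shape 3-D grid size.
#' @param amplitude Maximum displacement magnitude, mm.
#' @param seed Integer seed.
#' @param spacing Voxel spacing in mm.
#' @return A `bat_defo`.
#' @export
synthetic_deformation <- function(shape, amplitude = 1.5, seed = 1,
                                  spacing = c(1.1, 1.1, 1.1)) {
  set.seed(seed)
  disp <- array(0, dim = c(shape, 3))
  for (k in 1:3) {
    f <- smooth_random_field(shape, n_bumps = 10, width = c(0.3, 0.6))
    disp[, , , k] <- f
  }
  mx <- max(sqrt(apply(disp^2, 1:3, sum)))
  if (mx > 0) disp <- disp * amplitude / mx
  deformation_field(disp, spacing)
}

#' Numerically invert a deformation field
#'
#' Fixed-point iteration `d_inv(x) <- -d(x + d_inv(x))`, adequate for the
#' smooth small-amplitude fields used here.
#'
#' @param field A `bat_defo`.
#' @param n_iter Number of fixed-point iterations.
#' @return A `bat_defo` approximating the inverse mapping.
#' @export
invert_deformation <- function(field, n_iter = 30) {
  disp <- field$displacements
  inv <- array(0, dim = dim(disp))
  for (it in seq_len(n_iter)) {
    for (k in 1:3) {
      inv[, , , k] <- -sample_displaced(disp[, , , k], inv, field$spacing,
                                        outside = 0)
    }
  }
  deformation_field(inv, field$spacing)
}

## Vectorised trilinear sampling of `vol` at fractional voxel coordinates
## (1-based). Coordinates are clamped to the volume; `outside` is unused
## after clamping but kept for clarity of intent at exact borders.
sample_trilinear <- function(vol, xi, yi, zi) {
  d <- dim(vol)
  xi <- clamp(xi, 1, d[1]); yi <- clamp(yi, 1, d[2]); zi <- clamp(zi, 1, d[3])
  x0 <- pmin(floor(xi), d[1] - 1L); y0 <- pmin(floor(yi), max(d[2] - 1L, 1L))
  z0 <- pmin(floor(zi), max(d[3] - 1L, 1L))
  if (d[1] == 1) x0 <- rep(1, length(xi))
  fx <- xi - x0; fy <- yi - y0; fz <- zi - z0
  x1 <- pmin(x0 + 1L, d[1]); y1 <- pmin(y0 + 1L, d[2]); z1 <- pmin(z0 + 1L, d[3])
  lin <- function(x, y, z) vol[cbind(x, y, z)]
  v000 <- lin(x0, y0, z0); v100 <- lin(x1, y0, z0)
  v010 <- lin(x0, y1, z0); v110 <- lin(x1, y1, z0)
  v001 <- lin(x0, y0, z1); v101 <- lin(x1, y0, z1)
  v011 <- lin(x0, y1, z1); v111 <- lin(x1, y1, z1)
  c00 <- v000 * (1 - fx) + v100 * fx
  c10 <- v010 * (1 - fx) + v110 * fx
  c01 <- v001 * (1 - fx) + v101 * fx
  c11 <- v011 * (1 - fx) + v111 * fx
  c0 <- c00 * (1 - fy) + c10 * fy
  c1 <- c01 * (1 - fy) + c11 * fy
  c0 * (1 - fz) + c1 * fz
}

## Sample `vol` at x + d(x) given a displacement array (mm) and spacing.
sample_displaced <- function(vol, disp, spacing, outside = 0) {
  d <- dim(vol)
  g <- expand.grid(x = seq_len(d[1]), y = seq_len(d[2]), z = seq_len(d[3]))
  xi <- g$x + as.vector(disp[, , , 1]) / spacing[1]
  yi <- g$y + as.vector(disp[, , , 2]) / spacing[2]
  zi <- g$z + as.vector(disp[, , , 3]) / spacing[3]
  out_of_grid <- xi < 1 | xi > d[1] | yi < 1 | yi > d[2] | zi < 1 | zi > d[3]
  v <- sample_trilinear(vol, xi, yi, zi)
  v[out_of_grid] <- outside
  array(v, dim = d)
}

#' Resample a volume through a deformation field
#'
#' Pulling convention: the output at grid point x is the input sampled
#' (trilinearly) at x + d(x). Samples falling outside the source grid are
#' set to `outside`.
#'
#' @param vol 3-D array on the field's grid.
#' @param field A `bat_defo`.
#' @param outside Fill value for out-of-grid samples.
#' @return Transformed 3-D array.
#' @export
transform_volume <- function(vol, field, outside = 0) {
  if (!identical(dim(vol), as.integer(field$shape)) &&
      !identical(dim(vol), field$shape))
    stop(sprintf("volume grid (%s) does not match field grid (%s)",
                 paste(dim(vol), collapse = "x"),
                 paste(field$shape, collapse = "x")))
  sample_displaced(vol, field$displacements, field$spacing, outside)
}

#' Transform an ROI mask through a deformation field
#'
#' The mask is resampled trilinearly and retained as floating-point weights;
#' with `binarize_threshold` set, weights are thresholded back to a binary
#' mask for integer voxel-counting analyses.
#'
#' @param mask A `bat_roi`.
#' @param field A `bat_defo` on the same grid.
#' @param binarize_threshold Optional fraction in (0, 1).
#' @return A transformed `bat_roi`.
#' @export
transform_mask <- function(mask, field, binarize_threshold = NULL) {
  v <- transform_volume(mask$values, field, outside = 0)
  v <- clamp(v, 0, 1)
  if (!is.null(binarize_threshold)) v <- (v >= binarize_threshold) * 1
  roi_mask(v, mask$voxel_volume, mask$label)
}

#' In-plane neighborhood mean filter
#'
#' Assigns each voxel the mean of its k x k in-plane neighborhood (edge
#' replication at slice borders), applied identically to both time points
#' before voxel-wise differencing to suppress interpolation bias and small
#' registration inconsistencies. A 3-D k x k x k variant is available via
#' `three_d`.
#'
#' @param map 3-D array.
#' @param k Odd neighborhood size (default 3).
#' @param three_d If TRUE, average over the k x k x k neighborhood instead.
#' @return Filtered array of the same dimension.
#' @export
neighborhood_mean <- function(map, k = 3, three_d = FALSE) {
  if (k %% 2 == 0) stop("neighborhood size k must be odd")
  d <- dim(map)
  h <- (k - 1) / 2
  acc <- array(0, dim = d)
  ix <- function(n, o) clamp(seq_len(n) + o, 1, n)
  dz_range <- if (three_d) -h:h else 0
  n_terms <- 0
  for (dx in -h:h) for (dy in -h:h) for (dz in dz_range) {
    acc <- acc + map[ix(d[1], dx), ix(d[2], dy), ix(d[3], dz), drop = FALSE]
    n_terms <- n_terms + 1
  }
  acc / n_terms
}
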