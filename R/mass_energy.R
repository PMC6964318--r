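#' Tissue composition constants
#'
#' Density and metabolizable energy equivalents of the two MRI-visible
#' compartments: 1 uL of lipid is taken as 0.92 mg and 9.4e-3 kcal; 1 uL of
#' lean (water-bound) tissue as 1.06 mg and 1.0e-3 kcal. The constants are
#' data, not hard-coded at call sites, so they can be audited and
#' overridden.
#'
#' @param fat_density,lean_density mg per uL.
#' @param fat_energy,lean_energy kcal per uL.
#' @return An object of class `bat_constants`.
#' @export
composition_constants <- function(fat_density = 0.92, lean_density = 1.06,
                                  fat_energy = 9.4e-3, lean_energy = 1.0e-3) {
  stopifnot(fat_density > 0, lean_density > 0, fat_energy > 0,
            lean_energy > 0)
  structure(list(fat_density = fat_density, lean_density = lean_density,
                 fat_energy = fat_energy, lean_energy = lean_energy),
            class = "bat_constants")
}

#' Per-voxel fat/lean composition
#'
#' The signal fat fraction is used directly as a volume fraction: a voxel of
#' volume v with fat fraction ff holds `ff * v` uL fat and `(1 - ff) * v` uL
#' lean tissue (a 1 uL voxel at FF 50% partitions into 0.5 uL of each);
#' masses and energies follow from the composition constants.
#'
#' @param ff Fat fraction(s) in [0, 1]; vectorised.
#' @param voxel_volume Voxel volume in uL.
#' @param constants A `bat_constants`.
#' @return Data frame with `fat_volume`, `lean_volume` (uL), `fat_mass`,
#'   `lean_mass` (mg), `fat_energy`, `lean_energy`, `total_energy` (kcal).
#' @export
voxel_composition <- function(ff, voxel_volume,
                              constants = composition_constants()) {
  if (any(ff < 0 | ff > 1, na.rm = TRUE) || anyNA(ff))
    stop("ff must lie in [0, 1]")
  fv <- ff * voxel_volume
  lv <- (1 - ff) * voxel_volume
  data.frame(fat_volume = fv, lean_volume = lv,
             fat_mass = fv * constants$fat_density,
             lean_mass = lv * constants$lean_density,
             fat_energy = fv * constants$fat_energy,
             lean_energy = lv * constants$lean_energy,
             total_energy = fv * constants$fat_energy +
               lv * constants$lean_energy)
}

## Total metabolizable energy (kcal) per voxel, vectorised over an array.
voxel_energy <- function(ff, voxel_volume,
                         constants = composition_constants()) {
  voxel_volume * (ff * constants$fat_energy +
                    (1 - ff) * constants$lean_energy)
}

#' Depot fat/lean mass and energy totals
#'
#' Sums the per-voxel composition over the segmented depot, with a
#' fat-fraction-binned breakdown (0.5% bins by default) for
#' mass-versus-FF and energy-versus-FF curves. Masses are reported in g,
#' energies in kcal.
#'
#' @param ff FF array in [0, 1].
#' @param roi A `bat_roi`.
#' @param range A `bat_range` (percent).
#' @param constants A `bat_constants`.
#' @param bin_width Bin width of the FF breakdown, percent.
#' @return An object of class `bat_composition`: `totals` (one-row data
#'   frame: volumes in mL, masses in g, energies in kcal), `by_bin` (data
#'   frame per FF bin) and the constants used.
#' @export
depot_totals <- function(ff, roi, range = threshold_range(),
                         constants = composition_constants(),
                         bin_width = 0.5) {
  w <- roi_weights(roi)
  vv <- roi$voxel_volume
  lo <- range$lower / 100; hi <- range$upper / 100
  sel <- w > 0 & !is.na(ff) & ff >= lo & ff <= hi
  if (!any(sel)) warning("empty segmentation: totals are zero")
  ffs <- ff[sel]; ws <- w[sel]
  fat_ul <- sum(ws * ffs) * vv
  lean_ul <- sum(ws * (1 - ffs)) * vv
  totals <- data.frame(
    n_voxels = sum(ws),
    tissue_volume_ml = estimated_volume(sum(ws), vv),
    fat_volume_ml = fat_ul / 1000, lean_volume_ml = lean_ul / 1000,
    fat_mass_g = fat_ul * constants$fat_density / 1000,
    lean_mass_g = lean_ul * constants$lean_density / 1000,
    fat_energy_kcal = fat_ul * constants$fat_energy,
    lean_energy_kcal = lean_ul * constants$lean_energy)
  totals$total_energy_kcal <- totals$fat_energy_kcal +
    totals$lean_energy_kcal

  edges <- seq(range$lower, range$upper, by = bin_width)
  if (edges[length(edges)] < range$upper) edges <- c(edges, range$upper)
  bin <- findInterval(ffs * 100, edges, rightmost.closed = TRUE)
  nb <- length(edges) - 1
  acc <- function(x) {
    out <- numeric(nb)
    if (length(x)) {
      agg <- rowsum(x, bin)
      out[as.integer(rownames(agg))] <- agg[, 1]
    }
    out
  }
  wfat <- acc(ws * ffs) * vv
  wlean <- acc(ws * (1 - ffs)) * vv
  by_bin <- data.frame(
    bin_lower = edges[-length(edges)], bin_upper = edges[-1],
    n_voxels = acc(ws),
    fat_mass_g = wfat * constants$fat_density / 1000,
    lean_mass_g = wlean * constants$lean_density / 1000,
    fat_energy_kcal = wfat * constants$fat_energy,
    lean_energy_kcal = wlean * constants$lean_energy)
  structure(list(totals = totals, by_bin = by_bin, constants = constants,
                 range = range),
            class = "bat_composition")
}

#' @export
print.bat_composition <- function(x, ...) {
  t <- x$totals
  cat(sprintf("Depot composition, FF %g-%g%%\n", x$range$lower,
              x$range$upper))
  cat(sprintf("  volume %.1f mL; fat %.1f g, lean %.1f g; energy %.1f kcal (%.0f%% from fat)\n",
              t$tissue_volume_ml, t$fat_mass_g, t$lean_mass_g,
              t$total_energy_kcal,
              100 * t$fat_energy_kcal / t$total_energy_kcal))
  invisible(x)
}

#' Threshold sweep of cold-induced energy change
#'
#' Cohort-mean post-minus-pre change in total metabolizable energy for every
#' admissible threshold pair; a thin wrapper around `threshold_sweep` with
#' `quantity = "energy"`. Because lipid dominates the energy equivalent,
#' the sign of the change depends on the analysed range: restricting to
#' 30-70% FF can invert the conclusion drawn from the lipid-rich 70-100%
#' range.
#'
#' @inheritParams threshold_sweep
#' @return A `bat_sweep` with `quantity = "energy"` (kcal).
#' @export
energy_threshold_grid <- function(cohort, constants = composition_constants(),
                                  step = 1, lower_min = 30) {
  threshold_sweep(cohort, quantity = "energy", step = step,
                  lower_min = lower_min, constants = constants)
}

#' Regression of depot mass on depot volume
#'
#' Ordinary least squares of per-subject mass (g) on per-subject volume
#' (mL), reporting slope, intercept and R-squared.
#'
#' @param volumes Per-subject volumes, mL (>= 3 subjects).
#' @param masses Per-subject masses, g.
#' @return List with `slope`, `intercept`, `r2` and `p` (slope test).
#' @export
mass_volume_r2 <- function(volumes, masses) {
  if (length(volumes) < 3) stop("need at least 3 subjects")
  if (length(volumes) != length(masses)) stop("length mismatch")
  if (stats::sd(volumes) == 0) stop("zero variance in volumes")
  fit <- stats::lm(masses ~ volumes)
  s <- summary(fit)
  list(slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       r2 = s$r.squared,
       p = unname(s$coefficients[2, 4]))
}
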