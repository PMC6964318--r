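test_that("voxel composition follows the published constants", {
  cc <- composition_constants()
  ## a 1-uL voxel at FF 50% is half fat, half lean by volume
  v <- voxel_composition(0.5, 1, cc)
  expect_equal(v$fat_volume, 0.5)
  expect_equal(v$lean_volume, 0.5)
  expect_equal(v$fat_mass, 0.5 * 0.92)
  expect_equal(v$lean_mass, 0.5 * 1.06)
  ## pure fat: 0.92 mg and 9.4e-3 kcal per uL
  p <- voxel_composition(1, 1, cc)
  expect_equal(p$fat_mass, 0.92)
  expect_equal(p$fat_energy, 9.4e-3)
  expect_equal(p$lean_mass, 0)
  expect_error(voxel_composition(1.2, 1, cc), "\\[0, 1\\]")
  expect_error(composition_constants(fat_density = -1))
})

test_that("depot totals scale linearly and match the brute-force oracle", {
  cc <- composition_constants()
  shape <- c(10, 10, 10)
  roi <- roi_mask(array(TRUE, shape), 1)
  ones <- array(1, shape)
  dt <- depot_totals(ones, roi, threshold_range(30, 100), cc)
  expect_equal(dt$totals$fat_mass_g, 0.92)
  expect_equal(dt$totals$fat_energy_kcal, 9.4)
  expect_equal(dt$totals$lean_mass_g, 0)

  zeros <- array(0, shape)
  dt0 <- depot_totals(zeros, roi, threshold_range(0, 100), cc)
  expect_equal(dt0$totals$total_energy_kcal, dt0$totals$lean_energy_kcal)

  rv <- random_volume_fixture(seed = 17)
  dtr <- depot_totals(rv$ff_pre, rv$roi, threshold_range(30, 100), cc)
  oracle <- naive_depot_totals(rv$ff_pre, rv$roi$values, 30, 100, 0.548, cc)
  expect_equal(dtr$totals$fat_mass_g, unname(oracle["fat_mass_g"]),
               tolerance = 1e-10)
  expect_equal(dtr$totals$lean_mass_g, unname(oracle["lean_mass_g"]),
               tolerance = 1e-10)
  expect_equal(dtr$totals$total_energy_kcal,
               unname(oracle["total_energy_kcal"]), tolerance = 1e-10)
  ## binned breakdown sums back to the totals
  expect_equal(sum(dtr$by_bin$fat_mass_g), dtr$totals$fat_mass_g,
               tolerance = 1e-10)

  expect_warning(depot_totals(zeros, roi, threshold_range(30, 100), cc),
                 "empty")
})

test_that("fat and lean volumes partition the analysed volume exactly", {
  rv <- random_volume_fixture(seed = 23)
  for (rng in list(c(30, 100), c(50, 90), c(70, 100))) {
    dt <- depot_totals(rv$ff_pre, rv$roi, threshold_range(rng[1], rng[2]))
    expect_equal(dt$totals$fat_volume_ml + dt$totals$lean_volume_ml,
                 dt$totals$tissue_volume_ml, tolerance = 1e-12)
  }
})

test_that("energy is additive over disjoint voxel sets and fat-dominated", {
  cc <- composition_constants()
  set.seed(6)
  shape <- c(12, 12, 4)
  ff <- array(runif(prod(shape), 0.3, 1), shape)
  half1 <- array(FALSE, shape); half1[1:6, , ] <- TRUE
  roi_all <- roi_mask(array(TRUE, shape), 1)
  roi_a <- roi_mask(half1, 1)
  roi_b <- roi_mask(!half1, 1)
  rng <- threshold_range(0.001, 100)
  e_all <- depot_totals(ff, roi_all, rng, cc)$totals$total_energy_kcal
  e_a <- depot_totals(ff, roi_a, rng, cc)$totals$total_energy_kcal
  e_b <- depot_totals(ff, roi_b, rng, cc)$totals$total_energy_kcal
  expect_equal(e_all, e_a + e_b, tolerance = 1e-12)

  ## lipid dominates the energy equivalent whenever mean FF >= 0.3
  for (s in 1:5) {
    set.seed(s)
    ffs <- array(runif(prod(shape), 0.28, 1), shape)
    if (mean(ffs) < 0.3) next
    t <- depot_totals(ffs, roi_all, rng, cc)$totals
    expect_gte(t$fat_energy_kcal / t$total_energy_kcal, 0.8)
  }
})

test_that("energy threshold grid is consistent with direct depot totals", {
  rv <- random_volume_fixture(seed = 41)
  sub <- list(ff_pre = rv$ff_pre, ff_post = rv$ff_post,
              roi_pre = rv$roi, roi_post = rv$roi)
  eg <- energy_threshold_grid(list(sub), step = 10)
  cc <- composition_constants()
  rng <- threshold_range(30, 100)
  direct <- depot_totals(rv$ff_post, rv$roi, rng, cc)$totals$total_energy_kcal -
    depot_totals(rv$ff_pre, rv$roi, rng, cc)$totals$total_energy_kcal
  expect_equal(sweep_at(eg, 30, 100), direct, tolerance = 1e-9)

  sub0 <- sub; sub0$ff_post <- sub0$ff_pre
  eg0 <- energy_threshold_grid(list(sub0), step = 10)
  expect_equal(max(abs(eg0$delta), na.rm = TRUE), 0)
})

test_that("mass-volume regression matches closed-form least squares", {
  ## hand-computable 5-point set
  x <- c(1, 2, 3, 4, 5)
  y <- c(2.1, 3.9, 6.2, 7.8, 10.1)
  sxx <- sum((x - mean(x))^2)
  sxy <- sum((x - mean(x)) * (y - mean(y)))
  b <- sxy / sxx
  a <- mean(y) - b * mean(x)
  r2 <- (sxy^2 / sxx) / sum((y - mean(y))^2)
  fit <- mass_volume_r2(x, y)
  expect_equal(fit$slope, b, tolerance = 1e-12)
  expect_equal(fit$intercept, a, tolerance = 1e-12)
  expect_equal(fit$r2, r2, tolerance = 1e-12)

  ## exact collinearity (lm warns about the perfect fit, by design here)
  expect_equal(suppressWarnings(mass_volume_r2(x, 2 * x + 1)$r2), 1)
  ## pure noise: no association
  set.seed(14)
  expect_lt(mass_volume_r2(x, rnorm(5))$r2, 0.5)
  expect_error(mass_volume_r2(rep(1, 5), x), "variance")
  expect_error(mass_volume_r2(1:2, 1:2), "3 subjects")
})
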