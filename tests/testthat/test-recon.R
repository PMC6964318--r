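acq0 <- acquisition_params(noise_sd = 0)

test_that("signal model has the stated closed forms", {
  te <- echo_times(acq0)
  ## pure water, on resonance, no decay: constant 1
  s <- model_signal(1, 0, 0, Inf, acq0)
  expect_equal(s, rep(1 + 0i, 6), tolerance = 1e-12)
  ## T2* damping is exactly exp(-t/T2*) relative to the undamped signal
  s_inf <- model_signal(0.4, 0.6, 30, Inf, acq0)
  s_t2 <- model_signal(0.4, 0.6, 30, 15, acq0)
  expect_equal(Mod(s_t2) / Mod(s_inf), exp(-te * 1000 / 15),
               tolerance = 1e-12)
  expect_error(model_signal(1, 0, 0, -5, acq0), "positive")
})

test_that("single-voxel fit recovers noiseless parameters", {
  te <- echo_times(acq0)
  sig <- model_signal(0.3, 0.7, 40, 15, acq0)
  fit <- fit_voxel(sig, te, psi_init = 40, acq0)
  expect_true(fit$fit_ok)
  expect_equal(fit$water, 0.3, tolerance = 1e-6)
  expect_equal(fit$fat, 0.7, tolerance = 1e-6)
  expect_equal(fit$fieldmap, 40, tolerance = 1e-4)
  expect_equal(fit$t2star, 15, tolerance = 1e-4)
  expect_lt(fit$residual, 1e-8)
})

test_that("initialising across the ambiguity yields the swapped solution", {
  ## the field-map ambiguity: shifting psi by about the dominant fat
  ## frequency exchanges the water and fat roles; this is what region
  ## growing protects against
  te <- echo_times(acq0)
  sig <- model_signal(0.3, 0.7, 40, 15, acq0)
  f_main <- acq0$fat_peaks$freq_hz[which.max(acq0$fat_peaks$rel_amp)]
  fit <- fit_voxel(sig, te, psi_init = 40 + f_main, acq0)
  expect_gt(abs(fit$fieldmap - 40), 100)  # different psi basin
  expect_gt(fit$water, fit$fat)           # roles exchanged
})

test_that("degenerate voxels are flagged, not fitted", {
  te <- echo_times(acq0)
  fit <- fit_voxel(rep(0 + 0i, 6), te, 0, acq0)
  expect_false(fit$fit_ok)
  expect_error(fit_voxel(rep(1 + 0i, 3), te[1:3], 0, acq0), "4 echoes")
})

test_that("field-map estimation tracks a smooth truth without swaps", {
  rt <- roundtrip_fixture()
  fm <- estimate_fieldmap(rt$echoes, downsample_factor = 2)
  truth <- rt$phantom$fieldmap_true
  body <- rt$phantom$body
  err <- abs(fm$psi_init - truth)[body]
  ## within one 2-Hz grid step at nearly all foreground voxels (upsampling
  ## smears a thin rim at the body boundary)
  expect_gt(mean(err <= 3), 0.97)

  ## null field: returned psi ~ 0 everywhere on the foreground
  ph0 <- generate_phantom(c(16, 16, 4), seed = 2)
  ph0$fieldmap_true[] <- 0
  ec0 <- simulate_echo_series(ph0, acq0, seed = 1)
  fm0 <- estimate_fieldmap(ec0, downsample_factor = 1)
  expect_lt(max(abs(fm0$psi_init[ph0$body])), 2.5)

  ## empty input rejected
  ph0$pd[] <- 0
  ec_empty <- simulate_echo_series(ph0, acq0, seed = 1)
  expect_error(estimate_fieldmap(ec_empty), "foreground")
})

test_that("noiseless round trip recovers FF, T2* and the printed equation", {
  rt <- roundtrip_fixture()
  ph <- rt$phantom; mp <- rt$maps
  roi <- ph$roi
  expect_lt(max(abs(mp$ff[roi] - ph$ff_true[roi])), 0.005)
  expect_lt(sqrt(mean((mp$t2star[roi] - ph$t2s_true[roi])^2)), 0.5)
  ## no water-fat swaps anywhere in the fitted volume
  ok <- mp$fit_ok & ph$body
  expect_equal(mean(abs(mp$ff[ok] - ph$ff_true[ok]) > 0.25), 0)
  ## ff is exactly fat/(fat+water) wherever defined
  tot <- mp$fat[ok] + mp$water[ok]
  expect_equal(mp$ff[ok], mp$fat[ok] / tot, tolerance = 1e-12)
  ## direct application of the fat-fraction equation
  expect_equal(75 / (75 + 25), 0.75)
  sig <- model_signal(25, 75, 10, 18, acq0)
  fit <- fit_voxel(sig, echo_times(acq0), 10, acq0)
  expect_equal(fit$fat / (fit$fat + fit$water), 0.75, tolerance = 1e-6)
})

test_that("FF bias stays small at realistic noise levels", {
  ph <- generate_phantom(c(40, 40, 8), seed = 21)
  ec <- simulate_echo_series(ph, acquisition_params(noise_sd = 0.02),
                             seed = 3)
  mp <- reconstruct_maps(ec)
  roi <- ph$roi & mp$fit_ok
  expect_gt(sum(roi), 1000)
  expect_lt(abs(mean(mp$ff[roi] - ph$ff_true[roi])), 0.01)
})

test_that("echo metadata inconsistencies are rejected", {
  rt <- roundtrip_fixture()
  bad <- rt$echoes
  bad$te <- bad$te[-1]
  expect_error(reconstruct_maps(bad), "disagrees")
  bad2 <- rt$echoes
  bad2$te <- rev(bad2$te)
  expect_error(reconstruct_maps(bad2), "increasing")
})
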