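test_that("phantom generation is deterministic and respects its invariants", {
  ph1 <- generate_phantom(c(32, 32, 8), seed = 7)
  ph2 <- generate_phantom(c(32, 32, 8), seed = 7)
  expect_identical(ph1, ph2)

  expect_true(all(ph1$ff_true >= 0 & ph1$ff_true <= 1))
  expect_true(all(ph1$ff_true[ph1$roi] >= 0.3))
  expect_true(all(ph1$t2s_true[ph1$roi] > 0))
  expect_false(any(ph1$roi & ph1$sat_roi))
  expect_true(sum(ph1$sat_roi) > 0)
  ## SAT control sits in the subcutaneous-fat FF range
  expect_true(all(ph1$ff_true[ph1$sat_roi] >= 0.7))

  expect_error(generate_phantom(c(32, 32, 8), seed = 1, voxel_volume = 0),
               "voxel_volume")
  expect_error(generate_phantom(c(8, 8, 2)), "16 x 16 x 4")
})

test_that("phantom T2* rises with lipid content", {
  ph <- generate_phantom(c(32, 32, 8), seed = 7)
  hi <- ph$roi & ph$ff_true > 0.9
  lo <- ph$roi & ph$ff_true < 0.5
  expect_gt(sum(hi), 10)
  expect_gt(sum(lo), 10)
  expect_gt(median(ph$t2s_true[hi]), median(ph$t2s_true[lo]))
})

test_that("cold effect follows the logistic response formula", {
  ph <- generate_phantom(c(32, 32, 8), seed = 3)

  ## identity: no loss, no gain, no noise
  null_cold <- cold_effect_params(0, 0, 0.45, 0.05, t2s_shift = 0,
                                  noise_sd = 0)
  post0 <- apply_cold_effect(ph, null_cold, seed = 1)
  expect_identical(post0$ff_true, ph$ff_true)

  ## pure-loss, noiseless, homogeneous: delta = -L * logistic((ff - t)/w)
  cold <- cold_effect_params(0.1, 0, 0.45, 0.05, t2s_shift = 0,
                             noise_sd = 0, heterogeneity = 0)
  post <- apply_cold_effect(ph, cold, seed = 1)
  d <- (post$ff_true - ph$ff_true)[ph$roi]
  expected <- -0.1 * plogis((ph$ff_true[ph$roi] - 0.45) / 0.05)
  expect_equal(d, expected, tolerance = 1e-12)
  ## near-pure-fat voxels lose close to the full saturated amplitude
  top <- ph$ff_true[ph$roi] > 0.99
  if (any(top)) expect_equal(d[top], rep(-0.1, sum(top)), tolerance = 1e-3)

  ## T2* shift confined to the depot
  cold2 <- cold_effect_params(0, 0, 0.45, 0.05, t2s_shift = 2, noise_sd = 0)
  post2 <- apply_cold_effect(ph, cold2, seed = 1)
  expect_equal(post2$t2s_true[ph$roi], ph$t2s_true[ph$roi] + 2)
  expect_identical(post2$t2s_true[ph$sat_roi], ph$t2s_true[ph$sat_roi])
})

test_that("default cold response loses fat at high FF, gains at low FF", {
  ph <- generate_phantom(c(64, 64, 16), seed = 11)
  post <- apply_cold_effect(ph, cold_effect_params(), seed = 12)
  d <- post$ff_true - ph$ff_true
  expect_lt(mean(d[ph$roi & ph$ff_true > 0.8]), 0)
  expect_gte(mean(d[ph$roi & ph$ff_true < 0.4]), 0)
  ## clipping never leaves [0, 1] and touches under 1% of voxels
  expect_true(all(post$ff_true >= 0 & post$ff_true <= 1))
  expect_lt(attr(post, "clipped_frac"), 0.01)
  ## SAT control untouched
  expect_identical(post$ff_true[ph$sat_roi], ph$ff_true[ph$sat_roi])
})

test_that("echo simulation matches the closed-form signal model", {
  ph <- generate_phantom(c(16, 16, 4), seed = 5)
  ## fat-free limit: |signal| = W * exp(-t / T2*)
  ph$ff_true[] <- 0
  ph$fieldmap_true[] <- 0
  acq <- acquisition_params(noise_sd = 0)
  ec <- simulate_echo_series(ph, acq, seed = 1)
  v <- which(ph$body)[1]
  idx <- arrayInd(v, dim(ph$ff_true))
  sig <- ec$data[idx[1], idx[2], idx[3], ]
  expect_equal(Mod(sig),
               exp(-ec$te * 1000 / ph$t2s_true[v]), tolerance = 1e-12)

  ## single fat peak, no decay, no off-resonance: periodic with 1/f1
  peak <- data.frame(ppm = -3.4, freq_hz = -400, rel_amp = 1)
  acq1 <- acquisition_params(fat_peaks = peak, noise_sd = 0)
  s <- model_signal(0, 1, 0, Inf, acq1, te = c(0, 1, 2, 3) / 400)
  expect_equal(s, rep(1 + 0i, 4), tolerance = 1e-9)

  ## determinism with noise
  acqn <- acquisition_params(noise_sd = 0.01)
  e1 <- simulate_echo_series(generate_phantom(c(16, 16, 4), 5), acqn, seed = 2)
  e2 <- simulate_echo_series(generate_phantom(c(16, 16, 4), 5), acqn, seed = 2)
  expect_identical(e1$data, e2$data)
})

test_that("acquisition parameter validation rejects bad spectra", {
  bad <- fat_spectrum_6peak()
  bad$rel_amp[1] <- bad$rel_amp[1] + 0.01
  expect_error(acquisition_params(fat_peaks = bad), "sum to 1")
  expect_error(acquisition_params(n_echoes = 2))
  expect_equal(sum(fat_spectrum_6peak()$rel_amp), 1, tolerance = 1e-9)
})
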