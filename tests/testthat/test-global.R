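test_that("joint segmentation applies the threshold rule at both time points", {
  shape <- c(16, 16, 4)
  roi <- roi_mask(array(TRUE, dim = shape), 0.548)
  ff <- array(0.5, dim = shape)
  ## vacuous 0-100 threshold keeps the whole ROI
  seg <- segment_joint(ff, ff, roi, roi, threshold_range(0.001, 100))
  expect_equal(length(seg$idx_pre), prod(shape))

  ## direct rule on values 20/40/80%: 40 and 80 retained at 30-100
  ff3 <- array(0.5, dim = shape)
  ff3[1:3] <- c(0.2, 0.4, 0.8)
  seg3 <- segment_joint(ff3, ff3, roi, roi, threshold_range(30, 100))
  expect_false(1 %in% seg3$idx_pre)
  expect_true(all(c(2, 3) %in% seg3$idx_pre))

  expect_error(segment_joint(ff, ff, roi, roi, list(lower = 30, upper = 100)),
               "bat_range")
  expect_error(threshold_range(80, 40))
  expect_error(threshold_range(-1, 50))
})

test_that("segmentation and histograms match brute-force per-voxel loops", {
  rv <- random_volume_fixture()
  w <- rv$roi$values
  for (rng in list(c(30, 100), c(50, 100), c(70, 100), c(30, 70))) {
    seg <- segment_joint(rv$ff_pre, rv$ff_post, rv$roi, rv$roi,
                         threshold_range(rng[1], rng[2]))
    expect_identical(sum(seg$w_pre),
                     naive_segment_count(rv$ff_pre, w, rng[1], rng[2]))
    expect_identical(sum(seg$w_post),
                     naive_segment_count(rv$ff_post, w, rng[1], rng[2]))
  }
  h <- volume_histogram(rv$ff_pre, rv$roi, bin_width = 0.5,
                        range = threshold_range(30, 100))
  expect_equal(h$volume_ml,
               naive_volume_histogram(rv$ff_pre, w, 0.5, 30, 100, 0.548))

  ## fractional ROI weights behave identically
  set.seed(3)
  wfrac <- array(runif(prod(dim(w))), dim = dim(w))
  roif <- roi_mask(wfrac, 0.548)
  segf <- segment_joint(rv$ff_pre, rv$ff_post, roif, roif,
                        threshold_range(30, 100))
  expect_equal(sum(segf$w_pre),
               naive_segment_count(rv$ff_pre, wfrac, 30, 100),
               tolerance = 1e-10)
})

test_that("estimated volume converts voxel counts as published", {
  expect_equal(round(estimated_volume(93275, 0.548)), 51)
  expect_equal(estimated_volume(0, 0.548), 0)
  expect_equal(estimated_volume(1000, 1.0), 1.0)
})

test_that("histogram bars conserve the segmented volume", {
  rv <- random_volume_fixture(seed = 5)
  rng <- threshold_range(30, 100)
  h <- volume_histogram(rv$ff_pre, rv$roi, 0.5, rng)
  seg <- segment_joint(rv$ff_pre, rv$ff_pre, rv$roi, rv$roi, rng)
  expect_identical(sum(h$n_voxels), sum(seg$w_pre))
  expect_equal(sum(h$volume_ml), estimated_volume(sum(seg$w_pre), 0.548))

  ## a single uniform-FF ROI lands in exactly one bin
  shape <- c(16, 16, 4)
  u <- array(0.552, dim = shape)
  hu <- volume_histogram(u, roi_mask(array(TRUE, shape), 1), 0.5)
  nz <- hu[hu$n_voxels > 0, ]
  expect_equal(nrow(nz), 1)
  expect_equal(nz$bin_lower, 55)
  expect_equal(nz$n_voxels, prod(shape))

  ## one full-range bin holds everything
  h1 <- volume_histogram(rv$ff_pre, rv$roi, 100)
  expect_equal(nrow(h1), 1)
  expect_equal(h1$n_voxels, sum(rv$roi$values))
})

test_that("widening the threshold range never loses voxels", {
  rv <- random_volume_fixture(seed = 12)
  set.seed(2)
  for (i in 1:20) {
    lo <- runif(1, 0, 50); hi <- runif(1, 60, 100)
    wider <- segment_joint(rv$ff_pre, rv$ff_post, rv$roi, rv$roi,
                           threshold_range(max(lo - 10, 0), min(hi + 10, 100)))
    inner <- segment_joint(rv$ff_pre, rv$ff_post, rv$roi, rv$roi,
                           threshold_range(lo, hi))
    expect_gte(sum(wider$w_pre), sum(inner$w_pre))
    expect_gte(sum(wider$w_paired), sum(inner$w_paired))
  }
})

test_that("paired statistics handle textbook and degenerate cases", {
  ## closed-form t on a 3-pair example, computed from first principles
  pre <- c(1, 2, 3); post <- c(2, 4, 5)
  d <- post - pre
  t_hand <- mean(d) / (sd(d) / sqrt(3))
  st <- paired_stats(pre, post)
  expect_equal(st$t, t_hand, tolerance = 1e-12)
  expect_equal(st$p, 2 * pt(-abs(t_hand), df = 2), tolerance = 1e-12)

  ## identical pairs: p = 1 by convention
  st0 <- paired_stats(pre, pre)
  expect_equal(st0$mean_diff, 0)
  expect_equal(st0$p, 1)
  expect_true(st0$degenerate)

  ## constant nonzero differences: flagged, not p = 0
  st1 <- paired_stats(c(0, 0), c(1, 1))
  expect_true(st1$degenerate)
  expect_true(is.na(st1$p))

  ## translation equivariance
  st2 <- paired_stats(pre, pre + 1)
  expect_equal(st2$mean_diff, 1)

  expect_error(paired_stats(1:3, 1:4), "differ")
})

test_that("threshold sweep matches the naive per-pair loop", {
  rv <- random_volume_fixture(seed = 31)
  sub <- list(ff_pre = rv$ff_pre, ff_post = rv$ff_post,
              roi_pre = rv$roi, roi_post = rv$roi,
              t2_pre = rv$ff_pre * 30, t2_post = rv$ff_post * 30)
  for (q in c("volume", "energy", "ff", "t2star")) {
    sw <- threshold_sweep(list(sub), q, step = 10, lower_min = 30)
    for (lo in c(30, 50, 70)) for (hi in c(80, 100)) {
      expect_equal(sweep_at(sw, lo, hi),
                   naive_sweep_delta(sub, q, lo, hi), tolerance = 1e-9,
                   label = sprintf("%s at %d-%d", q, lo, hi))
    }
    ## invalid cells flagged
    expect_true(is.na(sweep_at(sw, 20, 80)))
    expect_true(is.na(sweep_at(sw, 50, 40)))
  }

  ## identical time points give an all-zero grid
  sub0 <- list(ff_pre = rv$ff_pre, ff_post = rv$ff_pre,
               roi_pre = rv$roi, roi_post = rv$roi,
               t2_pre = rv$ff_pre * 30, t2_post = rv$ff_pre * 30)
  for (q in c("volume", "ff")) {
    sw0 <- threshold_sweep(list(sub0), q, step = 10, lower_min = 30)
    expect_equal(max(abs(sw0$delta), na.rm = TRUE), 0)
  }
})

test_that("binned volume change reports per-interval tests", {
  rv <- random_volume_fixture(seed = 9)
  sub <- list(ff_pre = rv$ff_pre, ff_post = rv$ff_post,
              roi_pre = rv$roi, roi_post = rv$roi)
  ## identical pre/post: all-zero deltas, p = 1 by convention
  sub0 <- sub; sub0$ff_post <- sub0$ff_pre
  out0 <- binned_volume_change(list(sub0, sub0, sub0))
  expect_equal(out0$mean_dvol_ml, rep(0, 7))
  expect_equal(out0$p, rep(1, 7))
  expect_true(all(out0$degenerate))

  ## single subject: descriptive only, with a warning
  expect_warning(out1 <- binned_volume_change(list(sub)), "fewer than 2")
  expect_true(all(is.na(out1$p)))
  expect_equal(nrow(out1), 7)
})
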