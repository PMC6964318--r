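## Shared fixtures (built once per run) and brute-force oracles.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- builder()
  .fixtures[[name]]
}

## Noiseless phantom -> acquisition -> reconstruction round trip, 32x32x8.
roundtrip_fixture <- function() {
  fixture("roundtrip", function() {
    ph <- generate_phantom(c(32, 32, 8), seed = 7)
    ec <- simulate_echo_series(ph, acquisition_params(noise_sd = 0), seed = 1)
    list(phantom = ph, echoes = ec, maps = reconstruct_maps(ec))
  })
}

## Default seeded 9-subject synthetic cohort (truth maps + measurement noise).
cohort_fixture <- function() {
  fixture("cohort", function() simulate_cohort(default_config(seed = 1)))
}

## Small random FF volume + binary ROI for oracle-equivalence tests.
random_volume_fixture <- function(seed = 42, shape = c(16, 16, 16)) {
  set.seed(seed)
  ff_pre <- array(runif(prod(shape)), dim = shape)
  ff_post <- array(runif(prod(shape)), dim = shape)
  roi <- array(runif(prod(shape)) > 0.3, dim = shape)
  list(ff_pre = ff_pre, ff_post = ff_post,
       roi = roi_mask(roi, voxel_volume = 0.548))
}

## ---- brute-force oracles (independent per-voxel loops) ----------------

naive_segment_count <- function(ff, roi_values, lower, upper) {
  n <- 0
  for (i in seq_along(ff)) {
    if (roi_values[i] > 0 && !is.na(ff[i]) &&
        ff[i] * 100 >= lower && ff[i] * 100 <= upper)
      n <- n + roi_values[i]
  }
  n
}

naive_volume_histogram <- function(ff, roi_values, bin_width, lower, upper,
                                   voxel_volume) {
  edges <- seq(lower, upper, by = bin_width)
  counts <- numeric(length(edges) - 1)
  for (i in seq_along(ff)) {
    if (roi_values[i] <= 0 || is.na(ff[i])) next
    v <- ff[i] * 100
    if (v < lower || v > upper) next
    b <- min(floor((v - lower) / bin_width) + 1, length(counts))
    counts[b] <- counts[b] + roi_values[i]
  }
  counts * voxel_volume / 1000
}

naive_joint_histogram <- function(x, y, x_breaks, y_breaks) {
  nx <- length(x_breaks) - 1; ny <- length(y_breaks) - 1
  m <- matrix(0L, nx, ny)
  for (i in seq_along(x)) {
    bx <- by <- NA
    for (b in seq_len(nx))
      if (x[i] >= x_breaks[b] &&
          (x[i] < x_breaks[b + 1] || (b == nx && x[i] <= x_breaks[b + 1])))
        bx <- b
    for (b in seq_len(ny))
      if (y[i] >= y_breaks[b] &&
          (y[i] < y_breaks[b + 1] || (b == ny && y[i] <= y_breaks[b + 1])))
        by <- b
    if (!is.na(bx) && !is.na(by)) m[bx, by] <- m[bx, by] + 1L
  }
  m
}

naive_depot_totals <- function(ff, roi_values, lower, upper, voxel_volume,
                               constants) {
  fat_ul <- lean_ul <- 0
  for (i in seq_along(ff)) {
    if (roi_values[i] <= 0 || is.na(ff[i])) next
    v <- ff[i] * 100
    if (v < lower || v > upper) next
    fat_ul <- fat_ul + roi_values[i] * ff[i] * voxel_volume
    lean_ul <- lean_ul + roi_values[i] * (1 - ff[i]) * voxel_volume
  }
  c(fat_mass_g = fat_ul * constants$fat_density / 1000,
    lean_mass_g = lean_ul * constants$lean_density / 1000,
    total_energy_kcal = fat_ul * constants$fat_energy +
      lean_ul * constants$lean_energy)
}

## Per-pair sweep values by direct masking (no prefix-sum tricks).
naive_sweep_delta <- function(sub, quantity, lower, upper,
                              constants = composition_constants()) {
  vv <- sub$roi_pre$voxel_volume
  wp <- sub$roi_pre$values; wq <- sub$roi_post$values
  lo <- lower / 100; hi <- upper / 100
  in_pre <- wp > 0 & sub$ff_pre >= lo & sub$ff_pre <= hi
  in_post <- wq > 0 & sub$ff_post >= lo & sub$ff_post <= hi
  if (quantity == "volume") {
    sum(wq[in_post]) * vv / 1000 - sum(wp[in_pre]) * vv / 1000
  } else if (quantity == "energy") {
    epost <- voxel_energy(sub$ff_post, vv, constants)
    epre <- voxel_energy(sub$ff_pre, vv, constants)
    sum(wq[in_post] * epost[in_post]) - sum(wp[in_pre] * epre[in_pre])
  } else {
    both <- in_pre & in_post
    w <- pmin(wp, wq)[both]
    if (sum(w) == 0) return(NA_real_)
    pre_v <- if (quantity == "ff") sub$ff_pre * 100 else sub$t2_pre
    post_v <- if (quantity == "ff") sub$ff_post * 100 else sub$t2_post
    sum(w * post_v[both]) / sum(w) - sum(w * pre_v[both]) / sum(w)
  }
}

## Four well-separated planted Gaussian blobs in 2-D.
planted_blobs <- function(n_per = 150, seed = 99, sep = 12) {
  set.seed(seed)
  centers <- matrix(c(0, 0, sep, 0, 0, sep, sep, sep), ncol = 2,
                    byrow = TRUE)
  X <- do.call(rbind, lapply(1:4, function(k)
    cbind(rnorm(n_per, centers[k, 1], 0.5),
          rnorm(n_per, centers[k, 2], 0.5))))
  list(x = X, labels = rep(1:4, each = n_per))
}

## Best-case label agreement under cluster relabelling.
label_agreement <- function(found, truth) {
  tab <- table(found, truth)
  sum(apply(tab, 1, max)) / length(truth)
}
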