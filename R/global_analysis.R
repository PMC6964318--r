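#' Fat-fraction threshold range
#'
#' Thresholds are expressed in percent and applied inclusively on both ends
#' (`lower <= FF <= upper`). For BAT analyses a lower threshold of 30% is
#' the default floor: voxels in the 10-30% interval sit mostly at the depot
#' boundary adjacent to muscle, so excluding them avoids non-fatty tissue
#' and partial-volume effects.
#'
#' @param lower,upper Thresholds in percent, `0 <= lower < upper <= 100`.
#' @return An object of class `bat_range`.
#' @export
threshold_range <- function(lower = 30, upper = 100) {
  if (!(lower >= 0 && lower < upper && upper <= 100))
    stop("need 0 <= lower < upper <= 100")
  structure(list(lower = lower, upper = upper), class = "bat_range")
}

roi_weights <- function(roi) {
  if (inherits(roi, "bat_roi")) roi$values else roi * 1
}

#' Joint fat-fraction segmentation of paired time points
#'
#' Selects voxels with `lower <= FF <= upper` within the ROI at each time
#' point independently. For volume analyses the two selections are kept
#' separate (segmented volumes may differ between time points); for paired
#' FF/T2* analyses only voxels passing the threshold at both time points
#' contribute, i.e. sub-threshold voxels are excluded in both the
#' thermoneutral and post-cooling ROIs.
#'
#' @param ff_pre,ff_post FF arrays in [0, 1].
#' @param roi_pre,roi_post `bat_roi` masks (weights in [0, 1]) or arrays.
#' @param range A `bat_range` in percent.
#' @return List with per-timepoint indices/weights (`idx_pre`, `w_pre`,
#'   `idx_post`, `w_post`) and the paired set (`idx_paired`, `w_paired`,
#'   elementwise minimum of the two weights).
#' @export
segment_joint <- function(ff_pre, ff_post, roi_pre, roi_post,
                          range = threshold_range()) {
  if (!inherits(range, "bat_range")) stop("range must be a bat_range")
  w_pre <- roi_weights(roi_pre); w_post <- roi_weights(roi_post)
  stopifnot(identical(dim(ff_pre), dim(ff_post)),
            identical(dim(ff_pre), dim(w_pre)))
  lo <- range$lower / 100; hi <- range$upper / 100
  in_pre <- w_pre > 0 & !is.na(ff_pre) & ff_pre >= lo & ff_pre <= hi
  in_post <- w_post > 0 & !is.na(ff_post) & ff_post >= lo & ff_post <= hi
  both <- in_pre & in_post
  list(idx_pre = which(in_pre), w_pre = w_pre[in_pre],
       idx_post = which(in_post), w_post = w_post[in_post],
       idx_paired = which(both),
       w_paired = pmin(w_pre, w_post)[both],
       range = range)
}

#' Estimated depot volume from a voxel count
#'
#' `n_voxels * voxel_volume / 1000`, i.e. microlitres to millilitres. With
#' the protocol voxel volume of 0.548 uL, 93275 segmented voxels give 51 mL.
#'
#' @param n_voxels Number of (possibly fractionally weighted) voxels.
#' @param voxel_volume Volume of a single voxel in microlitres.
#' @return Volume in millilitres.
#' @export
estimated_volume <- function(n_voxels, voxel_volume) {
  stopifnot(all(n_voxels >= 0), voxel_volume > 0)
  n_voxels * voxel_volume / 1000
}

#' Volume histogram across the fat-fraction axis
#'
#' Bins are half-open `[b, b + w)` except the last, which includes the upper
#' edge so that the bars partition the inclusive segmentation `lower <= FF
#' <= upper` exactly: the bar heights (voxel count times voxel volume) sum
#' to the segmented volume of the analysed range.
#'
#' @param ff FF array in [0, 1].
#' @param roi A `bat_roi` (or array of weights).
#' @param bin_width Bin width in percent (default 0.5).
#' @param range A `bat_range`; only FF values inside it are binned.
#' @param voxel_volume Voxel volume in uL; taken from `roi` if a `bat_roi`.
#' @return Data frame with `bin_lower`, `bin_upper`, `n_voxels` (weighted)
#'   and `volume_ml`.
#' @export
volume_histogram <- function(ff, roi, bin_width = 0.5,
                             range = threshold_range(0, 100),
                             voxel_volume = NULL) {
  stopifnot(bin_width > 0)
  vv <- voxel_volume %||% (if (inherits(roi, "bat_roi")) roi$voxel_volume
                           else stop("voxel_volume required"))
  w <- roi_weights(roi)
  sel <- w > 0 & !is.na(ff)
  ffp <- ff[sel] * 100
  wv <- w[sel]
  keep <- ffp >= range$lower & ffp <= range$upper
  ffp <- ffp[keep]; wv <- wv[keep]
  edges <- seq(range$lower, range$upper, by = bin_width)
  if (edges[length(edges)] < range$upper) edges <- c(edges, range$upper)
  bin <- findInterval(ffp, edges, rightmost.closed = TRUE)
  n <- length(edges) - 1
  counts <- numeric(n)
  if (length(bin)) {
    agg <- rowsum(wv, bin)
    counts[as.integer(rownames(agg))] <- agg[, 1]
  }
  data.frame(bin_lower = edges[-length(edges)], bin_upper = edges[-1],
             n_voxels = counts,
             volume_ml = estimated_volume(counts, vv))
}

#' Paired pre/post statistics
#'
#' Shapiro-Wilk normality check on the paired differences, then a two-sided
#' paired Student's t-test at the 0.05 level, uncorrected for multiple
#' comparisons. Zero-variance differences are flagged as degenerate rather
#' than reported as p = 0; identical pairs (all differences zero) return
#' p = 1 by convention.
#'
#' @param pre,post Per-subject values, equal length >= 2.
#' @return List with means and SEMs of both arms, mean and SEM of the
#'   difference, `shapiro_p`, `t`, `p`, `significant` and `degenerate`.
#' @export
paired_stats <- function(pre, post) {
  if (length(pre) != length(post)) stop("pre and post lengths differ")
  if (length(pre) < 2) stop("need at least 2 paired observations")
  d <- post - pre
  sem <- function(x) stats::sd(x) / sqrt(length(x))
  shapiro_p <- if (length(d) >= 3 && stats::sd(d) > 0)
    tryCatch(stats::shapiro.test(d)$p.value, error = function(e) NA_real_)
  else NA_real_
  if (stats::sd(d) == 0) {
    degenerate <- TRUE
    p <- if (all(d == 0)) 1 else NA_real_
    tstat <- NA_real_
  } else {
    degenerate <- FALSE
    tt <- stats::t.test(post, pre, paired = TRUE)
    p <- tt$p.value
    tstat <- unname(tt$statistic)
  }
  list(mean_pre = mean(pre), sem_pre = sem(pre),
       mean_post = mean(post), sem_post = sem(post),
       mean_diff = mean(d), sem_diff = sem(d),
       shapiro_p = shapiro_p, t = tstat, p = p,
       significant = isTRUE(p < 0.05), degenerate = degenerate)
}

#' Global depot summary at one time point
#'
#' Weighted segmented voxel count, estimated volume (`Vol_BAT`), global mean
#' FF (`FF_Glob`, percent) and global mean T2* (`T2*_Glob`, ms) within a
#' threshold range. Applied to a deltoid subcutaneous ROI with a 70-100%
#' range this yields `FF_SAT`.
#'
#' @param ff FF array in [0, 1].
#' @param t2star T2* array in ms (may be NULL).
#' @param roi A `bat_roi`.
#' @param range A `bat_range`.
#' @param timepoint Label, e.g. "thermoneutral" or "post_cooling".
#' @return One-row data frame with `n_voxels`, `vol_ml`, `ff_glob`,
#'   `t2_glob`, range bounds, label and time point.
#' @export
depot_summary <- function(ff, t2star = NULL, roi, range = threshold_range(),
                          timepoint = "thermoneutral") {
  w <- roi_weights(roi)
  lo <- range$lower / 100; hi <- range$upper / 100
  sel <- w > 0 & !is.na(ff) & ff >= lo & ff <= hi
  wn <- w[sel]
  n <- sum(wn)
  data.frame(label = if (inherits(roi, "bat_roi")) roi$label else "roi",
             timepoint = timepoint,
             lower = range$lower, upper = range$upper,
             n_voxels = n,
             vol_ml = estimated_volume(n, roi$voxel_volume),
             ff_glob = if (n > 0) 100 * sum(wn * ff[sel]) / n else NA_real_,
             t2_glob = if (!is.null(t2star) && n > 0)
               sum(wn * t2star[sel]) / n else NA_real_)
}

#' Cold-induced volume change per 10% fat-fraction interval
#'
#' For each FF interval, the per-subject post-minus-pre change in segmented
#' volume (each time point segmented independently), with cohort mean, SEM,
#' Shapiro-Wilk check and a two-sided paired t-test. With fewer than two
#' subjects the test is omitted with a warning.
#'
#' @param cohort List of subjects, each a list with `ff_pre`, `ff_post`,
#'   `roi_pre`, `roi_post` (`bat_roi`).
#' @param bin_width Interval width in percent (default 10).
#' @param range Overall analysed `bat_range`.
#' @return Data frame, one row per interval, with per-bin mean change,
#'   SEM, `shapiro_p`, `p` and `significant`.
#' @export
binned_volume_change <- function(cohort, bin_width = 10,
                                 range = threshold_range(30, 100)) {
  edges <- seq(range$lower, range$upper, by = bin_width)
  n_sub <- length(cohort)
  lowers <- edges[-length(edges)]; uppers <- edges[-1]
  deltas <- matrix(NA_real_, n_sub, length(lowers))
  for (s in seq_len(n_sub)) {
    sub <- cohort[[s]]
    for (b in seq_along(lowers)) {
      rng <- threshold_range(lowers[b], uppers[b])
      seg <- segment_joint(sub$ff_pre, sub$ff_post, sub$roi_pre,
                           sub$roi_post, rng)
      vv <- sub$roi_pre$voxel_volume
      deltas[s, b] <- estimated_volume(sum(seg$w_post), vv) -
        estimated_volume(sum(seg$w_pre), vv)
    }
  }
  out <- data.frame(lower = lowers, upper = uppers,
                    mean_dvol_ml = colMeans(deltas),
                    sem_dvol_ml = apply(deltas, 2, stats::sd) / sqrt(n_sub),
                    shapiro_p = NA_real_, p = NA_real_, t = NA_real_,
                    significant = NA, degenerate = NA)
  if (n_sub < 2) {
    warning("fewer than 2 subjects: paired tests omitted")
    return(out)
  }
  for (b in seq_along(lowers)) {
    st <- paired_stats(rep(0, n_sub), deltas[, b])
    out$shapiro_p[b] <- st$shapiro_p
    out$p[b] <- st$p
    out$t[b] <- st$t
    out$significant[b] <- st$significant
    out$degenerate[b] <- st$degenerate
  }
  out
}

## Per-subject per-timepoint segmented totals for every (lower, upper) pair
## at step granularity, via sorted-FF prefix sums: count and value sums for
## lower <= FF <= upper are differences of cumulative sums, evaluated
## exactly (thresholds compared against the actual FF values, not bins).
pair_totals_independent <- function(ff, w, lowers, uppers, values = NULL) {
  sel <- w > 0 & !is.na(ff)
  x <- ff[sel] * 100
  wv <- w[sel]
  ord <- order(x)
  x <- x[ord]; wv <- wv[ord]
  vv <- if (!is.null(values)) values[sel][ord] * wv
  cw <- c(0, cumsum(wv))
  cv <- if (!is.null(values)) c(0, cumsum(vv))
  n_le <- findInterval(uppers, x)                 # FF <= upper
  n_lt <- findInterval(lowers, x, left.open = TRUE)  # FF < lower
  count <- outer(n_lt, n_le, function(a, b) cw[b + 1] - cw[a + 1])
  count[count < 0] <- 0
  val <- if (!is.null(values))
    outer(n_lt, n_le, function(a, b) cv[b + 1] - cv[a + 1])
  list(count = count, value = val)   # matrices [lower x upper]
}

## Jointly segmented paired sums over a 2-D FF-bin grid at step granularity.
pair_sums_joint <- function(ff_pre, ff_post, w, pre_val, post_val, edges) {
  sel <- w > 0 & !is.na(ff_pre) & !is.na(ff_post)
  nb <- length(edges) - 1
  bp <- findInterval(ff_pre[sel] * 100, edges, rightmost.closed = TRUE)
  bq <- findInterval(ff_post[sel] * 100, edges, rightmost.closed = TRUE)
  ok <- bp >= 1 & bp <= nb & bq >= 1 & bq <= nb
  lin <- bp[ok] + (bq[ok] - 1) * nb
  wv <- w[sel][ok]
  scatter <- function(vals) {
    m <- numeric(nb * nb)
    agg <- rowsum(vals, lin)
    m[as.integer(rownames(agg))] <- agg[, 1]
    matrix(m, nb, nb)
  }
  W <- scatter(wv)
  P <- scatter(wv * pre_val[sel][ok])
  Q <- scatter(wv * post_val[sel][ok])
  ## 2-D prefix sums -> box queries
  pref <- function(M) apply(apply(M, 2, cumsum), 1, cumsum)  # transposed
  list(W = pref(W), P = pref(P), Q = pref(Q), nb = nb)
}

box_query <- function(pref, i0, i1, j0, j1) {
  ## pref is transposed prefix (rows = second index); query inclusive bins
  at <- function(i, j) if (i < 1 || j < 1) 0 else pref[j, i]
  at(i1, j1) - at(i0 - 1, j1) - at(i1, j0 - 1) + at(i0 - 1, j0 - 1)
}

#' Threshold sweep of cold-induced changes
#'
#' Evaluates the cohort-mean post-minus-pre change of a quantity for every
#' admissible (lower, upper) FF threshold pair at the given step, the grids
#' behind the threshold heatmaps. Volume and energy are computed from
#' per-timepoint independent segmentations; global FF and T2* use the joint
#' (both-time-point) segmentation. Pairs with `lower >= upper` or `lower`
#' below `lower_min` are flagged invalid.
#'
#' @param cohort List of subjects, each with `ff_pre`, `ff_post`, `roi_pre`,
#'   `roi_post`, and for `quantity = "t2star"` also `t2_pre`, `t2_post`.
#' @param quantity One of "volume" (mL), "ff" (percentage points),
#'   "t2star" (ms), "energy" (kcal).
#' @param step Threshold step in percent (default 1; fine enough to resolve
#'   single-percent extrema).
#' @param lower_min Minimum admissible lower threshold (default 30).
#' @param constants `bat_constants`, used when `quantity = "energy"`.
#' @return An object of class `bat_sweep`: `delta` matrix (rows = lower,
#'   cols = upper, NA where invalid), `lowers`, `uppers`, `valid`,
#'   per-subject array, and the arg-extrema `argmin`/`argmax`.
#' @export
threshold_sweep <- function(cohort, quantity = c("volume", "ff", "t2star",
                                                 "energy"),
                            step = 1, lower_min = 30,
                            constants = composition_constants()) {
  quantity <- match.arg(quantity)
  stopifnot(100 %% step == 0)
  lowers <- seq(0, 100 - step, by = step)
  uppers <- seq(step, 100, by = step)
  valid <- outer(lowers, uppers, function(l, u) l < u & l >= lower_min)
  n_sub <- length(cohort)
  per_subject <- array(NA_real_, c(length(lowers), length(uppers), n_sub))
  edges <- seq(0, 100, by = step)
  for (s in seq_len(n_sub)) {
    sub <- cohort[[s]]
    vv <- sub$roi_pre$voxel_volume
    if (quantity %in% c("volume", "energy")) {
      vals <- if (quantity == "energy") {
        list(pre = voxel_energy(sub$ff_pre, vv, constants),
             post = voxel_energy(sub$ff_post, vv, constants))
      } else NULL
      a <- pair_totals_independent(sub$ff_pre, roi_weights(sub$roi_pre),
                                   lowers, uppers, vals$pre)
      b <- pair_totals_independent(sub$ff_post, roi_weights(sub$roi_post),
                                   lowers, uppers, vals$post)
      per_subject[, , s] <- if (quantity == "volume")
        estimated_volume(b$count, vv) - estimated_volume(a$count, vv)
      else b$value - a$value
    } else {
      pre_val <- if (quantity == "ff") sub$ff_pre * 100 else sub$t2_pre
      post_val <- if (quantity == "ff") sub$ff_post * 100 else sub$t2_post
      w <- pmin(roi_weights(sub$roi_pre), roi_weights(sub$roi_post))
      ps <- pair_sums_joint(sub$ff_pre, sub$ff_post, w, pre_val, post_val,
                            edges)
      for (i in seq_along(lowers)) for (j in seq_along(uppers)) {
        if (!valid[i, j]) next
        i0 <- i; i1 <- uppers[j] / step   # bins covering [lower, upper)
        wsum <- box_query(ps$W, i0, i1, i0, i1)
        if (wsum > 0) {
          per_subject[i, j, s] <-
            (box_query(ps$Q, i0, i1, i0, i1) -
               box_query(ps$P, i0, i1, i0, i1)) / wsum
        }
      }
    }
  }
  delta <- apply(per_subject, 1:2, mean)
  delta[!valid] <- NA
  arg <- function(f) {
    k <- which(delta == f(delta, na.rm = TRUE))[1]
    i <- (k - 1) %% length(lowers) + 1
    j <- (k - 1) %/% length(lowers) + 1
    list(lower = lowers[i], upper = uppers[j], value = delta[k])
  }
  structure(list(quantity = quantity, step = step, lowers = lowers,
                 uppers = uppers, delta = delta, valid = valid,
                 per_subject = per_subject,
                 argmin = arg(min), argmax = arg(max)),
            class = "bat_sweep")
}

#' @export
print.bat_sweep <- function(x, ...) {
  cat(sprintf("Threshold sweep of %s change (step %g%%)\n", x$quantity,
              x$step))
  cat(sprintf("  largest decrease %.4g at %g-%g%%; largest increase %.4g at %g-%g%%\n",
              x$argmin$value, x$argmin$lower, x$argmin$upper,
              x$argmax$value, x$argmax$lower, x$argmax$upper))
  invisible(x)
}

#' Cohort paired change of a global quantity at one threshold range
#'
#' Per-subject pre/post values of a depot quantity at the given range, with
#' the paired test. Volume (mL) and energy (kcal) segment each time point
#' independently; global FF (percent) and T2* (ms) use the joint rule
#' (voxels below threshold excluded in both the thermoneutral and
#' post-cooling ROIs).
#'
#' @param cohort List of subjects as for `threshold_sweep`.
#' @param range A `bat_range`.
#' @param quantity One of "ff", "t2star", "volume", "energy".
#' @param constants `bat_constants` for `quantity = "energy"`.
#' @return List with `pre`, `post` per-subject vectors and the
#'   `paired_stats` result under `stats`.
#' @export
paired_global_change <- function(cohort, range = threshold_range(),
                                 quantity = c("ff", "t2star", "volume",
                                              "energy"),
                                 constants = composition_constants()) {
  quantity <- match.arg(quantity)
  vals <- vapply(cohort, function(sub) {
    seg <- segment_joint(sub$ff_pre, sub$ff_post, sub$roi_pre,
                         sub$roi_post, range)
    vv <- sub$roi_pre$voxel_volume
    switch(quantity,
      volume = c(estimated_volume(sum(seg$w_pre), vv),
                 estimated_volume(sum(seg$w_post), vv)),
      energy = c(sum(seg$w_pre *
                       voxel_energy(sub$ff_pre[seg$idx_pre], vv, constants)),
                 sum(seg$w_post *
                       voxel_energy(sub$ff_post[seg$idx_post], vv,
                                    constants))),
      ff = 100 * c(stats::weighted.mean(sub$ff_pre[seg$idx_paired],
                                        seg$w_paired),
                   stats::weighted.mean(sub$ff_post[seg$idx_paired],
                                        seg$w_paired)),
      t2star = c(stats::weighted.mean(sub$t2_pre[seg$idx_paired],
                                      seg$w_paired),
                 stats::weighted.mean(sub$t2_post[seg$idx_paired],
                                      seg$w_paired)))
  }, numeric(2))
  list(pre = vals[1, ], post = vals[2, ],
       stats = paired_stats(vals[1, ], vals[2, ]),
       range = range, quantity = quantity)
}

#' Look up one threshold pair in a sweep grid
#' @param sweep A `bat_sweep`.
#' @param lower,upper Thresholds in percent (multiples of the sweep step).
#' @return The cohort-mean change at that pair.
#' @export
sweep_at <- function(sweep, lower, upper) {
  i <- match(lower, sweep$lowers); j <- match(upper, sweep$uppers)
  if (is.na(i) || is.na(j)) stop("thresholds not on the sweep grid")
  sweep$delta[i, j]
}
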