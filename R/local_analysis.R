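#' Paired voxel-wise FF and T2* table
#'
#' Builds the voxel-level comparison table: if a deformation field is
#' supplied, the thermoneutral maps and ROI are first pulled to the
#' post-cooling coordinates; both image stacks are then smoothed with the
#' in-plane k x k neighborhood mean (compensating interpolation bias and
#' small co-registration inconsistencies) before voxel-wise differencing.
#' Rows are restricted to voxels inside the (transformed) ROI at both time
#' points.
#'
#' @param maps_pre,maps_post `bat_maps` (or lists with `ff` and `t2star`
#'   arrays) on a common grid.
#' @param roi A `bat_roi` drawn at the thermoneutral time point.
#' @param field Optional `bat_defo` mapping post-cooling coordinates into
#'   thermoneutral space (pulling); NULL means already co-registered.
#' @param k Neighborhood size for the smoothing (odd, default 3).
#' @param three_d Use the 3-D neighborhood instead of in-plane.
#' @return Data frame with `ff_pre`, `ff_post`, `dff` (percent),
#'   `t2_pre`, `t2_post`, `dt2` (ms), `weight` and the voxel index.
#' @export
voxel_deltas <- function(maps_pre, maps_post, roi, field = NULL, k = 3,
                         three_d = FALSE) {
  ff_pre <- maps_pre$ff; t2_pre <- maps_pre$t2star
  ff_post <- maps_post$ff; t2_post <- maps_post$t2star
  stopifnot(identical(dim(ff_pre), dim(ff_post)))
  w_pre <- roi_weights(roi)
  if (!is.null(field)) {
    ff_pre <- transform_volume(zero_na(ff_pre), field)
    t2_pre <- transform_volume(zero_na(t2_pre), field)
    w_pre <- transform_volume(w_pre, field)
  }
  sm <- function(m) neighborhood_mean(zero_na(m), k = k, three_d = three_d)
  ff_pre_s <- sm(ff_pre); ff_post_s <- sm(ff_post)
  t2_pre_s <- sm(t2_pre); t2_post_s <- sm(t2_post)
  w <- clamp(w_pre, 0, 1)
  sel <- w > 0 & is.finite(ff_pre_s) & is.finite(ff_post_s)
  if (!any(sel)) stop("empty ROI intersection between time points")
  data.frame(voxel = which(sel),
             ff_pre = 100 * ff_pre_s[sel], ff_post = 100 * ff_post_s[sel],
             dff = 100 * (ff_post_s[sel] - ff_pre_s[sel]),
             t2_pre = t2_pre_s[sel], t2_post = t2_post_s[sel],
             dt2 = t2_post_s[sel] - t2_pre_s[sel],
             weight = w[sel])
}

zero_na <- function(m) { m[!is.finite(m)] <- 0; m }

#' Two-dimensional joint histogram
#'
#' Counts voxels per rectangular (x, y) bin; bins are half-open with the
#' top edge closed, so marginal sums conserve the total count whenever the
#' breaks span the data.
#'
#' @param x,y Per-voxel values of equal length.
#' @param x_breaks,y_breaks Bin edges; default unit-width bins spanning the
#'   data (1% in FF, 1 ms in T2*).
#' @return List with `counts` (matrix, rows = x bins), `x_breaks`,
#'   `y_breaks`.
#' @export
joint_histogram <- function(x, y, x_breaks = NULL, y_breaks = NULL) {
  if (length(x) != length(y)) stop("x and y lengths differ")
  span <- function(v) seq(floor(min(v)), ceiling(max(v)) + 1e-9, by = 1)
  x_breaks <- x_breaks %||% span(x)
  y_breaks <- y_breaks %||% span(y)
  bx <- findInterval(x, x_breaks, rightmost.closed = TRUE)
  by <- findInterval(y, y_breaks, rightmost.closed = TRUE)
  nx <- length(x_breaks) - 1; ny <- length(y_breaks) - 1
  ok <- bx >= 1 & bx <= nx & by >= 1 & by <= ny
  counts <- matrix(0L, nx, ny)
  if (any(ok)) {
    tab <- table(factor(bx[ok], levels = seq_len(nx)),
                 factor(by[ok], levels = seq_len(ny)))
    counts <- matrix(as.integer(tab), nx, ny)
  }
  list(counts = counts, x_breaks = x_breaks, y_breaks = y_breaks)
}

#' K-means clustering with the explained-variance elbow rule
#'
#' Runs k-means for k = 1..k_max with seeded random restarts plus a warm
#' start from the previous k (which guarantees a non-decreasing
#' explained-variance curve), where explained variance is the ratio of the
#' between-group sum of squares to the total sum of squares. The selected k
#' is the smallest reaching the cutoff (default 95%). Variables are
#' z-scored before clustering because FF (percent) and T2* (ms) are on
#' incommensurate scales; centroids and per-cluster summaries are reported
#' on the original scale.
#'
#' @param table Data frame (e.g. from `voxel_deltas`) or numeric matrix.
#' @param columns Columns to cluster on; default all numeric columns of a
#'   matrix, or `c("ff_pre", "dff")` for a voxel table.
#' @param k_max Largest candidate k (>= 2).
#' @param variance_cutoff Explained-variance cutoff in (0, 1].
#' @param seed Integer seed; identical seeds give identical results.
#' @param n_restarts Random restarts per k.
#' @param standardize Z-score the variables first.
#' @return An object of class `bat_clusters`: `k_selected`, `labels`,
#'   `centroids`, `explained_variance_curve`, `summary` (per-cluster mean,
#'   SD and size for each variable) and the settings used.
#' @export
cluster_elbow <- function(table, columns = NULL, k_max = 8,
                          variance_cutoff = 0.95, seed = 1, n_restarts = 10,
                          standardize = TRUE) {
  stopifnot(k_max >= 2, variance_cutoff > 0, variance_cutoff <= 1)
  if (is.data.frame(table)) {
    columns <- columns %||%
      intersect(c("ff_pre", "dff"), names(table))
    X <- as.matrix(table[, columns, drop = FALSE])
  } else {
    X <- as.matrix(table)
    if (!is.null(columns)) X <- X[, columns, drop = FALSE]
    if (is.null(colnames(X))) colnames(X) <- paste0("v", seq_len(ncol(X)))
  }
  n <- nrow(X)
  if (n <= k_max) stop("fewer points than the largest candidate k")
  ctr <- colMeans(X); scl <- apply(X, 2, stats::sd)
  scl[scl == 0] <- 1
  Z <- if (standardize) scale(X, center = ctr, scale = scl) else X
  tot_ss <- sum(scale(Z, scale = FALSE)^2)
  set.seed(seed)
  ev <- numeric(k_max)
  fits <- vector("list", k_max)
  for (k in seq_len(k_max)) {
    if (k == 1) {
      fits[[k]] <- list(cluster = rep(1L, n),
                        centers = matrix(colMeans(Z), 1),
                        betweenss = 0, totss = tot_ss, tot.withinss = tot_ss)
      ev[k] <- 0
      next
    }
    best <- suppressWarnings(
      stats::kmeans(Z, centers = k, nstart = n_restarts, iter.max = 100))
    ## warm start: previous centres plus the worst-fitted point; keeps the
    ## within-SS (hence the explained-variance curve) monotone in k
    prev <- fits[[k - 1]]
    d2 <- rowSums((Z - prev$centers[prev$cluster, , drop = FALSE])^2)
    warm_centers <- rbind(prev$centers, Z[which.max(d2), ])
    warm <- tryCatch(
      suppressWarnings(stats::kmeans(Z, centers = warm_centers,
                                     iter.max = 100)),
      error = function(e) NULL)
    if (!is.null(warm) && warm$tot.withinss < best$tot.withinss) best <- warm
    fits[[k]] <- best
    ev[k] <- best$betweenss / best$totss
  }
  ev <- cummax(ev)
  k_selected <- which(ev >= variance_cutoff)[1]
  if (is.na(k_selected)) {
    warning("explained-variance cutoff not reached by k_max; using k_max")
    k_selected <- k_max
  }
  fit <- fits[[k_selected]]
  centroids <- fit$centers
  if (standardize)
    centroids <- sweep(sweep(centroids, 2, scl, `*`), 2, ctr, `+`)
  colnames(centroids) <- colnames(X)
  summ <- do.call(rbind, lapply(seq_len(k_selected), function(cl) {
    sub <- X[fit$cluster == cl, , drop = FALSE]
    data.frame(cluster = cl, n = nrow(sub),
               t(colMeans(sub)),
               setNames(as.data.frame(t(apply(sub, 2, stats::sd))),
                        paste0(colnames(X), "_sd")))
  }))
  structure(list(k_selected = k_selected, labels = fit$cluster,
                 centroids = centroids, explained_variance_curve = ev,
                 summary = summ, columns = colnames(X),
                 variance_cutoff = variance_cutoff, seed = seed,
                 n_restarts = n_restarts, standardize = standardize,
                 betweenss = fit$betweenss, totss = fit$totss,
                 tot_withinss = fit$tot.withinss),
            class = "bat_clusters")
}

#' @export
print.bat_clusters <- function(x, ...) {
  cat(sprintf("K-means elbow analysis of (%s): k = %d at %.0f%% explained-variance cutoff\n",
              paste(x$columns, collapse = ", "), x$k_selected,
              100 * x$variance_cutoff))
  cat("  explained variance by k:",
      paste(sprintf("%.3f", x$explained_variance_curve), collapse = " "),
      "\n")
  print(x$summary, digits = 3, row.names = FALSE)
  invisible(x)
}
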