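## Chemical-shift water-fat separation.
##
## Signal model per voxel, echo time t (s):
##   s(t) = (W + F * sum_m a_m exp(i 2 pi f_m t)) * exp(i 2 pi psi t) * exp(-t R2*)
## with complex water/fat amplitudes W, F, off-resonance psi (Hz) and
## R2* = 1/T2* (1/s). For fixed (psi, R2*) the amplitudes enter linearly, so
## fitting uses variable projection: a 2-column complex least-squares
## subproblem per voxel, with (psi, R2*) refined by Gauss-Newton on the
## projected residual. The field-map ambiguity (a shifted psi branch with
## water and fat exchanged) is resolved by a low-resolution grid search plus
## region growing that propagates the spatially smooth psi branch.

#' Fat modulation factor at the echo times
#'
#' `sum_m a_m exp(i 2 pi f_m t)` for a multi-peak fat spectrum.
#' @param te Echo times in seconds.
#' @param fat_peaks Data frame with `freq_hz` and `rel_amp`.
#' @return Complex vector, one value per echo.
#' @export
fat_modulation <- function(te, fat_peaks) {
  as.vector(exp(2i * pi * outer(te, fat_peaks$freq_hz)) %*% fat_peaks$rel_amp)
}

#' Evaluate the multi-echo signal model
#'
#' @param water,fat Water and fat amplitudes (may be complex).
#' @param fieldmap Off-resonance in Hz.
#' @param t2star T2* in ms (use `Inf` for no decay).
#' @param acq A `bat_acq`; echo times and fat spectrum are taken from it.
#' @param te Optional explicit echo times (s), overriding `acq`.
#' @return Complex signal vector over echoes.
#' @export
model_signal <- function(water, fat, fieldmap, t2star, acq, te = NULL) {
  if (t2star <= 0) stop("t2star must be positive")
  te <- te %||% echo_times(acq)
  cmod <- fat_modulation(te, acq$fat_peaks)
  (water + fat * cmod) * exp((2i * pi * fieldmap - 1000 / t2star) * te)
}

## Variable-projection linear solve for many voxels at once.
## S: V x E complex signal matrix; psi (Hz), r2s (1/s): length-V vectors.
## Returns amplitudes, model matrix, residuals and the Gram determinant.
varpro_solve <- function(S, te, psi, r2s, cmod) {
  V <- nrow(S); E <- length(te)
  Emat <- exp(outer(2i * pi * psi - r2s, te))
  eabs2 <- exp(outer(-2 * r2s, te))
  g11 <- rowSums(eabs2)
  g12 <- as.vector(eabs2 %*% cmod)
  g22 <- as.vector(eabs2 %*% (Mod(cmod)^2))
  CE <- Conj(Emat) * S
  h1 <- rowSums(CE)
  h2 <- as.vector(CE %*% Conj(cmod))
  det <- g11 * g22 - Mod(g12)^2
  ok <- is.finite(det) & det > 1e-12 * pmax(g11 * g22, 1e-300)
  det[!ok] <- 1
  a1 <- (g22 * h1 - g12 * h2) / det
  a2 <- (g11 * h2 - Conj(g12) * h1) / det
  a1[!ok] <- 0i; a2[!ok] <- 0i
  M <- Emat * (a1 + a2 %o% cmod)
  R <- S - M
  list(a1 = a1, a2 = a2, model = M, resid2 = rowSums(Mod(R)^2),
       resid = R, ok = ok)
}

## Gauss-Newton refinement of (psi, r2s) per voxel on the projected
## residual; the cross term of the normal matrix vanishes analytically, so
## the two parameters update independently, with per-voxel step halving.
gn_refine <- function(S, te, psi, r2s, cmod, n_iter = 40,
                      r2s_bounds = c(1000 / 200, 1000 / 1)) {
  V <- nrow(S)
  Tmat <- matrix(te, V, length(te), byrow = TRUE)
  sol <- varpro_solve(S, te, psi, r2s, cmod)
  for (it in seq_len(n_iter)) {
    M <- sol$model; R <- sol$resid
    cmr <- Conj(M) * R
    m2t <- Tmat * Mod(M)^2
    g_psi <- -4 * pi * rowSums(Tmat * Im(cmr))
    g_r2 <- 2 * rowSums(Tmat * Re(cmr))
    h_pp <- 8 * pi^2 * rowSums(Tmat * m2t)
    h_rr <- 2 * rowSums(Tmat * m2t)
    d_psi <- ifelse(h_pp > 1e-300, -g_psi / h_pp, 0)
    d_r2 <- ifelse(h_rr > 1e-300, -g_r2 / h_rr, 0)
    step <- rep(1, V)
    active <- rep(TRUE, V)
    for (half in 1:8) {
      idx <- which(active)
      if (!length(idx)) break
      p_new <- psi[idx] + step[idx] * d_psi[idx]
      r_new <- clamp(r2s[idx] + step[idx] * d_r2[idx],
                     r2s_bounds[1], r2s_bounds[2])
      trial <- varpro_solve(S[idx, , drop = FALSE], te, p_new, r_new, cmod)
      better <- trial$resid2 <= sol$resid2[idx] + 1e-15
      acc <- idx[better]
      if (length(acc)) {
        psi[acc] <- p_new[better]
        r2s[acc] <- r_new[better]
        sol$a1[acc] <- trial$a1[better]
        sol$a2[acc] <- trial$a2[better]
        sol$resid2[acc] <- trial$resid2[better]
        sol$model[acc, ] <- trial$model[better, , drop = FALSE]
        sol$resid[acc, ] <- trial$resid[better, , drop = FALSE]
        sol$ok[acc] <- trial$ok[better]
      }
      active[acc] <- FALSE
      step[active] <- step[active] / 2
    }
  }
  list(psi = psi, r2s = r2s, a1 = sol$a1, a2 = sol$a2,
       resid2 = sol$resid2, ok = sol$ok)
}

## Shared-grid residual search: per-voxel psi = psi_init + offset with a
## shared offset set and shared T2* candidates. Exploits |exp(i phi)| = 1 so
## the projector depends only on the shared decay.
grid_search_init <- function(S, te, psi_init, offsets, t2s_grid, cmod) {
  V <- nrow(S)
  total2 <- rowSums(Mod(S)^2)
  best <- rep(Inf, V)
  best_off <- numeric(V)
  best_t2s <- rep(t2s_grid[1], V)
  Qs <- lapply(t2s_grid, function(t2s) {
    d <- exp(-(1000 / t2s) * te)
    qr.Q(qr(cbind(d, d * cmod)))
  })
  for (off in offsets) {
    Sd <- S * exp(outer(-2i * pi * (psi_init + off), te))
    for (j in seq_along(t2s_grid)) {
      Z <- Sd %*% Conj(Qs[[j]])
      r2 <- total2 - rowSums(Mod(Z)^2)
      upd <- r2 < best
      best[upd] <- r2[upd]
      best_off[upd] <- off
      best_t2s[upd] <- t2s_grid[j]
    }
  }
  list(psi = psi_init + best_off, r2s = 1000 / best_t2s, resid2 = best)
}

#' Fit the water-fat model at a single voxel
#'
#' Nonlinear least squares over (field map, R2*) with the complex water and
#' fat amplitudes solved linearly at each candidate (variable projection).
#' The fit converges to the solution basin of `psi_init`; initialising on
#' the wrong side of the water-fat ambiguity yields the swapped solution,
#' which is why field-map estimation (region growing) precedes voxel fitting
#' in `reconstruct_maps`.
#'
#' @param signal Complex signal vector over echoes.
#' @param te Echo times in seconds (at least 4).
#' @param psi_init Initial field-map value, Hz.
#' @param acq A `bat_acq` (fat spectrum source).
#' @return List with `water`, `fat` (magnitude amplitudes), `fieldmap` (Hz),
#'   `t2star` (ms), `residual` (residual norm) and `fit_ok`.
#' @export
fit_voxel <- function(signal, te, psi_init, acq) {
  if (length(te) < 4) stop("at least 4 echoes are required")
  if (length(signal) != length(te)) stop("signal and te lengths differ")
  S <- matrix(signal, 1)
  if (sum(Mod(signal)) == 0)
    return(list(water = 0, fat = 0, fieldmap = NA_real_, t2star = NA_real_,
                residual = 0, fit_ok = FALSE))
  cmod <- fat_modulation(te, acq$fat_peaks)
  init <- grid_search_init(S, te, psi_init, offsets = seq(-6, 6, by = 2),
                           t2s_grid = exp(seq(log(3), log(60), length.out = 25)),
                           cmod = cmod)
  fit <- gn_refine(S, te, init$psi, init$r2s, cmod)
  list(water = Mod(fit$a1), fat = Mod(fit$a2), fieldmap = fit$psi,
       t2star = 1000 / fit$r2s, residual = sqrt(fit$resid2),
       fit_ok = fit$ok)
}

## Block-average a complex 4-D echo array in-plane by an integer factor.
downsample_echoes <- function(data, factor) {
  if (factor == 1) return(data)
  d <- dim(data)
  nx <- d[1] %/% factor; ny <- d[2] %/% factor
  out <- array(0i, dim = c(nx, ny, d[3], d[4]))
  for (i in seq_len(factor)) for (j in seq_len(factor)) {
    out <- out + data[seq(i, by = factor, length.out = nx),
                      seq(j, by = factor, length.out = ny), , , drop = FALSE]
  }
  out / factor^2
}

## 6-connected neighbour indices of voxel v on an nx x ny x nz grid.
neighbours6 <- function(v, nx, ny, nz) {
  v0 <- v - 1
  x <- v0 %% nx; y <- (v0 %/% nx) %% ny; z <- v0 %/% (nx * ny)
  nb <- c(if (x > 0) v - 1, if (x < nx - 1) v + 1,
          if (y > 0) v - nx, if (y < ny - 1) v + nx,
          if (z > 0) v - nx * ny, if (z < nz - 1) v + nx * ny)
  nb
}

#' Estimate the off-resonance field map by grid search and region growing
#'
#' A low-resolution reconstruction first: per voxel, a 1-D grid search over
#' psi within plus/minus 1/(2 delta-TE) (the period of the water-fat
#' ambiguity) minimising the variable-projection residual over a small T2*
#' candidate set. The residual-vs-psi profile has multiple local minima
#' (swapped branches); region growing from the highest-magnitude voxel then
#' propagates the spatially smooth branch: each voxel, visited in order of
#' decreasing signal magnitude along the growing front, accepts the local
#' minimum nearest the median psi of its already-labelled 6-neighbours. The
#' result is upsampled as the initial field map for full-resolution fitting.
#'
#' @param echoes A `bat_echoes` series.
#' @param downsample_factor Integer in-plane downsampling factor (>= 1).
#' @param step_hz Grid step of the psi search, Hz.
#' @param t2s_grid T2* candidates (ms) for the residual evaluation.
#' @return List with `psi_init` (full-resolution array, Hz), `psi_low`
#'   (low-resolution array) and `foreground` (low-resolution logical array).
#' @export
estimate_fieldmap <- function(echoes, downsample_factor = 2, step_hz = 2,
                              t2s_grid = c(8, 14, 22, 35)) {
  stopifnot(downsample_factor >= 1)
  te <- echoes$te
  cmod <- fat_modulation(te, echoes$acq$fat_peaks)
  dat <- downsample_echoes(echoes$data, as.integer(downsample_factor))
  d <- dim(dat)
  nx <- d[1]; ny <- d[2]; nz <- d[3]; V <- nx * ny * nz
  S <- matrix(dat, V, d[4])
  mag <- rowMeans(Mod(S))
  fg <- mag > 0.05 * stats::quantile(mag, 0.99)
  if (!any(fg)) stop("empty foreground: all voxel magnitudes are at the noise floor")

  psimax <- 1 / (2 * echoes$acq$delta_te)
  psis <- seq(-psimax, psimax - step_hz, by = step_hz)
  P <- length(psis)
  total2 <- rowSums(Mod(S)^2)
  Qs <- lapply(t2s_grid, function(t2s) {
    dec <- exp(-(1000 / t2s) * te)
    qr.Q(qr(cbind(dec, dec * cmod)))
  })
  Sf <- S[fg, , drop = FALSE]
  Rm <- matrix(Inf, sum(fg), P)
  for (p in seq_len(P)) {
    Sd <- Sf * matrix(exp(-2i * pi * psis[p] * te), sum(fg), length(te),
                      byrow = TRUE)
    for (Q in Qs) {
      Z <- Sd %*% Conj(Q)
      Rm[, p] <- pmin(Rm[, p], total2[fg] - rowSums(Mod(Z)^2))
    }
  }
  ## local minima of the circular residual profile per foreground voxel
  left <- Rm[, c(P, seq_len(P - 1)), drop = FALSE]
  right <- Rm[, c(seq_len(P - 1) + 1, 1), drop = FALSE]
  is_min <- (Rm < left) & (Rm <= right)

  fg_idx <- which(fg)
  n_fg <- length(fg_idx)
  pos_of <- integer(V); pos_of[fg_idx] <- seq_len(n_fg)
  assigned <- logical(n_fg)
  psi_est <- numeric(n_fg)
  frontier_val <- rep(-Inf, n_fg)
  mag_fg <- mag[fg_idx]
  period <- 2 * psimax
  circ_dist <- function(a, b) {
    dd <- abs(a - b) %% period
    pmin(dd, period - dd)
  }
  pick_minimum <- function(row, ref) {
    cand <- psis[is_min[row, ]]
    if (!length(cand)) cand <- psis[which.min(Rm[row, ])]
    cand[which.min(circ_dist(cand, ref))]
  }
  remaining <- n_fg
  while (remaining > 0) {
    ## seed a new connected component at its strongest voxel, global minimum
    seeds <- which(!assigned)
    s <- seeds[which.max(mag_fg[seeds])]
    psi_est[s] <- psis[which.min(Rm[s, ])]
    assigned[s] <- TRUE
    remaining <- remaining - 1
    frontier_val[s] <- -Inf
    nb <- neighbours6(fg_idx[s], nx, ny, nz)
    nb <- pos_of[nb[fg[nb]]]
    frontier_val[nb[!assigned[nb]]] <- mag_fg[nb[!assigned[nb]]]
    repeat {
      v <- which.max(frontier_val)
      if (!is.finite(frontier_val[v])) break
      frontier_val[v] <- -Inf
      if (assigned[v]) next
      nbv <- neighbours6(fg_idx[v], nx, ny, nz)
      nbv <- pos_of[nbv[fg[nbv]]]
      lab <- nbv[assigned[nbv]]
      ref <- stats::median(psi_est[lab])
      psi_est[v] <- pick_minimum(v, ref)
      assigned[v] <- TRUE
      remaining <- remaining - 1
      new <- nbv[!assigned[nbv]]
      frontier_val[new] <- mag_fg[new]
    }
  }
  psi_low_vec <- numeric(V)
  psi_low_vec[fg_idx] <- psi_est
  ## background voxels take the nearest assigned value along x for continuity
  if (any(!fg)) {
    fill <- stats::median(psi_est)
    psi_low_vec[!fg] <- fill
  }
  psi_low <- array(psi_low_vec, dim = c(nx, ny, nz))

  full <- dim(echoes$data)[1:3]
  f <- as.integer(downsample_factor)
  ix <- pmin(((seq_len(full[1]) - 1) %/% f) + 1, nx)
  iy <- pmin(((seq_len(full[2]) - 1) %/% f) + 1, ny)
  psi_init <- psi_low[ix, iy, , drop = FALSE]
  dim(psi_init) <- full
  list(psi_init = psi_init, psi_low = psi_low,
       foreground = array(fg, dim = c(nx, ny, nz)))
}

#' Reconstruct quantitative maps from a multi-echo series
#'
#' Runs field-map estimation (`estimate_fieldmap`), then the per-voxel
#' variable-projection fit everywhere, and derives the signal fat fraction
#' `FF(x,y,z) = SignalFat(x,y,z) / (SignalFat(x,y,z) + SignalWater(x,y,z))`
#' from the magnitude water and fat amplitudes, together with T2* (ms,
#' 1/R2*) and the field map (Hz). Voxels with signal at the noise floor or a
#' singular linear subproblem are flagged in `fit_ok` and carry NA fat
#' fraction rather than a silent zero.
#'
#' @param echoes A `bat_echoes` series.
#' @param downsample_factor Passed to `estimate_fieldmap`.
#' @param n_iter Gauss-Newton iterations for the full-resolution fit.
#' @return An object of class `bat_maps` with arrays `water`, `fat`, `ff`,
#'   `t2star`, `fieldmap`, `fit_ok` and scalar `voxel_volume`.
#' @export
reconstruct_maps <- function(echoes, downsample_factor = 2, n_iter = 40) {
  d <- dim(echoes$data)
  if (length(echoes$te) != d[4])
    stop("number of echoes disagrees with stored TE list")
  if (is.unsorted(echoes$te, strictly = TRUE))
    stop("echo times must be strictly increasing")
  te <- echoes$te
  cmod <- fat_modulation(te, echoes$acq$fat_peaks)
  fm <- estimate_fieldmap(echoes, downsample_factor = downsample_factor)
  V <- prod(d[1:3])
  S <- matrix(echoes$data, V, d[4])
  mag <- rowMeans(Mod(S))
  fit_mask <- mag > 1e-9 * max(mag)
  idx <- which(fit_mask)

  psi <- as.vector(fm$psi_init)[idx]
  init <- grid_search_init(S[idx, , drop = FALSE], te, psi,
                           offsets = seq(-4, 4, by = 2),
                           t2s_grid = exp(seq(log(3), log(60),
                                              length.out = 25)),
                           cmod = cmod)
  fit <- gn_refine(S[idx, , drop = FALSE], te, init$psi, init$r2s, cmod,
                   n_iter = n_iter)

  water <- fat <- ff <- t2s <- psi_map <- rep(NA_real_, V)
  ok <- rep(FALSE, V)
  water[idx] <- Mod(fit$a1)
  fat[idx] <- Mod(fit$a2)
  tot <- water[idx] + fat[idx]
  ffv <- rep(NA_real_, length(idx))
  pos <- tot > 0
  ffv[pos] <- fat[idx][pos] / tot[pos]
  ff[idx] <- ffv
  t2s[idx] <- 1000 / fit$r2s
  psi_map[idx] <- fit$psi
  ok[idx] <- fit$ok & pos
  shape <- d[1:3]
  structure(list(water = array(water, shape), fat = array(fat, shape),
                 ff = array(ff, shape), t2star = array(t2s, shape),
                 fieldmap = array(psi_map, shape),
                 fit_ok = array(ok, shape),
                 voxel_volume = echoes$voxel_volume %||% NA_real_),
            class = "bat_maps")
}

#' @export
print.bat_maps <- function(x, ...) {
  ok <- x$fit_ok
  cat(sprintf("Quantitative water-fat maps: %s grid, %d fitted voxels\n",
              paste(dim(x$ff), collapse = " x "), sum(ok)))
  if (any(ok))
    cat(sprintf("  FF %.3f-%.3f, T2* %.1f-%.1f ms, field map %.0f..%.0f Hz\n",
                min(x$ff[ok]), max(x$ff[ok]),
                min(x$t2star[ok]), max(x$t2star[ok]),
                min(x$fieldmap[ok]), max(x$fieldmap[ok])))
  invisible(x)
}

#' @export
summary.bat_maps <- function(object, ...) {
  ok <- object$fit_ok
  out <- data.frame(
    map = c("ff", "t2star", "fieldmap", "water", "fat"),
    mean = vapply(object[c("ff", "t2star", "fieldmap", "water", "fat")],
                  function(m) mean(m[ok]), 0),
    sd = vapply(object[c("ff", "t2star", "fieldmap", "water", "fat")],
                function(m) stats::sd(m[ok]), 0))
  out
}
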