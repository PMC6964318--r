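#' @keywords internal
"_PACKAGE"

`%||%` <- function(a, b) if (is.null(a)) b else a

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

logistic <- function(x) 1 / (1 + exp(-x))

## gyromagnetic ratio of 1H in MHz/T
GAMMA_MHZ_PER_T <- 42.577

#' Grid coordinate arrays for a 3-D volume
#'
#' Returns voxel-centre coordinates normalised to [-1, 1] along each axis,
#' as three arrays of dimension `shape`.
#' @keywords internal
grid_coords <- function(shape) {
  ax <- lapply(shape, function(n) if (n > 1) seq(-1, 1, length.out = n) else 0)
  list(
    x = array(rep(ax[[1]], times = shape[2] * shape[3]), dim = shape),
    y = array(rep(rep(ax[[2]], each = shape[1]), times = shape[3]), dim = shape),
    z = array(rep(ax[[3]], each = shape[1] * shape[2]), dim = shape)
  )
}

## Smooth random field as a sum of seeded Gaussian bumps; mean ~0, sd ~1.
smooth_random_field <- function(shape, n_bumps = 30, width = c(0.15, 0.4)) {
  g <- grid_coords(shape)
  f <- array(0, dim = shape)
  for (i in seq_len(n_bumps)) {
    cx <- stats::runif(1, -1, 1); cy <- stats::runif(1, -1, 1)
    cz <- stats::runif(1, -1, 1)
    s <- stats::runif(1, width[1], width[2])
    a <- stats::rnorm(1)
    f <- f + a * exp(-((g$x - cx)^2 + (g$y - cy)^2 + (g$z - cz)^2) / (2 * s^2))
  }
  f <- f - mean(f)
  sdf <- stats::sd(f)
  if (sdf > 0) f <- f / sdf
  f
}
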