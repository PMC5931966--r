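# Separable n-D convolution with edge-replicate boundary handling.
#
# conv_sep() computes true convolution with each 1-D tap vector along the
# corresponding array dimension. The adjoint of convolution with `taps` is
# convolution with rev(taps); helpers below keep that explicit so asymmetric
# kernels stay correct even though the shipped Gaussian PSFs are symmetric.

# Gaussian taps sampled at voxel centres, unit sum. Support half-width is
# support_factor * fwhm (>= 2*FWHM each side satisfies the >= 4*FWHM total
# support requirement).
gaussian_taps <- function(fwhm, spacing, support_factor = 2) {
  sigma <- fwhm / (2 * sqrt(2 * log(2)))
  sigma_taps(sigma, spacing, half_width = support_factor * fwhm)
}

sigma_taps <- function(sigma, spacing, half_width = 4 * sigma) {
  r <- max(1L, as.integer(ceiling(half_width / spacing)))
  off <- (-r:r) * spacing
  taps <- stats::dnorm(off, sd = sigma)
  taps / sum(taps)
}

# Convolve along one dimension of an n-D array, replicating edge values.
# Shift-and-add: one clamped-index slice copy per tap, all vectorized.
# True convolution: out[i] = sum_j taps[j] * a[i - (j - r - 1)].
conv_axis <- function(a, taps, axis) {
  nt <- length(taps)
  if (nt == 1L) return(a * taps)
  if (nt %% 2L == 0L) stop("tap vectors must have odd length")
  r <- (nt - 1L) %/% 2L
  d <- dim(a)
  if (is.null(d)) {
    n <- length(a)
    out <- numeric(n)
    s <- seq_len(n)
    for (j in seq_len(nt)) {
      ii <- pmin(pmax(s - (j - r - 1L), 1L), n)
      out <- out + taps[j] * a[ii]
    }
    return(out)
  }
  n <- d[axis]
  s <- seq_len(n)
  out <- array(0, d)
  idx <- rep(list(quote(expr = )), length(d))
  for (j in seq_len(nt)) {
    idx[[axis]] <- pmin(pmax(s - (j - r - 1L), 1L), n)
    out <- out + taps[j] * do.call(`[`, c(list(a), idx, list(drop = FALSE)))
  }
  out
}

# taps_list: one tap vector per array dimension (or a single vector for a
# plain numeric vector input).
conv_sep <- function(a, taps_list) {
  if (is.numeric(taps_list)) taps_list <- list(taps_list)
  d <- dim(a)
  nd <- if (is.null(d)) 1L else length(d)
  if (length(taps_list) != nd)
    stop("need one tap vector per array dimension")
  for (axis in seq_len(nd)) a <- conv_axis(a, taps_list[[axis]], axis)
  a
}

adjoint_taps <- function(taps_list) {
  if (is.numeric(taps_list)) return(rev(taps_list))
  lapply(taps_list, rev)
}

# Shift an array along one axis with edge replication.
shift_axis <- function(a, axis, by) {
  d <- dim(a)
  if (is.null(d)) {
    n <- length(a)
    idx <- pmin(pmax(seq_len(n) + by, 1L), n)
    return(a[idx])
  }
  idx <- rep(list(quote(expr = )), length(d))
  n <- d[axis]
  idx[[axis]] <- pmin(pmax(seq_len(n) + by, 1L), n)
  do.call(`[`, c(list(a), idx, list(drop = FALSE)))
}

# Discrete grad-transpose-grad (negative Laplacian) with replicate edges,
# in voxel units; used as the Tikhonov smoothing term of the solver.
neg_laplacian <- function(a) {
  d <- dim(a)
  nd <- if (is.null(d)) 1L else length(d)
  out <- 2 * nd * a
  for (axis in seq_len(nd))
    out <- out - shift_axis(a, axis, 1L) - shift_axis(a, axis, -1L)
  out
}

# Full width at half maximum of sampled taps by linear interpolation of the
# half-maximum crossings, in mm.
taps_fwhm_crossing <- function(taps, spacing) {
  n <- length(taps)
  pos <- (seq_len(n) - (n + 1) / 2) * spacing
  pk <- which.max(taps)
  half <- taps[pk] / 2
  cross <- function(side) {
    idx <- if (side < 0) seq(pk, 1L) else seq(pk, n)
    below <- which(taps[idx] < half)
    if (length(below) == 0L) return(pos[idx[length(idx)]])
    j <- below[1]
    a <- idx[j - 1L]; b <- idx[j]
    frac <- (taps[a] - half) / (taps[a] - taps[b])
    pos[a] + frac * (pos[b] - pos[a])
  }
  abs(cross(1) - cross(-1))
}

# FWHM via a log-parabola fit through the peak and its neighbours; exact for
# point-sampled Gaussians, so unbiased even at coarse (axial) sampling.
taps_fwhm_gaussfit <- function(taps, spacing) {
  n <- length(taps)
  pk <- which.max(taps)
  if (pk == 1L || pk == n) return(taps_fwhm_crossing(taps, spacing))
  c0 <- log(taps[pk])
  cl <- log(taps[pk - 1L]); cr <- log(taps[pk + 1L])
  curv <- (cl + cr - 2 * c0) # = -spacing^2 / sigma^2
  if (curv >= 0) return(taps_fwhm_crossing(taps, spacing))
  sigma <- spacing / sqrt(-curv)
  2 * sqrt(2 * log(2)) * sigma
}
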