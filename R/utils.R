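# Internal helpers shared across modules.

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

fwhm_to_sigma <- function(fwhm) fwhm / (2 * sqrt(2 * log(2)))
sigma_to_fwhm <- function(sigma) sigma * 2 * sqrt(2 * log(2))

# FWHM of a sampled profile y(x) by linear interpolation at half maximum.
# Returns NA if the profile does not cross half maximum on both sides.
profile_fwhm <- function(x, y) {
  i0 <- which.max(y)
  half <- y[i0] / 2
  left <- right <- NA_real_
  for (i in seq(i0, 2L)) {
    if (y[i - 1L] <= half && y[i] > half) {
      f <- (half - y[i - 1L]) / (y[i] - y[i - 1L])
      left <- x[i - 1L] + f * (x[i] - x[i - 1L])
      break
    }
  }
  for (i in seq(i0, length(y) - 1L)) {
    if (y[i + 1L] <= half && y[i] > half) {
      f <- (y[i] - half) / (y[i] - y[i + 1L])
      right <- x[i] + f * (x[i + 1L] - x[i])
      break
    }
  }
  right - left
}

# Standard deviation (second central moment) of a non-negative profile.
profile_sigma <- function(x, y) {
  w <- y / sum(y)
  mu <- sum(w * x)
  sqrt(sum(w * (x - mu)^2))
}

# Integer shift of a 3D array along one axis; vacated planes filled with `fill`.
# out[i] = a[i - n] along `axis` (content moves by +n voxels).
shift_int <- function(a, n, axis, fill = 0) {
  if (n == 0L) return(a)
  d <- dim(a)
  idx <- lapply(d, seq_len)
  src <- seq_len(d[axis]) - n
  keep <- src >= 1L & src <= d[axis]
  out <- array(fill, d)
  if (!any(keep)) return(out)
  ito <- idx; ito[[axis]] <- which(keep)
  ifrom <- idx; ifrom[[axis]] <- src[keep]
  out[ito[[1]], ito[[2]], ito[[3]]] <- a[ifrom[[1]], ifrom[[2]], ifrom[[3]]]
  out
}

# Separable 1D convolution of a 3D array along one axis with an odd-length
# symmetric-support kernel; out-of-grid values padded with `pad`.
conv_axis <- function(a, w, axis, pad = 0) {
  m <- (length(w) - 1L) / 2L
  stopifnot(m == floor(m))
  d <- dim(a)
  perm <- c(axis, setdiff(1:3, axis))
  ap <- aperm(a, perm)
  n1 <- d[axis]
  M <- matrix(ap, nrow = n1)
  nc <- ncol(M)
  padM <- matrix(pad, m, nc)
  P <- rbind(padM, M, padM)
  out <- matrix(0, n1, nc)
  for (j in seq_along(w)) {
    out <- out + w[j] * P[(j - 1L) + seq_len(n1), , drop = FALSE]
  }
  res <- array(out, d[perm])
  aperm(res, order(perm))
}

# Trilinear interpolation of a 3D array at world positions (mm).
# `pts` is an n x 3 matrix; values outside the grid return `fill`.
interp3 <- function(a, spacing, origin, pts, fill = 0) {
  d <- dim(a)
  fx <- (pts[, 1] - origin[1]) / spacing[1] + 1
  fy <- (pts[, 2] - origin[2]) / spacing[2] + 1
  fz <- (pts[, 3] - origin[3]) / spacing[3] + 1
  x0 <- floor(fx); y0 <- floor(fy); z0 <- floor(fz)
  inside <- x0 >= 1 & (x0 + 1) <= d[1] & y0 >= 1 & (y0 + 1) <= d[2] &
    z0 >= 1 & (z0 + 1) <= d[3]
  # allow points exactly on the far face
  hi <- fx == d[1] | fy == d[2] | fz == d[3]
  x0[fx == d[1]] <- d[1] - 1; y0[fy == d[2]] <- d[2] - 1; z0[fz == d[3]] <- d[3] - 1
  inside <- inside | (hi & fx >= 1 & fx <= d[1] & fy >= 1 & fy <= d[2] & fz >= 1 & fz <= d[3])
  out <- rep(fill, nrow(pts))
  if (!any(inside)) return(out)
  x0 <- x0[inside]; y0 <- y0[inside]; z0 <- z0[inside]
  tx <- fx[inside] - x0; ty <- fy[inside] - y0; tz <- fz[inside] - z0
  n1 <- d[1]; n12 <- d[1] * d[2]
  base <- (x0) + (y0 - 1) * n1 + (z0 - 1) * n12  # linear index of (x0,y0,z0)
  v000 <- a[base];             v100 <- a[base + 1]
  v010 <- a[base + n1];        v110 <- a[base + n1 + 1]
  v001 <- a[base + n12];       v101 <- a[base + n12 + 1]
  v011 <- a[base + n1 + n12];  v111 <- a[base + n1 + n12 + 1]
  out[inside] <-
    v000 * (1 - tx) * (1 - ty) * (1 - tz) + v100 * tx * (1 - ty) * (1 - tz) +
    v010 * (1 - tx) * ty * (1 - tz)       + v110 * tx * ty * (1 - tz) +
    v001 * (1 - tx) * (1 - ty) * tz       + v101 * tx * (1 - ty) * tz +
    v011 * (1 - tx) * ty * tz             + v111 * tx * ty * tz
  out
}
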