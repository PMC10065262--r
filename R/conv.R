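# Separable and FFT convolution primitives shared by the imaging model,
# the augmentation transforms and the edge-quality metric.

# Symmetric (edge-including) reflection of indices 1..n onto the lattice.
reflect_index <- function(i, n) {
  if (n == 1L) return(rep(1L, length(i)))
  # period of the symmetric extension is 2n
  i <- (i - 1L) %% (2L * n)
  ifelse(i < n, i + 1L, 2L * n - i)
}

# 1D convolution of a 3D array along one axis with an odd-length kernel,
# symmetric boundary. Implemented as shift-and-add: L slice reads, no loops
# over voxels.
conv1d_axis <- function(a, kernel, axis) {
  stopifnot(length(dim(a)) == 3L, axis %in% 1:3)
  L <- length(kernel)
  if (L == 1L) return(a * kernel)
  if (L %% 2L == 0L) stop("kernel length must be odd", call. = FALSE)
  h <- (L - 1L) %/% 2L
  d <- dim(a)
  n <- d[axis]
  out <- array(0, d)
  for (j in seq_len(L)) {
    off <- j - h - 1L
    idx <- reflect_index(seq_len(n) + off, n)
    shifted <- switch(axis,
      a[idx, , , drop = FALSE],
      a[, idx, , drop = FALSE],
      a[, , idx, drop = FALSE]
    )
    out <- out + kernel[j] * shifted
  }
  out
}

# Discrete Gaussian kernel; radius 3 sigma (minimum 1), unit sum.
gaussian_kernel1d <- function(sigma) {
  if (sigma <= 0) return(1)
  r <- max(1L, ceiling(3 * sigma))
  k <- stats::dnorm(seq(-r, r), sd = sigma)
  k / sum(k)
}

# Separable Gaussian smoothing of a 3D array; sigma per axis (z, y, x),
# 0 disables an axis.
gaussian_smooth <- function(a, sigma) {
  sigma <- rep_len(sigma, 3L)
  for (axis in 1:3) {
    if (sigma[axis] > 0) {
      a <- conv1d_axis(a, gaussian_kernel1d(sigma[axis]), axis)
    }
  }
  a
}

# Full 3D convolution with an arbitrary odd-extent kernel, symmetric
# boundary. FFT-based: the volume is reflect-padded by the kernel
# half-extent, circularly convolved, and cropped back.
conv3d_fft <- function(a, kernel) {
  stopifnot(length(dim(a)) == 3L, length(dim(kernel)) == 3L)
  kd <- dim(kernel)
  if (any(kd %% 2L == 0L)) {
    stop("kernel extents must be odd", call. = FALSE)
  }
  h <- (kd - 1L) %/% 2L
  d <- dim(a)
  pd <- d + 2L * h
  idx <- lapply(1:3, function(ax) reflect_index(seq_len(pd[ax]) - h[ax], d[ax]))
  padded <- a[idx[[1]], idx[[2]], idx[[3]], drop = FALSE]
  # embed the reversed kernel centered at the origin of the circular
  # lattice, so the circular product computes the same correlation
  # (filtering) orientation as conv1d_axis; symmetric PSFs are unaffected
  kpad <- array(0, pd)
  kidx <- lapply(1:3, function(ax) {
    ((seq_len(kd[ax]) - 1L - h[ax]) %% pd[ax]) + 1L
  })
  kpad[kidx[[1]], kidx[[2]], kidx[[3]]] <-
    kernel[kd[1]:1, kd[2]:1, kd[3]:1, drop = FALSE]
  conv <- Re(stats::fft(stats::fft(padded) * stats::fft(kpad), inverse = TRUE)) /
    prod(pd)
  conv[h[1] + seq_len(d[1]), h[2] + seq_len(d[2]), h[3] + seq_len(d[3]),
    drop = FALSE]
}

# Binary Chebyshev (cube) dilation by `radius` voxels: separable running
# maximum along each axis, zero-padded (no wraparound into the volume).
dilate_chebyshev <- function(mask, radius) {
  stopifnot(radius >= 0)
  if (radius == 0L) return(mask)
  d <- dim(mask)
  out <- array(as.logical(mask), d)
  for (axis in 1:3) {
    n <- d[axis]
    acc <- array(FALSE, d)
    for (off in seq(-radius, radius)) {
      src <- seq_len(n) + off
      keep <- src >= 1L & src <= n
      if (!any(keep)) next
      dst <- which(keep)
      src <- src[keep]
      slab <- switch(axis,
        out[src, , , drop = FALSE],
        out[, src, , drop = FALSE],
        out[, , src, drop = FALSE]
      )
      switch(axis,
        acc[dst, , ] <- acc[dst, , , drop = FALSE] | slab,
        acc[, dst, ] <- acc[, dst, , drop = FALSE] | slab,
        acc[, , dst] <- acc[, , dst, drop = FALSE] | slab
      )
    }
    out <- acc
  }
  out
}

# Sobel gradient magnitude of every (y, x) slice of a 3D array.
# Separable: Gx = smooth_y [1 2 1] x diff_x [1 0 -1], Gy transposed.
sobel_magnitude_slices <- function(a) {
  smooth <- c(1, 2, 1)
  diff <- c(1, 0, -1)
  gx <- conv1d_axis(conv1d_axis(a, smooth, 2L), diff, 3L)
  gy <- conv1d_axis(conv1d_axis(a, diff, 2L), smooth, 3L)
  sqrt(gx^2 + gy^2)
}
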