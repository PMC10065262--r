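# Shared fixtures and independent oracles, all built in code.

# Independent dense-loop 2D convolution (correlation-free, symmetric
# boundary), used as the oracle for the separable filtering primitives.
dense_conv2d <- function(m, k) {
  hr <- (nrow(k) - 1) / 2
  hc <- (ncol(k) - 1) / 2
  refl <- function(i, n) {
    i <- (i - 1) %% (2 * n)
    ifelse(i < n, i + 1, 2 * n - i)
  }
  out <- matrix(0, nrow(m), ncol(m))
  for (r in seq_len(nrow(m))) {
    for (cc in seq_len(ncol(m))) {
      acc <- 0
      for (dr in -hr:hr) {
        for (dc in -hc:hc) {
          acc <- acc + k[dr + hr + 1, dc + hc + 1] *
            m[refl(r + dr, nrow(m)), refl(cc + dc, ncol(m))]
        }
      }
      out[r, cc] <- acc
    }
  }
  out
}

# Independent dense 3D convolution oracle (interior only is compared).
dense_conv3d <- function(a, k) {
  h <- (dim(k) - 1) / 2
  d <- dim(a)
  refl <- function(i, n) {
    i <- (i - 1) %% (2 * n)
    ifelse(i < n, i + 1, 2 * n - i)
  }
  out <- array(0, d)
  for (z in seq_len(d[1])) for (y in seq_len(d[2])) for (x in seq_len(d[3])) {
    acc <- 0
    for (dz in -h[1]:h[1]) for (dy in -h[2]:h[2]) for (dx in -h[3]:h[3]) {
      acc <- acc + k[dz + h[1] + 1, dy + h[2] + 1, dx + h[3] + 1] *
        a[refl(z + dz, d[1]), refl(y + dy, d[2]), refl(x + dx, d[3])]
    }
    out[z, y, x] <- acc
  }
  out
}

# Brute-force exact Wilcoxon signed-rank p by enumerating all 2^n sign
# vectors (mid-ranks for ties; zeros removed by the caller).
brute_wilcoxon_p <- function(d, alternative = "greater") {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  w_obs <- sum(r[d > 0])
  ws <- vapply(0:(2^n - 1), function(bits) {
    signs <- bitwAnd(bits, 2^(0:(n - 1))) > 0
    sum(r[signs])
  }, numeric(1))
  switch(alternative,
    greater = mean(ws >= w_obs),
    less = mean(ws <= w_obs)
  )
}

# Brute-force optimal-transport oracle for equal-size samples: W1 equals
# the minimum average |a - b_perm| over all pairings (attained by sorting,
# but enumerated independently here).
brute_transport_w1 <- function(a, b) {
  stopifnot(length(a) == length(b), length(a) <= 8)
  perms <- function(v) {
    if (length(v) == 1) return(list(v))
    out <- list()
    for (i in seq_along(v)) {
      for (p in perms(v[-i])) out[[length(out) + 1]] <- c(v[i], p)
    }
    out
  }
  min(vapply(perms(b), function(p) mean(abs(a - p)), numeric(1)))
}

# Independent oracle for the per-section edge curve: dense 2D Gaussian
# smoothing + dense Sobel magnitude + type-7 quantile, computed with the
# brute-force convolution helper (no shared code with the package path).
oracle_e_curve <- function(vol_section, sigma, probs = 0.95) {
  r <- max(1, ceiling(3 * sigma))
  g1 <- stats::dnorm(seq(-r, r), sd = sigma); g1 <- g1 / sum(g1)
  G <- outer(g1, g1)
  Ky <- outer(c(1, 0, -1), c(1, 2, 1))
  Kx <- outer(c(1, 2, 1), c(1, 0, -1))
  vapply(seq_len(dim(vol_section)[1]), function(z) {
    sm <- dense_conv2d(vol_section[z, , ], G)
    gy <- dense_conv2d(sm, Ky)
    gx <- dense_conv2d(sm, Kx)
    stats::quantile(sqrt(gx^2 + gy^2), probs = probs, names = FALSE)
  }, numeric(1))
}

# Deterministic textured pattern with clear edges inside a 20 x 20 tile.
tile_pattern <- function() {
  p <- matrix(0, 20, 20)
  p[6:15, 6:15] <- 100
  p[9:12, 9:12] <- 40
  p
}

# z envelope peaked at `peak` (1-based), strictly unimodal, no ties.
z_envelope <- function(nz, peak) {
  0.2 + 0.8 * exp(-((seq_len(nz) - peak) / 2.5)^2)
}

# 26-connected component containing `seed_idx` grown by iterated Chebyshev
# dilation; used to check mask connectivity.
flood_component <- function(mask, seed_idx) {
  comp <- array(FALSE, dim(mask))
  comp[seed_idx[1], seed_idx[2], seed_idx[3]] <- TRUE
  repeat {
    grown <- spheroidsim:::dilate_chebyshev(comp, 1L) & mask
    if (sum(grown) == sum(comp)) return(comp)
    comp <- grown
  }
}

# Small cached scene shared across test files (placement is the slow part).
.fixture_cache <- new.env(parent = emptyenv())

toy_scene <- function() {
  if (is.null(.fixture_cache$scene)) {
    .fixture_cache$scene <- make_toy_spheroid(
      shape = c(20, 56, 56), max_consecutive_failures = 150, seed = 42)
  }
  .fixture_cache$scene
}

small_db <- function() {
  if (is.null(.fixture_cache$db)) {
    .fixture_cache$db <- make_fixture_database(
      n_prototypes = 2,
      cfg = augmentation_config(variants_per_prototype = 2),
      seed = 11)
  }
  .fixture_cache$db
}
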