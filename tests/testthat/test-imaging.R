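test_that("occlusion depth is the exclusive column count, verified per voxel", {
  expect_true(all(occlusion_depth(shape_mask(array(FALSE, c(4, 3, 3)))) == 0))

  full <- shape_mask(array(TRUE, c(10, 2, 2)))
  occ <- occlusion_depth(full)
  for (z in 1:10) expect_true(all(occ[z, , ] == z - 1))

  single <- array(FALSE, c(8, 3, 3)); single[4, 2, 2] <- TRUE  # 0-based z=3
  occ2 <- occlusion_depth(shape_mask(single))
  expect_true(all(occ2[1:4, 2, 2] == 0))
  expect_true(all(occ2[5:8, 2, 2] == 1))
  expect_true(all(occ2[, 1, ] == 0))

  # brute-force oracle on a random mask
  set.seed(12)
  m <- array(runif(6 * 4 * 5) < 0.4, c(6, 4, 5))
  occ3 <- occlusion_depth(shape_mask(m))
  for (z in 1:6) for (y in 1:4) for (x in 1:5) {
    expected <- if (z == 1) 0L else sum(m[1:(z - 1), y, x])
    expect_identical(occ3[z, y, x], as.integer(expected))
  }
})

test_that("brightness factor matches direct arithmetic and its monotonicities", {
  expect_equal(brightness_factor(0, 150), 1)
  expect_equal(brightness_factor(150, 150), 2^-6)
  expect_equal(brightness_factor(15, 150), 1.1^-6)
  expect_error(brightness_factor(1, 0), "positive")

  set.seed(5)
  i <- c(0, sort(stats::rexp(50, 1 / 100)))
  p <- stats::runif(20, 1, 500)
  for (pp in p) {
    b <- brightness_factor(i, pp)
    raw <- (i / pp + 1)^(-6)
    expect_equal(b, raw, tolerance = 1e-15)      # clamps inert
    expect_true(all(b > 0 & b <= 1))
    expect_true(all(diff(b) < 0))                # decreasing in i
  }
  # increasing in p for i > 0
  b_by_p <- vapply(c(10, 50, 150, 400), function(pp) {
    brightness_factor(42, pp)
  }, numeric(1))
  expect_true(all(diff(b_by_p) > 0))

  img <- volume3d(array(200, c(3, 2, 2)))
  occ <- occlusion_depth(shape_mask(array(TRUE, c(3, 2, 2))))
  out <- brightness_reduction(img, occ, p = 150)
  expect_equal(out[2, 1, 1], 200 * (1 / 150 + 1)^-6)
  expect_equal(out[1, 1, 1], 200)
})

test_that("PSF convolution: identity kernel, constant field, point response", {
  set.seed(21)
  a <- volume3d(array(runif(7 * 8 * 9), c(7, 8, 9)))
  delta <- array(0, c(3, 3, 3)); delta[2, 2, 2] <- 1
  out <- psf_convolve(a, psf_stack(delta))
  expect_equal(as.vector(out), as.vector(a), tolerance = 1e-12)

  k <- array(runif(3 * 5 * 5), c(3, 5, 5)); k <- k / sum(k)
  const <- volume3d(array(3.7, c(9, 11, 11)))
  outc <- psf_convolve(const, psf_stack(k))
  expect_equal(as.vector(outc), rep(3.7, length(const)), tolerance = 1e-10)

  # single bright voxel: response equals the kernel scaled by the value
  pt <- array(0, c(11, 11, 11)); pt[6, 6, 6] <- 5
  g <- gaussian_psf(c(1, 1, 1), c(1, 1, 1))
  outp <- psf_convolve(volume3d(pt), g)
  kd <- dim(g$kernels[[1]])
  h <- (kd - 1) / 2
  sub <- outp[(6 - h[1]):(6 + h[1]), (6 - h[2]):(6 + h[2]),
    (6 - h[3]):(6 + h[3])]
  expect_equal(sub, 5 * g$kernels[[1]], tolerance = 1e-10)

  # full independent dense-convolution oracle on a small random volume
  set.seed(22)
  small <- array(runif(5 * 6 * 6), c(5, 6, 6))
  k2 <- array(runif(3 * 3 * 3), c(3, 3, 3)); k2 <- k2 / sum(k2)
  mine <- psf_convolve(volume3d(small), psf_stack(k2))
  oracle <- dense_conv3d(small, k2)
  expect_equal(as.vector(mine), as.vector(oracle), tolerance = 1e-10)
})

test_that("unit-sum convolution conserves interior intensity and stacks interpolate", {
  set.seed(30)
  # compact source away from the borders: boundary handling cannot leak,
  # so a unit-sum kernel conserves the total exactly
  a <- array(0, c(12, 14, 14))
  a[5:8, 6:9, 6:9] <- runif(4 * 4 * 4)
  k <- array(runif(3 * 3 * 3), c(3, 3, 3)); k <- k / sum(k)
  out <- psf_convolve(volume3d(a), psf_stack(k))
  expect_lt(abs(sum(out) - sum(a)) / sum(a), 1e-6)

  # depth-varying with two identical kernels == global convolution
  two <- psf_stack(list(k, k), depth_anchors = c(0, 11))
  outd <- psf_convolve(volume3d(a), two, mode = "depth_varying")
  outg <- psf_convolve(volume3d(a), psf_stack(k))
  expect_equal(as.vector(outd), as.vector(outg), tolerance = 1e-10)

  expect_error(psf_convolve(volume3d(a), two, mode = "global"), "one kernel")
  expect_error(psf_convolve(volume3d(a), psf_stack(k), mode = "depth_varying"),
    ">= 2")
})

test_that("label enlargement keeps instances disjoint and originals intact", {
  delta <- psf_stack({d <- array(0, c(3, 3, 3)); d[2, 2, 2] <- 1; d})
  lab <- array(0L, c(5, 7, 7)); lab[2:3, 2:3, 2:3] <- 1L; lab[4, 6, 6] <- 2L
  lv <- label_volume(lab)
  same <- psf_enlarge_labels(lv, delta, 0.5)
  expect_identical(as.vector(same), as.vector(lv))

  # single voxel + 3^3 uniform kernel at threshold 0.5: only the center
  # reaches half of the maximum response (hand convolution: max = 1/27,
  # neighbors' response = 1/27 as well within the 3^3 box... use the
  # Gaussian-weighted kernel instead, where neighbors fall below threshold)
  g <- gaussian_psf(c(0.5, 0.5, 0.5), c(1, 1, 1))
  one <- array(0L, c(5, 5, 5)); one[3, 3, 3] <- 1L
  out1 <- psf_enlarge_labels(label_volume(one), g, 0.9)
  expect_identical(as.vector(out1), as.vector(one))

  # wide kernel enlarges; two adjacent instances stay disjoint
  wide <- gaussian_psf(c(1.5, 1.5, 1.5), c(1, 1, 1))
  two <- array(0L, c(7, 9, 9))
  two[3:4, 3:4, 3:4] <- 1L
  two[3:4, 3:4, 6:7] <- 2L
  out2 <- psf_enlarge_labels(label_volume(two), wide, 0.3)
  expect_gt(sum(out2 == 1L), sum(two == 1L))
  expect_true(all(out2[two == 1L] == 1L))
  expect_true(all(out2[two == 2L] == 2L))
  expect_identical(sort(label_ids(out2)), c(1L, 2L))
})

test_that("downsampling: identity, constants, mass conservation, labels", {
  set.seed(40)
  v <- volume3d(array(runif(6 * 8 * 8), c(6, 8, 8)), c(1, 1, 1))
  same <- downsample(v, c(1, 1, 1))
  expect_equal(as.vector(same), as.vector(v))

  const <- volume3d(array(4.2, c(8, 12, 12)), c(1, 1, 1))
  dc <- downsample(const, c(2, 1.5, 1.5))
  expect_identical(dim(dc), c(4L, 8L, 8L))
  expect_equal(as.vector(dc), rep(4.2, length(dc)), tolerance = 1e-9)
  expect_equal(unname(voxel_size(dc)), c(2, 1.5, 1.5))

  # 2x2x2 block of value 8 in zeros, factor-2: mass conserved within 1%
  blk <- array(0, c(12, 12, 12)); blk[6:7, 6:7, 6:7] <- 8
  down <- downsample(volume3d(blk, c(1, 1, 1)), c(2, 2, 2))
  mass_src <- sum(blk)
  mass_out <- sum(down) * 8          # voxel volume grows 8-fold
  expect_lt(abs(mass_out - mass_src) / mass_src, 0.01)

  expect_error(downsample(v, c(0.5, 1, 1)), "upsampling|>=")

  lab <- array(0L, c(8, 8, 8)); lab[1:4, 1:4, 1:4] <- 3L; lab[5:8, 5:8, 5:8] <- 9L
  dl <- downsample(label_volume(lab, c(1, 1, 1)), c(2, 2, 2),
    method = "nearest")
  expect_s3_class(dl, "label_volume")
  expect_true(all(dl %in% c(0L, 3L, 9L)))
  expect_identical(sort(label_ids(dl)), c(3L, 9L))
})

test_that("Poisson stage: zeros, determinism, mean and variance scaling", {
  z <- volume3d(array(0, c(4, 4, 4)))
  expect_true(all(apply_poisson_noise(z, gain = 2, seed = 1) == 0))

  v <- volume3d(array(100, c(100, 100, 100)))
  n1 <- apply_poisson_noise(v, gain = 1, seed = 7)
  n2 <- apply_poisson_noise(v, gain = 1, seed = 7)
  expect_identical(as.vector(n1), as.vector(n2))
  expect_lt(abs(mean(n1) - 100), 0.05)           # 5 sigma at n = 1e6

  g4 <- apply_poisson_noise(v, gain = 4, seed = 8)
  expect_lt(abs(stats::var(as.vector(g4)) - 100 / 4) / (100 / 4), 0.05)

  neg <- volume3d(array(1, c(2, 2, 2)))
  expect_error(apply_poisson_noise(neg, gain = -1), "positive")
})

test_that("full imaging composition: identity limit and depth dimming", {
  scene <- toy_scene()
  img <- scene$placement$image
  lab <- scene$placement$labels

  idcfg <- imaging_config(p = 150, enable_brightness = FALSE,
    enable_psf = FALSE, enable_downsample = FALSE, enable_noise = FALSE)
  out <- simulate_imaging(img, lab, scene$mask, idcfg)
  expect_equal(as.vector(out$image), as.vector(img))
  expect_identical(as.vector(out$labels), as.vector(lab))

  cfg <- imaging_config(p = 50, psf_sigma_um = c(1.2, 0.6, 0.6),
    gain = 2, seed = 5, enable_downsample = FALSE)
  sim <- simulate_imaging(img, lab, scene$mask, cfg)
  expect_identical(n_instances(sim$labels), n_instances(lab))

  # deep foreground slices are dimmer than shallow ones (decay direction)
  fg <- array(as.integer(lab), dim(lab)) > 0
  zs <- which(apply(fg, 1, any))
  shallow <- zs[zs <= stats::median(zs)]
  deep <- zs[zs > stats::median(zs)]
  mean_at <- function(z) mean(sim$image[z, , ][fg[z, , ]])
  expect_gt(mean(sapply(shallow, mean_at)), mean(sapply(deep, mean_at)))
})
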