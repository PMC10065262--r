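test_that("constant volumes yield an empty profile with s_n = 0", {
  prof <- q95_edge_profile(volume3d(array(7, c(6, 120, 120))))
  expect_identical(edge_profile_sn(prof), 0L)
  expect_identical(nrow(tibble::as_tibble(prof)), 0L)
  expect_error(q95_edge_profile(volume3d(array(1, c(3, 40, 40)))),
    "smaller than the section")
})

test_that("a single section aligns its peak slice to d = 0", {
  nz <- 14
  vol <- array(0, c(nz, 20, 20))
  env <- z_envelope(nz, peak = 11)            # 0-based slice 10
  for (z in seq_len(nz)) vol[z, , ] <- env[z] * tile_pattern()
  prof <- q95_edge_profile(volume3d(vol), section_size = c(20, 20),
    sigma = 1, t_r = 12)
  sec <- attr(prof, "sections")
  expect_identical(edge_profile_sn(prof), 1L)
  expect_identical(sec$peak_index, 10L)
  tb <- tibble::as_tibble(prof)
  expect_identical(tb$d[which.max(tb$e095)], 0L)
  expect_identical(range(tb$d), c(-10L, 3L))
})

test_that("two shifted sections average to the hand-computed aligned curve", {
  nz <- 16
  shift <- 5
  vol <- array(0, c(nz, 20, 40))
  envA <- z_envelope(nz, peak = 6)            # 0-based peak 5
  envB <- z_envelope(nz, peak = 6 + shift)    # 0-based peak 10
  pat <- tile_pattern()
  for (z in seq_len(nz)) {
    vol[z, , 1:20] <- envA[z] * pat
    vol[z, , 21:40] <- envB[z] * pat
  }
  prof <- q95_edge_profile(volume3d(vol), section_size = c(20, 20),
    sigma = 1, t_r = 12)
  expect_identical(edge_profile_sn(prof), 2L)

  # oracle: full e-curves per section, aligned at their argmax, then
  # averaged over the sections possessing each aligned index
  eA <- oracle_e_curve(vol[, , 1:20, drop = FALSE], sigma = 1)
  eB <- oracle_e_curve(vol[, , 21:40, drop = FALSE], sigma = 1)
  dA <- seq_len(nz) - which.max(eA)
  dB <- seq_len(nz) - which.max(eB)
  all_d <- sort(union(dA, dB))
  expected <- vapply(all_d, function(dd) {
    vals <- c(eA[match(dd, dA)], eB[match(dd, dB)])
    mean(vals[!is.na(vals)])
  }, numeric(1))
  tb <- tibble::as_tibble(prof)
  expect_identical(tb$d, as.integer(all_d))
  expect_equal(tb$e095, expected, tolerance = 1e-10)

  # where both sections contribute, the equal curves mean their own value
  both <- intersect(dA, dB)
  expect_equal(tb$e095[match(both, tb$d)], eA[match(both, dA)],
    tolerance = 1e-8)
  expect_true(all(tb$n_sections[match(both, tb$d)] == 2L))
})

test_that("section-aligned translation leaves the profile unchanged", {
  nz <- 10
  vol <- array(0, c(nz, 20, 60))
  env <- z_envelope(nz, peak = 4)
  for (z in seq_len(nz)) vol[z, , 1:20] <- env[z] * tile_pattern()
  shifted <- array(0, c(nz, 20, 60))
  shifted[, , 21:40] <- vol[, , 1:20]          # shift by one section width
  p1 <- q95_edge_profile(volume3d(vol), section_size = c(20, 20), sigma = 1,
    t_r = 9)
  p2 <- q95_edge_profile(volume3d(shifted), section_size = c(20, 20),
    sigma = 1, t_r = 9)
  expect_identical(edge_profile_sn(p1), edge_profile_sn(p2))
  expect_equal(tibble::as_tibble(p1)$e095, tibble::as_tibble(p2)$e095,
    tolerance = 1e-12)
})

test_that("scaling intensities scales the profile; dim peaks get discarded", {
  nz <- 10
  vol <- array(0, c(nz, 20, 20))
  env <- z_envelope(nz, peak = 4)
  for (z in seq_len(nz)) vol[z, , ] <- env[z] * tile_pattern()
  p1 <- q95_edge_profile(volume3d(vol), section_size = c(20, 20), sigma = 1,
    t_r = 9)
  p3 <- q95_edge_profile(volume3d(3 * vol), section_size = c(20, 20),
    sigma = 1, t_r = 9)
  expect_equal(tibble::as_tibble(p3)$e095, 3 * tibble::as_tibble(p1)$e095,
    tolerance = 1e-10)

  # t_r: a section whose peak lies too deep is dropped
  pr <- q95_edge_profile(volume3d(vol), section_size = c(20, 20), sigma = 1,
    t_r = 1)
  expect_identical(edge_profile_sn(pr), 0L)
  # t_b: raising the background threshold above the max drops everything
  pb <- q95_edge_profile(volume3d(vol), section_size = c(20, 20), sigma = 1,
    t_b = 1e9, t_r = 9)
  expect_identical(edge_profile_sn(pb), 0L)
})

test_that("separable Gaussian + Sobel match the dense-convolution oracle", {
  set.seed(80)
  sl <- matrix(runif(20 * 20), 20, 20)
  vol <- array(0, c(1, 20, 20)); vol[1, , ] <- sl
  sm <- spheroidsim:::gaussian_smooth(vol, c(0, 1.5, 1.5))
  r <- ceiling(3 * 1.5)
  g1 <- stats::dnorm(seq(-r, r), sd = 1.5); g1 <- g1 / sum(g1)
  expect_equal(sm[1, , ], dense_conv2d(sl, outer(g1, g1)),
    tolerance = 1e-12)

  mag <- spheroidsim:::sobel_magnitude_slices(vol)
  gy <- dense_conv2d(sl, outer(c(1, 0, -1), c(1, 2, 1)))
  gx <- dense_conv2d(sl, outer(c(1, 2, 1), c(1, 0, -1)))
  expect_equal(mag[1, , ], sqrt(gx^2 + gy^2), tolerance = 1e-12)
})
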