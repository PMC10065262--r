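test_that("region partition is disjoint, exhaustive and dilation-aware", {
  d <- c(6, 10, 10)
  mask <- shape_mask(array(rep(c(TRUE, FALSE), each = prod(d) / 2), d))
  empty <- label_volume(array(0L, d))
  part <- partition_regions(mask, empty, dilation_radius = 1)
  expect_true(all(part[as.vector(mask)] == 1L))   # all mask is bg_inside
  expect_true(all(part[!as.vector(mask)] == 0L))

  full_mask <- shape_mask(array(TRUE, d))
  full_lab <- label_volume(array(1L, d))
  part2 <- partition_regions(full_mask, full_lab, 1)
  expect_true(all(part2 == 2L))

  set.seed(70)
  m <- array(runif(prod(d)) < 0.6, d)
  lab <- array(0L, d); lab[3:4, 4:6, 4:6] <- 1L
  part3 <- partition_regions(shape_mask(m), label_volume(lab), 1)
  counts <- tabulate(as.vector(part3) + 1L, 3L)
  expect_identical(sum(counts), as.integer(prod(d)))  # partition property
  # foreground = dilated labels intersected with mask
  dil <- spheroidsim:::dilate_chebyshev(lab > 0, 1)
  expect_identical(part3 == 2L, dil & m)
})

test_that("1D Wasserstein distance: closed forms and metric behavior", {
  expect_equal(wasserstein_1d(c(1, 5, 9), c(1, 5, 9)), 0)
  expect_equal(wasserstein_1d(rep(50, 10), rep(100, 7)), 50)
  expect_equal(wasserstein_1d(c(0, 0, 100, 100), c(0, 100)), 0)
  expect_error(wasserstein_1d(numeric(0), 1), "empty")

  # equal-size samples: matches the brute-force optimal pairing
  set.seed(71)
  for (rep in 1:5) {
    a <- round(runif(6, 0, 20), 1)
    b <- round(runif(6, 0, 20), 1)
    expect_equal(wasserstein_1d(a, b), brute_transport_w1(a, b),
      tolerance = 1e-12)
    # symmetry
    expect_equal(wasserstein_1d(a, b), wasserstein_1d(b, a))
  }
  # triangle inequality spot-check
  for (rep in 1:5) {
    a <- runif(5); b <- runif(5); cc <- runif(5)
    expect_lte(wasserstein_1d(a, cc),
      wasserstein_1d(a, b) + wasserstein_1d(b, cc) + 1e-12)
  }
})

test_that("normalized Wasserstein endpoints and point-mass case", {
  set.seed(72)
  d <- c(4, 8, 8)
  real <- volume3d(array(runif(prod(d), 10, 200), d))
  mask <- shape_mask(array(TRUE, d))
  lab <- array(0L, d); lab[, 3:6, 3:6] <- 1L
  part <- partition_regions(mask, label_volume(lab), 0)

  res_same <- normalized_wasserstein(real, real, part, part)
  expect_true(all(abs(res_same$w_norm - 1) < 1e-12))

  black <- volume3d(array(0, d))
  res_black <- normalized_wasserstein(real, black, part, part)
  expect_true(all(abs(res_black$w_norm) < 1e-12))

  # point masses: real 100, syn 50 -> W_norm = 1 - 50/100 = 0.5
  r100 <- volume3d(array(100, d))
  s50 <- volume3d(array(50, d))
  res_half <- normalized_wasserstein(r100, s50, part, part)
  expect_true(all(abs(res_half$w_norm - 0.5) < 1e-12))

  # all-zero real slices are excluded, not crashed on
  rz <- array(runif(prod(d), 1, 10), d); rz[2, , ] <- 0
  res_ex <- normalized_wasserstein(volume3d(rz), s50, part, part)
  excluded <- attr(res_ex, "excluded")
  expect_true(all(res_ex$z != 1))                 # 0-based slice 1 dropped
  expect_true("black_real_slice" %in% excluded$reason)
})

test_that("depth grouping uses half-open pixel intervals", {
  df <- tibble::tibble(z = c(0, 40, 41, 81, 82, 200), v = 1:6)
  g <- group_by_depth(df, depth_grouping(), index = "z")
  expect_identical(as.character(g$group),
    c("upper", "upper", "middle", "middle", "lower", "lower"))
  empty <- group_by_depth(df[0, ], depth_grouping(), index = "z")
  expect_identical(nrow(empty), 0L)
  # out-of-interval values are dropped
  g2 <- group_by_depth(tibble::tibble(z = c(-1, 5), v = 1:2),
    depth_grouping(upper = c(0, 41), middle = NULL, lower = NULL))
  expect_identical(nrow(g2), 1L)
  expect_error(depth_grouping(upper = c(0, 50), middle = c(40, 80)),
    "overlap")
})

test_that("wasserstein summaries and plots are well-formed", {
  set.seed(73)
  d <- c(6, 8, 8)
  real <- volume3d(array(runif(prod(d), 10, 100), d))
  syn <- volume3d(array(runif(prod(d), 10, 100), d))
  mask <- shape_mask(array(TRUE, d))
  lab <- array(0L, d); lab[, 3:5, 3:5] <- 1L
  part <- partition_regions(mask, label_volume(lab), 0)
  res <- normalized_wasserstein(real, syn, part, part,
    depth_grouping(upper = c(0, 3), middle = c(3, 6), lower = NULL))
  expect_true(all(res$w_norm <= 1))
  summ <- summarize_wasserstein(res)
  expect_true(all(c("region", "group", "median_w_norm") %in% names(summ)))
  pl <- ggplot2::autoplot(res)
  expect_s3_class(pl, "ggplot")
})
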