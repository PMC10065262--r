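test_that("unperturbed spheroid mask is the exact discrete ball", {
  r <- 20
  m <- generate_spheroid_mask(c(42, 42, 42), c(r, r, r),
    perturb_amplitude = 0)
  # independent brute-force lattice count
  ctr <- (42 + 1) / 2
  cnt <- 0L
  inside <- array(FALSE, c(42, 42, 42))
  for (z in 1:42) for (y in 1:42) for (x in 1:42) {
    if (((z - ctr)^2 + (y - ctr)^2 + (x - ctr)^2) <= r^2) {
      cnt <- cnt + 1L
      inside[z, y, x] <- TRUE
    }
  }
  expect_identical(array(as.logical(m), dim(m)), inside)
  expect_lt(abs(sum(m) - 4 / 3 * pi * r^3) / (4 / 3 * pi * r^3), 0.05)
  # amplitude 0: independent of seed
  m2 <- generate_spheroid_mask(c(42, 42, 42), c(r, r, r),
    perturb_amplitude = 0, seed = 999)
  expect_identical(as.vector(m), as.vector(m2))
})

test_that("perturbed masks differ by seed but stay one connected component", {
  sh <- c(24, 40, 40)
  ra <- c(9, 16, 16)
  m1 <- generate_spheroid_mask(sh, ra, perturb_amplitude = 0.1, seed = 1)
  m2 <- generate_spheroid_mask(sh, ra, perturb_amplitude = 0.1, seed = 2)
  expect_false(identical(as.vector(m1), as.vector(m2)))
  for (m in list(m1, m2)) {
    seed_idx <- which(m, arr.ind = TRUE)[1, ]
    comp <- flood_component(array(as.logical(m), dim(m)), seed_idx)
    expect_identical(sum(comp), sum(m))
  }
  expect_error(generate_spheroid_mask(c(10, 10, 10), c(8, 4, 4)),
    "exceed")
})

test_that("check_position verdicts match the contract", {
  d <- c(8, 12, 12)
  labels <- label_volume(array(0L, d))
  mask <- shape_mask(array(TRUE, d))
  p <- make_ellipsoid_prototype(c(1.5, 2.5, 2.5), 0, seed = 1)
  cfg <- placement_config(require_fully_inside_mask = TRUE)

  expect_true(check_position(labels, mask, p, c(1, 1, 1), cfg)$valid)
  expect_identical(
    check_position(labels, mask, p, c(7, 1, 1), cfg)$reason,
    "out_of_bounds")

  holey <- array(TRUE, d); holey[2, 3, 3] <- FALSE
  v <- check_position(labels, shape_mask(holey), p, c(1, 1, 1), cfg)
  expect_identical(v$reason, "outside_mask")

  occupied <- array(0L, d); occupied[2, 3, 3] <- 1L
  v2 <- check_position(label_volume(occupied), mask, p, c(1, 1, 1), cfg)
  expect_identical(v2$reason, "overlap")

  # min_gap: a voxel just beyond the box, Chebyshev-adjacent to the mask's
  # x-extreme voxel, collides only under the dilated test
  pd <- dim(p$mask)
  near <- array(0L, d)
  near[(pd[1] + 1) / 2, (pd[2] + 1) / 2, pd[3] + 1] <- 1L
  cfg_gap <- placement_config(min_gap = 1)
  v3 <- check_position(label_volume(near), mask, p, c(1, 1, 1), cfg_gap)
  expect_identical(v3$reason, "overlap")
  v4 <- check_position(label_volume(near), mask, p, c(1, 1, 1), cfg)
  expect_true(v4$valid)
})

test_that("placement respects disjointness, mask containment and determinism", {
  scene <- toy_scene()
  res <- scene$placement
  expect_gt(res$n_placed, 0)
  lab <- array(as.integer(res$labels), dim(res$labels))
  # zero overlap: per-instance voxel counts add up to the labeled total
  per <- table(lab[lab > 0])
  expect_identical(sum(lab > 0), sum(per))
  expect_identical(sort(as.integer(names(per))), seq_len(res$n_placed))
  # containment in the shape mask
  expect_true(all(scene$mask[lab > 0]))
  # image support inside label support
  expect_true(all(res$image[lab == 0] == 0))

  # seed determinism
  cfg <- placement_config(max_consecutive_failures = 150, seed = 42)
  r2 <- place_nuclei(scene$mask, scene$db, cfg)
  r3 <- place_nuclei(scene$mask, scene$db, cfg)
  expect_identical(as.vector(r2$labels), as.vector(r3$labels))
  expect_identical(as.vector(r2$image), as.vector(r3$image))
  expect_identical(r2$attempts, r3$attempts)
})

test_that("an all-false mask places nothing", {
  db <- small_db()
  mask <- shape_mask(array(FALSE, c(8, 20, 20)))
  res <- place_nuclei(mask, db,
    placement_config(max_consecutive_failures = 50, seed = 1))
  expect_identical(res$n_placed, 0L)
  expect_true(all(res$labels == 0L))
  expect_identical(nrow(res$attempts), 50L)
})

test_that("a mask admitting exactly one pose saturates at one nucleus", {
  p <- make_ellipsoid_prototype(c(1.5, 3, 3), 0, seed = 2)
  db <- build_database(list(p), identity_augmentation(1,
    online_flip = FALSE, online_swap = FALSE), seed = 1)
  d <- dim(p$mask) + c(2L, 2L, 2L)
  mvox <- array(FALSE, d)
  mvox[2:(1 + dim(p$mask)[1]), 2:(1 + dim(p$mask)[2]),
    2:(1 + dim(p$mask)[3])] <- p$mask
  mask <- shape_mask(mvox)
  cfg <- placement_config(max_consecutive_failures = 500, seed = 3)

  # oracle: exhaustive scan of every corner — exactly one is valid
  empty <- label_volume(array(0L, d))
  valid_corners <- 0L
  room <- d - dim(p$mask)
  for (z in 1:(room[1] + 1)) for (y in 1:(room[2] + 1)) {
    for (x in 1:(room[3] + 1)) {
      if (check_position(empty, mask, p, c(z, y, x), cfg)$valid) {
        valid_corners <- valid_corners + 1L
      }
    }
  }
  expect_identical(valid_corners, 1L)

  res <- place_nuclei(mask, db, cfg)
  expect_identical(res$n_placed, 1L)
})
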