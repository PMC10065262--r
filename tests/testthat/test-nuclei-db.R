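test_that("extract_prototype crops tight and zeroes outside the mask", {
  img <- volume3d(array(runif(6 * 8 * 8) + 1, c(6, 8, 8)))
  lab <- array(0L, c(6, 8, 8))
  lab[3, 4, 4] <- 1L            # single voxel
  lab[2:4, 2:6, 3:7] <- ifelse(lab[2:4, 2:6, 3:7] == 1L, 1L, 2L)
  lab[3, 4, 4] <- 1L
  labv <- label_volume(lab)

  p1 <- extract_prototype(img, labv, 1L)
  expect_identical(dim(p1$mask), c(1L, 1L, 1L))
  expect_equal(p1$intensity[1, 1, 1], img[3, 4, 4])

  lab2 <- array(0L, c(6, 8, 8))
  lab2[2:4, 2:6, 3:7] <- 2L     # solid box
  p2 <- extract_prototype(img, label_volume(lab2), 2L)
  expect_identical(dim(p2$mask), c(3L, 5L, 5L))
  expect_true(all(p2$mask))
  expect_equal(p2$intensity, img[2:4, 2:6, 3:7])

  expect_error(extract_prototype(img, labv, 99L), "not present")

  lab3 <- array(0L, c(6, 8, 8)); lab3[1, 1:2, 1:2] <- 5L
  expect_message(extract_prototype(img, label_volume(lab3), 5L), "border")
})

test_that("identity augmentation reproduces the input exactly", {
  p <- make_ellipsoid_prototype(c(2, 4, 4), 0.3, seed = 3)
  out <- augment_offline(p, identity_augmentation(3), seed = 9)
  expect_length(out, 3)
  for (v in out) {
    expect_identical(dim(v$mask), dim(p$mask))
    expect_true(max(abs(v$intensity - p$intensity)) == 0)
    expect_identical(v$mask, p$mask)
  }
})

test_that("fixed 90-degree rotation equals the direct index permutation", {
  set.seed(4)
  a <- array(0, c(2, 5, 7))
  for (z in 1:2) a[z, , ] <- matrix(runif(35), 5, 7)
  p <- nucleus_prototype(a, array(TRUE, c(2, 5, 7)))
  cfg <- augmentation_config(rotation = c(90, 90), scale = c(1, 1),
    blur = c(0, 0), contrast = c(1, 1), gamma = c(1, 1),
    elastic_amplitude = c(0, 0), variants_per_prototype = 1)
  r <- augment_offline(p, cfg, seed = 2)[[1]]
  expect_identical(dim(r$intensity), c(2L, 7L, 5L))
  for (z in 1:2) {
    expect_equal(r$intensity[z, , ], t(a[z, , ])[7:1, ], tolerance = 1e-12)
  }
})

test_that("offline augmentation is deterministic per seed and keeps invariants", {
  p <- make_ellipsoid_prototype(c(2, 4, 5), 0.3, seed = 8)
  cfg <- augmentation_config(variants_per_prototype = 6)
  a1 <- augment_offline(p, cfg, seed = 33)
  a2 <- augment_offline(p, cfg, seed = 33)
  a3 <- augment_offline(p, cfg, seed = 34)
  expect_identical(a1, a2)
  expect_false(identical(a1, a3))
  for (v in a1) {
    expect_true(any(v$mask))
    expect_true(all(v$intensity[!v$mask] == 0))
    expect_true(all(v$intensity >= 0))
    # tight box: every face touches the mask
    for (ax in 1:3) {
      marg <- apply(v$mask, ax, any)
      expect_true(marg[1] && marg[length(marg)])
    }
  }
})

test_that("build_database bookkeeping and reproducibility", {
  p <- make_ellipsoid_prototype(c(2, 3, 3), 0.2, seed = 5)
  db <- build_database(list(p), identity_augmentation(1), seed = 1)
  expect_identical(db_size(db), 1L)
  expect_true(max(abs(db$prototypes[[1]]$intensity - p$intensity)) == 0)

  db2 <- build_database(list(p, p, p),
    augmentation_config(variants_per_prototype = 4), seed = 2)
  expect_identical(db_size(db2), 12L)
  db3 <- build_database(list(p, p, p),
    augmentation_config(variants_per_prototype = 4), seed = 2)
  expect_identical(db2$prototypes, db3$prototypes)

  expect_error(build_database(list()), "empty")
})

test_that("database survives a disk round-trip", {
  db <- small_db()
  dir <- withr::local_tempdir()
  write_database(db, dir)
  back <- read_database(dir)
  expect_identical(db_size(back), db_size(db))
  for (i in seq_len(db_size(db))) {
    expect_lt(max(abs(back$prototypes[[i]]$intensity -
      db$prototypes[[i]]$intensity)), 1e-4)
    expect_identical(back$prototypes[[i]]$mask, db$prototypes[[i]]$mask)
  }
  expect_identical(back$manifest$variants_per_prototype,
    db$manifest$variants_per_prototype)
})

test_that("online augmentation preserves content and is uniform over entries", {
  p <- make_ellipsoid_prototype(c(2, 4, 4), 0.25, seed = 6)
  db1 <- build_database(list(p), identity_augmentation(1,
    online_flip = FALSE, online_swap = FALSE), seed = 1)
  s <- withr::with_seed(1, sample_prototype(db1))
  expect_true(max(abs(s$intensity - db1$prototypes[[1]]$intensity)) == 0)

  # flips/swaps are index permutations: voxel count and value multiset kept
  db2 <- build_database(list(p), identity_augmentation(1,
    online_flip = TRUE, online_swap = TRUE), seed = 1)
  withr::with_seed(42, {
    for (i in 1:20) {
      s2 <- sample_prototype(db2)
      expect_identical(sum(s2$mask), sum(p$mask))
      expect_equal(sort(s2$intensity[s2$mask]), sort(p$intensity[p$mask]))
    }
  })

  # uniformity: 10000 draws over 4 distinguishable entries, 5 sigma band
  protos <- lapply(1:4, function(i) {
    nucleus_prototype(array(i, c(1, 1, 1)), array(TRUE, c(1, 1, 1)))
  })
  db4 <- build_database(protos, identity_augmentation(1,
    online_flip = FALSE, online_swap = FALSE), seed = 3)
  draws <- withr::with_seed(99, vapply(1:10000, function(i) {
    sample_prototype(db4)$intensity[1, 1, 1]
  }, numeric(1)))
  counts <- table(factor(draws, levels = 1:4))
  sigma <- sqrt(10000 * 0.25 * 0.75)
  expect_true(all(abs(counts - 2500) < 5 * sigma))
})
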