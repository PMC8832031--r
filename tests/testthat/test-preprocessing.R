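# Normalization, cropping, resizing, augmentation, and partitioning.

test_that("pooled dataset statistics match forced arithmetic and a two-pass oracle", {
  r1 <- makeRecord(matrix(c(0, 2), 1, 2))
  r2 <- makeRecord(matrix(c(2, 0), 1, 2))
  s <- computeDatasetStats(list(r1, r2))
  expect_equal(s@mean, 1.0)
  expect_equal(s@sd, 1.0)
  expect_true(s@valid)

  sc <- computeDatasetStats(list(makeRecord(matrix(7, 4, 4))))
  expect_equal(sc@sd, 0)
  expect_false(sc@valid)

  set.seed(10)
  recs <- lapply(1:100, function(i) {
    makeRecord(matrix(rnorm(30, mean = i %% 5), 5, 6))
  })
  pooled <- unlist(lapply(recs, function(r) as.numeric(sliceImage(r))))
  m <- sum(pooled) / length(pooled)
  v <- sum((pooled - m)^2) / length(pooled)   # two-pass population variance
  s2 <- computeDatasetStats(recs)
  expect_equal(s2@mean, m, tolerance = 1e-10)
  expect_equal(s2@sd, sqrt(v), tolerance = 1e-10)

  per <- computeDatasetStats(recs, scope = "per_image")
  expect_length(per, 100)
  expect_equal(per[[1]]@mean, mean(sliceImage(recs[[1]])))

  expect_error(computeDatasetStats(list()), "no slices")
})

test_that("Z-score normalization matches its definition and inverts exactly", {
  s <- new("DatasetStats", mean = 1, sd = 2, valid = TRUE)
  expect_equal(zscoreNormalize(matrix(3), s)[1, 1], 1.0)

  set.seed(2)
  img <- matrix(runif(64, 10, 200), 8, 8)
  own <- computeDatasetStats(list(makeRecord(img)))
  z <- zscoreNormalize(img, own)
  expect_lt(abs(mean(z)), 1e-9)
  expect_lt(abs(mean(z^2) - 1), 1e-6)

  # inverse transform recovers the input
  expect_lt(max(abs(z * own@sd + own@mean - img)), 1e-9)

  const <- computeDatasetStats(list(makeRecord(matrix(5, 3, 3))))
  expect_error(zscoreNormalize(matrix(5, 3, 3), const), "degenerate")
})

test_that("ROI cropping follows the bounding box + margin + clipping rule", {
  img <- matrix(seq_len(100), 10, 10)
  msk <- matrix(0, 10, 10); msk[5:6, 5:6] <- 1
  out <- cropToRoi(makeRecord(img, msk), margin = 2L)
  expect_equal(dim(sliceImage(out)), c(6L, 6L))
  expect_equal(sliceImage(out), img[3:8, 3:8])
  expect_equal(sum(sliceMask(out)), 4)

  full <- makeRecord(img, matrix(1, 10, 10))
  expect_equal(sliceImage(cropToRoi(full, 0L)), img)

  corner <- matrix(0, 10, 10); corner[1:2, 1:2] <- 1
  big <- cropToRoi(makeRecord(img, corner), margin = 50L)
  expect_equal(dim(sliceImage(big)), c(10L, 10L))

  expect_error(cropToRoi(makeRecord(img), 1L), "empty mask")
})

test_that("resizing respects shape, identity, constants, and binarity", {
  set.seed(3)
  rec <- makeRecord(matrix(runif(512^2), 512, 512),
                    {m <- matrix(0, 512, 512); m[200:300, 220:310] <- 1; m})
  out <- resizeTo(rec, 256L)
  expect_equal(dim(sliceImage(out)), c(256L, 256L))
  expect_true(all(sliceMask(out) %in% c(0, 1)))
  expect_gt(sum(sliceMask(out)), 0)

  same <- resizeTo(rec, 512L)
  expect_identical(sliceImage(same), sliceImage(rec))

  const <- resizeTo(makeRecord(matrix(3.5, 32, 32)), 16L)
  expect_true(all(abs(sliceImage(const) - 3.5) < 1e-12))

  expect_error(resizeTo(rec, 4L), "side")
})

test_that("augmentation transforms image and mask identically and deterministically", {
  set.seed(4)
  img <- matrix(runif(32 * 32), 32, 32)
  msk <- matrix(0, 32, 32); msk[10:18, 14:22] <- 1
  rec <- makeRecord(img, msk)

  mir <- applyTransform <- attrunet:::applyTransform
  m1 <- mir(rec, list(type = "mirror"))
  m2 <- mir(m1, list(type = "mirror"))
  expect_identical(sliceImage(m2), img)   # involution
  expect_identical(sliceMask(m2), msk)

  r0 <- mir(rec, list(type = "rotate", angle = 0))
  expect_identical(sliceImage(r0), img)

  expect_error(augment(rec, list(list(type = "swirl"))), "unknown transform")

  a1 <- augment(rec, seed = 9L)
  a2 <- augment(rec, seed = 9L)
  expect_identical(a1, a2)
  expect_length(a1, length(defaultAugmentation()) + 1L)
  expect_identical(a1[[1]], rec)

  # mask is the same geometric transform as the image: transform an
  # indicator image and compare with the transformed mask support
  ind <- makeRecord(msk * 1, msk)
  rot <- mir(ind, list(type = "rotate", angle = 10))
  expect_equal(sliceMask(rot), (sliceImage(rot) > 0.5) * 1)

  grown <- augmentDataset(SliceSet(list(rec)), 7L, seed = 2L)
  expect_length(grown, 7L)
})

test_that("80/10/10 split reproduces the printed test-set size and partitions cleanly", {
  sp <- splitDataset(4775, seed = 1L)
  expect_length(sp@train, 3820)
  expect_length(sp@validation, 477)
  expect_length(sp@test, 478)

  sp100 <- splitDataset(100, seed = 2L)
  expect_equal(vapply(list(sp100@train, sp100@validation, sp100@test),
                      length, integer(1)), c(80L, 10L, 10L))
  sp10 <- splitDataset(10, seed = 3L)
  expect_equal(vapply(list(sp10@train, sp10@validation, sp10@test),
                      length, integer(1)), c(8L, 1L, 1L))

  expect_error(splitDataset(2), "at least 3")

  for (seed in 1:5) {
    n <- sample(10:500, 1)
    sp <- splitDataset(n, seed = seed)
    all_idx <- c(sp@train, sp@validation, sp@test)
    expect_equal(sort(all_idx), seq_len(n))       # exhaustive
    expect_equal(anyDuplicated(all_idx), 0L)      # disjoint
  }
})

test_that("patient folds are balanced, deterministic, and patient-disjoint", {
  ids <- paste0("P", 1:93)
  fa <- assignPatientFolds(ids, k = 5L, seed = 1L)
  expect_equal(sort(tabulate(foldOf(fa), 5L)), c(18L, 18L, 19L, 19L, 19L))

  one <- assignPatientFolds(paste0("P", 1:5), k = 5L, seed = 2L)
  expect_equal(sort(tabulate(foldOf(one), 5L)), rep(1L, 5))

  expect_identical(assignPatientFolds(ids, 5L, seed = 7L),
                   assignPatientFolds(ids, 5L, seed = 7L))

  expect_error(assignPatientFolds(paste0("P", 1:3), k = 5L), "fewer")

  # repeated slice-level ids map to a single fold each
  slices <- rep(ids, times = rep_len(c(1, 4, 9), 93))
  fa2 <- assignPatientFolds(slices, k = 5L, seed = 3L)
  expect_length(foldOf(fa2), 93)
  expect_false(anyDuplicated(names(foldOf(fa2))) > 0)
})
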