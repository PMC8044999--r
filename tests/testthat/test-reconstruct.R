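test_that("stuck-pixel repair replaces flagged pixels with the neighbour median", {
  img <- matrix(100, 3, 3); img[2, 2] <- 65535
  msk <- matrix(FALSE, 3, 3); msk[2, 2] <- TRUE
  out <- repair_stuck_pixels(img, msk)
  expect_equal(out[2, 2], 100)
  expect_equal(out[-5], img[-5])  # all other pixels untouched

  # corner pixel: median of its 3 enumerated neighbours {10, 20, 30} is 20
  img2 <- matrix(0, 2, 2)
  img2[1, 2] <- 10; img2[2, 1] <- 20; img2[2, 2] <- 30
  msk2 <- matrix(FALSE, 2, 2); msk2[1, 1] <- TRUE
  expect_equal(repair_stuck_pixels(img2, msk2)[1, 1], 20)

  # empty mask is the identity
  expect_identical(repair_stuck_pixels(img, matrix(FALSE, 3, 3)), img)

  # flagged neighbours are excluded from the median
  img3 <- matrix(c(1, 2, 3, 4, 1000, 6, 7, 8, 9), 3, 3)
  msk3 <- matrix(FALSE, 3, 3); msk3[2, 2] <- TRUE; msk3[1, 1] <- TRUE
  out3 <- repair_stuck_pixels(img3, msk3)
  expect_equal(out3[2, 2], stats::median(c(4, 7, 2, 8, 3, 6, 9)))

  # pathological mask: no usable neighbours
  expect_error(repair_stuck_pixels(matrix(1, 1, 1), matrix(TRUE, 1, 1)),
               "no usable neighbours")
})

test_that("repair is idempotent for a fixed mask", {
  set.seed(2)
  img <- matrix(stats::rpois(400, 50), 20, 20)
  msk <- matrix(FALSE, 20, 20); msk[cbind(c(3, 7, 19), c(4, 7, 20))] <- TRUE
  once <- repair_stuck_pixels(img, msk)
  expect_identical(repair_stuck_pixels(once, msk), once)
})

test_that("planted constant hot pixels are detected, and only those", {
  set.seed(31)
  nr <- 40; nc <- 36
  hot <- cbind(row = c(5, 11, 20, 28, 33), col = c(7, 30, 15, 3, 22))
  slices <- lapply(1:8, function(s) {
    img <- matrix(stats::rnorm(nr * nc, 500, 20), nr, nc)
    img[hot] <- 65535
    img
  })
  mask <- detect_stuck_pixels(slices)
  expect_equal(sum(mask), 5L)
  expect_true(all(mask[hot]))
})

test_that("noise-only stacks produce no false positives over 20 seeds", {
  for (seed in 1:20) {
    set.seed(seed)
    slices <- lapply(1:6, function(s) matrix(stats::rnorm(900, 500, 20), 30, 30))
    expect_equal(sum(detect_stuck_pixels(slices)), 0L)
  }
})

test_that("an all-constant stack yields no flags", {
  slices <- lapply(1:6, function(s) matrix(7, 16, 16))
  expect_equal(sum(detect_stuck_pixels(slices)), 0L)
})

test_that("detection needs at least five slices", {
  expect_error(detect_stuck_pixels(lapply(1:3, function(s) matrix(0, 8, 8))),
               "at least 5")
})

test_that("block-mean rescale reduces 3x and stacks slices in order", {
  # constant slice stays constant
  const <- rescale_isotropic(lapply(1:4, function(s) matrix(11, 9, 9)),
                             pixel_pitch = 15, slice_thickness = 45)
  expect_true(all(const$intensities == 11))
  expect_equal(dim(const$intensities), c(4, 3, 3))
  expect_equal(const$pitch_um, 45)

  # top-left 3x3 block holding 0..8 averages to 4
  img <- matrix(0, 6, 6)
  img[1:3, 1:3] <- matrix(0:8, 3, 3)
  v <- rescale_isotropic(list(img), pixel_pitch = 15, slice_thickness = 45)
  expect_equal(v$intensities[1, 1, 1], 4)

  # stacking preserves acquisition order along axis 1
  slices <- lapply(1:5, function(s) matrix(s, 6, 6))
  v2 <- rescale_isotropic(slices, pixel_pitch = 15, slice_thickness = 45)
  expect_equal(v2$intensities[, 1, 1], 1:5)
})

test_that("block averaging preserves the global mean exactly", {
  set.seed(8)
  slices <- lapply(1:3, function(s) matrix(stats::runif(36 * 27), 36, 27))
  v <- rescale_isotropic(slices, pixel_pitch = 15, slice_thickness = 45)
  expect_equal(mean(v$intensities), mean(unlist(slices)))
})

test_that("non-integer reduction factors are refused", {
  expect_error(rescale_isotropic(list(matrix(0, 10, 10)),
                                 pixel_pitch = 20, slice_thickness = 45),
               "does not divide")
  expect_error(rescale_isotropic(list(matrix(0, 10, 10)),
                                 pixel_pitch = 15, slice_thickness = 45),
               "not divisible")
})

test_that("pipeline order matters: repairing after rescaling leaks defects into volumes", {
  set.seed(77)
  nr <- 18; nc <- 18
  hot <- cbind(row = c(4, 9, 14), col = c(4, 10, 16))
  slices <- lapply(1:6, function(s) {
    img <- matrix(stats::rnorm(nr * nc, 300, 15), nr, nc)
    img[hot] <- 65535
    img
  })
  msk <- detect_stuck_pixels(slices)
  # declared order: repair each slice, then rescale
  good <- rescale_isotropic(lapply(slices, repair_stuck_pixels, stuck_mask = msk),
                            pixel_pitch = 15, slice_thickness = 45)
  # wrong order: rescale the defective slices directly
  bad <- rescale_isotropic(slices, pixel_pitch = 15, slice_thickness = 45)
  thr <- 2000
  n_good <- sum(good$intensities >= thr)
  n_bad <- sum(bad$intensities >= thr)
  expect_equal(n_good, 0L)
  expect_gt(n_bad, 0L)
})
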