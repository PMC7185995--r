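test_that("innervation density is the supra-threshold ROI fraction", {
  img <- matrix(0, 10, 10)
  roi <- matrix(FALSE, 10, 10); roi[3:6, 3:6] <- TRUE
  img[roi] <- 100
  expect_equal(innervation_density(img, roi, 50), 1)
  img[roi] <- 10
  expect_equal(innervation_density(img, roi, 50), 0)
  img[3:4, 3:6] <- 80  # exactly half the 16 ROI pixels
  expect_equal(innervation_density(img, roi, 50), 0.5)
  expect_error(innervation_density(img, matrix(FALSE, 10, 10), 50),
               "empty ROI")
})

test_that("innervation density is monotone non-increasing in threshold", {
  set.seed(41)
  img <- matrix(runif(400, 0, 100), 20, 20)
  roi <- matrix(TRUE, 20, 20)
  d <- sapply(seq(0, 100, by = 5), function(th)
    innervation_density(img, roi, th))
  expect_true(all(diff(d) <= 0))
})

test_that("3D puncta counting finds constructed blobs with size gates", {
  a <- array(0, c(8, 20, 20))
  # 7 disjoint 10-voxel blobs at intensity 60 (2x5 plates, well separated)
  origins <- list(c(2, 2, 2), c(2, 8, 2), c(2, 14, 2), c(5, 2, 8),
                  c(5, 8, 8), c(5, 14, 8), c(2, 2, 14))
  for (o in origins)
    a[o[1], o[2]:(o[2] + 1), o[3]:(o[3] + 4)] <- 60
  stack <- image_stack(a)
  roi <- array(TRUE, dim(a))
  r <- count_puncta_3d(stack, roi)
  expect_identical(r$count, 7L)
  expect_equal(r$density * r$roi_volume_vox, r$count)

  # single voxel (size 1 < 2) is gated out
  b <- array(0, c(5, 5, 5)); b[3, 3, 3] <- 60
  expect_identical(count_puncta_3d(image_stack(b), array(TRUE, dim(b)))$count,
                   0L)
  # a 100-voxel blob (> 80) is gated out
  d <- array(0, c(6, 10, 10)); d[2:5, 2:6, 2:6] <- 60  # 100 voxels
  expect_identical(sum(d == 60), 100L)
  expect_identical(count_puncta_3d(image_stack(d), array(TRUE, dim(d)))$count,
                   0L)
  expect_error(count_puncta_3d(stack, roi, min_size = 10, max_size = 2),
               "min_size")
})

test_that("diagonally touching voxels are one 26-connected component", {
  a <- array(0, c(4, 4, 4))
  a[1, 1, 1] <- 60; a[2, 2, 2] <- 60  # corner contact
  r <- count_puncta_3d(image_stack(a), array(TRUE, dim(a)),
                       min_size = 1, max_size = 10)
  expect_identical(r$count, 1L)
  r6 <- count_puncta_3d(image_stack(a), array(TRUE, dim(a)),
                        min_size = 1, max_size = 10, connectivity = 6)
  expect_identical(r6$count, 2L)
})

test_that("puncta counts are invariant to axis permutation and padding", {
  set.seed(42)
  sim <- simulate_image_stack(5, dims = c(12, 24, 24), seed = 99)
  base <- count_puncta_3d(sim$stack, sim$roi)
  perm <- aperm(sim$stack$voxels, c(3, 1, 2))
  roi_p <- aperm(sim$roi$mask, c(3, 1, 2))
  r2 <- count_puncta_3d(image_stack(perm), roi_p)
  expect_identical(r2$count, base$count)
  # pad the stack and ROI with below-threshold voxels
  d <- dim(sim$stack$voxels)
  padded <- array(0, d + 2L)
  padded[2:(d[1] + 1), 2:(d[2] + 1), 2:(d[3] + 1)] <- sim$stack$voxels
  roi_pad <- array(FALSE, d + 2L)
  roi_pad[2:(d[1] + 1), 2:(d[2] + 1), 2:(d[3] + 1)] <- sim$roi$mask
  r3 <- count_puncta_3d(image_stack(padded), roi_pad)
  expect_identical(r3$count, base$count)
})

test_that("CTCF follows its formula and is linear in its inputs", {
  expect_equal(ctcf(5000, 100, 10), 4000)
  expect_equal(ctcf(5000, 100, 0), 5000)   # zero background
  # uniform cell equal to background: exactly zero
  img <- matrix(10, 20, 20)
  cell <- matrix(FALSE, 20, 20); cell[5:10, 5:10] <- TRUE
  bg <- matrix(FALSE, 20, 20); bg[15:18, 15:18] <- TRUE
  expect_equal(ctcf_from_image(img, cell, bg)$ctcf, 0)
  # linear in integrated density (slope 1) and background mean (slope -area)
  ids <- seq(1000, 9000, by = 2000)
  expect_equal(diff(ctcf(ids, 50, 7)), diff(ids))
  bgs <- seq(0, 20, by = 5)
  expect_equal(diff(ctcf(5000, 50, bgs)) / diff(bgs), rep(-50, 4))
  expect_error(ctcf(100, 0, 1), "positive")
})

test_that("normalised ROI signal divides by the reference and keeps mode", {
  r <- normalized_roi_signal(80, 40, "adjacent_background")
  expect_equal(r$ratio, 2)
  expect_identical(r$mode, "adjacent_background")
  expect_equal(normalized_roi_signal(55, 55, "same_roi_reference")$ratio, 1)
  expect_error(normalized_roi_signal(10, 0), "reference")
  # constructed single sections reproduce hand-computed ratios exactly
  img <- matrix(0, 10, 10)
  roi <- matrix(FALSE, 10, 10); roi[1:5, 1:5] <- TRUE
  ref <- matrix(FALSE, 10, 10); ref[6:10, 6:10] <- TRUE
  img[roi] <- 12; img[ref] <- 4
  expect_equal(normalized_roi_signal(mean(img[roi]), mean(img[ref]),
                                     "adjacent_background")$ratio, 3)
})

test_that("cohort presence scoring gives the positive percentage with CI", {
  mk_brain <- function(dens) {
    img <- matrix(0, 10, 10)
    roi <- matrix(FALSE, 10, 10); roi[1:10, 1:10] <- TRUE
    img[seq_len(round(dens * 100))] <- 100
    list(img = img, roi = roi_mask(roi, "dFSB"))
  }
  all_pos <- innervation_presence(lapply(rep(0.5, 10), mk_brain),
                                  threshold = 50, min_fraction = 0.1)
  expect_equal(all_pos$percent_positive, 100)
  none <- innervation_presence(lapply(rep(0.02, 10), mk_brain),
                               threshold = 50, min_fraction = 0.1)
  expect_equal(none$percent_positive, 0)
  mixed <- innervation_presence(lapply(c(rep(0.3, 4), rep(0.02, 6)),
                                       mk_brain),
                                threshold = 50, min_fraction = 0.1)
  expect_equal(mixed$percent_positive, 40)
  expect_lt(mixed$ci_low, 40); expect_gt(mixed$ci_high, 40)
  expect_error(innervation_presence(list(), 50, 0.1), "empty cohort")
})
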