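test_that("lung-window normalization maps HU affinely onto [0, 1]", {
  v <- array(c(-1000, 400, -300, -2000, 1000, 0), c(1, 2, 3))
  g <- window_to_grayscale(v)
  expect_equal(g[1, 1, 1], 0)
  expect_equal(g[1, 2, 1], 1)
  expect_equal(g[1, 1, 2], 0.5)        # (-300 + 1000) / 1400
  expect_equal(g[1, 2, 2], 0)          # clipped below
  expect_equal(g[1, 1, 3], 1)          # clipped above
  # monotone non-decreasing in HU
  hu <- sort(runif(50, -1500, 800))
  expect_false(is.unsorted(window_to_grayscale(array(hu, c(50, 1, 1)))))
  expect_error(window_to_grayscale(array(c(NA, 1), c(2, 1, 1))), "non-finite")
  expect_error(window_to_grayscale(v, 400, -1000), "lo_hu")
})

test_that("parenchyma extraction recovers the phantom lung mask", {
  s <- memo("phantom64", generate_phantom(phantom_config(seed = 7)))
  mask <- segment_lung_parenchyma(s$ct)
  expect_gte(dice_coefficient(mask, s$lung_mask), 0.9)
})

test_that("parenchyma extraction ignores the bed slab", {
  a <- generate_phantom(phantom_config(volume_shape = c(48, 96, 96),
                                       seed = 11, include_bed = TRUE))
  b <- generate_phantom(phantom_config(volume_shape = c(48, 96, 96),
                                       seed = 11, include_bed = FALSE))
  expect_identical(unclass(segment_lung_parenchyma(a$ct)),
                   unclass(segment_lung_parenchyma(b$ct)))
})

test_that("an all-air volume yields an empty-parenchyma error", {
  ct <- ct_volume(array(-1000, c(8, 16, 16)), c(3, 1.5, 1.5))
  expect_error(segment_lung_parenchyma(ct), "empty parenchyma")
})

test_that("resampling follows the rounded shape formula", {
  ct <- ct_volume(array(rnorm(30 * 128 * 128), c(30, 128, 128)),
                  c(1.0, 0.7, 0.7))
  out <- resample_volume(ct)
  expect_equal(dim(out$values), c(10, 60, 60))   # round(shape * sp / target)
  expect_equal(out$spacing_mm, c(3, 1.5, 1.5))
  # identity when already on the target grid
  ct2 <- ct_volume(array(rnorm(16 * 32 * 32), c(16, 32, 32)), c(3, 1.5, 1.5))
  expect_identical(resample_volume(ct2)$values, ct2$values)
  # constant field stays constant under trilinear interpolation
  ct3 <- ct_volume(array(-77, c(20, 40, 40)), c(2, 1, 1))
  expect_true(all(resample_volume(ct3)$values == -77))
  expect_error(resample_volume(ct2, c(0, 1, 1)), "positive")
})

test_that("resampling preserves a mask's physical center of mass", {
  shape <- c(40, 60, 60); sp <- c(1, 0.8, 0.8)
  m <- array(0L, shape)
  ctr <- c(18, 31, 24)
  for (w in 1:shape[3]) for (h in 1:shape[2]) for (d in 1:shape[1]) {
    if (sum((((c(d, h, w)) - ctr) * sp)^2) <= 36) m[d, h, w] <- 1L
  }
  rm_ <- resample_mask(m, sp, c(3, 1.5, 1.5))
  com_src <- colMeans(which(m == 1, arr.ind = TRUE) - 1) * sp
  com_dst <- colMeans(which(unclass(rm_) == 1, arr.ind = TRUE) - 1) * c(3, 1.5, 1.5)
  expect_true(all(abs(com_src - com_dst) <= c(3, 1.5, 1.5)))
})

test_that("subcase splitting is exact for 96 slices and pads shorter cases", {
  ct <- ct_volume(array(rnorm(96 * 192 * 192), c(96, 192, 192)), c(3, 1.5, 1.5))
  r <- split_subcases(ct)
  expect_equal(dim(r$subcases[[1]]$values), c(48, 192, 192))
  expect_identical(abind_axial(r$subcases[[1]]$values, r$subcases[[2]]$values),
                   ct$values)

  ct2 <- ct_volume(array(0, c(90, 192, 192)), c(3, 1.5, 1.5))
  r2 <- split_subcases(ct2)
  for (half in 1:2) {
    v <- r2$subcases[[half]]$values
    expect_equal(dim(v), c(48, 192, 192))
    pad_slices <- sum(apply(v, 1, function(sl) all(sl == -1000)))
    expect_equal(pad_slices, 3)
  }
})

test_that("subcase coordinates round-trip to case coordinates", {
  ct <- ct_volume(array(0, c(80, 160, 200)), c(3, 1.5, 1.5))
  r <- split_subcases(ct)
  pts <- rbind(c(0, 0, 0), c(10, 100, 150), c(47, 191, 191))
  for (half in 1:2) {
    back <- case_to_subcase(subcase_to_case(pts, r$transform, half),
                            r$transform, half)
    expect_equal(back, pts, ignore_attr = TRUE)
  }
  # a voxel copied into the subcase carries its case value
  ct$values[41, 80, 100] <- 555    # case voxel (40, 79, 99), second half
  r <- split_subcases(ct)
  sub_coord <- case_to_subcase(matrix(c(40, 79, 99), 1), r$transform, 2)
  expect_equal(r$subcases[[2]]$values[sub_coord[1] + 1, sub_coord[2] + 1,
                                      sub_coord[3] + 1], 555)
})

test_that("ROI cropping is centered, padded and translation-equivariant", {
  ct <- ct_volume(array(rnorm(32 * 96 * 96), c(32, 96, 96)), c(3, 1.5, 1.5))
  comp <- array(0L, c(32, 96, 96)); comp[17, 49, 49] <- 1L
  roi <- crop_roi(ct, comp)
  expect_equal(dim(roi), c(16, 48, 48))
  expect_equal(roi[9, 25, 25], ct$values[17, 49, 49])   # centroid at the center

  # corner component: padding count equals the window overhang
  comp2 <- array(0L, c(32, 96, 96)); comp2[1, 1, 1] <- 1L
  roi2 <- crop_roi(ct, comp2)
  expect_equal(dim(roi2), c(16, 48, 48))
  inside <- 8 * 24 * 24                       # window clipped at the origin
  expect_equal(sum(roi2 == -1000), 16 * 48 * 48 - inside)

  # translating the component by (2, 4, 4) translates the window identically
  comp3 <- array(0L, c(32, 96, 96)); comp3[19, 53, 53] <- 1L
  roi3 <- crop_roi(ct, comp3)
  expect_equal(roi3[9, 25, 25], ct$values[19, 53, 53])
  expect_identical(roi3, ct$values[11:26, 29:76, 29:76])
  expect_identical(roi, ct$values[9:24, 25:72, 25:72])
  expect_error(crop_roi(ct, array(0L, c(32, 96, 96))), "empty")
})

test_that("consensus masks count distinct raters", {
  g <- c(4, 4, 4)
  mk <- function(idx) { a <- array(0L, g); a[idx] <- 1L; a }
  anns <- list(
    nodule_annotation(1, 1, mask = mk(1:10)),
    nodule_annotation(2, 2, mask = mk(1:8)),
    nodule_annotation(3, 1, mask = mk(c(1:6, 11:12))),
    nodule_annotation(4, 2, mask = mk(5:14)))
  cm3 <- consensus_mask(anns, 3)
  votes <- mk(1:10) + mk(1:8) + mk(c(1:6, 11:12)) + mk(5:14)
  expect_identical(unclass(cm3), array(as.integer(votes >= 3), g))
  expect_equal(unclass(consensus_mask(anns, 1)),
               array(as.integer(votes >= 1), g), ignore_attr = TRUE)
  # antitone in min_raters
  for (k in 1:3) {
    hi <- unclass(consensus_mask(anns, k + 1))
    lo <- unclass(consensus_mask(anns, k))
    expect_true(all(lo[hi == 1] == 1))
  }
  # a rater voting twice still counts once
  dup <- c(anns, list(nodule_annotation(4, 2, mask = mk(5:14))))
  expect_identical(unclass(consensus_mask(dup, 3)), unclass(cm3))
  bad <- list(nodule_annotation(1, 1, mask = mk(1:4)),
              nodule_annotation(2, 1, mask = array(0L, c(3, 3, 3))))
  expect_error(consensus_mask(bad), "different grids")
})

test_that("malignancy labels follow the median 1-2/4-5/3 rule", {
  expect_equal(malignancy_label(c(1, 2, 2, 1)), "benign")
  expect_equal(malignancy_label(c(5, 4, 4)), "malignant")
  expect_equal(malignancy_label(3), "excluded")
  expect_equal(malignancy_label(c(2, 3)), "benign")      # tie rounds down
  expect_equal(malignancy_label(c(3, 4)), "excluded")
  expect_error(malignancy_label(integer(0)), "empty")
  expect_error(malignancy_label(c(1, 6)), "1..5")
})

test_that("size bins are left-open right-closed at 5, 10 and 30 mm", {
  expect_equal(as.character(size_category(5)), "micro")
  expect_equal(as.character(size_category(10)), "small")
  expect_equal(as.character(size_category(10.1)), "nodule")
  expect_equal(as.character(size_category(30)), "nodule")
  expect_equal(as.character(size_category(35)), "mass")
  expect_error(size_category(0), "positive")
})
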