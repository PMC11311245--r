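test_that("default grid tiles a 2080 x 256 frame into 81 registered patches", {
  f <- toy_frame(2080, 256, seed = 7)
  p <- extract_patches(f, patch_grid())
  expect_identical(n_patches(p), 81L)
  expect_identical(sort(unique(p$info$zone)), 0:8)
  expect_identical(sort(unique(p$info$lateral_pos)), 0:8)
  expect_true(all(p$info$class_label == 1L))

  # first patch covers axial rows 541..740 (0-based [540, 740)), columns 1..26
  first <- p$data[, , which(p$info$zone == 0 & p$info$lateral_pos == 0)]
  expect_identical(first, f$samples[541:740, 1:26])

  # deepest zone covers rows 1341..1540, inside the frame
  last <- p$data[, , which(p$info$zone == 8 & p$info$lateral_pos == 8)]
  expect_identical(last, f$samples[1341:1540, 209:234])

  # every extracted value equals the frame value at its source index
  k <- which(p$info$zone == 4 & p$info$lateral_pos == 2)
  expect_identical(p$data[, , k], f$samples[941:1140, 53:78])
})

test_that("frames too small for the grid raise a geometry error", {
  f <- toy_frame(600, 256, seed = 1)
  expect_error(extract_patches(f, patch_grid()), "600")
  expect_error(extract_patches(toy_frame(2080, 100), patch_grid()), "too small")
})

test_that("z-score statistics follow the population convention elementwise", {
  d <- array(0, c(4, 3, 2))
  d[, , 1] <- 1; d[, , 2] <- 3
  p <- toy_patch_set(d, zone = c(0, 0), label = c(0, 1),
                     grid = patch_grid(patch_axial = 4, patch_lateral = 3))
  st <- compute_zscore_stats(p, "train")
  expect_equal(st$mean_patch, matrix(2, 4, 3))
  expect_equal(st$std_patch, matrix(1, 4, 3))     # population: sqrt(mean((x-2)^2))
  expect_identical(st$n_source_patches, 2L)

  # identical patches: std floored, normalization stays finite
  d2 <- array(5, c(4, 3, 3))
  st2 <- compute_zscore_stats(toy_patch_set(d2, zone = 0:2, label = c(0, 1, 0),
                                            grid = p$grid), "train")
  expect_true(all(st2$std_patch > 0))
  normed <- apply_zscore(toy_patch_set(d2, zone = 0:2, label = c(0, 1, 0),
                                       grid = p$grid), st2)
  expect_true(all(is.finite(normed$data)))

  # permutation invariance
  set.seed(1)
  d3 <- array(rnorm(4 * 3 * 10), c(4, 3, 10))
  p3 <- toy_patch_set(d3, zone = rep(0, 10), grid = p$grid)
  p3r <- toy_patch_set(d3[, , 10:1], zone = rep(0, 10), grid = p$grid)
  expect_equal(compute_zscore_stats(p3, "train")$std_patch,
               compute_zscore_stats(p3r, "train")$std_patch)

  expect_error(compute_zscore_stats(toy_patch_set(d[, , 1, drop = FALSE],
                                                  zone = 0, label = 0,
                                                  grid = p$grid), "train"),
               "at least 2")
})

test_that("z-score application normalizes, preserves labels, checks shapes", {
  set.seed(2)
  d <- array(rnorm(200 * 26 * 40, mean = 3, sd = 2), c(200, 26, 40))
  p <- toy_patch_set(d)
  st <- compute_zscore_stats(p, "train")
  pn <- apply_zscore(p, st)
  expect_lt(abs(mean(pn$data)), 1e-10)
  expect_equal(mean(rowMeans(pn$data^2, dims = 2L)), 1, tolerance = 1e-6)
  expect_identical(pn$info, p$info)

  # identity statistics leave the data untouched
  id <- st
  id$mean_patch[] <- 0; id$std_patch[] <- 1
  expect_identical(apply_zscore(p, id)$data, p$data)

  # normalizing a shifted set with foreign statistics leaves a nonzero mean
  shifted <- p
  shifted$data <- shifted$data + 1
  expect_gt(abs(mean(apply_zscore(shifted, st)$data)), 0.3)

  st_bad <- compute_zscore_stats(toy_patch_set(array(1:24, c(4, 3, 2)),
                                               zone = c(0, 0), label = c(0, 1),
                                               grid = patch_grid(patch_axial = 4,
                                                                 patch_lateral = 3)),
                                 "train")
  expect_error(apply_zscore(p, st_bad), "shape")
})

test_that("train/validation split is 4:1, stratified and reproducible", {
  set.seed(3)
  d <- array(rnorm(4 * 3 * 180), c(4, 3, 180))
  # 2 classes x 9 zones, 10 patches per cell
  zone <- rep(rep(0:8, each = 10), 2)
  label <- rep(c(0L, 1L), each = 90)
  p <- toy_patch_set(d, zone = zone, label = label,
                     grid = patch_grid(patch_axial = 4, patch_lateral = 3))
  sp <- split_train_val(p, seed = 9)
  expect_identical(n_patches(sp$train), 144L)
  expect_identical(n_patches(sp$val), 36L)
  # stratification: every (class, zone) cell splits 8/2
  tab <- table(sp$train$info$class_label, sp$train$info$zone)
  expect_true(all(tab == 8L))

  sp2 <- split_train_val(p, seed = 9)
  expect_identical(sp$train$info, sp2$train$info)
  expect_identical(sp$train$data, sp2$train$data)
  sp3 <- split_train_val(p, seed = 10)
  expect_false(identical(sp$train$data, sp3$train$data))

  expect_error(split_train_val(toy_patch_set(d[, , 1:3], zone = 0:2,
                                             label = c(0, 1, 0),
                                             grid = p$grid)),
               "at least 5")
})
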