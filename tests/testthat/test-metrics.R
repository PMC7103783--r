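test_that("box overlap follows the closed-form interval arithmetic", {
  g <- image_grid(c(20, 20, 20), 1)
  a <- bounding_box3d(c(2, 2, 2), c(7, 7, 7), g)
  expect_equal(iou_3d(a, a), 1)
  expect_equal(centroid_distance(a, a), 0)
  b <- bounding_box3d(c(10, 10, 10), c(14, 14, 14), g)
  expect_equal(iou_3d(a, b), 0)
  # unit cube against itself shifted by half an edge: IoU = 0.5 / 1.5
  u1 <- list(lower_mm = c(0, 0, 0), upper_mm = c(1, 1, 1))
  u2 <- list(lower_mm = c(0.5, 0, 0), upper_mm = c(1.5, 1, 1))
  expect_equal(iou_3d(u1, u2), 1 / 3)
  expect_equal(centroid_distance(u1, u2), 0.5)
})

test_that("mask overlap and Hausdorff distance match exhaustive oracles", {
  g <- image_grid(c(16, 16, 16), c(1, 1.5, 1))
  m1 <- array(0, c(16, 16, 16)); m1[3:8, 3:8, 3:8] <- 1
  a <- mask_volume(m1, g)
  expect_equal(dice_score(a, a), 1)
  expect_equal(hausdorff(a, a), 0)

  # two single voxels 3 mm apart (two-point geometry)
  p1 <- array(0, c(16, 16, 16)); p1[2, 2, 2] <- 1
  p2 <- array(0, c(16, 16, 16)); p2[2, 4, 2] <- 1   # axis-2 spacing 1.5 mm
  expect_equal(hausdorff(mask_volume(p1, g), mask_volume(p2, g)), 3)

  set.seed(50)
  r1 <- mask_volume(array(rbinom(4096, 1, 0.02), c(16, 16, 16)), g)
  r2 <- mask_volume(array(rbinom(4096, 1, 0.02), c(16, 16, 16)), g)
  w1 <- index_to_world(g, t(which(r1$values > 0.5, arr.ind = TRUE)) - 1)
  w2 <- index_to_world(g, t(which(r2$values > 0.5, arr.ind = TRUE)) - 1)
  dmat <- outer(seq_len(ncol(w1)), seq_len(ncol(w2)),
                Vectorize(function(i, j) sqrt(sum((w1[, i] - w2[, j])^2))))
  oracle <- max(max(apply(dmat, 1, min)), max(apply(dmat, 2, min)))
  expect_equal(hausdorff(r1, r2), oracle, tolerance = 1e-9)
  # symmetry
  expect_equal(hausdorff(r2, r1), hausdorff(r1, r2))
  expect_equal(dice_score(r2, r1), dice_score(r1, r2))

  empty <- mask_volume(array(0, c(16, 16, 16)), g)
  expect_error(dice_score(empty, empty), "undefined-metric")
  expect_error(hausdorff(empty, empty), "undefined-metric")
})

test_that("the slice similarity suite matches per-formula oracles", {
  set.seed(51)
  y <- matrix(runif(16, 1, 3), 4)
  suite_self <- similarity_suite(y, y)
  expect_equal(unname(suite_self["NCC"]), 1)
  expect_equal(unname(suite_self["RMSE"]), 0)
  expect_equal(unname(suite_self["MAE"]), 0)
  expect_equal(unname(suite_self["SSIM"]), 1)
  expect_equal(unname(suite_self["PSNR"]), 100)  # documented cap

  shifted <- similarity_suite(y, y + 0.7)
  expect_equal(unname(shifted["NCC"]), 1, tolerance = 1e-12)
  expect_equal(unname(shifted["RMSE"]), 0.7, tolerance = 1e-12)
  expect_equal(unname(shifted["MAE"]), 0.7, tolerance = 1e-12)

  # worked 4x4 pair against independent scalar formulas
  ys <- matrix(runif(16, 0, 2), 4)
  s <- similarity_suite(y, ys)
  a <- as.numeric(y); b <- as.numeric(ys)
  expect_equal(unname(s["NCC"]),
               sum((a - mean(a)) * (b - mean(b))) /
                 sqrt(sum((a - mean(a))^2) * sum((b - mean(b))^2)),
               tolerance = 1e-9)
  expect_equal(unname(s["RMSE"]), sqrt(mean((a - b)^2)), tolerance = 1e-9)
  expect_equal(unname(s["MAE"]), mean(abs(a - b)), tolerance = 1e-9)
  expect_equal(unname(s["PSNR"]),
               10 * log10(diff(range(a))^2 / mean((a - b)^2)), tolerance = 1e-9)
  expect_equal(unname(s["NMI"]), nmi(a, b), tolerance = 1e-12)

  # degenerate comparisons flag undefined entries
  flat <- similarity_suite(matrix(1, 4, 4), ys)
  expect_true(all(c("NCC", "PSNR") %in% attr(flat, "undefined")))
})
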