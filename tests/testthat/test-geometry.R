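test_that("voxel-world mapping round-trips and validates its inputs", {
  set.seed(1)
  g <- image_grid(c(8, 10, 12), spacing = c(1, 1.2, 0.9), origin = c(-3, 2, 1),
                  direction = rigid_from_params(c(12, -7, 31, 0, 0, 0))$rotation)
  p <- matrix(runif(30, 0, 7), 3)
  expect_lt(max(abs(world_to_index(g, index_to_world(g, p)) - p)), 1e-9)

  expect_error(image_grid(c(8, 8, 8), spacing = c(1, 0, 1)), "invalid-geometry")
  expect_error(image_grid(c(8, 8, 8), direction = matrix(1, 3, 3)),
               "invalid-geometry")
  flip <- diag(3); flip[1, 1] <- -1
  expect_error(image_grid(c(8, 8, 8), direction = flip), "invalid-geometry")
})

test_that("rigid transforms compose, invert and round-trip their parameters", {
  a <- rigid_from_params(c(10, -5, 30, 1, 2, 3))
  b <- rigid_from_params(c(-3, 8, 12, -1, 0, 2))

  # composition against the 4x4 homogeneous matrix product oracle
  set.seed(2)
  pts <- matrix(rnorm(300), 3)
  oracle <- (hom4(a) %*% hom4(b) %*% rbind(pts, 1))[1:3, ]
  expect_lt(max(abs(apply_transform(rigid_compose(a, b), pts) - oracle)), 1e-9)

  expect_lt(max(abs(hom4(rigid_compose(a, rigid_invert(a))) - diag(4))), 1e-9)
  expect_lt(max(abs(hom4(rigid_compose(a, rigid_transform())) - hom4(a))), 1e-12)

  p <- c(10, -5, 30, 1, 2, 3)
  expect_lt(max(abs(rigid_params(rigid_from_params(p)) - p)), 1e-9)

  # rigid maps preserve pairwise distances
  q <- apply_transform(a, pts)
  expect_lt(max(abs(dist(t(q)) - dist(t(pts)))), 1e-9)
})

test_that("resampling is exact on identity and matches the shift oracle", {
  set.seed(3)
  g <- image_grid(c(8, 8, 8), spacing = 1)
  v <- volume3d(array(runif(512), c(8, 8, 8)), g)
  expect_identical(resample(v, g, interpolation = "nearest")$values, v$values)
  expect_lt(max(abs(resample(v, g, interpolation = "linear")$values - v$values)),
            1e-12)

  # constant volume stays constant under an interior transform
  cv <- volume3d(array(4.2, c(8, 8, 8)), g)
  r <- resample(cv, image_grid(c(4, 4, 4), 1, origin = c(2, 2, 2)),
                rigid_from_params(c(3, 2, -4, 0.3, -0.2, 0.1), center = c(3.5, 3.5, 3.5)))
  expect_lt(max(abs(r$values - 4.2)), 1e-9)

  # one-voxel translation, nearest: array-roll oracle
  tr <- rigid_transform(diag(3), c(1, 0, 0))
  shifted <- resample(v, g, tr, "nearest")$values
  oracle <- v$values[c(2:8, 8), , ]
  oracle[8, , ] <- 0
  expect_identical(shifted, oracle)

  # cubic interpolation reproduces the volume at grid points
  expect_lt(max(abs(resample(v, g, interpolation = "bspline")$values[3:6, 3:6, 3:6] -
                      v$values[3:6, 3:6, 3:6])), 1e-9)
})

test_that("slices and stacks validate their structure", {
  tr <- rigid_transform()
  expect_error(slice2d(matrix(0, 4, 4), 1, 2, tr, mask = matrix(1, 3, 3)),
               "invalid-geometry")
  expect_error(slice2d(matrix(0, 4, 4), -1, 2, tr), "invalid-geometry")
  s0 <- slice2d(matrix(0, 4, 4), 1, 2, tr, slice_index = 0L)
  s2 <- slice2d(matrix(0, 4, 4), 1, 2, tr, slice_index = 2L)
  expect_error(slice_stack(list(s0, s2)), "invalid-geometry")
  st <- slice_stack(list(s0, slice2d(matrix(1, 4, 4), 1, 2, tr, slice_index = 1L)))
  expect_length(st$slices, 2)
  vol <- stack_to_volume(st)
  expect_equal(dim(vol$values), c(4L, 4L, 2L))
  expect_equal(vol$values[, , 2], matrix(1, 4, 4))
})
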