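test_that("the Dice loss matches its closed form", {
  A <- matrix(c(1, 1, 0, 0), 2)
  B <- matrix(c(0, 0, 1, 1), 2)
  expect_equal(dice_loss(A, A), 0)
  expect_equal(dice_loss(A, B), 1, tolerance = 1e-6)
  # hand-expanded: Y=(0.5,0.5), G=(1,0): 1 - 2*0.5/(0.5+1) = 1/3
  expect_equal(dice_loss(c(0.5, 0.5), c(1, 0)), 1 / 3, tolerance = 1e-6)
  expect_error(dice_loss(matrix(0, 2, 2), matrix(0, 3, 3)), "invalid-input")
})

test_that("average pooling halves resolution and conserves mass", {
  expect_equal(downscale(matrix(c(0, 0, 1, 1), 2)), matrix(0.5, 1, 1))
  cm <- matrix(0.3, 6, 8)
  expect_equal(downscale(cm), matrix(0.3, 3, 4))

  # 4x4 ramp against the explicit block-mean oracle
  r <- matrix(1:16, 4)
  oracle <- matrix(0, 2, 2)
  for (i in 1:2) for (j in 1:2)
    oracle[i, j] <- mean(r[(2 * i - 1):(2 * i), (2 * j - 1):(2 * j)])
  expect_lt(max(abs(downscale(r) - oracle)), 1e-12)

  # mass conservation for even shapes
  set.seed(27)
  y <- matrix(runif(64 * 64), 64)
  expect_equal(4 * sum(downscale(y)), sum(y), tolerance = 1e-9)

  expect_error(downscale(matrix(1, 1, 1)), "cannot-downscale")
})

test_that("the multi-scale loss averages per-scale Dice losses", {
  set.seed(28)
  Y <- matrix(runif(32 * 32), 32)
  G <- (matrix(runif(32 * 32), 32) > 0.6) * 1

  expect_equal(multiscale_loss(Y, G, multiscale_loss_spec(1)), dice_loss(Y, G))

  # per-scale oracle at S = 4
  ys <- Y; gs <- G; acc <- 0
  for (s in 1:4) {
    acc <- acc + dice_loss(ys, gs)
    if (s < 4) {
      blockmean <- function(m) {
        out <- matrix(0, nrow(m) / 2, ncol(m) / 2)
        for (i in seq_len(nrow(out))) for (j in seq_len(ncol(out)))
          out[i, j] <- mean(m[(2 * i - 1):(2 * i), (2 * j - 1):(2 * j)])
        out
      }
      ys <- blockmean(ys); gs <- blockmean(gs)
    }
  }
  expect_lt(abs(multiscale_loss(Y, G, multiscale_loss_spec(4)) - acc / 4), 1e-10)

  # perfect binary predictions give zero at every scale count
  for (S in 1:4)
    expect_equal(multiscale_loss(G, G, multiscale_loss_spec(S)), 0)

  # symmetric in (Y, G), bounded in [0, 1]
  L <- multiscale_loss(Y, G, multiscale_loss_spec(3))
  expect_equal(L, multiscale_loss(G, Y, multiscale_loss_spec(3)))
  expect_gte(L, 0); expect_lte(L, 1)

  expect_error(multiscale_loss(matrix(1, 4, 4), matrix(1, 4, 4),
                               multiscale_loss_spec(4)), "invalid-scale-count")
})

test_that("coarse maps become bounding boxes with an exact world margin", {
  g <- image_grid(c(32, 32, 24), 1)
  prob <- array(0, c(32, 32, 24))
  prob[10:19, 8:17, 8:17] <- 1  # solid 10^3 blob, >= 5 voxels from every face
  bb <- coarse_to_bbox(prob, g, threshold = 0.5, margin = 5)
  # 5 mm margin at 1 mm spacing = 5 voxels per face (0-based indices)
  expect_equal(bb$lower_vox, c(9, 7, 7) - 5)
  expect_equal(bb$upper_vox, c(18, 16, 16) + 5)

  # a blob against the face clips to the image extent
  edge <- array(0, c(32, 32, 24))
  edge[10:19, 8:17, 2:6] <- 1
  bbe <- coarse_to_bbox(edge, g, threshold = 0.5, margin = 5)
  expect_equal(bbe$lower_vox[3], 0)

  # speckles are removed by the largest-component step; verified against the
  # brute-force flood-fill labelling oracle
  spk <- prob
  set.seed(29)
  pts <- cbind(sample(1:32, 8), sample(1:32, 8),
               sample(c(1:3, 21:24), 8, replace = TRUE))
  spk[pts] <- 1
  morph <- fetalsrr:::opening3d(fetalsrr:::closing3d((spk >= 0.5) * 1))
  lab_oracle <- r_label26(morph)
  counts <- table(lab_oracle[lab_oracle > 0])
  biggest <- as.integer(names(counts)[which.max(counts)])
  keep_oracle <- (lab_oracle == biggest) * 1
  expect_identical(largest_component(morph), keep_oracle * 1)
  bb2 <- coarse_to_bbox(spk, g, threshold = 0.5, margin = 5)
  expect_equal(bb2$lower_vox, bb$lower_vox)
  expect_equal(bb2$upper_vox, bb$upper_vox)

  # idempotent on its own output region
  again <- array(0, dim(prob))
  again[(bb$lower_vox[1] + 6):(bb$upper_vox[1] - 4),
        (bb$lower_vox[2] + 6):(bb$upper_vox[2] - 4),
        (bb$lower_vox[3] + 6):(bb$upper_vox[3] - 4)] <- 1
  expect_equal(coarse_to_bbox(again, g, margin = 5)$lower_vox, bb$lower_vox)

  expect_error(coarse_to_bbox(array(0, c(8, 8, 8)), image_grid(c(8, 8, 8), 1)),
               "no-detection")
})

test_that("bounding-box mapping respects anisotropic downsampled grids", {
  # blob detected on a coarse grid maps back into the fine grid through world
  # coordinates, including the margin
  fine <- image_grid(c(96, 96, 10), c(1, 1, 4))
  coarse <- image_grid(c(48, 48, 10), c(2, 2, 4), origin = c(0.5, 0.5, 0))
  prob <- array(0, c(48, 48, 10))
  prob[12:20, 15:25, 3:6] <- 1
  bb <- coarse_to_bbox(prob, coarse, margin = 5, target_grid = fine)
  expect_true(all(bb$lower_vox >= 0) && all(bb$upper_vox <= c(95, 95, 9)))
  # world extent includes the blob's world extent plus the margin
  blob_lo <- index_to_world(coarse, c(11, 14, 2))
  expect_lte(bb$lower_mm[1], blob_lo[1] - 5 + 1e-9)
})

test_that("localization input preparation normalizes and records scaling", {
  ph <- make_phantom(phantom_spec(shape = c(96, 96, 6), spacing = c(1, 1, 4),
                                  seed = 30))
  st <- volume_to_stack(ph$volume, stack_id = "t")
  li <- prepare_locnet_input(st, size = 96)
  expect_equal(dim(li$volume$values), c(96L, 96L, 6L))
  expect_lt(abs(mean(li$volume$values)), 1e-6)
  expect_equal(sd(li$volume$values), 1, tolerance = 1e-6)
  expect_equal(li$scale, c(1, 1))

  # downsampling by two stays consistent with plain linear resampling
  ph2 <- make_phantom(phantom_spec(shape = c(192, 192, 4), spacing = c(0.5, 0.5, 4),
                                   seed = 30))
  st2 <- volume_to_stack(ph2$volume, stack_id = "t2")
  li2 <- prepare_locnet_input(st2, size = 96)
  expect_equal(dim(li2$volume$values)[1:2], c(96L, 96L))
  ref <- resample(ph2$volume, li2$grid, interpolation = "linear")
  zref <- (ref$values - mean(ref$values)) / sd(ref$values)
  expect_lt(max(abs(li2$volume$values - zref)), 0.01 * diff(range(zref)))

  const <- volume_to_stack(volume3d(array(1, c(16, 16, 4)),
                                    image_grid(c(16, 16, 4), c(1, 1, 4))),
                           stack_id = "c")
  expect_warning(lc <- prepare_locnet_input(const, size = 16), "degenerate")
  expect_equal(max(abs(lc$volume$values)), 0)
})
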