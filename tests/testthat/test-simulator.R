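test_that("phantoms are deterministic, connected and elongated", {
  a <- make_phantom(phantom_spec(shape = c(32, 32, 32), spacing = 1.5, seed = 40))
  b <- make_phantom(phantom_spec(shape = c(32, 32, 32), spacing = 1.5, seed = 40))
  expect_identical(a$volume$values, b$volume$values)
  expect_identical(a$mask$values, b$mask$values)
  expect_gte(min(a$volume$values), 0)
  expect_lte(max(a$volume$values), 1)

  lab <- largest_component(a$mask$values)
  expect_equal(sum(lab), sum(a$mask$values))  # a single 26-connected component

  pc <- fetalsrr:::mask_pca(a$mask)
  expect_gte(pc$values[1] / pc$values[2], 1.2)
  expect_gte(pc$values[2] / pc$values[3], 1.2)

  c_ <- make_phantom(phantom_spec(shape = c(32, 32, 32), spacing = 1.5, seed = 41))
  expect_gt(max(abs(a$volume$values - c_$volume$values)), 0.05)
})

test_that("a motion- and artifact-free acquisition equals the forward model", {
  ph <- make_phantom(phantom_spec(shape = c(24, 24, 24), spacing = 2, seed = 42))
  sim <- simulate_acquisition(ph$volume, ph$mask, in_plane_spacing = 2,
                              thickness = 4,
                              motion = motion_spec(max_rotation = 0,
                                                   max_translation = 0,
                                                   step_rotation = 0,
                                                   step_translation = 0, seed = 1),
                              artifacts = artifact_spec(outlier_fraction = 0),
                              noise_sd = 0,
                              intensity_scale = rep(list(c(1, 0)), 3))
  psf <- sim$psf
  for (st in sim$stacks[1:2]) {
    sl <- st$slices[[ceiling(length(st$slices) / 2)]]
    expect_lt(max(abs(sl$pixels - forward_project(ph$volume, sl, psf))), 1e-12)
  }
})

test_that("motion respects its declared bounds and seeds reproduce exactly", {
  ph <- make_phantom(phantom_spec(shape = c(24, 24, 24), spacing = 2, seed = 42))
  run <- function(seed) simulate_acquisition(
    ph$volume, ph$mask, in_plane_spacing = 2, thickness = 4,
    motion = motion_spec(seed = seed),
    artifacts = artifact_spec(outlier_fraction = 0.1, seed = 9), noise_sd = 0.02)
  s1 <- run(3); s2 <- run(3); s3 <- run(4)
  expect_identical(s1$truth$params, s2$truth$params)
  expect_identical(s1$stacks[[1]]$slices[[3]]$pixels,
                   s2$stacks[[1]]$slices[[3]]$pixels)
  expect_gt(max(abs(s1$truth$params$rx - s3$truth$params$rx)), 0.1)

  tp <- s1$truth$params
  expect_lte(max(abs(as.matrix(tp[, c("rx", "ry", "rz")]))), 5)
  expect_lte(max(abs(as.matrix(tp[, c("tx", "ty", "tz")]))), 3)
  # outlier labels are the realized Bernoulli draw, reproducibly
  expect_identical(s1$truth$params$outlier, s2$truth$params$outlier)
})

test_that("corrupted slices fall below the final inlier threshold", {
  sim <- study_sim_art()
  clean <- study_sim_clean()
  tp <- sim$truth$params
  checked <- 0
  for (r in which(tp$outlier)) {
    oi <- match(tp$stack_id[r],
                vapply(sim$stacks, function(s) s$slices[[1]]$stack_id, character(1)))
    k <- tp$slice_index[r] + 1
    a <- sim$stacks[[oi]]$slices[[k]]
    b <- clean$stacks[[oi]]$slices[[k]]
    if (sum(a$mask) < 10) next
    checked <- checked + 1
    # a fully zeroed (degenerate) corrupted region counts as maximally corrupt
    v <- tryCatch(slice_similarity(a$pixels, b$pixels, a$mask),
                  error = function(e) -1)
    expect_lt(v, 0.8)
  }
  expect_gte(checked, 1)
})

test_that("simulations serialize to NIfTI stacks plus a ground-truth record", {
  ph <- make_phantom(phantom_spec(shape = c(16, 16, 16), spacing = 2, seed = 43))
  sim <- simulate_acquisition(ph$volume, ph$mask, in_plane_spacing = 2,
                              thickness = 4, motion = motion_spec(seed = 2),
                              artifacts = artifact_spec(outlier_fraction = 0.2,
                                                        seed = 3))
  d <- file.path(tempdir(), "sim-out")
  write_simulation(sim, d)
  files <- list.files(d)
  expect_true("ground_truth.json" %in% files)
  expect_length(grep("_mask\\.nii$", files), 3)
  gt <- jsonlite::read_json(file.path(d, "ground_truth.json"),
                            simplifyVector = TRUE)
  expect_equal(nrow(gt$params), nrow(sim$truth$params))
  # the written stack re-reads with the slice axis on the largest spacing
  st <- read_stack(file.path(d, paste0(sim$stacks[[1]]$slices[[1]]$stack_id, ".nii")))
  expect_equal(st$slices[[1]]$thickness, 4)
})
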