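test_that("the gradient operator differentiates exactly and is self-adjoint", {
  g <- image_grid(c(8, 8, 8), spacing = c(1, 2, 0.5))
  ramp <- volume3d(array(rep(0:7, 64) * 1.0, c(8, 8, 8)), g)
  gr <- gradient_op(ramp)
  expect_lt(max(abs(gr[[1]][1:7, , ] - 1)), 1e-12)  # slope 1 / spacing 1
  expect_equal(gr[[1]][8, , ], matrix(0, 8, 8))
  expect_lt(max(abs(gr[[2]])), 1e-12)

  cv <- volume3d(array(5, c(8, 8, 8)), g)
  expect_lt(max(abs(unlist(gradient_op(cv)))), 1e-12)

  set.seed(14)
  x <- volume3d(array(rnorm(512), c(8, 8, 8)), g)
  h <- lapply(1:3, function(i) array(rnorm(512), c(8, 8, 8)))
  lhs <- sum(mapply(function(a, b) sum(a * b), gradient_op(x), h))
  rhs <- sum(x$values * adjoint_gradient_op(h, g)$values)
  expect_lt(abs(lhs - rhs), 1e-10)
})

test_that("solve_srr solves consistent systems and clips negatives once", {
  ph <- make_phantom(phantom_spec(shape = c(10, 10, 10), spacing = 1, seed = 3))
  g <- ph$volume$grid
  psf <- make_psf(1, 1)
  sls <- mk_slices(ph$volume, in_plane = 1, thickness = 1, step = 1,
                   npx = 12, K = 12, psf = psf)
  # shift the slice plane so pixels cover the volume symmetrically
  xh <- solve_srr(sls, g, psf = psf, alpha = 0, lsq_max_iter = 300,
                  lsq_tol = 1e-12)
  rel <- sqrt(sum((xh$values - ph$volume$values)^2)) /
    sqrt(sum(ph$volume$values^2))
  expect_lt(rel, 1e-3)
  expect_gte(min(xh$values), 0)

  zero <- lapply(sls[1:6], function(s) { s$pixels[] <- 0; s })
  xz <- solve_srr(zero, g, psf = psf, alpha = 0, lsq_max_iter = 20)
  expect_equal(max(abs(xz$values)), 0)

  expect_error(solve_srr(list(), g, psf = psf), "no-inliers")

  sol <- attr(xh, "solver")
  expect_true(all(diff(sol$rnorms) <= 1e-10))
  expect_true(all(diff(sol$objective) <= 1e-10))
})

test_that("stronger regularization monotonically smooths the estimate", {
  ph <- make_phantom(phantom_spec(shape = c(10, 10, 10), spacing = 1, seed = 3))
  g <- ph$volume$grid
  psf <- make_psf(1, 1.5)
  set.seed(15)
  sls <- lapply(mk_slices(ph$volume, in_plane = 1, thickness = 1.5, step = 1,
                          npx = 12, K = 12, psf = psf),
                function(s) { s$pixels <- s$pixels + matrix(rnorm(144, 0, 0.05), 12); s })
  gn <- vapply(c(0.01, 0.1, 1, 10), function(a) {
    xa <- solve_srr(sls, g, psf = psf, alpha = a, lsq_max_iter = 120,
                    lsq_tol = 1e-10)
    sqrt(sum(unlist(gradient_op(xa))^2))
  }, numeric(1))
  expect_true(all(diff(gn) <= 0))
})

test_that("slice similarity is masked NCC with its degenerate cases flagged", {
  set.seed(16)
  y <- matrix(runif(36), 6)
  m <- matrix(1, 6, 6)
  expect_equal(slice_similarity(y, y, m), 1, tolerance = 1e-12)
  expect_equal(slice_similarity(y, -y + 3, m), -1, tolerance = 1e-12)

  # hand oracle: y = (1,2,3), y_sim = (2,2,5)
  a <- c(1, 2, 3) - 2
  b <- c(2, 2, 5) - 3
  oracle <- sum(a * b) / sqrt(sum(a^2) * sum(b^2))
  y3 <- matrix(c(1, 2, 3, 9, 9, 9), 3)
  s3 <- matrix(c(2, 2, 5, 9, 9, 9), 3)
  m3 <- matrix(c(1, 1, 1, 0, 0, 0), 3)
  expect_equal(slice_similarity(y3, s3, m3), oracle, tolerance = 1e-12)

  expect_error(slice_similarity(y, y, matrix(0, 6, 6)), "undefined-similarity")
  expect_error(slice_similarity(matrix(1, 6, 6), y, m), "undefined-similarity")
})

test_that("inlier selection applies the threshold to masked projections", {
  ph <- make_phantom(phantom_spec(shape = c(16, 16, 16), spacing = 2, seed = 17))
  psf <- make_psf(2, 4)
  sls <- mk_slices(ph$volume, in_plane = 2, thickness = 4, step = 4, psf = psf)
  sls <- lapply(sls, function(sl) {
    sl$mask <- (forward_project(volume3d(ph$mask$values, ph$mask$grid), sl, psf) >= 0.5) * 1
    sl
  })
  sls <- Filter(function(s) sum(s$mask) > 4, sls)
  # corrupt one slice beyond recognition (pixel shuffle kills correlation)
  set.seed(18)
  sls[[2]]$pixels[] <- sample(sls[[2]]$pixels)
  mask_hr <- ph$mask
  inl <- select_inliers(sls, ph$volume, mask_hr, psf, beta = 0.8)
  expect_false(inl$table$member[2])
  expect_true(all(inl$table$member[-2]))

  # a vacuous threshold admits every evaluable slice
  inl_all <- select_inliers(sls, ph$volume, mask_hr, psf, beta = -0.999)
  expect_true(all(inl_all$table$member))

  # thresholding is exactly >= beta on the recorded similarities
  b2 <- 0.9
  inl2 <- select_inliers(sls, ph$volume, mask_hr, psf, beta = b2)
  expect_identical(inl2$table$member,
                   !is.na(inl2$table$similarity) & inl2$table$similarity >= b2)
})
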