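test_that("the PSF follows the FWHM conversion and scales quadratically", {
  # closed form: sigma_through = thickness / (2 sqrt(2 ln 2)); for 3 mm
  # slices this is 1.27398... (half-maximum of the Gaussian sits at 1.5 mm)
  psf <- make_psf(1.0, 3.0)
  s_th <- sqrt(psf$covariance[3, 3])
  expect_equal(s_th, 3 / (2 * sqrt(2 * log(2))), tolerance = 1e-12)
  expect_equal(s_th, 1.27398, tolerance = 1e-5)
  g <- function(x) exp(-0.5 * (x / s_th)^2)
  expect_equal(g(1.5), 0.5, tolerance = 1e-12)  # FWHM/2 numerically

  p1 <- make_psf(1, 1)
  expect_equal(p1$covariance[1, 1], p1$covariance[2, 2])
  p2 <- make_psf(2, 2)
  expect_equal(p2$covariance, 4 * p1$covariance)

  expect_error(make_psf(0, 1), "invalid-geometry")
  expect_error(psf_spec(matrix(c(1, 2, 0, 0, 1, 0, 0, 0, 1), 3)),
               "invalid-geometry")
})

test_that("discrete kernel weights are non-negative and sum to one", {
  g <- image_grid(c(12, 12, 12), 1, origin = c(-5.5, -5.5, -5.5))
  geom <- slice_geometry(c(5, 5), 1.5, 2.5,
                         rigid_from_params(c(20, -10, 5, -3, -3, 0)))
  k <- psf_discrete_kernel(g, geom, make_psf(1.5, 2.5), pixel = c(2, 2))
  expect_true(all(k >= 0))
  expect_equal(sum(k), 1, tolerance = 1e-9)
})

test_that("forward projection preserves constants and is linear", {
  g <- image_grid(c(10, 10, 10), 1, origin = c(-4.5, -4.5, -4.5))
  psf <- make_psf(1, 2)
  geom <- slice_geometry(c(5, 5), 1, 2, rigid_transform(diag(3), c(-2, -2, 0.5)))

  cv <- volume3d(array(2.5, c(10, 10, 10)), g)
  expect_lt(max(abs(forward_project(cv, geom, psf) - 2.5)), 1e-6)

  expect_equal(forward_project(volume3d(array(0, c(10, 10, 10)), g), geom, psf),
               matrix(0, 5, 5))

  set.seed(4)
  x1 <- volume3d(array(runif(1000), c(10, 10, 10)), g)
  x2 <- volume3d(array(runif(1000), c(10, 10, 10)), g)
  lin <- forward_project(volume3d(3 * x1$values + x2$values, g), geom, psf)
  sep <- 3 * forward_project(x1, geom, psf) + forward_project(x2, geom, psf)
  expect_lt(max(abs(lin - sep)) / max(abs(sep)), 1e-9)

  far <- slice_geometry(c(4, 4), 1, 2, rigid_transform(diag(3), c(100, 100, 100)))
  expect_error(forward_project(x1, far, psf), "empty-projection")
})

test_that("projector matches the dense brute-force matrix on an 8^3 instance", {
  g <- image_grid(c(8, 8, 8), 1, origin = c(-3.5, -3.5, -3.5))
  psf <- make_psf(1.5, 2.0)
  geom <- slice_geometry(c(6, 6), 1.5, 2.0,
                         rigid_from_params(c(15, -10, 5, -3.5, -3.5, 0.7)))
  A <- r_dense_A(geom, psf, g)

  set.seed(5)
  xv <- runif(512)
  fwd <- as.numeric(forward_project(volume3d(array(xv, c(8, 8, 8)), g), geom, psf))
  expect_lt(max(abs(fwd - drop(A %*% xv))), 1e-10)

  y <- matrix(runif(36), 6)
  adj <- as.numeric(adjoint_project(y, geom, psf, g)$values)
  expect_lt(max(abs(adj - drop(t(A) %*% as.numeric(y)))), 1e-10)
})

test_that("forward and adjoint are exact adjoints across random geometries", {
  set.seed(6)
  g <- image_grid(c(8, 9, 7), spacing = c(1, 1.1, 1.3), origin = c(-4, -4, -4))
  worst <- 0
  for (i in 1:20) {
    geom <- slice_geometry(c(6, 5), runif(1, 0.8, 2), runif(1, 1.5, 3),
                           rigid_from_params(c(runif(3, -25, 25), runif(3, -3, 3))))
    psf <- make_psf(geom$in_plane_spacing, geom$thickness)
    x <- volume3d(array(runif(prod(g$shape)), g$shape), g)
    y <- matrix(runif(30), 6, 5)
    Ax <- tryCatch(forward_project(x, geom, psf), error = function(e) NULL)
    if (is.null(Ax)) next
    Aty <- adjoint_project(y, geom, psf, g)
    gap <- abs(sum(Ax * y) - sum(x$values * Aty$values)) /
      (sqrt(sum(Ax^2)) * sqrt(sum(y^2)))
    worst <- max(worst, gap)
  }
  expect_lt(worst, 1e-10)
})

test_that("projection commutes with a joint rotation of volume and slice", {
  # a smooth phantom projected through a rotated geometry equals the
  # projection of the correspondingly rotated volume (up to interpolation)
  ph <- make_phantom(phantom_spec(shape = c(32, 32, 32), spacing = 1.5, seed = 9))
  psf <- make_psf(1.5, 3)
  R <- rigid_from_params(c(0, 0, 25, 0, 0, 0))
  geom0 <- slice_geometry(c(16, 16), 1.5, 3,
                          rigid_transform(diag(3), c(-11, -11, 1)))
  geom1 <- geom0
  geom1$transform <- rigid_compose(R, geom0$transform)
  rotated <- resample(ph$volume, ph$volume$grid, transform = R)
  p_rot_geom <- forward_project(ph$volume, geom1, psf)
  p_rot_vol <- forward_project(rotated, geom0, psf)
  keep <- abs(p_rot_geom) > 0.05 & abs(p_rot_vol) > 0.05
  expect_gt(sum(keep), 50)
  expect_lt(mean(abs(p_rot_geom[keep] - p_rot_vol[keep])), 0.03)
})
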