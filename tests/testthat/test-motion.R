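test_that("target-stack selection follows the 70%-of-median-volume rule", {
  mk <- function(nmask, id) {
    sls <- lapply(0:1, function(k) {
      m <- matrix(0, 10, 10)
      if (nmask > 0) m[seq_len(nmask)] <- 1
      slice2d(matrix(1, 10, 10), 1, 1, rigid_transform(diag(3), c(0, 0, k)),
              mask = m, slice_index = k, stack_id = id)
    })
    slice_stack(sls)
  }
  # volumes proportional to {50, 70, 100}; 70% of median 70 is 49 -> pick 50
  sel <- select_target_stack(list(mk(25, "a"), mk(35, "b"), mk(50, "c")))
  expect_equal(as.character(sel), "a")
  expect_equal(unname(attr(sel, "volumes")), c(50, 70, 100))

  expect_equal(as.character(select_target_stack(list(mk(10, "only")))), "only")

  # exact tie: lower stack index wins
  tie <- select_target_stack(list(mk(20, "x"), mk(20, "y")))
  expect_equal(as.character(tie), "x")

  expect_error(select_target_stack(list(mk(0, "e1"), mk(0, "e2"))),
               "no-brain-found")
})

test_that("intensity correction fits the linear map to the target stack", {
  ph <- make_phantom(phantom_spec(shape = c(24, 24, 24), spacing = 1.5, seed = 23))
  psf <- make_psf(1.5, 3)
  sls <- mk_slices(ph$volume, in_plane = 1.5, thickness = 3, step = 3, psf = psf)
  sls <- lapply(sls, function(sl) {
    sl$mask <- (forward_project(volume3d(ph$mask$values, ph$mask$grid), sl, psf) >= 0.5) * 1
    sl
  })
  ids <- vapply(sls, `[[`, character(1), "stack_id")
  target <- slice_stack(sls[ids == "axial"])

  # a stack already equal to the target on the overlap: identity regression
  same <- slice_stack(lapply(sls[ids == "axial"], function(s) {
    s$stack_id <- "copy"; s
  }))
  co <- attr(intensity_correct(same, target), "coefficients")
  expect_equal(unname(co["a"]), 1, tolerance = 1e-6)
  expect_lt(abs(co["b"]), 1e-6)

  # stack = (target - 5) / 2 on the overlap -> corrected by (a, b) = (2, 5)
  dist <- slice_stack(lapply(sls[ids == "axial"], function(s) {
    s$pixels <- (s$pixels - 5) / 2
    s$stack_id <- "dist"
    s
  }))
  fixed <- intensity_correct(dist, target)
  co2 <- attr(fixed, "coefficients")
  expect_equal(unname(co2["a"]), 2, tolerance = 1e-6)
  expect_equal(unname(co2["b"]), 5, tolerance = 1e-5)
  # and the corrected pixels now match the target's
  expect_lt(max(abs(fixed$slices[[3]]$pixels - target$slices[[3]]$pixels)),
            1e-6)

  # a cross-orientation stack of the same anatomy: near-identity regression
  cross <- slice_stack(sls[ids == "coronal"])
  co3 <- attr(intensity_correct(cross, target), "coefficients")
  expect_equal(unname(co3["a"]), 1, tolerance = 0.2)

  far <- slice_stack(lapply(sls[ids == "sagittal"], function(s) {
    s$transform$translation <- s$transform$translation + 500
    s
  }))
  expect_warning(out <- intensity_correct(far, target), "no-overlap")
  expect_equal(attr(out, "coefficients"), c(a = 1, b = 0))
})

test_that("zero cycles return the scattered-data initialization unchanged", {
  sim <- study_sim_clean()
  cfg <- srr_config(recon_spacing = 2, n_cycles = 0, beta_schedule = numeric(0),
                    v2v_levels = c(2, 1))
  fit <- srr_reconstruct(sim$stacks, cfg)
  expect_length(fit$inlier_history, 0)
  expect_identical(fit$volume$values, fit$sda_init$values)
  expect_s3_class(fit, "fetal_srr")
  # every input slice has a recorded transform
  expect_length(fit$slice_transforms,
                sum(vapply(sim$stacks, function(s) length(s$slices), integer(1))))
})

test_that("mean inlier similarity does not decrease across cycles", {
  fit <- study_fit_clean()
  sims <- vapply(fit$inlier_history, function(h)
    mean(h$table$similarity[h$table$member]), numeric(1))
  expect_true(all(diff(sims) > -1e-6))
})

test_that("fit methods expose coefficients, predictions and residuals", {
  fit <- study_fit_clean()
  co <- coef(fit)
  expect_equal(ncol(co), 6)
  expect_equal(nrow(co), length(fit$slices))
  last <- fit$inlier_history[[length(fit$inlier_history)]]$table
  ks <- which(last$member)[1:2]
  pred <- predict(fit, fit$slices[ks])
  expect_length(pred, 2)
  expect_equal(dim(pred[[1]]), dim(fit$slices[[ks[1]]]$pixels))
  # inlier slices agree well with their simulated counterparts
  k <- ks[1]
  expect_gt(slice_similarity(fit$slices[[k]]$pixels, pred[[1]],
                             fit$slices[[k]]$mask), 0.8)
  res <- Map(function(sl, ys) sl$pixels - ys, fit$slices[ks], pred)
  expect_equal(res[[1]], fit$slices[[k]]$pixels - pred[[1]])
  expect_output(print(fit), "super-resolution")
  expect_output(print(summary(fit)), "per-cycle")
})
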