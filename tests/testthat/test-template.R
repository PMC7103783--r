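test_that("template selection matches brain volumes with a stable tie-break", {
  g <- image_grid(c(10, 10, 10), 1)
  mk <- function(n, label) {
    m <- array(0, c(10, 10, 10)); m[seq_len(n)] <- 1
    template_entry(volume3d(array(runif(1000), c(10, 10, 10)), g),
                   mask_volume(m, g), label)
  }
  atlas <- list(mk(90, "t1"), mk(105, "t2"), mk(200, "t3"))
  subj <- array(0, c(10, 10, 10)); subj[1:100] <- 1
  subj <- mask_volume(subj, g)
  expect_equal(select_template(subj, atlas)$label, "t2")
  expect_equal(select_template(subj, atlas[2])$label, "t2")
  # exact tie at +/- 10: lexicographically lower label wins
  tieatlas <- list(mk(110, "b"), mk(90, "a"))
  expect_equal(select_template(subj, tieatlas)$label, "a")
  expect_error(select_template(subj, list()), "no-template")
})

test_that("principal-axes candidates are right-handed and contain the truth", {
  ph <- make_phantom(phantom_spec(shape = c(32, 32, 32), spacing = 1.5, seed = 25))
  m <- ph$mask

  cands <- pba_candidates(m, m)
  expect_length(cands, 4)
  for (cc in cands) expect_equal(det(cc$rotation), 1, tolerance = 1e-9)
  best <- min(vapply(cands, rot_angle, numeric(1)))
  expect_lt(best, 0.1)

  # rotated elongated mask: one candidate within 1 degree of the truth
  ctr <- index_to_world(m$grid, (m$grid$shape - 1) / 2)
  R <- rigid_from_params(c(20, -10, 30, 0, 0, 0), center = ctr)
  rot <- mask_volume((resample(volume3d(m$values, m$grid), m$grid,
                               transform = R,
                               interpolation = "nearest")$values > 0.5) * 1,
                     m$grid)
  cands2 <- pba_candidates(rot, m)
  resid <- vapply(cands2, function(cc)
    rot_angle(rigid_compose(cc, rigid_invert(R))), numeric(1))
  expect_lt(min(resid), 1)

  # spherical mask: isotropic spectrum warns
  g <- image_grid(c(20, 20, 20), 1, origin = rep(-9.5, 3))
  idx <- as.matrix(expand.grid(1:20, 1:20, 1:20)) - 10.5
  ball <- mask_volume(array((rowSums(idx^2) <= 49) * 1, c(20, 20, 20)), g)
  expect_warning(pba_candidates(ball, ball), "ambiguous-axes")
})

test_that("template alignment recovers large rigid offsets via NMI selection", {
  ph <- make_phantom(phantom_spec(shape = c(48, 48, 48), spacing = 1.2, seed = 21))
  tpl <- template_entry(ph$volume, ph$mask, "self")

  # self-alignment is the identity
  tr0 <- align_to_template(ph$volume, ph$mask, tpl)
  expect_lt(rot_angle(tr0), 0.2)
  expect_lt(sqrt(sum(tr0$translation^2)), 0.5)
  # the returned transform maximizes NMI among the refined candidates
  expect_equal(attr(tr0, "winner"), which.max(attr(tr0, "nmi")))

  set.seed(26)
  ctr <- mask_centroid <- fetalsrr:::mask_centroid(ph$mask)
  p <- c(runif(3, -30, 30), runif(3, -20, 20))
  Tt <- rigid_from_params(p, center = ctr)
  c_subj <- apply_transform(rigid_invert(Tt), ctr)
  gs <- image_grid(c(64, 64, 64), 1.2, origin = c_subj - (63 / 2) * 1.2)
  subj <- resample(ph$volume, gs, transform = Tt)
  subm <- mask_volume((resample(volume3d(ph$mask$values, ph$mask$grid), gs,
                                transform = Tt,
                                interpolation = "nearest")$values > 0.5) * 1, gs)
  tr <- align_to_template(subj, subm, tpl)
  # recovered transform inverts the applied one to about a degree / mm
  res <- rigid_compose(tr, rigid_invert(Tt))
  expect_lt(rot_angle(res), 1)
  expect_lt(sqrt(sum((apply_transform(res, ctr) - ctr)^2)), 1)
})

test_that("template-space solve reuses the inlier slices without resampling", {
  fit <- study_fit_clean()
  # identity transform onto the subject grid reproduces the subject solve
  v <- reconstruct_template_space(fit, rigid_transform(), fit$grid)
  rel <- sqrt(sum((v$values - fit$volume$values)^2)) /
    sqrt(sum(fit$volume$values^2))
  expect_lt(rel, 0.05)

  nofit <- fit
  for (k in seq_along(nofit$slices)) nofit$slices[[k]]$inlier <- FALSE
  expect_error(reconstruct_template_space(nofit, rigid_transform(), fit$grid),
               "no-inliers")
})

test_that("atlas directories round-trip through the manifest", {
  atlas <- synthetic_atlas(2, shape = c(24, 24, 24), spacing = 1.5)
  expect_length(atlas, 2)
  expect_gt(atlas[[2]]$brain_volume, atlas[[1]]$brain_volume)
  d <- file.path(tempdir(), "atlas-test")
  write_atlas(atlas, d)
  back <- read_atlas(d)
  expect_equal(back[[1]]$brain_volume, atlas[[1]]$brain_volume, tolerance = 1e-6)
  expect_lt(max(abs(back[[2]]$volume$values - atlas[[2]]$volume$values)), 1e-5)
})
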