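# Independent oracles (plain R, no calls into the package's compiled paths)
# and shared fixtures.

# homogeneous 4x4 matrix of a rigid transform
hom4 <- function(tr) rbind(cbind(tr$rotation, tr$translation), c(0, 0, 0, 1))

# geodesic rotation angle (degrees) of a rigid transform's rotation
rot_angle <- function(tr) {
  acos(min(1, max(-1, (sum(diag(tr$rotation)) - 1) / 2))) * 180 / pi
}

# Brute-force slice forward projection: explicit loops, truncated oriented
# Gaussian evaluated at voxel centers, renormalized over in-extent support.
r_forward_project <- function(vol, geom, psf) {
  g <- vol$grid
  R <- geom$transform$rotation
  cov_w <- R %*% psf$covariance %*% t(R)
  icov <- solve(cov_w)
  t2 <- psf$truncation_radius^2
  out <- matrix(0, geom$shape[1], geom$shape[2])
  idx <- as.matrix(expand.grid(i = 0:(g$shape[1] - 1), j = 0:(g$shape[2] - 1),
                               k = 0:(g$shape[3] - 1)))
  wpts <- g$direction %*% (t(idx) * g$spacing) + g$origin
  vals <- as.numeric(vol$values)
  for (jj in 0:(geom$shape[2] - 1)) {
    for (ii in 0:(geom$shape[1] - 1)) {
      ctr <- drop(R %*% c(ii * geom$in_plane_spacing,
                          jj * geom$in_plane_spacing, 0)) +
        geom$transform$translation
      d <- wpts - ctr
      m <- colSums(d * (icov %*% d))
      keep <- m <= t2
      if (!any(keep)) next
      w <- exp(-0.5 * m[keep])
      out[ii + 1, jj + 1] <- sum(w * vals[keep]) / sum(w)
    }
  }
  out
}

# dense system matrix of a slice operator, built row-by-row with the
# brute-force projector on unit volumes
r_dense_A <- function(geom, psf, grid) {
  nvox <- prod(grid$shape)
  npix <- prod(geom$shape)
  A <- matrix(0, npix, nvox)
  base <- array(0, grid$shape)
  for (v in seq_len(nvox)) {
    e <- base
    e[v] <- 1
    A[, v] <- as.numeric(r_forward_project(volume3d(e, grid), geom, psf))
  }
  A
}

# Brute-force discrete Nadaraya-Watson regression: per-sample nearest-voxel
# rounding (ties toward the lower index), separable truncated-Gaussian weight
# between the rounded sample position and every voxel, ratio of weighted sums.
r_nadaraya_watson <- function(slices, target, sigma = 1, use_masks = TRUE) {
  d <- target$shape
  kern <- function(delta) {
    r <- max(1L, ceiling(3 * sigma))
    k <- exp(-0.5 * ((-r:r) / sigma)^2)
    k <- k / sum(k)
    off <- delta + r + 1
    ifelse(off >= 1 & off <= 2 * r + 1,
           k[pmax(1, pmin(2 * r + 1, off))], 0)
  }
  num <- array(0, d)
  den <- array(0, d)
  qs <- as.matrix(expand.grid(0:(d[1] - 1), 0:(d[2] - 1), 0:(d[3] - 1)))
  for (sl in slices) {
    dd <- dim(sl$pixels)
    for (jj in 0:(dd[2] - 1)) for (ii in 0:(dd[1] - 1)) {
      if (use_masks && sl$mask[ii + 1, jj + 1] <= 0.5) next
      w <- apply_transform(sl$transform,
                           c(ii * sl$in_plane_spacing, jj * sl$in_plane_spacing, 0))
      ci <- world_to_index(target, w)
      n <- ceiling(ci - 0.5)
      if (any(n < 0) || any(n > d - 1)) next
      wts <- kern(qs[, 1] - n[1]) * kern(qs[, 2] - n[2]) * kern(qs[, 3] - n[3])
      num <- num + array(wts * sl$pixels[ii + 1, jj + 1], d)
      den <- den + array(wts, d)
    }
  }
  out <- array(0, d)
  keep <- den > 1e-8 * max(den)
  out[keep] <- num[keep] / den[keep]
  out
}

# brute-force 26-connected labelling by repeated flood fill over a queue
r_label26 <- function(mask) {
  d <- dim(mask)
  lab <- array(0L, d)
  nxt <- 0L
  offs <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  offs <- offs[rowSums(abs(offs)) > 0, ]
  for (s in which(mask > 0.5)) {
    if (lab[s] != 0L) next
    nxt <- nxt + 1L
    queue <- s
    lab[s] <- nxt
    while (length(queue)) {
      cur <- queue[length(queue)]
      queue <- queue[-length(queue)]
      ci <- arrayInd(cur, d)
      for (r in seq_len(nrow(offs))) {
        p <- ci + offs[r, ]
        if (any(p < 1) || any(p > d)) next
        q <- p[1] + d[1] * (p[2] - 1 + d[2] * (p[3] - 1))
        if (mask[q] > 0.5 && lab[q] == 0L) {
          lab[q] <- nxt
          queue <- c(queue, q)
        }
      }
    }
  }
  lab
}

# slices of a volume acquired noise-free along the standard orientations
mk_slices <- function(vol, in_plane = 1, thickness = 1, step = thickness,
                      npx = NULL, K = NULL, orientations = default_orientations(),
                      psf = make_psf(in_plane, thickness)) {
  g <- vol$grid
  fov <- max(g$shape * g$spacing)
  if (is.null(npx)) npx <- ceiling(fov / in_plane)
  if (is.null(K)) K <- ceiling(fov / step)
  c0 <- index_to_world(g, (g$shape - 1) / 2)
  out <- list()
  for (oi in seq_along(orientations)) {
    R <- orientations[[oi]]
    for (k in seq_len(K)) {
      off <- (k - 1 - (K - 1) / 2) * step
      tr <- rigid_transform(R, c0 + drop(R %*% c(-(npx - 1) / 2 * in_plane,
                                                 -(npx - 1) / 2 * in_plane, off)))
      geom <- slice_geometry(c(npx, npx), in_plane, thickness, tr)
      px <- forward_project(vol, geom, psf)
      out[[length(out) + 1]] <- slice2d(px, in_plane, thickness, tr,
                                        slice_index = k - 1L,
                                        stack_id = names(orientations)[oi] %||%
                                          paste0("s", oi))
    }
  }
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# ---- cached study fixtures (computed once per test run) --------------------

.fixtures <- new.env(parent = emptyenv())

fx <- function(name, build) {
  if (!exists(name, envir = .fixtures)) assign(name, build(), envir = .fixtures)
  get(name, envir = .fixtures)
}

study_phantom <- function() fx("phantom", function()
  make_phantom(phantom_spec(shape = c(64, 64, 64), spacing = 1, seed = 7)))

study_config <- function() srr_config(recon_spacing = 1.25, lsq_max_iter = 50,
                                      v2v_levels = c(2, 1))

# artifact-free acquisition: the motion-recovery experiment
study_sim_clean <- function() fx("sim_clean", function() {
  ph <- study_phantom()
  simulate_acquisition(ph$volume, ph$mask, in_plane_spacing = 1.5,
                       thickness = 2.5, motion = motion_spec(seed = 11),
                       artifacts = artifact_spec(outlier_fraction = 0, seed = 12),
                       noise_sd = 0.02)
})

study_fit_clean <- function() fx("fit_clean", function()
  srr_reconstruct(study_sim_clean()$stacks, study_config()))

# 10% artifact-corrupted acquisition: the outlier-rejection experiment
study_sim_art <- function() fx("sim_art", function() {
  ph <- study_phantom()
  simulate_acquisition(ph$volume, ph$mask, in_plane_spacing = 1.5,
                       thickness = 2.5, motion = motion_spec(seed = 11),
                       artifacts = artifact_spec(outlier_fraction = 0.1, seed = 12),
                       noise_sd = 0.02)
})

study_fit_art <- function() fx("fit_art", function()
  srr_reconstruct(study_sim_art()$stacks, study_config()))

# same corrupted data with the similarity threshold at its floor (no rejection)
study_fit_nofloor <- function() fx("fit_nofloor", function() {
  cfg <- srr_config(recon_spacing = 1.25, lsq_max_iter = 50,
                    v2v_levels = c(2, 1), beta_schedule = rep(-0.999, 3))
  srr_reconstruct(study_sim_art()$stacks, cfg)
})
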