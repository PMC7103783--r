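# evaluate code under a fixed seed without disturbing the caller's RNG state
local_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv())
          else suppressWarnings(rm(".Random.seed", envir = globalenv())))
  set.seed(seed)
  force(code)
}

#' Synthetic phantom specification
#'
#' @param shape voxel counts per axis.
#' @param spacing mm per axis (scalar or length 3).
#' @param seed structure seed; the phantom is deterministic given the seed.
#' @param feature_scales mm radii of nested internal structures.
#' @param brain_scale relative size of the "brain" ellipsoid (used to build
#'   atlas entries with distinct volumes).
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(shape = c(64, 64, 64), spacing = 1, seed = 1,
                         feature_scales = c(8, 6, 4, 3), brain_scale = 1) {
  structure(list(shape = as.integer(rep_len(shape, 3)),
                 spacing = as.numeric(rep_len(spacing, 3)),
                 seed = as.integer(seed), feature_scales = feature_scales,
                 brain_scale = brain_scale),
            class = "phantom_spec")
}

#' Structured 3D phantom with a "brain" mask
#'
#' Builds a smooth, asymmetric nested-ellipsoid volume standing in for fetal
#' anatomy: a faint "head" ellipsoid containing an elongated, tilted "brain"
#' ellipsoid with darker ventricle-like cavities, bright and dark internal
#' blobs at the requested feature scales, and a smooth intensity gradient.
#' Intensities lie in `[0, 1]`.  The mask is the (single-component) brain
#' ellipsoid, elongated so its principal axes are well separated and
#' principal-axes alignment is well posed.
#'
#' @param spec a [phantom_spec].
#' @return List with elements `volume` ([volume3d]) and `mask`
#'   ([mask_volume]); both deterministic given `spec$seed`.
#' @export
make_phantom <- function(spec = phantom_spec()) {
  g <- image_grid(spec$shape, spec$spacing,
                  origin = -(spec$shape - 1) / 2 * spec$spacing)
  h <- (spec$shape - 1) / 2 * spec$spacing
  xs <- lapply(1:3, function(a) ((0:(spec$shape[a] - 1)) - (spec$shape[a] - 1) / 2) * spec$spacing[a])
  P1 <- array(rep(xs[[1]], times = spec$shape[2] * spec$shape[3]), spec$shape)
  P2 <- array(rep(rep(xs[[2]], each = spec$shape[1]), times = spec$shape[3]), spec$shape)
  P3 <- array(rep(xs[[3]], each = spec$shape[1] * spec$shape[2]), spec$shape)

  local_seed(spec$seed, {
    ang <- runif(3, -20, 20)
    ctr <- runif(3, -0.05, 0.05) * h
    Rb <- rigid_from_params(c(ang, 0, 0, 0))$rotation
    inside <- function(center, radii, R = diag(3)) {
      d1 <- P1 - center[1]; d2 <- P2 - center[2]; d3 <- P3 - center[3]
      u1 <- R[1, 1] * d1 + R[2, 1] * d2 + R[3, 1] * d3
      u2 <- R[1, 2] * d1 + R[2, 2] * d2 + R[3, 2] * d3
      u3 <- R[1, 3] * d1 + R[2, 3] * d2 + R[3, 3] * d3
      (u1 / radii[1])^2 + (u2 / radii[2])^2 + (u3 / radii[3])^2 <= 1
    }
    vol <- array(0, spec$shape)
    vol[inside(c(0, 0, 0), 0.92 * h)] <- 0.3
    br <- spec$brain_scale * c(0.62, 0.50, 0.40) * h
    brain <- inside(ctr, br, Rb)
    vol[brain] <- 0.7
    # ventricle-like dark cavities along the leading brain axis
    ax1 <- Rb[, 1]; ax2 <- Rb[, 2]
    for (s in c(-1, 1)) {
      vc <- ctr + s * 0.35 * br[1] * ax1 + 0.1 * br[2] * ax2
      vol[inside(vc, 0.22 * br, Rb) & brain] <- 0.15
    }
    # internal blobs at the requested feature scales: enough distinct
    # structure that every oblique cross-section determines the slice pose
    # (registration is ill-posed on a featureless ellipsoid)
    vals <- rep(c(1.0, 0.35, 0.9, 0.5), length.out = 4 * length(spec$feature_scales))
    k <- 0
    for (r in spec$feature_scales) {
      for (rep_i in 1:4) {
        k <- k + 1
        bc <- ctr + runif(3, -0.6, 0.6) * br
        ecc <- runif(3, 0.6, 1.4)
        reg <- inside(bc, r * ecc) & brain
        vol[reg] <- vals[k]
      }
    }
    grad <- 0.12 * ((P1 * Rb[1, 1] + P2 * Rb[2, 1] + P3 * Rb[3, 1]) / max(br))
    vol[brain] <- vol[brain] + grad[brain]
    # fine-scale smooth texture inside the brain (parenchyma-like): pose
    # estimation is degenerate on textureless regions, as in real anatomy
    tex <- blur_separable(array(rnorm(prod(spec$shape)), spec$shape),
                          2 / spec$spacing)
    tex <- tex / stats::sd(tex)
    vol[brain] <- vol[brain] + 0.15 * tex[brain]
    vol <- blur_separable(vol, rep(0.8, 3))
    vol <- pmin(1, pmax(0, vol))
    list(volume = volume3d(array(vol, spec$shape), g),
         mask = mask_volume(brain * 1, g))
  })
}

#' Per-slice motion specification
#'
#' An M-interleaved acquisition yields M temporally sequential, spatially
#' interleaved sub-stacks; motion within a sub-stack is a smooth cumulative
#' random walk while each new sub-stack starts with an independent jump.
#'
#' @param interleave M (2 or 3 typically).
#' @param max_rotation,max_translation hard bounds, degrees / mm.
#' @param step_rotation,step_translation within-sub-stack random-walk step
#'   bounds.
#' @param jump_rotation,jump_translation between-sub-stack jump bounds;
#'   default to the hard bounds.
#' @param seed RNG seed.
#' @return An object of class `motion_spec`.
#' @export
motion_spec <- function(interleave = 2L, max_rotation = 5, max_translation = 3,
                        step_rotation = 1, step_translation = 0.5,
                        jump_rotation = max_rotation,
                        jump_translation = max_translation, seed = 1) {
  stopifnot(interleave >= 1, max_rotation >= 0, max_translation >= 0,
            step_rotation >= 0, step_translation >= 0)
  structure(list(interleave = as.integer(interleave),
                 max_rotation = max_rotation, max_translation = max_translation,
                 step_rotation = step_rotation,
                 step_translation = step_translation,
                 jump_rotation = jump_rotation,
                 jump_translation = jump_translation, seed = as.integer(seed)),
            class = "motion_spec")
}

#' Outlier-slice artifact specification
#'
#' Emulates the artifact families that corrupt individual slices in fast 2D
#' fetal MRI: intensity-band corruption (spin-history-like signal scaling over
#' a band of rows), in-plane blur, and signal dropout.  Default magnitudes are
#' calibrated so that a corrupted slice's masked NCC against its clean
#' counterpart falls below 0.8, the final inlier threshold.
#'
#' @param outlier_fraction per-slice corruption probability in `[0, 1]`.
#' @param types subset of `c("band", "blur", "dropout")`, applied cyclically.
#' @param band_factor multiplicative range for the intensity band.
#' @param blur_sigma in-plane blur sigma range, pixels.
#' @param seed RNG seed.
#' @return An object of class `artifact_spec`.
#' @export
artifact_spec <- function(outlier_fraction = 0.1,
                          types = c("band", "blur", "dropout"),
                          band_factor = c(4, 5), blur_sigma = c(4, 6),
                          seed = 1) {
  stopifnot(outlier_fraction >= 0, outlier_fraction <= 1)
  structure(list(outlier_fraction = outlier_fraction, types = types,
                 band_factor = band_factor, blur_sigma = blur_sigma,
                 seed = as.integer(seed)),
            class = "artifact_spec")
}

#' Standard acquisition orientations
#'
#' Right-handed slice-frame rotations with the slice normal along the world
#' z (axial), y (coronal) and x (sagittal) axes.
#'
#' @return Named list of 3x3 rotation matrices.
#' @export
default_orientations <- function() {
  list(axial = diag(3),
       coronal = cbind(c(1, 0, 0), c(0, 0, 1), c(0, -1, 0)),
       sagittal = cbind(c(0, 1, 0), c(0, 0, 1), c(1, 0, 0)))
}

# 2D separable Gaussian blur of a matrix (sigma in pixels)
blur2d <- function(m, sigma) {
  arr <- array(m, c(dim(m), 1))
  blur_separable(arr, c(sigma, sigma, 0))[, , 1]
}

# `u` is a vector of 4 pre-drawn uniforms fixing the artifact's randomness
apply_artifact <- function(px, type, spec, u) {
  d <- dim(px)
  switch(type,
    band = {
      # spin-history-like intensity striping: the gain oscillates across the
      # band between 1 and the peak factor, imposing banding uncorrelated
      # with the anatomy (a flat gain change would be invisible to
      # intensity-normalized similarity)
      h <- max(4L, round(0.6 * d[1]))
      i0 <- 1L + floor(u[1] * (d[1] - h))
      f <- spec$band_factor[1] + u[2] * diff(spec$band_factor)
      prof <- 1 + (f - 1) * 0.5 * (1 + sin(seq(0, 6 * pi, length.out = h)))
      px[i0:(i0 + h - 1L), ] <- prof * px[i0:(i0 + h - 1L), ]
      px
    },
    blur = blur2d(px, spec$blur_sigma[1] + u[3] * diff(spec$blur_sigma)),
    dropout = {
      j0 <- d[2] %/% 4 + 1L + floor(u[4] * max(1L, d[2] %/% 3))
      ramp <- pmin(1, pmax(0, (j0 - seq_len(d[2])) / 3 + 1))
      sweep(px, 2, ramp, `*`)
    })
}

#' Simulate a multi-stack interleaved acquisition with known ground truth
#'
#' Generates low-resolution stacks from a phantom exactly through the slice
#' acquisition model: each slice is the oriented-Gaussian forward projection
#' of the phantom under its true (motion-perturbed) rigid transform, plus
#' Gaussian observation noise.  Slice masks are the projected phantom mask.
#' The stored slice transforms are the nominal (motion-free) geometry — the
#' motion is what reconstruction has to recover — while the returned ground
#' truth holds the true transforms, the motion parameters and outlier labels.
#' Outlier slices are additionally corrupted per the artifact specification;
#' each stack is finally rescaled by its linear intensity distortion `a*I+b`.
#'
#' @param phantom a [volume3d].
#' @param mask a [mask_volume] on the phantom grid.
#' @param orientations list of 3x3 rotation matrices (or [rigid_transform]s),
#'   one stack per orientation.
#' @param in_plane_spacing,thickness slice geometry prototype, mm.
#' @param motion a [motion_spec].
#' @param artifacts an [artifact_spec].
#' @param noise_sd additive Gaussian noise standard deviation (intensity
#'   units; the phantom range is 1).
#' @param intensity_scale list of `c(a, b)` per stack, or `NULL` for the
#'   default cyclic distortions.
#' @param psf optional `psf_spec`; derived from the geometry by default.
#' @return An object of class `srr_simulation`: `stacks` (list of
#'   [slice_stack]), `truth` (data frame of per-slice motion parameters and
#'   outlier labels, plus the true transforms), `phantom`, `mask`.
#' @export
simulate_acquisition <- function(phantom, mask,
                                 orientations = default_orientations(),
                                 in_plane_spacing = 2, thickness = 4,
                                 motion = motion_spec(),
                                 artifacts = artifact_spec(),
                                 noise_sd = 0.02, intensity_scale = NULL,
                                 psf = NULL) {
  stopifnot(length(orientations) >= 1)
  if (is.null(psf)) psf <- make_psf(in_plane_spacing, thickness)
  g <- phantom$grid
  c0 <- index_to_world(g, (g$shape - 1) / 2)
  fov <- max(g$shape * g$spacing)
  nx <- ny <- ceiling(fov / in_plane_spacing)
  # slices are prescribed over the brain, as in clinical acquisitions: the
  # stack covers the mask extent along its normal plus a two-slice margin
  midx <- which(mask$values > 0.5, arr.ind = TRUE)
  mworld <- if (nrow(midx)) index_to_world(g, t(midx) - 1) else
    matrix(c0, 3, 1)
  mworld <- if (is.matrix(mworld)) mworld else matrix(mworld, 3)
  if (is.null(intensity_scale)) {
    ab <- list(c(1, 0), c(1.25, 0.05), c(0.8, -0.03))
    intensity_scale <- lapply(seq_along(orientations),
                              function(i) ab[[(i - 1) %% 3 + 1]])
  }

  stacks <- vector("list", length(orientations))
  truth_rows <- list()
  true_transforms <- list()
  n_out_total <- 0L

  # per-stack geometry (rotation, slice count, stack center along the normal)
  geoms <- lapply(seq_along(orientations), function(oi) {
    R <- orientations[[oi]]
    if (inherits(R, "rigid_transform")) R <- R$rotation
    proj <- drop(crossprod(R[, 3], mworld - c0))
    list(R = R,
         mid = (min(proj) + max(proj)) / 2,
         K = ceiling((diff(range(proj)) + 4 * thickness) / thickness))
  })
  Ks <- vapply(geoms, `[[`, numeric(1), "K")
  k_off <- c(0, cumsum(Ks))

  # artifact randomness comes from its own seed, pre-drawn per slice
  art_draw <- local_seed(artifacts$seed,
                         matrix(runif(5L * sum(Ks)), ncol = 5))

  local_seed(motion$seed, {
    for (oi in seq_along(orientations)) {
      R <- geoms[[oi]]$R
      mid <- geoms[[oi]]$mid
      K <- geoms[[oi]]$K
      sid <- names(orientations)[oi]
      if (is.null(sid) || sid == "") sid <- paste0("stack", oi)
      cx <- (nx - 1) / 2 * in_plane_spacing
      cy <- (ny - 1) / 2 * in_plane_spacing
      M <- motion$interleave
      # motion parameters in acquisition order (sub-stack by sub-stack)
      params <- matrix(0, K, 6)
      for (m in seq_len(M) - 1L) {
        ks <- seq(m + 1L, K, by = M)
        p <- c(runif(3, -motion$jump_rotation, motion$jump_rotation),
               runif(3, -motion$jump_translation, motion$jump_translation))
        p <- clamp6(p, motion$max_rotation, motion$max_translation)
        for (k in ks) {
          params[k, ] <- p
          p <- p + c(runif(3, -motion$step_rotation, motion$step_rotation),
                     runif(3, -motion$step_translation, motion$step_translation))
          p <- clamp6(p, motion$max_rotation, motion$max_translation)
        }
      }
      slices <- vector("list", K)
      for (k in seq_len(K)) {
        off <- mid + (k - 1 - (K - 1) / 2) * thickness
        base_tr <- rigid_transform(R, c0 + drop(R %*% c(-cx, -cy, off)))
        sl_center <- c0 + drop(R %*% c(0, 0, off))
        mo <- rigid_from_params(params[k, ], center = sl_center)
        true_tr <- rigid_compose(mo, base_tr)
        geom <- slice_geometry(c(nx, ny), in_plane_spacing, thickness, true_tr)
        px <- forward_project(phantom, geom, psf)
        mk <- (forward_project(volume3d(mask$values, mask$grid), geom, psf) >= 0.5) * 1
        if (noise_sd > 0) px <- px + array(rnorm(nx * ny, 0, noise_sd), dim(px))
        row_id <- k_off[oi] + k
        is_out <- art_draw[row_id, 1] < artifacts$outlier_fraction
        atype <- NA_character_
        if (is_out) {
          n_out_total <- n_out_total + 1L
          atype <- artifacts$types[(n_out_total - 1L) %% length(artifacts$types) + 1L]
          px <- apply_artifact(px, atype, artifacts, art_draw[row_id, 2:5])
        }
        ab <- intensity_scale[[oi]]
        px <- ab[1] * px + ab[2]
        slices[[k]] <- slice2d(px, in_plane_spacing, thickness, base_tr,
                               mask = mk, slice_index = k - 1L, stack_id = sid)
        true_transforms[[paste0(sid, ":", k - 1L)]] <- true_tr
        truth_rows[[length(truth_rows) + 1L]] <- data.frame(
          stack_id = sid, slice_index = k - 1L,
          rx = params[k, 1], ry = params[k, 2], rz = params[k, 3],
          tx = params[k, 4], ty = params[k, 5], tz = params[k, 6],
          outlier = is_out, artifact = atype, stringsAsFactors = FALSE)
      }
      stacks[[oi]] <- slice_stack(slices, interleave = M)
    }
  })
  structure(list(stacks = stacks,
                 truth = list(params = do.call(rbind, truth_rows),
                              transforms = true_transforms,
                              seeds = c(motion = motion$seed,
                                        artifacts = artifacts$seed)),
                 phantom = phantom, mask = mask, psf = psf),
            class = "srr_simulation")
}

clamp6 <- function(p, max_rot, max_tr) {
  c(pmin(max_rot, pmax(-max_rot, p[1:3])),
    pmin(max_tr, pmax(-max_tr, p[4:6])))
}

#' @export
print.srr_simulation <- function(x, ...) {
  cat(sprintf("srr_simulation: %d stacks, %d slices, %d labeled outliers\n",
              length(x$stacks), nrow(x$truth$params), sum(x$truth$params$outlier)))
  invisible(x)
}

#' Write a simulation to disk
#'
#' Writes one NIfTI volume and one mask per stack plus a `ground_truth.json`
#' with the per-slice motion parameters, outlier labels and seeds.
#'
#' @param sim an `srr_simulation`.
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
write_simulation <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (st in sim$stacks) {
    sid <- st$slices[[1]]$stack_id
    write_volume(stack_to_volume(st), file.path(dir, paste0(sid, ".nii")))
    write_volume(stack_to_volume(st, "mask"),
                 file.path(dir, paste0(sid, "_mask.nii")))
  }
  jsonlite::write_json(
    list(params = sim$truth$params, seeds = as.list(sim$truth$seeds)),
    file.path(dir, "ground_truth.json"), auto_unbox = TRUE, digits = NA,
    na = "null")
  invisible(dir)
}
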