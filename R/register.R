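# masked NCC between two equal-length vectors; NA when degenerate
ncc_vec <- function(a, b) {
  a <- a - mean(a); b <- b - mean(b)
  den <- sqrt(sum(a^2) * sum(b^2))
  if (den == 0 || !is.finite(den)) return(NA_real_)
  sum(a * b) / den
}

# Powell-class derivative-free search: cyclic coordinate descent with Brent
# line searches over +/- step per parameter, steps halved between passes.
# `order` fixes which parameters are searched first (well-identified ones
# before weakly-identified ones).
powell_search <- function(par, fn, step, passes = 2, order = seq_along(par)) {
  best <- fn(par)
  for (pass in seq_len(passes)) {
    for (d in order) {
      f1 <- function(t) {
        p <- par; p[d] <- t; fn(p)
      }
      lo <- par[d] - step[d]
      hi <- par[d] + step[d]
      if (pass == 1L) {
        # Brent assumes unimodality; a coarse pre-scan picks the right basin
        grid <- seq(lo, hi, length.out = 7)
        fg <- vapply(grid, f1, numeric(1))
        g <- which.min(fg)
        lo <- grid[max(1, g - 1)]
        hi <- grid[min(7, g + 1)]
      }
      opt <- stats::optimize(f1, interval = c(lo, hi),
                             tol = max(step[d] * 0.02, 1e-6))
      if (opt$objective < best) {
        best <- opt$objective
        par[d] <- opt$minimum
      }
    }
    step <- step / 2
  }
  list(par = par, value = best)
}

# Gaussian-smoothed decimation of a volume by an integer factor
downsample_volume <- function(volume, factor, is_mask = FALSE) {
  if (factor <= 1) return(volume)
  g <- volume$grid
  vals <- if (is_mask) volume$values else blur_separable(volume$values, rep(factor / 2, 3))
  shape <- pmax(1L, as.integer(floor((g$shape - 1) / factor) + 1))
  tg <- image_grid(shape, g$spacing * factor, g$origin, g$direction)
  v <- volume3d(vals, g)
  out <- resample(v, tg, interpolation = if (is_mask) "nearest" else "linear")
  out
}

#' Rigid volume-to-volume registration (masked NCC)
#'
#' Finds the rigid transform mapping `moving`-world points onto `fixed`-world
#' points that maximizes normalized cross-correlation over the masked overlap,
#' by a multi-resolution Powell-class (cyclic coordinate descent with Brent
#' line searches) search over the 6 rigid parameters.
#'
#' @param moving,fixed [volume3d] objects.
#' @param moving_mask,fixed_mask optional [mask_volume] objects constraining
#'   the metric.
#' @param init initial [rigid_transform] (moving to fixed); identity default.
#' @param levels integer decimation factors, coarse to fine.
#' @param rot_step,trans_step base line-search half-widths (degrees, mm),
#'   scaled by the level factor.
#' @param passes coordinate-descent passes per level.
#' @return The optimal [rigid_transform] (moving world to fixed world), with
#'   attribute `"metric"` (final NCC).
#' @export
volume_to_volume_register <- function(moving, fixed, moving_mask = NULL,
                                      fixed_mask = NULL,
                                      init = rigid_transform(),
                                      levels = c(4, 2, 1), rot_step = 4,
                                      trans_step = 4, passes = 2) {
  center <- if (!is.null(fixed_mask) && sum(fixed_mask$values) > 0) {
    mask_centroid(fixed_mask)
  } else {
    index_to_world(fixed$grid, (fixed$grid$shape - 1) / 2)
  }
  current <- init
  final_metric <- NA_real_
  mg <- moving$grid
  any_valid <- FALSE
  for (f in levels) {
    fx <- downsample_volume(fixed, f)
    fm <- if (!is.null(fixed_mask)) downsample_volume(fixed_mask, f, is_mask = TRUE)
    # metric samples the moving volume only at the masked fixed voxels
    keep0 <- if (is.null(fm)) array(TRUE, fx$grid$shape) else fm$values > 0.5
    idx <- which(keep0, arr.ind = TRUE)
    if (nrow(idx) < 8) next
    pts <- index_to_world(fx$grid, t(idx) - 1)
    pts <- if (is.matrix(pts)) pts else matrix(pts, 3)
    fvals <- fx$values[keep0]
    if (length(unique(fvals)) < 2) next
    mmask_vals <- if (!is.null(moving_mask)) moving_mask$values
    metric <- function(p) {
      tr <- rigid_compose(rigid_from_params(p, center = center), current)
      inv <- rigid_invert(tr)
      mv <- cpp_interp_points(moving$values, mg$shape, mg$direction, mg$spacing,
                              mg$origin, pts, inv$rotation, inv$translation, 1L)
      sel <- !is.na(mv)
      if (!is.null(mmask_vals)) {
        wm <- cpp_interp_points(mmask_vals, mg$shape, mg$direction, mg$spacing,
                                mg$origin, pts, inv$rotation, inv$translation, 0L)
        sel <- sel & !is.na(wm) & wm > 0.5
      }
      if (sum(sel) < 8) return(1)
      v <- ncc_vec(mv[sel], fvals[sel])
      if (is.na(v)) return(1)
      -v
    }
    if (metric(rep(0, 6)) < 1) any_valid <- TRUE
    st <- c(rep(rot_step, 3), rep(trans_step, 3)) * f
    opt <- powell_search(rep(0, 6), metric, st, passes = passes)
    current <- rigid_compose(rigid_from_params(opt$par, center = center), current)
    final_metric <- -opt$value
  }
  if (!any_valid || !is.finite(final_metric) || final_metric <= -1)
    stop("registration-failure: degenerate or non-overlapping masked volumes")
  attr(current, "metric") <- final_metric
  current
}

# centroid (world mm) of a mask volume
mask_centroid <- function(mask) {
  idx <- which(mask$values > 0.5, arr.ind = TRUE)
  if (nrow(idx) == 0) stop("no-brain-found: empty mask")
  index_to_world(mask$grid, colMeans(idx) - 1)
}

# 2x2 in-plane average-pooled copy of a slice with consistent geometry
downsample_slice <- function(slice) {
  px <- slice$pixels
  d <- dim(px)
  n0 <- d[1] %/% 2L; n1 <- d[2] %/% 2L
  if (n0 < 2 || n1 < 2) return(slice)
  sub <- px[seq_len(2 * n0), seq_len(2 * n1)]
  pooled <- 0.25 * (sub[seq(1, 2 * n0, 2), seq(1, 2 * n1, 2)] +
                    sub[seq(2, 2 * n0, 2), seq(1, 2 * n1, 2)] +
                    sub[seq(1, 2 * n0, 2), seq(2, 2 * n1, 2)] +
                    sub[seq(2, 2 * n0, 2), seq(2, 2 * n1, 2)])
  m <- slice$mask[seq(1, 2 * n0, 2), seq(1, 2 * n1, 2)]
  s <- slice$in_plane_spacing
  shift <- drop(slice$transform$rotation %*% c(0.5 * s, 0.5 * s, 0))
  tr <- rigid_transform(slice$transform$rotation,
                        slice$transform$translation + shift)
  slice2d(pooled, 2 * s, slice$thickness, tr, mask = m,
          slice_index = slice$slice_index, stack_id = slice$stack_id,
          inlier = slice$inlier)
}

#' Rigid slice-to-volume registration
#'
#' Re-estimates the rigid pose of a single 2D slice by maximizing NCC between
#' the acquired pixels and the slice's forward projection from the current
#' high-resolution iterate, over pixels inside both the slice mask and the
#' slice-projected high-resolution brain mask (evaluated at the initial pose).
#' The search is a multi-resolution Powell-class local search starting at
#' `init` (the previous cycle's estimate).
#'
#' @param slice a [slice2d].
#' @param x the current high-resolution [volume3d].
#' @param mask_hr high-resolution [mask_volume] constraining the metric.
#' @param psf a `psf_spec`.
#' @param init initial [rigid_transform] (slice frame to world); defaults to
#'   the slice's stored transform.
#' @param inplane_rot_step,inplane_trans_step line-search half-widths for the
#'   well-identified in-plane parameters (degrees, mm).
#' @param tilt_step,thick_step half-widths for the through-plane tilt
#'   rotations and the through-plane shift, which a single thick slice
#'   constrains only weakly; kept deliberately small (a trust region) so the
#'   estimate refines gradually over the outer cycles instead of chasing
#'   spurious optima of the blurred reference.
#' @param levels in-plane pooling factors, coarse to fine (from 2x2 pooled to
#'   full resolution).
#' @param passes coordinate-descent passes per level.
#' @return The re-estimated [rigid_transform], with attribute `"metric"`.
#'   A degenerate (constant) masked slice signals `registration-failure`;
#'   callers keep the previous transform and flag the slice.
#' @export
slice_to_volume_register <- function(slice, x, mask_hr, psf,
                                     init = slice$transform,
                                     inplane_rot_step = 2,
                                     inplane_trans_step = 2,
                                     tilt_step = 0.75, thick_step = 1,
                                     levels = c(2, 1), passes = 2) {
  base <- slice
  base$transform <- init
  pm <- tryCatch(
    forward_project(volume3d(mask_hr$values, mask_hr$grid), base, psf) >= 0.5,
    error = function(e) NULL)
  if (is.null(pm)) stop("registration-failure: slice does not overlap the volume")
  keep_full <- (slice$mask > 0.5) & pm
  if (sum(keep_full) < 2 || length(unique(slice$pixels[keep_full])) < 2)
    stop("registration-failure: degenerate masked slice")
  s <- slice$in_plane_spacing
  d <- dim(slice$pixels)
  # perturbations live in the slice-local frame, rotating about the slice
  # center: rz/tx/ty are in-plane, rx/ry are tilts, tz the through-plane shift
  c_loc <- c((d[1] - 1) / 2 * s, (d[2] - 1) / 2 * s, 0)
  current <- init
  final_metric <- NA_real_
  for (f in levels) {
    sl <- base
    sl$transform <- current
    keep <- keep_full
    if (f == 2) {
      sl <- downsample_slice(sl)
      if (identical(dim(sl$pixels), d)) next  # too small to pool
      n0 <- dim(sl$pixels)[1]; n1 <- dim(sl$pixels)[2]
      keep <- keep_full[seq(1, 2 * n0, 2), seq(1, 2 * n1, 2)]
      if (sum(keep) < 8) next
    }
    if (sum(keep) < 2) next
    geom0 <- geometry_of(sl)
    offset <- rigid_compose(rigid_invert(current), sl$transform)
    metric <- function(p) {
      tr <- rigid_compose(current, rigid_from_params(p, center = c_loc))
      g <- geom0
      g$transform <- rigid_compose(tr, offset)
      ys <- tryCatch(forward_project(x, g, psf), error = function(e) NULL)
      if (is.null(ys)) return(1)
      v <- ncc_vec(sl$pixels[keep], ys[keep])
      if (is.na(v)) return(1)
      -v
    }
    st <- c(tilt_step, tilt_step, inplane_rot_step,
            inplane_trans_step, inplane_trans_step, thick_step) * f
    opt <- powell_search(rep(0, 6), metric, st, passes = passes,
                         order = c(4, 5, 3, 6, 1, 2))
    current <- rigid_compose(current, rigid_from_params(opt$par, center = c_loc))
    final_metric <- -opt$value
  }
  attr(current, "metric") <- final_metric
  current
}
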