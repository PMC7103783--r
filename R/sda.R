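#' Scattered data approximation (discrete Nadaraya-Watson regression)
#'
#' Grids irregularly located slice samples onto a regular 3D grid: each
#' contributing slice pixel deposits its value and unit weight onto its nearest
#' target voxel (ties toward the lower index), then both the value and the
#' weight accumulations are blurred with a separable Gaussian, and the output
#' is their ratio wherever the blurred weight exceeds a floor — the discrete
#' Nadaraya-Watson estimator.  This builds the initial high-resolution volume
#' and all high-resolution brain-mask volumes from motion-corrected slices.
#'
#' Only pixels where the slice mask is 1 contribute when `use_masks = TRUE`.
#' `sigma` defaults to 1 target-grid voxel (set `sigma_unit = "mm"` for a
#' physical kernel width).
#'
#' @param slices list of [slice2d].
#' @param target an [image_grid].
#' @param sigma Gaussian smoothing standard deviation.
#' @param sigma_unit `"voxel"` (default) or `"mm"`.
#' @param use_masks if `TRUE`, only mask-positive pixels contribute.
#' @param eps_rel denominator floor, relative to the maximum blurred weight.
#' @return A [volume3d] on `target`.
#' @export
sda_reconstruct <- function(slices, target, sigma = 1,
                            sigma_unit = c("voxel", "mm"),
                            use_masks = TRUE, eps_rel = 1e-8) {
  sigma_unit <- match.arg(sigma_unit)
  acc <- sda_splat(slices, target, what = "pixels", use_masks = use_masks)
  sig_vox <- if (sigma_unit == "mm") sigma / target$spacing else rep(sigma, 3)
  num <- blur_separable(acc$num, sig_vox)
  den <- blur_separable(acc$den, sig_vox)
  floor_w <- eps_rel * max(den)
  out <- array(0, target$shape)
  keep <- den > floor_w
  out[keep] <- num[keep] / den[keep]
  volume3d(out, target)
}

#' @param slice_masks list of [slice2d] whose masks are gridded.
#' @param threshold probability at which the soft mask is binarized.
#' @return `sda_mask()` a binary [mask_volume] on `target`.
#' @rdname sda_reconstruct
#' @export
sda_mask <- function(slice_masks, target, sigma = 1,
                     sigma_unit = c("voxel", "mm"), threshold = 0.5) {
  sigma_unit <- match.arg(sigma_unit)
  acc <- sda_splat(slice_masks, target, what = "mask", use_masks = FALSE)
  sig_vox <- if (sigma_unit == "mm") sigma / target$spacing else rep(sigma, 3)
  num <- blur_separable(acc$num, sig_vox)
  den <- blur_separable(acc$den, sig_vox)
  soft <- array(0, target$shape)
  keep <- den > 1e-8 * max(den)
  soft[keep] <- num[keep] / den[keep]
  mask_volume((soft >= threshold) * 1, target)
}

# nearest-voxel splat of all contributing pixels of a slice set
sda_splat <- function(slices, target, what = "pixels", use_masks = TRUE) {
  if (length(slices) == 0L) stop("empty-input: no slices provided")
  pts <- vector("list", length(slices))
  vals <- vector("list", length(slices))
  for (s in seq_along(slices)) {
    sl <- slices[[s]]
    v <- sl[[what]]
    d <- dim(v)
    keep <- if (use_masks) sl$mask > 0.5 else array(TRUE, d)
    if (!any(keep)) next
    ij <- which(keep, arr.ind = TRUE) - 1L
    local <- rbind(ij[, 1] * sl$in_plane_spacing, ij[, 2] * sl$in_plane_spacing,
                   0)
    world <- apply_transform(sl$transform, local)
    pts[[s]] <- world_to_index(target, if (is.matrix(world)) world else matrix(world, 3))
    vals[[s]] <- v[keep]
  }
  pts <- do.call(cbind, pts[!vapply(pts, is.null, logical(1))])
  if (is.null(pts)) stop("empty-input: no contributing pixels")
  vals <- unlist(vals)
  acc <- cpp_splat(pts, vals, rep(1, length(vals)), target$shape)
  if (max(acc$den) == 0) stop("empty-input: no in-extent pixel")
  acc
}

# separable truncated-Gaussian blur; sigma in voxels per axis (0 = no blur)
blur_separable <- function(arr, sigma_vox) {
  d <- dim(arr)
  for (ax in 1:3) {
    s <- sigma_vox[ax]
    if (s <= 1e-12) next
    r <- max(1L, ceiling(3 * s))
    k <- exp(-0.5 * ((-r:r) / s)^2)
    k <- k / sum(k)
    n <- d[ax]
    K <- matrix(0, n, n)
    for (off in -r:r) {
      i <- seq_len(n)
      j <- i + off
      ok <- j >= 1 & j <= n
      K[cbind(i[ok], j[ok])] <- k[off + r + 1]
    }
    arr <- switch(ax,
      array(K %*% matrix(arr, d[1], d[2] * d[3]), d),
      {
        out <- arr
        for (i3 in seq_len(d[3])) out[, , i3] <- arr[, , i3] %*% t(K)
        out
      },
      array(matrix(arr, d[1] * d[2], d[3]) %*% t(K), d))
  }
  arr
}
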