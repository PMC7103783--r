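#' Soft Dice loss
#'
#' `1 - 2*sum(y*g) / (sum(y^2) + sum(g^2))` between a per-pixel probability
#' prediction `Y` and a probabilistic ground truth `G`, stabilized by adding
#' `eps` to both numerator and denominator (so identical maps — including two
#' empty ones — give exactly 0).  Values lie in `[0, 1]`.
#'
#' @param Y,G numeric arrays of identical shape with values in `[0, 1]`.
#' @param eps stabilizer; default `1e-7`.
#' @return The Dice loss.
#' @export
dice_loss <- function(Y, G, eps = 1e-7) {
  if (!all(dim1(Y) == dim1(G)))
    stop("invalid-input: prediction and ground truth shapes differ")
  1 - (2 * sum(Y * G) + eps) / (sum(Y^2) + sum(G^2) + eps)
}

dim1 <- function(x) if (is.null(dim(x))) length(x) else dim(x)

#' 2x2 average-pooling downscale
#'
#' Average pooling with kernel 2x2 and stride 2; a trailing odd row/column is
#' averaged over the available partial (2x1 / 1x2 / 1x1) block.  For 3D
#' inputs the pooling is applied slice-wise in-plane.
#'
#' @param Y 2D (or slice-stacked 3D) numeric array with both spatial dims
#'   >= 2.
#' @return The pooled array (spatial dims halved, rounded up).
#' @export
downscale <- function(Y) {
  d <- dim(Y)
  if (length(d) == 3L) {
    out <- NULL
    for (k in seq_len(d[3])) {
      p <- downscale(Y[, , k])
      if (is.null(out)) out <- array(0, c(dim(p), d[3]))
      out[, , k] <- p
    }
    return(out)
  }
  if (any(d < 2)) stop("cannot-downscale: spatial dims must be >= 2")
  i_blk <- (seq_len(d[1]) + 1L) %/% 2L
  j_blk <- (seq_len(d[2]) + 1L) %/% 2L
  sums <- rowsum(Y, i_blk)
  sums <- t(rowsum(t(sums), j_blk))
  cnt <- tcrossprod(as.numeric(table(i_blk)), as.numeric(table(j_blk)))
  unname(sums / cnt)
}

#' Multi-scale loss specification
#'
#' @param n_scales total number of scales S (>= 1); default 4.
#' @param base_loss per-scale loss; `"dice"`.
#' @return An object of class `multiscale_loss_spec` (pooling is fixed at
#'   2x2, stride 2).
#' @export
multiscale_loss_spec <- function(n_scales = 4, base_loss = "dice") {
  stopifnot(n_scales >= 1)
  structure(list(n_scales = as.integer(n_scales), pool_kernel = c(2L, 2L),
                 pool_stride = c(2L, 2L), base_loss = base_loss),
            class = "multiscale_loss_spec")
}

#' Multi-scale Dice loss
#'
#' The average of the per-scale Dice losses over `S` recursive 2x2
#' average-pooled versions of the prediction and the ground truth (scale 1 is
#' the input resolution).  Penalizes disagreement not only pixel-wise but at
#' multiple non-local scales, encouraging spatially consistent segmentations.
#'
#' @inheritParams dice_loss
#' @param spec a [multiscale_loss_spec].
#' @return The loss value in `[0, 1]`.
#' @export
multiscale_loss <- function(Y, G, spec = multiscale_loss_spec()) {
  if (!all(dim1(Y) == dim1(G)))
    stop("invalid-input: prediction and ground truth shapes differ")
  S <- spec$n_scales
  d <- dim1(Y)
  if (min(d[1:2]) < 2^(S - 1))
    stop("invalid-scale-count: spatial dims must be >= 2^(S-1)")
  total <- 0
  for (s in seq_len(S)) {
    total <- total + dice_loss(Y, G)
    if (s < S) { Y <- downscale(Y); G <- downscale(G) }
  }
  total / S
}

# binary 3D morphology with a 3x3x3 cube: min/max over the 27 shifts
morph3d <- function(mask, op = c("dilate", "erode")) {
  op <- match.arg(op)
  d <- dim(mask)
  out <- if (op == "dilate") array(0, d) else array(1, d)
  for (d3 in -1:1) for (d2 in -1:1) for (d1 in -1:1) {
    src <- list(valid_range(d[1], d1), valid_range(d[2], d2), valid_range(d[3], d3))
    dst <- list(valid_range(d[1], -d1), valid_range(d[2], -d2), valid_range(d[3], -d3))
    shifted <- if (op == "dilate") array(0, d) else array(1, d)
    shifted[dst[[1]], dst[[2]], dst[[3]]] <- mask[src[[1]], src[[2]], src[[3]]]
    out <- if (op == "dilate") pmax(out, shifted) else pmin(out, shifted)
  }
  out
}

valid_range <- function(n, off) max(1, 1 + off):min(n, n + off)

closing3d <- function(mask) morph3d(morph3d(mask, "dilate"), "erode")
opening3d <- function(mask) morph3d(morph3d(mask, "erode"), "dilate")

#' Largest 26-connected component of a binary 3D array
#'
#' @param mask binary 3D array.
#' @return Binary array keeping only the largest component (ties toward the
#'   first label encountered in array order); all zeros if the input is empty.
#' @export
largest_component <- function(mask) {
  lab <- cpp_label3d(array(as.integer(mask > 0.5), dim(mask)), dim(mask))
  n <- attr(lab, "n_components")
  if (n == 0L) return(array(0, dim(mask)))
  counts <- tabulate(lab[lab > 0L], nbins = n)
  (lab == which.max(counts)) * 1
}

#' 3D bounding boxes
#'
#' Axis-aligned boxes in both 0-based voxel indices and world mm (corners at
#' the extreme voxel centers mapped through the grid affine).
#'
#' @param lower_vox,upper_vox 0-based voxel index corners (lower <= upper).
#' @param grid the [image_grid] the indices refer to.
#' @param margin margin (mm) already applied, recorded for provenance.
#' @return An object of class `bounding_box3d`.
#' @export
bounding_box3d <- function(lower_vox, upper_vox, grid, margin = 0) {
  lower_vox <- as.numeric(lower_vox); upper_vox <- as.numeric(upper_vox)
  if (any(lower_vox > upper_vox))
    stop("invalid-input: lower corner must not exceed upper corner")
  u <- crossprod(grid$direction,
                 cbind(index_to_world(grid, lower_vox),
                       index_to_world(grid, upper_vox)))
  structure(list(lower_vox = lower_vox, upper_vox = upper_vox,
                 lower_mm = pmin(u[, 1], u[, 2]), upper_mm = pmax(u[, 1], u[, 2]),
                 grid = grid, margin = margin),
            class = "bounding_box3d")
}

#' @export
print.bounding_box3d <- function(x, ...) {
  cat("bounding_box3d: voxels [",
      paste(x$lower_vox, collapse = ","), "] .. [",
      paste(x$upper_vox, collapse = ","), "], margin", x$margin, "mm\n")
  invisible(x)
}

#' Coarse probability map to brain bounding box
#'
#' The deterministic localization post-processing: binarize the slice-stacked
#' coarse probability map, apply one 3D morphological closing then opening
#' (3x3x3 cube), keep the largest 26-connected component, fit the tight voxel
#' bounding box, map it into the original (non-downsampled) grid through
#' world coordinates, expand by a world-space margin per face and clip to the
#' image extent.
#'
#' @param prob 3D array of foreground probabilities (slice-stacked 2D
#'   predictions), or a [volume3d].
#' @param grid the [image_grid] `prob` lives on (ignored when `prob` is a
#'   [volume3d]).
#' @param threshold binarization threshold; default 0.5.
#' @param margin world-space margin in mm; default 5.
#' @param target_grid the original stack grid the box is mapped back to;
#'   defaults to `grid`.
#' @return A [bounding_box3d] on `target_grid`.
#' @export
coarse_to_bbox <- function(prob, grid = NULL, threshold = 0.5, margin = 5,
                           target_grid = NULL) {
  if (inherits(prob, "volume3d")) { grid <- prob$grid; prob <- prob$values }
  if (is.null(target_grid)) target_grid <- grid
  m <- opening3d(closing3d((prob >= threshold) * 1))
  m <- largest_component(m)
  if (sum(m) == 0) stop("no-detection: empty mask after morphology")
  idx <- which(m > 0.5, arr.ind = TRUE) - 1L
  lo <- apply(idx, 2, min)
  hi <- apply(idx, 2, max)
  # tight box in the source grid's frame coordinates, then margin in mm
  u <- crossprod(grid$direction, cbind(index_to_world(grid, lo),
                                       index_to_world(grid, hi)))
  lo_mm <- pmin(u[, 1], u[, 2]) - margin
  hi_mm <- pmax(u[, 1], u[, 2]) + margin
  # map to target-grid voxel indices and clip to extent
  w_lo <- drop(target_grid$direction %*% lo_mm)
  w_hi <- drop(target_grid$direction %*% hi_mm)
  v1 <- world_to_index(target_grid, w_lo)
  v2 <- world_to_index(target_grid, w_hi)
  lo_v <- pmax(0, floor(pmin(v1, v2)))
  hi_v <- pmin(target_grid$shape - 1, ceiling(pmax(v1, v2)))
  bounding_box3d(lo_v, hi_v, target_grid, margin = margin)
}

#' Prepare a stack for coarse localization
#'
#' Downsamples every slice in-plane to `size` x `size` (bilinear, aspect not
#' preserved; the per-axis scale factors are recorded so boxes can be mapped
#' back exactly), keeps the through-plane sampling unchanged, and normalizes
#' the whole stack by its mean and standard deviation.
#'
#' @param stack a [slice_stack].
#' @param size target in-plane size in pixels (>= 8); default 96.
#' @return A list of class `locnet_input`: `volume` (normalized, downsampled
#'   [volume3d]), `grid` (its grid), `source_grid`, and `scale` (per-axis
#'   in-plane scale factors).
#' @export
prepare_locnet_input <- function(stack, size = 96) {
  stopifnot(size >= 8)
  src <- stack_to_volume(stack)
  g <- src$grid
  # target grid spans the same world extent with size x size in-plane samples
  sp_new <- c(g$spacing[1] * g$shape[1] / size, g$spacing[2] * g$shape[2] / size,
              g$spacing[3])
  org <- index_to_world(g, c(-0.5, -0.5, 0)) +
    drop(g$direction %*% c(sp_new[1] / 2, sp_new[2] / 2, 0))
  tg <- image_grid(c(size, size, g$shape[3]), sp_new, org, g$direction)
  vol <- resample(src, tg, interpolation = "linear")
  v <- vol$values
  s <- stats::sd(v)
  if (s == 0) {
    warning("degenerate normalization: constant stack; returning zeros")
    v[] <- 0
  } else {
    v <- (v - mean(v)) / s
  }
  structure(list(volume = volume3d(v, tg), grid = tg, source_grid = g,
                 scale = g$spacing[1:2] / sp_new[1:2]),
            class = "locnet_input")
}
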