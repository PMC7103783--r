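#' Image grid geometry
#'
#' An `image_grid` describes a regular 3D sampling lattice: voxel counts,
#' physical spacing in mm, the world position of voxel `(0, 0, 0)` and an
#' orthonormal, right-handed direction matrix.  Voxel indices are 0-based and
#' refer to voxel centers, so the voxel-to-world map is the affine
#' `world = origin + direction %*% diag(spacing) %*% index`.
#'
#' @param shape integer vector of length 3, voxels per axis.
#' @param spacing numeric vector of length 3 (or scalar), mm per axis, all > 0.
#' @param origin world coordinates (mm) of voxel `(0, 0, 0)`.
#' @param direction 3x3 orthonormal matrix with determinant +1.
#' @return An object of class `image_grid`.
#' @examples
#' g <- image_grid(c(32, 32, 32), spacing = 0.8)
#' index_to_world(g, c(0, 0, 0))
#' @export
image_grid <- function(shape, spacing = c(1, 1, 1), origin = c(0, 0, 0),
                       direction = diag(3)) {
  shape <- as.integer(rep_len(shape, 3L))
  spacing <- as.numeric(rep_len(spacing, 3L))
  origin <- as.numeric(rep_len(origin, 3L))
  direction <- as.matrix(direction)
  if (any(shape < 1L)) stop("invalid-geometry: grid shape must be positive")
  if (any(!is.finite(spacing)) || any(spacing <= 0))
    stop("invalid-geometry: spacing must be strictly positive")
  if (max(abs(crossprod(direction) - diag(3))) > 1e-6)
    stop("invalid-geometry: direction matrix must be orthonormal")
  if (det(direction) < 0)
    stop("invalid-geometry: direction matrix must be right-handed (det +1)")
  structure(list(shape = shape, spacing = spacing, origin = origin,
                 direction = direction),
            class = "image_grid")
}

#' @export
print.image_grid <- function(x, ...) {
  cat("image_grid:", paste(x$shape, collapse = " x "),
      "voxels, spacing", paste(signif(x$spacing, 4), collapse = "/"),
      "mm\n  origin", paste(signif(x$origin, 4), collapse = ", "), "mm\n")
  invisible(x)
}

#' Map voxel indices to world coordinates (and back)
#'
#' Indices are 0-based voxel centers; world coordinates are mm.  `idx` may be a
#' length-3 vector or a 3-row matrix of points.
#'
#' @param grid an [image_grid].
#' @param idx,world length-3 vector or 3 x n matrix.
#' @return A vector or 3 x n matrix of mapped coordinates.
#' @export
index_to_world <- function(grid, idx) {
  idx <- if (is.matrix(idx)) idx else matrix(idx, nrow = 3)
  out <- grid$direction %*% (idx * grid$spacing) + grid$origin
  if (ncol(out) == 1L) drop(out) else out
}

#' @rdname index_to_world
#' @export
world_to_index <- function(grid, world) {
  world <- if (is.matrix(world)) world else matrix(world, nrow = 3)
  out <- (crossprod(grid$direction, world - grid$origin)) / grid$spacing
  if (ncol(out) == 1L) drop(out) else out
}

# 4x4 homogeneous voxel->world affine of a grid
grid_affine <- function(grid) {
  rbind(cbind(grid$direction %*% diag(grid$spacing), grid$origin), c(0, 0, 0, 1))
}

#' Rigid transforms
#'
#' A proper rigid transform: `p -> rotation %*% p + translation`, rotation a
#' 3x3 orthonormal matrix with determinant +1, translation in mm.
#'
#' @param rotation 3x3 rotation matrix.
#' @param translation length-3 vector, mm.
#' @return An object of class `rigid_transform`.
#' @seealso [rigid_from_params()], [rigid_compose()], [rigid_invert()]
#' @export
rigid_transform <- function(rotation = diag(3), translation = c(0, 0, 0)) {
  rotation <- as.matrix(rotation)
  if (max(abs(crossprod(rotation) - diag(3))) > 1e-6 || det(rotation) < 0)
    stop("invalid-geometry: rotation must be proper orthonormal")
  structure(list(rotation = rotation, translation = as.numeric(translation)),
            class = "rigid_transform")
}

#' @export
print.rigid_transform <- function(x, ...) {
  p <- rigid_params(x)
  cat(sprintf("rigid_transform: rot (%.3f, %.3f, %.3f) deg, trans (%.3f, %.3f, %.3f) mm\n",
              p[1], p[2], p[3], p[4], p[5], p[6]))
  invisible(x)
}

rot_x <- function(a) matrix(c(1, 0, 0, 0, cos(a), sin(a), 0, -sin(a), cos(a)), 3)
rot_y <- function(b) matrix(c(cos(b), 0, -sin(b), 0, 1, 0, sin(b), 0, cos(b)), 3)
rot_z <- function(c) matrix(c(cos(c), sin(c), 0, -sin(c), cos(c), 0, 0, 0, 1), 3)

#' Six-parameter rigid parameterization
#'
#' Transforms are parameterized as `(rx, ry, rz, tx, ty, tz)` with rotations in
#' degrees (intrinsic Z-Y-X Euler angles, `R = Rz(rz) Ry(ry) Rx(rx)`) and
#' translations in mm, matching the units conventionally reported for per-slice
#' fetal head motion.
#'
#' @param params numeric vector `(rx, ry, rz, tx, ty, tz)`; degrees and mm.
#' @param transform a [rigid_transform].
#' @param center optional rotation center (mm); the rotation is applied about
#'   this point rather than the world origin.
#' @return `rigid_from_params()` a `rigid_transform`; `rigid_params()` the
#'   6-parameter vector.
#' @export
rigid_from_params <- function(params, center = NULL) {
  a <- params[1:3] * pi / 180
  R <- rot_z(a[3]) %*% rot_y(a[2]) %*% rot_x(a[1])
  t <- as.numeric(params[4:6])
  if (!is.null(center)) t <- t + as.numeric(center) - drop(R %*% as.numeric(center))
  rigid_transform(R, t)
}

#' @rdname rigid_from_params
#' @export
rigid_params <- function(transform) {
  R <- transform$rotation
  ry <- asin(max(-1, min(1, -R[3, 1])))
  rx <- atan2(R[3, 2], R[3, 3])
  rz <- atan2(R[2, 1], R[1, 1])
  c(rx, ry, rz) * 180 / pi -> ang
  c(ang, transform$translation)
}

#' Compose and invert rigid transforms
#'
#' `rigid_compose(a, b)` applies `b` first, then `a`:
#' `(a o b)(p) = a(b(p))`.
#'
#' @param a,b,transform [rigid_transform] objects.
#' @return A `rigid_transform`.
#' @export
rigid_compose <- function(a, b) {
  rigid_transform(a$rotation %*% b$rotation,
                  drop(a$rotation %*% b$translation) + a$translation)
}

#' @rdname rigid_compose
#' @export
rigid_invert <- function(transform) {
  Rt <- t(transform$rotation)
  rigid_transform(Rt, -drop(Rt %*% transform$translation))
}

#' Apply a rigid transform to world points
#'
#' @param transform a [rigid_transform].
#' @param points length-3 vector or 3 x n matrix of world points (mm).
#' @return Transformed points, same shape as the input.
#' @export
apply_transform <- function(transform, points) {
  pts <- if (is.matrix(points)) points else matrix(points, nrow = 3)
  out <- transform$rotation %*% pts + transform$translation
  if (ncol(out) == 1L) drop(out) else out
}

#' Scalar volumes and mask volumes
#'
#' `volume3d` couples a 3D scalar array with an [image_grid]; `mask_volume`
#' additionally constrains values to `[0, 1]` and records whether the mask is
#' hard (binary) or soft (probabilistic).
#'
#' @param values 3D numeric array matching `grid$shape`; all finite.
#' @param grid an [image_grid].
#' @param binary flag: `TRUE` if values are thresholded 0/1.
#' @return An object of class `volume3d` or `mask_volume`.
#' @export
volume3d <- function(values, grid) {
  values <- as.array(values)
  if (!identical(dim(values), NULL) && length(dim(values)) != 3L)
    stop("invalid-geometry: values must be a 3D array")
  if (!all(dim(values) == grid$shape))
    stop("invalid-geometry: values shape does not match grid shape")
  if (any(!is.finite(values))) stop("invalid-geometry: non-finite voxel values")
  structure(list(values = values, grid = grid), class = "volume3d")
}

#' @rdname volume3d
#' @export
mask_volume <- function(values, grid, binary = TRUE) {
  v <- volume3d(values, grid)
  if (min(v$values) < 0 || max(v$values) > 1)
    stop("invalid-geometry: mask values must lie in [0, 1]")
  structure(list(values = v$values, grid = grid, binary = isTRUE(binary)),
            class = c("mask_volume", "volume3d"))
}

#' @export
print.volume3d <- function(x, ...) {
  cat(if (inherits(x, "mask_volume")) "mask_volume" else "volume3d", "on ")
  print(x$grid)
  cat("  range [", signif(min(x$values), 4), ",", signif(max(x$values), 4), "]\n")
  invisible(x)
}

#' 2D slices and slice stacks
#'
#' A `slice2d` is one acquired 2D image: pixel intensities, in-plane spacing and
#' slice thickness in mm, a [rigid_transform] mapping the slice's local frame
#' (pixel `(i, j)` at local point `(i*s, j*s, 0)`, 0-based) into world space, a
#' same-shape binary mask, its index within the stack, the stack identifier and
#' an inlier flag.  A `slice_stack` is the ordered, interleaved collection.
#'
#' @param pixels 2D numeric array of intensities.
#' @param in_plane_spacing in-plane pixel spacing, mm (> 0).
#' @param thickness slice thickness, mm (> 0).
#' @param transform a [rigid_transform] placing the slice plane in world space.
#' @param mask 2D binary array, same shape as `pixels`; defaults to all ones.
#' @param slice_index 0-based index within the stack.
#' @param stack_id stack identifier.
#' @param inlier logical inlier flag.
#' @return A `slice2d` object.
#' @export
slice2d <- function(pixels, in_plane_spacing, thickness, transform,
                    mask = NULL, slice_index = 0L, stack_id = "stack",
                    inlier = TRUE) {
  pixels <- as.matrix(pixels)
  if (is.null(mask)) mask <- array(1, dim(pixels))
  mask <- as.matrix(mask)
  if (!all(dim(mask) == dim(pixels)))
    stop("invalid-geometry: mask shape must equal pixels shape")
  if (any(in_plane_spacing <= 0) || thickness <= 0)
    stop("invalid-geometry: spacing and thickness must be positive")
  structure(list(pixels = pixels, in_plane_spacing = in_plane_spacing[1],
                 thickness = thickness, transform = transform,
                 mask = (mask > 0.5) * 1, slice_index = as.integer(slice_index),
                 stack_id = as.character(stack_id), inlier = isTRUE(inlier)),
            class = "slice2d")
}

#' @param slices list of [slice2d] sharing `stack_id`, indices `0..K-1`.
#' @param interleave interleave factor M >= 1.
#' @param source_path optional provenance string.
#' @rdname slice2d
#' @export
slice_stack <- function(slices, interleave = 1L, source_path = NULL) {
  idx <- vapply(slices, `[[`, integer(1), "slice_index")
  if (!identical(sort(idx), seq_along(slices) - 1L))
    stop("invalid-geometry: slice_index values must be 0..K-1 without gaps")
  sp <- vapply(slices, `[[`, numeric(1), "in_plane_spacing")
  th <- vapply(slices, `[[`, numeric(1), "thickness")
  if (diff(range(sp)) > 1e-9 || diff(range(th)) > 1e-9)
    stop("invalid-geometry: slices must share in-plane spacing and thickness")
  structure(list(slices = slices[order(idx)], interleave = as.integer(interleave),
                 source_path = source_path),
            class = "slice_stack")
}

#' @export
print.slice_stack <- function(x, ...) {
  s <- x$slices[[1]]
  cat(sprintf("slice_stack '%s': %d slices of %d x %d px, %.3g mm in-plane, %.3g mm thick, interleave %d\n",
              s$stack_id, length(x$slices), nrow(s$pixels), ncol(s$pixels),
              s$in_plane_spacing, s$thickness, x$interleave))
  invisible(x)
}

# grid of a stack viewed as a nominal 3D volume (slice axis = 3rd axis)
stack_grid <- function(stack) {
  s <- stack$slices[[1]]
  image_grid(c(dim(s$pixels), length(stack$slices)),
             spacing = c(s$in_plane_spacing, s$in_plane_spacing, s$thickness),
             origin = s$transform$translation,
             direction = s$transform$rotation)
}

#' View a stack as a nominal 3D volume
#'
#' Stacks the slice pixel arrays along the slice axis using the geometry of the
#' first slice; per-slice motion is ignored, so this is the "as acquired"
#' volume used for volume-to-volume alignment and intensity correction.
#'
#' @param stack a [slice_stack].
#' @param what `"pixels"` or `"mask"`.
#' @return A [volume3d] (or [mask_volume] for `what = "mask"`).
#' @export
stack_to_volume <- function(stack, what = c("pixels", "mask")) {
  what <- match.arg(what)
  g <- stack_grid(stack)
  arr <- array(0, g$shape)
  for (k in seq_along(stack$slices)) arr[, , k] <- stack$slices[[k]][[what]]
  if (what == "mask") mask_volume(arr, g) else volume3d(arr, g)
}

#' Resample a volume onto a target grid
#'
#' Samples `volume` at the target voxel centers: the value at target world
#' point `w` is the interpolated source value at `transform(w)` (the transform
#' maps target-world points into source-world points, the usual resampling
#' convention).  Points outside the source extent receive 0.
#'
#' @param volume a [volume3d].
#' @param target an [image_grid].
#' @param transform a [rigid_transform] mapping target world to source world;
#'   identity by default.
#' @param interpolation `"nearest"`, `"linear"` or `"bspline"` (cubic spline).
#' @return A [volume3d] on `target`.
#' @export
resample <- function(volume, target, transform = rigid_transform(),
                     interpolation = c("linear", "nearest", "bspline")) {
  interpolation <- match.arg(interpolation)
  method <- match(interpolation, c("nearest", "linear", "bspline")) - 1L
  g <- volume$grid
  vals <- cpp_resample(volume$values, g$shape, g$direction, g$spacing, g$origin,
                       target$shape, target$direction, target$spacing,
                       target$origin, transform$rotation, transform$translation,
                       method)
  volume3d(vals, target)
}
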