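#' NIfTI input/output
#'
#' Volumes and masks are read and written through the NIfTI-1 sform affine,
#' interpreted as-is (RAS+ convention), so voxel-to-world geometry round-trips
#' bit-faithfully.  A grid requires an orthonormal, right-handed affine; shear
#' or flip in the sform signals an error.
#'
#' @param path path to a `.nii` / `.nii.gz` file.
#' @param volume a [volume3d] or [mask_volume].
#' @return `read_volume()` a [volume3d]; `read_mask()` a [mask_volume];
#'   `write_volume()` the path, invisibly.
#' @export
read_volume <- function(path) {
  im <- RNifti::readNifti(path)
  aff <- RNifti::xform(im)
  volume3d(array(as.numeric(im), dim(im)[1:3]), grid_from_affine(aff, dim(im)[1:3]))
}

#' @rdname read_volume
#' @export
read_mask <- function(path) {
  v <- read_volume(path)
  mask_volume((v$values > 0.5) * 1, v$grid)
}

#' @rdname read_volume
#' @export
write_volume <- function(volume, path) {
  im <- RNifti::asNifti(volume$values)
  aff <- grid_affine(volume$grid)
  im <- RNifti::`sform<-`(im, structure(aff, code = 2L))
  RNifti::writeNifti(im, path)
  invisible(path)
}

grid_from_affine <- function(aff, shape) {
  M <- aff[1:3, 1:3]
  spacing <- sqrt(colSums(M^2))
  if (any(spacing <= 0)) stop("invalid-geometry: degenerate NIfTI affine")
  direction <- sweep(M, 2, spacing, "/")
  if (max(abs(crossprod(direction) - diag(3))) > 1e-4)
    stop("invalid-geometry: sheared NIfTI affine is not supported")
  if (det(direction) < 0)
    stop("invalid-geometry: left-handed NIfTI affine is not supported")
  # re-orthonormalize to numerical precision
  s <- svd(direction)
  direction <- s$u %*% t(s$v)
  image_grid(shape, spacing, aff[1:3, 4], direction)
}

#' Read a NIfTI volume as a stack of 2D slices
#'
#' The slice-select axis is taken as the axis with the largest spacing (headers
#' rarely mark it explicitly); the volume is permuted so that axis comes last,
#' then each 2D plane becomes a [slice2d] whose transform is implied by the
#' file's affine.  An optional companion mask volume supplies per-slice masks.
#'
#' @param path path to the stack NIfTI file.
#' @param mask_path optional path to a binary mask NIfTI on the same grid.
#' @param stack_id identifier; defaults to the file name.
#' @param interleave interleave factor M recorded on the stack.
#' @return A [slice_stack].
#' @export
read_stack <- function(path, mask_path = NULL, stack_id = NULL, interleave = 2L) {
  v <- read_volume(path)
  m <- if (!is.null(mask_path)) read_mask(mask_path) else NULL
  if (is.null(stack_id)) stack_id <- sub("\\.nii(\\.gz)?$", "", basename(path))
  volume_to_stack(v, mask = m, stack_id = stack_id, interleave = interleave,
                  source_path = path)
}

#' @param volume a [volume3d] to reinterpret as a stack.
#' @param mask optional [mask_volume] on the same grid.
#' @param source_path provenance string stored on the stack.
#' @rdname read_stack
#' @export
volume_to_stack <- function(volume, mask = NULL, stack_id = "stack",
                            interleave = 2L, source_path = NULL) {
  g <- volume$grid
  ax <- which.max(g$spacing)
  # cyclic permutation keeps the permuted direction matrix right-handed
  perm <- switch(ax, c(2L, 3L, 1L), c(3L, 1L, 2L), c(1L, 2L, 3L))
  vals <- aperm(volume$values, perm)
  mvals <- if (!is.null(mask)) aperm(mask$values, perm) else NULL
  dirp <- g$direction[, perm, drop = FALSE]
  spp <- g$spacing[perm]
  if (abs(spp[1] - spp[2]) > 1e-6)
    warning("anisotropic in-plane spacing; using the first in-plane axis spacing")
  K <- dim(vals)[3]
  slices <- vector("list", K)
  for (k in seq_len(K)) {
    tr <- rigid_transform(dirp, g$origin + dirp[, 3] * spp[3] * (k - 1))
    slices[[k]] <- slice2d(vals[, , k], in_plane_spacing = spp[1],
                           thickness = spp[3], transform = tr,
                           mask = if (is.null(mvals)) NULL else mvals[, , k],
                           slice_index = k - 1L, stack_id = stack_id)
  }
  slice_stack(slices, interleave = interleave, source_path = source_path)
}
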