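#' Slice point-spread-function specification
#'
#' The acquisition of one thick 2D slice from the underlying 3D anatomy is
#' modelled as a slice-aligned anisotropic Gaussian blur followed by in-plane
#' sampling.  `make_psf()` builds the standard single-shot fast-spin-echo
#' approximation: the in-plane full width at half maximum is a fixed multiple
#' of the pixel spacing and the through-plane FWHM equals the slice thickness,
#' each converted to a standard deviation via `sigma = FWHM / (2 sqrt(2 ln 2))`.
#' The covariance is diagonal in the slice-aligned frame.
#'
#' @param in_plane_spacing in-plane pixel spacing, mm (> 0).
#' @param thickness slice thickness, mm (> 0).
#' @param inplane_fwhm_factor in-plane FWHM as a multiple of the pixel spacing.
#' @param truncation_radius kernel cutoff in standard deviations (Mahalanobis).
#' @return An object of class `psf_spec` with fields `covariance` (3x3, mm^2,
#'   slice-aligned frame) and `truncation_radius`.
#' @examples
#' psf <- make_psf(1.0, 3.0)
#' sqrt(psf$covariance[3, 3])  # through-plane sigma = 3 / (2 sqrt(2 ln 2))
#' @export
make_psf <- function(in_plane_spacing, thickness, inplane_fwhm_factor = 1.2,
                     truncation_radius = 3) {
  if (in_plane_spacing <= 0 || thickness <= 0)
    stop("invalid-geometry: spacings must be positive")
  k <- 2 * sqrt(2 * log(2))
  s_in <- inplane_fwhm_factor * in_plane_spacing / k
  s_th <- thickness / k
  psf_spec(diag(c(s_in^2, s_in^2, s_th^2)), truncation_radius)
}

#' @param covariance 3x3 symmetric positive-definite matrix (mm^2) in the
#'   slice-aligned frame.
#' @rdname make_psf
#' @export
psf_spec <- function(covariance, truncation_radius = 3) {
  covariance <- as.matrix(covariance)
  if (max(abs(covariance - t(covariance))) > 1e-12)
    stop("invalid-geometry: PSF covariance must be symmetric")
  if (any(eigen(covariance, symmetric = TRUE, only.values = TRUE)$values <= 0))
    stop("invalid-geometry: PSF covariance must be positive definite")
  structure(list(covariance = covariance, truncation_radius = truncation_radius),
            class = "psf_spec")
}

#' Slice acquisition geometry
#'
#' The in-plane grid, thickness, and rigid world transform of one slice;
#' everything the forward operator needs besides the PSF.
#'
#' @param shape 2D pixel counts.
#' @param in_plane_spacing mm (> 0).
#' @param thickness mm (> 0).
#' @param transform a [rigid_transform]: slice frame to world.
#' @return An object of class `slice_geometry`.
#' @export
slice_geometry <- function(shape, in_plane_spacing, thickness,
                           transform = rigid_transform()) {
  if (in_plane_spacing <= 0 || thickness <= 0)
    stop("invalid-geometry: spacings must be positive")
  structure(list(shape = as.integer(rep_len(shape, 2L)),
                 in_plane_spacing = in_plane_spacing, thickness = thickness,
                 transform = transform),
            class = "slice_geometry")
}

# geometry of an existing slice2d
geometry_of <- function(slice) {
  slice_geometry(dim(slice$pixels), slice$in_plane_spacing, slice$thickness,
                 slice$transform)
}

# PSF covariance rotated from the slice-aligned frame into world coordinates
psf_world_cov <- function(psf, geom) {
  R <- geom$transform$rotation
  R %*% psf$covariance %*% t(R)
}

#' Matrix-free slice forward operator and adjoint
#'
#' `forward_project()` applies the acquisition operator A_k: every slice pixel
#' receives a normalized, oriented-Gaussian-weighted sum of volume voxel values,
#' the PSF covariance being rotated from the slice frame into world coordinates
#' by the slice transform.  Kernel weights are evaluated at voxel centers,
#' truncated at the PSF's Mahalanobis cutoff, and renormalized over the
#' in-extent support so that constants project to constants.
#' `adjoint_project()` is its exact adjoint with respect to the Euclidean inner
#' products (the identical weights are redistributed), which iterative
#' least-squares solvers require.  No system matrix is ever materialized.
#'
#' @param x a [volume3d] (the high-resolution iterate).
#' @param geom a `slice_geometry` (or a [slice2d], whose geometry is used).
#' @param psf a `psf_spec`.
#' @param y 2D numeric array of slice values (for the adjoint).
#' @param target an [image_grid] for the adjoint output.
#' @return `forward_project()` a 2D array of simulated slice intensities;
#'   `adjoint_project()` a [volume3d] on `target`.
#' @export
forward_project <- function(x, geom, psf) {
  if (inherits(geom, "slice2d")) geom <- geometry_of(geom)
  g <- x$grid
  out <- cpp_project(x$values, g$shape, g$direction, g$spacing, g$origin,
                     geom$transform$rotation, geom$transform$translation,
                     geom$in_plane_spacing, geom$shape[1], geom$shape[2],
                     psf_world_cov(psf, geom), psf$truncation_radius,
                     0L, matrix(0, 1, 1))
  if (attr(out, "n_support") == 0L)
    stop("empty-projection: slice has no spatial overlap with the volume")
  attr(out, "n_support") <- NULL
  out
}

#' @rdname forward_project
#' @export
adjoint_project <- function(y, geom, psf, target) {
  if (inherits(geom, "slice2d")) geom <- geometry_of(geom)
  y <- as.matrix(y)
  if (!all(dim(y) == geom$shape))
    stop("invalid-geometry: slice data shape does not match geometry")
  out <- cpp_project(numeric(0), target$shape, target$direction, target$spacing,
                     target$origin, geom$transform$rotation,
                     geom$transform$translation, geom$in_plane_spacing,
                     geom$shape[1], geom$shape[2],
                     psf_world_cov(psf, geom), psf$truncation_radius,
                     1L, y)
  if (attr(out, "n_support") == 0L)
    stop("empty-projection: slice has no spatial overlap with the target grid")
  volume3d(as.array(out), target)
}

#' Discrete PSF kernel weights at volume voxel centers
#'
#' Mainly a diagnostic: returns the normalized weights one slice pixel assigns
#' to the voxels of `grid`, i.e. one row of the (never materialized) system
#' matrix A_k.
#'
#' @inheritParams forward_project
#' @param grid the volume [image_grid].
#' @param pixel 0-based `(i, j)` pixel index.
#' @return 3D array of non-negative weights summing to 1 (if any support).
#' @export
psf_discrete_kernel <- function(grid, geom, psf, pixel = c(0, 0)) {
  if (inherits(geom, "slice2d")) geom <- geometry_of(geom)
  y <- matrix(0, geom$shape[1], geom$shape[2])
  y[pixel[1] + 1L, pixel[2] + 1L] <- 1
  out <- cpp_project(numeric(0), grid$shape, grid$direction, grid$spacing,
                     grid$origin, geom$transform$rotation,
                     geom$transform$translation, geom$in_plane_spacing,
                     geom$shape[1], geom$shape[2],
                     psf_world_cov(psf, geom), psf$truncation_radius,
                     1L, y)
  as.array(out)
}
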