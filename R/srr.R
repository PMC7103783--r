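#' Reconstruction configuration
#'
#' Scalar hyperparameters of the outlier-robust super-resolution estimator and
#' its iterative motion-correction loop.
#'
#' @param alpha Tikhonov regularization weight on the spacing-scaled gradient
#'   (>= 0); default 0.01.
#' @param beta_schedule inlier similarity thresholds, one per outer cycle;
#'   default `c(0.5, 0.65, 0.8)` (increasingly strict as the iterate sharpens).
#'   For NCC each value must lie in (-1, 1].
#' @param n_cycles outer two-step cycles; must equal `length(beta_schedule)`.
#' @param similarity slice similarity measure; `"NCC"`.
#' @param recon_spacing isotropic reconstruction spacing, mm; default 0.8.
#' @param sda_sigma Gaussian width of the scattered-data approximation.
#' @param sda_sigma_unit `"voxel"` or `"mm"`.
#' @param lsq_max_iter,lsq_tol iterative least-squares solver cap and relative
#'   residual tolerance.
#' @param mask_threshold binarization threshold for soft masks.
#' @param psf_inplane_fwhm_factor in-plane PSF FWHM as a multiple of pixel
#'   spacing.
#' @param psf_truncation PSF kernel cutoff in standard deviations.
#' @param grid_margin margin (mm) added around the union of aligned stack
#'   masks when building the reconstruction grid; default 10.
#' @param svr_levels multi-resolution levels for slice-to-volume registration.
#' @param svr_reference registration reference policy.  `"loso-final"`
#'   (default): slices register against the full previous iterate in early
#'   cycles, but in the final cycle each slice registers against a reference
#'   reconstructed from the other stacks only — removing the
#'   self-consistency bias of registering a slice to a volume that contains
#'   its own (mis-posed) contribution, once the pose estimates feeding that
#'   reference are accurate.  `"loso"`: leave-one-stack-out references in
#'   every cycle; `"full"`: always the full iterate.  Inlier selection
#'   always uses the full iterate.
#' @param svr_steps list of per-cycle line-search half-widths
#'   `c(in-plane rotation deg, in-plane translation mm, tilt deg,
#'   through-plane mm)`; the trust region for the weakly identified
#'   through-plane parameters widens as the reference sharpens.  The last
#'   entry is reused beyond its length.
#' @param svr_passes coordinate-descent passes per registration level.
#' @param v2v_levels multi-resolution decimation factors for volume-to-volume
#'   registration.
#' @return An object of class `srr_config`.
#' @export
srr_config <- function(alpha = 0.01, beta_schedule = c(0.5, 0.65, 0.8),
                       n_cycles = length(beta_schedule), similarity = "NCC",
                       recon_spacing = 0.8, sda_sigma = 1,
                       sda_sigma_unit = "voxel", lsq_max_iter = 100,
                       lsq_tol = 1e-6, mask_threshold = 0.5,
                       psf_inplane_fwhm_factor = 1.2, psf_truncation = 3,
                       grid_margin = 10, svr_levels = c(2, 1),
                       svr_reference = c("loso-final", "loso", "full"),
                       svr_steps = list(c(2.5, 2, 1, 1),
                                        c(2.5, 2, 1.5, 1.5),
                                        c(2, 1.5, 2, 1.5)),
                       svr_passes = 3,
                       v2v_levels = c(4, 2, 1)) {
  svr_reference <- match.arg(svr_reference)
  if (alpha < 0) stop("invalid-config: alpha must be >= 0")
  if (n_cycles != length(beta_schedule))
    stop("invalid-config: n_cycles must equal length(beta_schedule)")
  if (identical(toupper(similarity), "NCC") && length(beta_schedule) &&
      (any(beta_schedule <= -1) || any(beta_schedule > 1)))
    stop("invalid-config: NCC thresholds must lie in (-1, 1]")
  structure(list(alpha = alpha, beta_schedule = beta_schedule,
                 n_cycles = as.integer(n_cycles), similarity = similarity,
                 recon_spacing = recon_spacing, sda_sigma = sda_sigma,
                 sda_sigma_unit = sda_sigma_unit,
                 lsq_max_iter = as.integer(lsq_max_iter), lsq_tol = lsq_tol,
                 mask_threshold = mask_threshold,
                 psf_inplane_fwhm_factor = psf_inplane_fwhm_factor,
                 psf_truncation = psf_truncation, grid_margin = grid_margin,
                 svr_levels = svr_levels, svr_reference = svr_reference,
                 svr_steps = svr_steps, svr_passes = svr_passes,
                 v2v_levels = v2v_levels),
            class = "srr_config")
}

psf_for <- function(slice, config) {
  make_psf(slice$in_plane_spacing, slice$thickness,
           inplane_fwhm_factor = config$psf_inplane_fwhm_factor,
           truncation_radius = config$psf_truncation)
}

#' Masked slice similarity (NCC)
#'
#' Normalized cross-correlation between an acquired slice and its simulated
#' counterpart, computed over masked pixels only: the zero-mean, unit-variance
#' normalized dot product, in `[-1, 1]`.
#'
#' @param y a [slice2d] or 2D numeric array.
#' @param y_sim 2D numeric array of the same shape (e.g. the forward
#'   projection of the current iterate).
#' @param mask 2D binary array; at least 2 positive pixels.
#' @return NCC value.  A constant masked region signals
#'   `undefined-similarity`; callers treat the slice as an outlier.
#' @export
slice_similarity <- function(y, y_sim, mask = NULL) {
  if (inherits(y, "slice2d")) {
    if (is.null(mask)) mask <- y$mask
    y <- y$pixels
  }
  if (is.null(mask)) mask <- array(1, dim(y))
  if (!all(dim(y) == dim(y_sim)) || !all(dim(y) == dim(mask)))
    stop("invalid-input: slice, simulation and mask shapes must agree")
  keep <- mask > 0.5
  if (sum(keep) < 2) stop("undefined-similarity: fewer than 2 masked pixels")
  a <- y[keep] - mean(y[keep])
  b <- y_sim[keep] - mean(y_sim[keep])
  den <- sqrt(sum(a^2) * sum(b^2))
  if (den == 0) stop("undefined-similarity: constant masked region")
  sum(a * b) / den
}

#' Inlier-slice selection by similarity thresholding
#'
#' Every slice is forward-projected from the previous high-resolution iterate;
#' its similarity to the acquisition is evaluated over the pixels inside both
#' the slice mask and the slice-projected high-resolution brain mask, and
#' slices at or above the threshold `beta` form the inlier set that the
#' reconstruction step uses (complete rejection of the rest).
#'
#' @param slices list of [slice2d].
#' @param x_prev the previous iterate, a [volume3d].
#' @param mask_hr high-resolution [mask_volume] constraining the similarity.
#' @param psf a `psf_spec` (or `NULL` to derive one per slice from its
#'   geometry).
#' @param beta similarity threshold.
#' @param config an [srr_config] (used when `psf` is `NULL`).
#' @return An object of class `inlier_set`: a data frame of
#'   `stack_id, slice_index, similarity, member, reason` plus the `beta` used.
#' @export
select_inliers <- function(slices, x_prev, mask_hr, psf = NULL, beta,
                           config = srr_config()) {
  n <- length(slices)
  sim <- rep(NA_real_, n)
  reason <- rep("", n)
  for (i in seq_len(n)) {
    sl <- slices[[i]]
    p <- if (is.null(psf)) psf_for(sl, config) else psf
    res <- tryCatch({
      ysim <- forward_project(x_prev, sl, p)
      pm <- forward_project(volume3d(mask_hr$values, mask_hr$grid), sl, p)
      m <- (sl$mask > 0.5) & (pm >= 0.5)
      slice_similarity(sl$pixels, ysim, m * 1)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      reason[i] <- conditionMessage(res)
    } else {
      sim[i] <- res
    }
  }
  member <- !is.na(sim) & sim >= beta
  reason[!member & reason == ""] <- "similarity below beta"
  reason[member] <- "inlier"
  out <- data.frame(
    stack_id = vapply(slices, `[[`, character(1), "stack_id"),
    slice_index = vapply(slices, `[[`, integer(1), "slice_index"),
    similarity = sim, member = member, reason = reason,
    stringsAsFactors = FALSE)
  structure(list(table = out, beta = beta), class = "inlier_set")
}

#' @export
print.inlier_set <- function(x, ...) {
  cat(sprintf("inlier_set: %d / %d slices at beta = %.3g\n",
              sum(x$table$member), nrow(x$table), x$beta))
  invisible(x)
}

#' Outlier-robust super-resolution reconstruction (one solve)
#'
#' Minimizes the Tikhonov-regularized least-squares objective
#' `sum_k 0.5 ||y_k - A_k x||^2 + (alpha/2) ||grad x||^2` over the inlier
#' slices, with `A_k` the matrix-free oriented-Gaussian slice operator and
#' `grad` the spacing-scaled forward-difference gradient stacked over the
#' three axes.  The stacked system is solved by LSQR; non-negativity is
#' enforced by clipping negative values once after convergence.
#'
#' @param inliers list of [slice2d] (the inlier set).
#' @param target reconstruction [image_grid].
#' @param psf a `psf_spec`, or `NULL` to derive per-slice PSFs from geometry.
#' @param alpha regularization weight (>= 0).
#' @param lsq_max_iter,lsq_tol solver cap and relative residual tolerance.
#' @param x0 optional warm-start [volume3d] on `target`.
#' @param config an [srr_config] supplying PSF constants when `psf` is `NULL`.
#' @return A non-negative [volume3d] with attribute `"solver"` holding the
#'   iteration log (residual norms are non-increasing; objective values are
#'   `0.5 * rnorm^2` before clipping).
#' @export
solve_srr <- function(inliers, target, psf = NULL, alpha = 0.01,
                      lsq_max_iter = 100, lsq_tol = 1e-6, x0 = NULL,
                      config = srr_config()) {
  if (length(inliers) == 0L)
    stop("no-inliers: empty inlier set; relax beta (e.g. by 0.15) or abort")
  if (alpha < 0) stop("invalid-config: alpha must be >= 0")
  psfs <- lapply(inliers, function(sl) if (is.null(psf)) psf_for(sl, config) else psf)
  npix <- vapply(inliers, function(sl) length(sl$pixels), integer(1))
  nvox <- prod(target$shape)
  sqa <- sqrt(alpha)

  # batched slice-operator arguments, fixed for the whole solve
  nsl <- length(inliers)
  srots <- do.call(cbind, lapply(inliers, function(sl) sl$transform$rotation))
  strs <- vapply(inliers, function(sl) sl$transform$translation, numeric(3))
  ssps <- vapply(inliers, `[[`, numeric(1), "in_plane_spacing")
  nxs <- vapply(inliers, function(sl) dim(sl$pixels)[1], integer(1))
  nys <- vapply(inliers, function(sl) dim(sl$pixels)[2], integer(1))
  covs <- do.call(cbind, lapply(seq_len(nsl), function(k)
    psf_world_cov(psfs[[k]], geometry_of(inliers[[k]]))))
  trunc <- psfs[[1]]$truncation_radius
  g <- target
  npix_total <- sum(npix)

  aprod <- function(xv) {
    ys <- cpp_project_batch(xv, g$shape, g$direction, g$spacing, g$origin,
                            srots, strs, ssps, nxs, nys, covs, trunc,
                            0L, numeric(0))
    if (sqa > 0) {
      x <- volume3d(array(xv, g$shape), g)
      c(ys, sqa * unlist(gradient_op(x)))
    } else ys
  }
  atprod <- function(yv) {
    acc <- cpp_project_batch(numeric(0), g$shape, g$direction, g$spacing,
                             g$origin, srots, strs, ssps, nxs, nys, covs,
                             trunc, 1L, yv[seq_len(npix_total)])
    if (sqa > 0) {
      gr <- lapply(1:3, function(a)
        array(yv[(npix_total + (a - 1) * nvox + 1):(npix_total + a * nvox)],
              g$shape))
      acc <- acc + sqa * adjoint_gradient_op(gr, g)$values
    }
    as.numeric(acc)
  }

  b <- c(unlist(lapply(inliers, function(sl) as.numeric(sl$pixels))),
         if (sqa > 0) numeric(3L * nvox) else numeric(0))
  fit <- lsqr_solve(aprod, atprod, b, n_model = nvox,
                    max_iter = lsq_max_iter, tol = lsq_tol,
                    x0 = if (is.null(x0)) NULL else as.numeric(x0$values))
  vals <- array(pmax(fit$x, 0), target$shape)
  out <- volume3d(vals, target)
  attr(out, "solver") <- list(iterations = fit$iterations, rnorms = fit$rnorms,
                              objective = 0.5 * fit$rnorms^2,
                              reason = fit$reason)
  out
}
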