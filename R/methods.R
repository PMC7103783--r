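#' @export
print.fetal_srr <- function(x, ...) {
  cat("Fetal brain super-resolution reconstruction\n")
  cat("  target stack:", x$target_stack_id, "\n")
  cat("  grid:", paste(x$grid$shape, collapse = " x "), "voxels at",
      signif(x$grid$spacing[1], 3), "mm isotropic\n")
  cat("  slices:", length(x$slices), "in", length(x$stack_alignments),
      "stacks\n")
  if (length(x$inlier_history)) {
    last <- x$inlier_history[[length(x$inlier_history)]]
    cat(sprintf("  cycles: %d; final inliers %d/%d at beta = %.2f\n",
                length(x$inlier_history), sum(last$table$member),
                nrow(last$table), last$beta))
  } else {
    cat("  cycles: 0 (scattered-data initialization only)\n")
  }
  invisible(x)
}

#' @export
summary.fetal_srr <- function(object, ...) {
  hist <- lapply(seq_along(object$inlier_history), function(i) {
    tab <- object$inlier_history[[i]]$table
    data.frame(cycle = i, beta = object$inlier_history[[i]]$beta,
               n_slices = nrow(tab), n_inliers = sum(tab$member),
               mean_similarity = mean(tab$similarity[tab$member]))
  })
  hist <- if (length(hist)) do.call(rbind, hist) else NULL
  out <- list(target_stack_id = object$target_stack_id,
              stack_volumes = object$stack_volumes, grid = object$grid,
              cycles = hist,
              final_table = if (length(object$inlier_history))
                object$inlier_history[[length(object$inlier_history)]]$table
              else NULL)
  class(out) <- "summary.fetal_srr"
  out
}

#' @export
print.summary.fetal_srr <- function(x, ...) {
  cat("Fetal brain SRR fit\n  target stack:", x$target_stack_id, "\n")
  cat("  estimated stack brain volumes (mm^3):",
      paste(signif(x$stack_volumes, 4), collapse = ", "), "\n")
  if (!is.null(x$cycles)) {
    cat("  per-cycle inlier summary:\n")
    print(x$cycles, row.names = FALSE)
  }
  invisible(x)
}

#' Per-slice rigid motion parameters of a reconstruction
#'
#' @param object a `fetal_srr` fit.
#' @param ... unused.
#' @return Matrix with one row per slice and columns
#'   `rx, ry, rz` (degrees) and `tx, ty, tz` (mm).
#' @export
coef.fetal_srr <- function(object, ...) {
  p <- t(vapply(object$slice_transforms, rigid_params, numeric(6)))
  colnames(p) <- c("rx", "ry", "rz", "tx", "ty", "tz")
  p
}

#' Simulate slices from a fitted reconstruction
#'
#' Forward-projects the fitted high-resolution volume through each slice's
#' estimated acquisition geometry, i.e. computes `A_k x_hat`.
#'
#' @param object a `fetal_srr` fit.
#' @param slices optional list of [slice2d] to project; defaults to the fit's
#'   motion-corrected slices.
#' @param ... unused.
#' @return List of 2D arrays, one simulated slice each; slices with no
#'   spatial overlap with the reconstruction grid yield `NA`-filled arrays.
#' @export
predict.fetal_srr <- function(object, slices = object$slices, ...) {
  lapply(slices, function(sl)
    tryCatch(forward_project(object$volume, sl, psf_for(sl, object$config)),
             error = function(e) array(NA_real_, dim(sl$pixels))))
}

#' @export
fitted.fetal_srr <- function(object, ...) predict.fetal_srr(object)

#' Slice residuals of a reconstruction
#'
#' @param object a `fetal_srr` fit.
#' @param ... unused.
#' @return List of 2D arrays `y_k - A_k x_hat`, one per slice.
#' @export
residuals.fetal_srr <- function(object, ...) {
  sim <- predict.fetal_srr(object)
  Map(function(sl, ys) sl$pixels - ys, object$slices, sim)
}

#' Orthogonal mid-plane views of a reconstruction
#'
#' @param x a `fetal_srr` fit (or [volume3d] via `plot_volume()`).
#' @param ... passed to [graphics::image()].
#' @export
plot.fetal_srr <- function(x, ...) plot_volume(x$volume, ...)

#' @param volume a [volume3d].
#' @rdname plot.fetal_srr
#' @export
plot_volume <- function(volume, ...) {
  v <- volume$values
  d <- dim(v)
  op <- graphics::par(mfrow = c(1, 3), mar = c(1, 1, 2, 1))
  on.exit(graphics::par(op))
  g <- grDevices::gray.colors(128, 0, 1)
  graphics::image(v[ceiling(d[1] / 2), , ], col = g, axes = FALSE,
                  main = "sagittal", useRaster = TRUE, ...)
  graphics::image(v[, ceiling(d[2] / 2), ], col = g, axes = FALSE,
                  main = "coronal", useRaster = TRUE, ...)
  graphics::image(v[, , ceiling(d[3] / 2)], col = g, axes = FALSE,
                  main = "axial", useRaster = TRUE, ...)
  invisible(volume)
}
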