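#' Evaluate recovered slice motion against simulation ground truth
#'
#' Compares the per-slice rigid transforms of a fit with the true transforms
#' of an [simulate_acquisition()] run.  Because the joint
#' registration-reconstruction problem determines all slice poses only up to
#' one global rigid transform (the reconstruction grid, not the phantom
#' frame, anchors the ensemble), the best common rigid transform — the
#' chordal-mean of the per-slice residuals over the reference slices — is
#' removed before errors are measured.  Rotation error is the geodesic angle
#' of the residual rotation (equivalently the l2 norm of its small-angle
#' rotation parameters); translation error is the residual displacement of
#' the brain centroid in mm.
#'
#' @param fit a `fetal_srr` object.
#' @param sim the `srr_simulation` the stacks came from.
#' @param gauge_slices which slices define the gauge: `"inliers"` (default,
#'   the final inlier set) or `"all"`.
#' @return A data frame with one row per slice: `stack_id`, `slice_index`,
#'   `rot_err_deg`, `trans_err_mm`, `inlier`, plus attribute `"gauge"` (the
#'   removed [rigid_transform]).
#' @export
evaluate_motion <- function(fit, sim, gauge_slices = c("inliers", "all")) {
  gauge_slices <- match.arg(gauge_slices)
  tp <- sim$truth$params
  keys <- paste0(tp$stack_id, ":", tp$slice_index)
  res_list <- lapply(seq_len(nrow(tp)), function(r) {
    est <- fit$slice_transforms[[keys[r]]]
    tru <- sim$truth$transforms[[keys[r]]]
    rigid_compose(est, rigid_invert(tru))
  })
  inlier <- if (length(fit$inlier_history)) {
    tab <- fit$inlier_history[[length(fit$inlier_history)]]$table
    tab$member[match(keys, paste0(tab$stack_id, ":", tab$slice_index))]
  } else rep(TRUE, nrow(tp))
  ref <- if (gauge_slices == "inliers" && any(inlier)) which(inlier)
         else seq_len(nrow(tp))
  G <- mean_rigid(res_list[ref])
  Ginv <- rigid_invert(G)
  ctr <- mask_centroid(sim$mask)
  err <- t(vapply(res_list, function(rs) {
    dev <- rigid_compose(Ginv, rs)
    ang <- acos(min(1, max(-1, (sum(diag(dev$rotation)) - 1) / 2))) * 180 / pi
    c(ang, sqrt(sum((apply_transform(dev, ctr) - ctr)^2)))
  }, numeric(2)))
  out <- data.frame(stack_id = tp$stack_id, slice_index = tp$slice_index,
                    rot_err_deg = err[, 1], trans_err_mm = err[, 2],
                    inlier = inlier, outlier_true = tp$outlier,
                    stringsAsFactors = FALSE)
  attr(out, "gauge") <- G
  out
}

#' Evaluate reconstruction quality against the simulation phantom
#'
#' Resamples the reconstruction (and, for reference, each input stack viewed
#' as a volume) onto the phantom grid and reports the masked peak
#' signal-to-noise ratio of each against the phantom.
#'
#' Because motion correction determines the reconstruction's pose only up to
#' a global rigid transform, the gauge estimated by [evaluate_motion()] is
#' removed before the reconstruction is compared with the phantom (the input
#' stacks have no such ambiguity).
#'
#' @param fit a `fetal_srr` object (or any [volume3d]).
#' @param sim the `srr_simulation` providing phantom and mask.
#' @param gauge optional [rigid_transform] mapping phantom world to
#'   reconstruction world; by default taken from [evaluate_motion()] when
#'   `fit` is a `fetal_srr`.
#' @return Named numeric vector: `psnr_recon` followed by one `psnr_<stack>`
#'   per input stack.
#' @export
evaluate_reconstruction <- function(fit, sim, gauge = NULL) {
  vol <- if (inherits(fit, "fetal_srr")) fit$volume else fit
  if (is.null(gauge)) {
    gauge <- if (inherits(fit, "fetal_srr"))
      attr(evaluate_motion(fit, sim), "gauge") else rigid_transform()
  }
  rec <- resample(vol, sim$phantom$grid, transform = gauge)
  out <- c(psnr_recon = psnr_volume(rec, sim$phantom, sim$mask))
  for (st in sim$stacks) {
    sv <- resample(stack_to_volume(st), sim$phantom$grid)
    out[paste0("psnr_", st$slices[[1]]$stack_id)] <-
      psnr_volume(sv, sim$phantom, sim$mask)
  }
  out
}

#' Outlier-rejection recall on simulated data
#'
#' Fraction of truly corrupted slices (with at least `min_mask_px` masked
#' pixels, i.e. slices the brain-masked similarity can see) that are absent
#' from the final inlier set.
#'
#' @param fit a `fetal_srr` object.
#' @param sim the `srr_simulation`.
#' @param min_mask_px smallest mask support for a slice to count.
#' @return A list with `recall`, `n_outliers`, `n_rejected`.
#' @export
outlier_recall <- function(fit, sim, min_mask_px = 2) {
  tp <- sim$truth$params
  tab <- fit$inlier_history[[length(fit$inlier_history)]]$table
  keys <- paste0(tab$stack_id, ":", tab$slice_index)
  mask_px <- vapply(fit$slices, function(sl) sum(sl$mask), numeric(1))
  names(mask_px) <- paste0(vapply(fit$slices, `[[`, character(1), "stack_id"),
                           ":", vapply(fit$slices, `[[`, integer(1), "slice_index"))
  rows <- which(tp$outlier &
                  mask_px[paste0(tp$stack_id, ":", tp$slice_index)] >= min_mask_px)
  rejected <- vapply(rows, function(r) {
    i <- match(paste0(tp$stack_id[r], ":", tp$slice_index[r]), keys)
    !tab$member[i]
  }, logical(1))
  list(recall = if (length(rows)) mean(rejected) else NA_real_,
       n_outliers = length(rows), n_rejected = sum(rejected))
}
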