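#' Bounding-box overlap metrics
#'
#' Intersection over union (in world mm^3) and centroid distance (mm) between
#' two axis-aligned 3D boxes.
#'
#' @param a,b [bounding_box3d] objects (or lists with `lower_mm`/`upper_mm`).
#' @return `iou_3d()` a ratio in `[0, 1]`; `centroid_distance()` mm.
#' @export
iou_3d <- function(a, b) {
  lo <- pmax(a$lower_mm, b$lower_mm)
  hi <- pmin(a$upper_mm, b$upper_mm)
  inter <- prod(pmax(0, hi - lo))
  va <- prod(a$upper_mm - a$lower_mm)
  vb <- prod(b$upper_mm - b$lower_mm)
  if (va + vb - inter <= 0) return(0)
  inter / (va + vb - inter)
}

#' @rdname iou_3d
#' @export
centroid_distance <- function(a, b) {
  sqrt(sum(((a$lower_mm + a$upper_mm) / 2 - (b$lower_mm + b$upper_mm) / 2)^2))
}

#' Overlap and surface-distance metrics between masks
#'
#' `dice_score()` is `2|A n B| / (|A| + |B|)`; `hausdorff()` the symmetric
#' Hausdorff distance in mm between the voxel-center point sets (exhaustive
#' max-min distances).
#'
#' @param a,b [mask_volume] objects on the same grid.
#' @return A scalar; two empty masks signal `undefined-metric`.
#' @export
dice_score <- function(a, b) {
  if (!all(a$grid$shape == b$grid$shape))
    stop("invalid-input: masks must share a grid")
  na <- sum(a$values > 0.5); nb <- sum(b$values > 0.5)
  if (na + nb == 0) stop("undefined-metric: both masks are empty")
  2 * sum(a$values > 0.5 & b$values > 0.5) / (na + nb)
}

#' @rdname dice_score
#' @export
hausdorff <- function(a, b) {
  pa <- which(a$values > 0.5, arr.ind = TRUE)
  pb <- which(b$values > 0.5, arr.ind = TRUE)
  if (nrow(pa) == 0 && nrow(pb) == 0)
    stop("undefined-metric: both masks are empty")
  if (nrow(pa) == 0 || nrow(pb) == 0) return(Inf)
  wa <- index_to_world(a$grid, t(pa) - 1)
  wb <- index_to_world(b$grid, t(pb) - 1)
  wa <- if (is.matrix(wa)) wa else matrix(wa, 3)
  wb <- if (is.matrix(wb)) wb else matrix(wb, 3)
  max(cpp_maxmin_dist(wa, wb), cpp_maxmin_dist(wb, wa))
}

# 2D box filter (normalized over the in-extent window)
box_filter2d <- function(m, half = 3L) {
  d <- dim(m)
  filt_axis <- function(x, n) {
    K <- matrix(0, n, n)
    for (off in -half:half) {
      i <- seq_len(n); j <- i + off
      ok <- j >= 1 & j <= n
      K[cbind(i[ok], j[ok])] <- 1
    }
    K <- K / rowSums(K)
    K %*% x
  }
  t(filt_axis(t(filt_axis(m, d[1])), d[2]))
}

#' Slice similarity suite
#'
#' All six similarity measures between an acquired slice and its simulated
#' counterpart over masked pixels: NCC, NMI (32-bin), SSIM (7x7 uniform
#' window, K1 = 0.01, K2 = 0.03, computed on the masked bounding crop), PSNR
#' (dynamic range = masked target max - min, capped at 100 dB for identical
#' inputs), RMSE and MAE.  Degenerate inputs yield `NA` entries flagged in
#' the `"undefined"` attribute.
#'
#' @param y reference slice: [slice2d] or 2D array.
#' @param y_sim comparison 2D array of the same shape.
#' @param mask optional 2D binary array.
#' @return Named numeric vector `c(NCC, NMI, SSIM, PSNR, RMSE, MAE)`.
#' @export
similarity_suite <- function(y, y_sim, mask = NULL) {
  if (inherits(y, "slice2d")) {
    if (is.null(mask)) mask <- y$mask
    y <- y$pixels
  }
  if (is.null(mask)) mask <- array(1, dim(y))
  keep <- mask > 0.5
  a <- y[keep]; b <- y_sim[keep]
  undefined <- character(0)
  ncc <- ncc_vec(a, b)
  if (is.na(ncc)) undefined <- c(undefined, "NCC")
  nmi_v <- tryCatch(nmi(a, b), error = function(e) NA_real_)
  if (is.na(nmi_v)) undefined <- c(undefined, "NMI")
  mse <- mean((a - b)^2)
  rmse <- sqrt(mse)
  mae <- mean(abs(a - b))
  rng <- diff(range(a))
  psnr <- if (rng == 0) NA_real_
          else if (mse == 0) 100
          else min(100, 10 * log10(rng^2 / mse))
  if (is.na(psnr)) undefined <- c(undefined, "PSNR")
  ssim <- tryCatch(ssim2d(y, y_sim, keep), error = function(e) NA_real_)
  if (is.na(ssim)) undefined <- c(undefined, "SSIM")
  out <- c(NCC = ncc, NMI = nmi_v, SSIM = ssim, PSNR = psnr, RMSE = rmse,
           MAE = mae)
  attr(out, "undefined") <- undefined
  out
}

# mean SSIM over the masked bounding crop; 7x7 uniform window
ssim2d <- function(y, y_sim, keep, K1 = 0.01, K2 = 0.03) {
  idx <- which(keep, arr.ind = TRUE)
  if (nrow(idx) < 2) stop("undefined-metric: degenerate mask for SSIM")
  r1 <- range(idx[, 1]); r2 <- range(idx[, 2])
  A <- y[r1[1]:r1[2], r2[1]:r2[2], drop = FALSE]
  B <- y_sim[r1[1]:r1[2], r2[1]:r2[2], drop = FALSE]
  L <- diff(range(A))
  if (L == 0) stop("undefined-metric: constant reference for SSIM")
  C1 <- (K1 * L)^2; C2 <- (K2 * L)^2
  mA <- box_filter2d(A); mB <- box_filter2d(B)
  vA <- box_filter2d(A^2) - mA^2
  vB <- box_filter2d(B^2) - mB^2
  cAB <- box_filter2d(A * B) - mA * mB
  s <- ((2 * mA * mB + C1) * (2 * cAB + C2)) /
       ((mA^2 + mB^2 + C1) * (vA + vB + C2))
  mean(s[keep[r1[1]:r1[2], r2[1]:r2[2]]])
}

#' Masked peak signal-to-noise ratio between volumes
#'
#' @param x comparison [volume3d].
#' @param ref reference [volume3d] on the same grid (defines the dynamic
#'   range).
#' @param mask optional [mask_volume] restricting the evaluation.
#' @return PSNR in dB (capped at 100).
#' @export
psnr_volume <- function(x, ref, mask = NULL) {
  keep <- if (is.null(mask)) array(TRUE, ref$grid$shape) else mask$values > 0.5
  a <- ref$values[keep]; b <- x$values[keep]
  rng <- diff(range(a))
  mse <- mean((a - b)^2)
  if (rng == 0) stop("undefined-metric: constant reference")
  if (mse == 0) return(100)
  min(100, 10 * log10(rng^2 / mse))
}
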