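#' Automatic target-stack selection
#'
#' Computes each stack's (estimated) brain volume from its slice masks
#' (`sum(mask) * pixel area * thickness`, mm^3) and returns the stack whose
#' volume is closest to 70% of the median — a target with good brain coverage
#' that avoids stacks inflated by false-positive masks or heavy motion.
#' Ties break toward the lower stack index.
#'
#' @param stacks list of [slice_stack] with per-slice masks.
#' @return The selected stack's `stack_id`, with attribute `"volumes"` (mm^3
#'   per stack) and `"index"`.
#' @export
select_target_stack <- function(stacks) {
  vols <- vapply(stacks, function(st) {
    s <- st$slices[[1]]
    sum(vapply(st$slices, function(sl) sum(sl$mask), numeric(1))) *
      s$in_plane_spacing^2 * s$thickness
  }, numeric(1))
  if (all(vols == 0)) stop("no-brain-found: all stack masks are empty")
  targetv <- 0.7 * median(vols)
  i <- which.min(abs(vols - targetv))  # which.min takes the first on ties
  id <- stacks[[i]]$slices[[1]]$stack_id
  structure(id, volumes = vols, index = i)
}

#' Linear intensity correction against the target stack
#'
#' Fits scalars `(a, b)` by least squares so that `a * stack + b` best matches
#' the target stack over spatially corresponding masked samples after
#' volume-to-volume alignment (target-stack masked voxels paired with
#' trilinearly interpolated moving-stack values), then applies `a * I + b` to
#' every pixel of the stack.
#'
#' @param stack the [slice_stack] to correct.
#' @param target the target [slice_stack] providing reference intensities.
#' @param stack_mask,target_mask optional [mask_volume]s; by default the
#'   stacks' own slice masks are used.
#' @param v2v [rigid_transform] mapping `stack` world to `target` world.
#' @return The corrected stack with attribute `"coefficients"` `(a, b)`.
#'   Insufficient overlap warns (`no-overlap`) and returns the stack
#'   unchanged.
#' @export
intensity_correct <- function(stack, target, stack_mask = NULL,
                              target_mask = NULL, v2v = rigid_transform()) {
  mov <- stack_to_volume(stack)
  tgt <- stack_to_volume(target)
  if (is.null(target_mask)) target_mask <- stack_to_volume(target, "mask")
  if (is.null(stack_mask)) stack_mask <- stack_to_volume(stack, "mask")
  inv <- rigid_invert(v2v)
  warped <- resample(mov, tgt$grid, transform = inv)
  wmask <- resample(volume3d(stack_mask$values, stack_mask$grid), tgt$grid,
                    transform = inv, interpolation = "nearest")
  keep <- (target_mask$values > 0.5) & (wmask$values > 0.5)
  if (sum(keep) < 2) {
    warning("no-overlap: insufficient masked overlap; stack left unchanged")
    attr(stack, "coefficients") <- c(a = 1, b = 0)
    return(stack)
  }
  m <- warped$values[keep]
  t_ <- tgt$values[keep]
  if (stats::var(m) == 0) {
    warning("no-overlap: constant overlap intensities; stack left unchanged")
    attr(stack, "coefficients") <- c(a = 1, b = 0)
    return(stack)
  }
  a <- stats::cov(m, t_) / stats::var(m)
  b <- mean(t_) - a * mean(m)
  stack$slices <- lapply(stack$slices, function(sl) {
    sl$pixels <- a * sl$pixels + b
    sl
  })
  attr(stack, "coefficients") <- c(a = a, b = b)
  stack
}

# reconstruction grid: axis-aligned with the target stack, covering the union
# of aligned slice-mask world points plus a margin, at isotropic spacing
reconstruction_grid <- function(slices, direction, spacing, margin) {
  pts <- list()
  for (sl in slices) {
    keep <- sl$mask > 0.5
    if (!any(keep)) next
    ij <- which(keep, arr.ind = TRUE) - 1L
    local <- rbind(ij[, 1] * sl$in_plane_spacing, ij[, 2] * sl$in_plane_spacing, 0)
    pts[[length(pts) + 1L]] <- apply_transform(sl$transform, local)
  }
  if (length(pts) == 0L) stop("no-brain-found: no masked pixels in any stack")
  pts <- do.call(cbind, lapply(pts, function(p) if (is.matrix(p)) p else matrix(p, 3)))
  u <- crossprod(direction, pts)  # coordinates in the target orientation frame
  lo <- apply(u, 1, min) - margin
  hi <- apply(u, 1, max) + margin
  shape <- pmax(2L, as.integer(floor((hi - lo) / spacing)) + 1L)
  image_grid(shape, rep(spacing, 3), origin = drop(direction %*% lo),
             direction = direction)
}

#' Subject-space super-resolution reconstruction with motion correction
#'
#' The full two-step iterative pipeline: automatic target-stack selection,
#' rigid volume-to-volume alignment of every stack to the target, linear
#' intensity correction, scattered-data-approximation initialization of the
#' high-resolution volume and brain mask, then `n_cycles` cycles of per-slice
#' slice-to-volume registration, inlier selection at the cycle's similarity
#' threshold, outlier-robust super-resolution solve, and re-estimation of the
#' high-resolution mask from the inlier slice masks.
#'
#' `srr_reconstruct()` is the model-fitting entry point; the returned
#' `fetal_srr` object supports `print()`, `summary()`, `coef()` (per-slice
#' rigid parameters), `predict()` (simulated slices from the fitted volume),
#' `fitted()`, `residuals()` and `plot()`.
#'
#' @param stacks list of [slice_stack] with per-slice masks (all-ones masks
#'   are used for stacks without masks).
#' @param config an [srr_config].
#' @param verbose print per-cycle progress.
#' @return An object of class `fetal_srr` with elements `volume` (the
#'   reconstruction), `mask`, `slice_transforms`, `inlier_history`,
#'   `target_stack_id`, `stack_alignments`, `sda_init`, `slices`
#'   (motion-corrected, intensity-corrected), `config`, and `grid`.
#' @export
srr_reconstruct <- function(stacks, config = srr_config(), verbose = FALSE) {
  stopifnot(length(stacks) >= 1)
  target_id <- select_target_stack(stacks)
  ti <- attr(target_id, "index")

  # volume-to-volume alignment to the target stack + intensity correction
  tvol <- stack_to_volume(stacks[[ti]])
  tmask <- stack_to_volume(stacks[[ti]], "mask")
  v2vs <- vector("list", length(stacks))
  for (i in seq_along(stacks)) {
    if (i == ti) { v2vs[[i]] <- rigid_transform(); next }
    mvol <- stack_to_volume(stacks[[i]])
    mmask <- stack_to_volume(stacks[[i]], "mask")
    v2v <- tryCatch(
      volume_to_volume_register(mvol, tvol, moving_mask = mmask,
                                fixed_mask = tmask,
                                levels = config$v2v_levels),
      error = function(e) {
        warning("volume alignment failed for stack ", i, ": ",
                conditionMessage(e), "; using identity")
        rigid_transform()
      })
    v2vs[[i]] <- v2v
    stacks[[i]]$slices <- lapply(stacks[[i]]$slices, function(sl) {
      sl$transform <- rigid_compose(v2v, sl$transform)
      sl
    })
    stacks[[i]] <- intensity_correct(stacks[[i]], stacks[[ti]], v2v = rigid_transform())
  }
  names(v2vs) <- vapply(stacks, function(s) s$slices[[1]]$stack_id, character(1))

  slices <- unlist(lapply(stacks, `[[`, "slices"), recursive = FALSE)
  direction <- stacks[[ti]]$slices[[1]]$transform$rotation
  grid <- reconstruction_grid(slices, direction, config$recon_spacing,
                              config$grid_margin)
  if (verbose)
    message("reconstruction grid: ", paste(grid$shape, collapse = "x"),
            " at ", config$recon_spacing, " mm")

  x <- sda_reconstruct(slices, grid, sigma = config$sda_sigma,
                       sigma_unit = config$sda_sigma_unit, use_masks = FALSE)
  mask_hr <- sda_mask(slices, grid, sigma = config$sda_sigma,
                      sigma_unit = config$sda_sigma_unit,
                      threshold = config$mask_threshold)
  sda_init <- x
  inlier_history <- list()
  sids <- vapply(slices, `[[`, character(1), "stack_id")
  members <- seq_along(slices)

  for (cyc in seq_len(config$n_cycles)) {
    beta <- config$beta_schedule[cyc]
    st <- config$svr_steps[[min(cyc, length(config$svr_steps))]]

    # per-stack registration references: each slice is registered against a
    # volume built without its own stack, removing self-consistency bias
    refs <- svr_references(slices, members, x, grid, cyc, config)

    # slice-to-volume motion correction
    old <- lapply(slices, `[[`, "transform")
    updated <- integer(0)
    for (k in seq_along(slices)) {
      sl <- slices[[k]]
      if (!any(sl$mask > 0.5)) next
      ref <- refs[[sl$stack_id]] %||% x
      tr <- tryCatch(
        slice_to_volume_register(sl, ref, mask_hr, psf_for(sl, config),
                                 init = sl$transform,
                                 inplane_rot_step = st[1],
                                 inplane_trans_step = st[2],
                                 tilt_step = st[3], thick_step = st[4],
                                 levels = config$svr_levels,
                                 passes = config$svr_passes),
        error = function(e) NULL)
      if (!is.null(tr)) { slices[[k]]$transform <- tr; updated <- c(updated, k) }
    }
    # re-center the mean pose update so the subject frame stays anchored to
    # the target stack (the ensemble would otherwise drift as a whole);
    # slices rejected in the previous cycle do not vote
    updated <- intersect(updated, members)
    if (length(updated) >= 2) {
      upds <- lapply(updated, function(k)
        rigid_compose(slices[[k]]$transform, rigid_invert(old[[k]])))
      Dinv <- rigid_invert(mean_rigid(upds))
      for (k in seq_along(slices))
        slices[[k]]$transform <- rigid_compose(Dinv, slices[[k]]$transform)
    }

    inl <- select_inliers(slices, x, mask_hr, beta = beta, config = config)
    inlier_history[[cyc]] <- inl
    members <- which(inl$table$member)
    if (length(members) == 0L)
      stop("no-inliers: all slices rejected at beta = ", beta,
           "; retry with beta reduced by 0.15")
    for (k in seq_along(slices)) slices[[k]]$inlier <- k %in% members
    x <- solve_srr(slices[members], grid, alpha = config$alpha,
                   lsq_max_iter = config$lsq_max_iter,
                   lsq_tol = config$lsq_tol, x0 = x, config = config)
    mask_hr <- sda_mask(slices[members], grid, sigma = config$sda_sigma,
                        sigma_unit = config$sda_sigma_unit,
                        threshold = config$mask_threshold)
    if (verbose)
      message(sprintf("cycle %d: beta %.2f, %d/%d inliers, mean NCC %.3f",
                      cyc, beta, length(members), length(slices),
                      mean(inl$table$similarity[members])))
  }

  keys <- paste0(vapply(slices, `[[`, character(1), "stack_id"), ":",
                 vapply(slices, `[[`, integer(1), "slice_index"))
  transforms <- lapply(slices, `[[`, "transform")
  names(transforms) <- keys

  structure(list(volume = x, mask = mask_hr, slice_transforms = transforms,
                 inlier_history = inlier_history,
                 target_stack_id = as.character(target_id),
                 stack_alignments = v2vs, sda_init = sda_init,
                 slices = slices, config = config, grid = grid,
                 stack_volumes = attr(target_id, "volumes")),
            class = "fetal_srr")
}

#' @rdname srr_reconstruct
#' @export
reconstruct_subject_space <- srr_reconstruct

# registration references per stack; leave-one-stack-out unless configured
# otherwise or only one stack is present
svr_references <- function(slices, members, x, grid, cyc, config) {
  sids <- vapply(slices, `[[`, character(1), "stack_id")
  uniq <- unique(sids)
  loso <- switch(config$svr_reference,
                 full = FALSE,
                 loso = TRUE,
                 `loso-final` = cyc == config$n_cycles)
  if (!loso || length(uniq) < 2)
    return(setNames(rep(list(x), length(uniq)), uniq))
  refs <- vector("list", length(uniq))
  names(refs) <- uniq
  for (sid in uniq) {
    others <- intersect(members, which(sids != sid))
    if (length(others) == 0L) { refs[[sid]] <- x; next }
    refs[[sid]] <- if (cyc == 1L) {
      sda_reconstruct(slices[others], grid, sigma = config$sda_sigma,
                      sigma_unit = config$sda_sigma_unit, use_masks = FALSE)
    } else {
      tryCatch(solve_srr(slices[others], grid, alpha = config$alpha,
                         lsq_max_iter = config$lsq_max_iter,
                         lsq_tol = config$lsq_tol, config = config),
               error = function(e) x)
    }
  }
  refs
}

# chordal mean of a list of rigid transforms (SVD-projected rotation mean,
# arithmetic translation mean)
mean_rigid <- function(ts) {
  Rsum <- Reduce(`+`, lapply(ts, `[[`, "rotation"))
  sv <- svd(Rsum)
  R <- sv$u %*% t(sv$v)
  if (det(R) < 0) { sv$u[, 3] <- -sv$u[, 3]; R <- sv$u %*% t(sv$v) }
  rigid_transform(R, rowMeans(vapply(ts, `[[`, numeric(3), "translation")))
}
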