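#' Template atlas entries
#'
#' A template entry couples a template volume with its brain mask, the mask's
#' brain volume in mm^3 and a label (e.g. a gestational-age tag).  A small
#' synthetic atlas of smooth phantom templates with distinct volumes is
#' provided for self-contained runs; a real spatiotemporal atlas can be read
#' from a directory with `read_atlas()`.
#'
#' @param volume a [volume3d].
#' @param mask a [mask_volume] on the same grid.
#' @param label identifier string.
#' @return An object of class `template_entry`.
#' @export
template_entry <- function(volume, mask, label) {
  bv <- sum(mask$values > 0.5) * prod(mask$grid$spacing)
  structure(list(volume = volume, mask = mask, brain_volume = bv,
                 label = as.character(label)),
            class = "template_entry")
}

#' @export
print.template_entry <- function(x, ...) {
  cat(sprintf("template_entry '%s': brain volume %.0f mm^3\n",
              x$label, x$brain_volume))
  invisible(x)
}

#' @param n number of synthetic templates.
#' @param shape,spacing template grid shape and spacing (mm).
#' @param scales relative brain sizes of the entries.
#' @rdname template_entry
#' @export
synthetic_atlas <- function(n = 3, shape = c(48, 48, 48), spacing = 1.2,
                            scales = seq(0.7, 1.1, length.out = n)) {
  lapply(seq_len(n), function(i) {
    ph <- make_phantom(phantom_spec(shape = shape, spacing = spacing,
                                    seed = 90 + i, brain_scale = scales[i]))
    template_entry(ph$volume, ph$mask, label = sprintf("tpl%02d", i))
  })
}

#' Read / write a template atlas directory
#'
#' Layout: one `<label>.nii` volume + `<label>_mask.nii` per entry and a
#' plain-text `manifest.tsv` with columns `label` and `brain_volume`.
#'
#' @param dir atlas directory.
#' @param atlas list of [template_entry] to write.
#' @return `read_atlas()` a list of `template_entry`.
#' @export
read_atlas <- function(dir) {
  man <- utils::read.delim(file.path(dir, "manifest.tsv"),
                           stringsAsFactors = FALSE)
  lapply(seq_len(nrow(man)), function(i) {
    template_entry(read_volume(file.path(dir, paste0(man$label[i], ".nii"))),
                   read_mask(file.path(dir, paste0(man$label[i], "_mask.nii"))),
                   label = man$label[i])
  })
}

#' @rdname read_atlas
#' @export
write_atlas <- function(atlas, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (e in atlas) {
    write_volume(e$volume, file.path(dir, paste0(e$label, ".nii")))
    write_volume(e$mask, file.path(dir, paste0(e$label, "_mask.nii")))
  }
  man <- data.frame(label = vapply(atlas, `[[`, character(1), "label"),
                    brain_volume = vapply(atlas, `[[`, numeric(1), "brain_volume"))
  utils::write.table(man, file.path(dir, "manifest.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(dir)
}

#' Brain-volume-matched template selection
#'
#' Returns the atlas entry whose brain volume is closest to the subject's;
#' exact ties break toward the lexicographically lower label.
#'
#' @param subject_mask the subject's high-resolution [mask_volume].
#' @param atlas list of [template_entry].
#' @return The selected `template_entry`.
#' @export
select_template <- function(subject_mask, atlas) {
  if (length(atlas) == 0L) stop("no-template: empty atlas")
  sv <- sum(subject_mask$values > 0.5) * prod(subject_mask$grid$spacing)
  d <- vapply(atlas, function(e) abs(e$brain_volume - sv), numeric(1))
  labs <- vapply(atlas, `[[`, character(1), "label")
  cand <- which(d == min(d))
  atlas[[cand[order(labs[cand])][1]]]
}

# principal axes of a binary mask: centroid (mm) + right-handed eigenbasis
mask_pca <- function(mask) {
  idx <- which(mask$values > 0.5, arr.ind = TRUE)
  if (nrow(idx) < 4) stop("invalid-input: mask needs >= 4 positive voxels")
  pts <- index_to_world(mask$grid, t(idx) - 1)
  ctr <- rowMeans(pts)
  cc <- pts - ctr
  ev <- eigen(tcrossprod(cc) / ncol(cc), symmetric = TRUE)
  V <- ev$vectors
  if (det(V) < 0) V[, 3] <- -V[, 3]
  list(center = ctr, axes = V, values = ev$values, n = ncol(cc))
}

#' Principal-brain-axes alignment candidates
#'
#' Computes centroids and principal axes of the subject and template mask
#' voxel clouds (PCA of the voxel point sets) and returns the four rigid
#' transforms mapping the subject centroid and axes onto the template's: the
#' four sign combinations of the two leading eigenvectors that keep the basis
#' right-handed (the third axis is their cross product).  A near-isotropic
#' eigenvalue spectrum warns (`ambiguous-axes`) but still returns candidates.
#'
#' @param subject_mask,template_mask [mask_volume] objects with at least 4
#'   non-collinear positive voxels.
#' @return List of 4 [rigid_transform] (subject world to template world).
#' @export
pba_candidates <- function(subject_mask, template_mask) {
  s <- mask_pca(subject_mask)
  t_ <- mask_pca(template_mask)
  rel <- function(v) v / max(v)
  if (min(abs(diff(rel(s$values)))) < 0.02 || min(abs(diff(rel(t_$values)))) < 0.02)
    warning("ambiguous-axes: near-isotropic mask principal axes")
  out <- vector("list", 4)
  i <- 0
  for (s1 in c(1, -1)) for (s2 in c(1, -1)) {
    Vt <- t_$axes
    Vt[, 1] <- s1 * Vt[, 1]
    Vt[, 2] <- s2 * Vt[, 2]
    Vt[, 3] <- pracma_cross(Vt[, 1], Vt[, 2])
    R <- Vt %*% t(s$axes)
    i <- i + 1
    out[[i]] <- rigid_transform(R, t_$center - drop(R %*% s$center))
  }
  out
}

pracma_cross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2], a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Normalized mutual information of two masked images
#'
#' 32-bin joint-histogram estimator, `NMI = (H(A) + H(B)) / H(A, B)`.
#'
#' @param a,b numeric arrays of identical shape.
#' @param mask optional logical/binary array selecting voxels.
#' @param bins histogram bins per channel.
#' @return NMI value (>= 1; higher means more shared information).
#' @export
nmi <- function(a, b, mask = NULL, bins = 32) {
  if (!is.null(mask)) { a <- a[mask > 0.5]; b <- b[mask > 0.5] }
  a <- as.numeric(a); b <- as.numeric(b)
  if (length(a) < 2 || diff(range(a)) == 0 || diff(range(b)) == 0)
    stop("undefined-metric: degenerate inputs for NMI")
  cut_ <- function(x) pmin(bins, 1L + floor((x - min(x)) / diff(range(x)) * bins))
  h2 <- table(factor(cut_(a), levels = 1:bins), factor(cut_(b), levels = 1:bins))
  p2 <- h2 / sum(h2)
  ent <- function(p) { p <- p[p > 0]; -sum(p * log(p)) }
  (ent(rowSums(p2)) + ent(colSums(p2))) / ent(as.numeric(p2))
}

#' Pathology-robust rigid alignment to a template
#'
#' Each of the four principal-axes candidates initializes a masked rigid
#' NCC registration of the subject reconstruction to the template; the
#' refined transform with maximal normalized mutual information between the
#' warped reconstruction and the template is returned.
#'
#' @param srr subject-space reconstruction, a [volume3d].
#' @param mask the subject's high-resolution [mask_volume].
#' @param template a [template_entry].
#' @param levels multi-resolution decimation factors for the refinement.
#' @return The winning [rigid_transform] (subject world to template world)
#'   with attributes `"nmi"` (per candidate), `"winner"` and
#'   `"candidates"` (the refined transforms).
#' @export
align_to_template <- function(srr, mask, template, levels = c(2, 1)) {
  cands <- pba_candidates(mask, template$mask)
  refined <- vector("list", 4)
  scores <- rep(NA_real_, 4)
  for (i in 1:4) {
    refined[[i]] <- tryCatch(
      volume_to_volume_register(srr, template$volume, moving_mask = mask,
                                fixed_mask = template$mask, init = cands[[i]],
                                levels = levels, rot_step = 3, trans_step = 3),
      error = function(e) NULL)
    if (is.null(refined[[i]])) next
    warped <- resample(srr, template$volume$grid,
                       transform = rigid_invert(refined[[i]]))
    scores[i] <- tryCatch(
      nmi(warped$values, template$volume$values,
          mask = template$mask$values),
      error = function(e) NA_real_)
  }
  if (all(is.na(scores)))
    stop("alignment-failure: all candidate refinements failed; ",
         "manual initialization is the documented recovery")
  win <- which.max(scores)
  out <- refined[[win]]
  attr(out, "nmi") <- scores
  attr(out, "winner") <- win
  attr(out, "candidates") <- refined
  out
}

#' Final super-resolution reconstruction on the template grid
#'
#' Composes the template-space transform with every inlier slice's estimated
#' transform and runs one outlier-robust super-resolution solve directly on
#' the template grid, so the subject-space volume is never resampled.
#'
#' @param result a `fetal_srr` fit.
#' @param transform [rigid_transform] from subject world to template world
#'   (e.g. from [align_to_template()]).
#' @param template_grid the template [image_grid].
#' @param config an [srr_config]; defaults to the fit's.
#' @return A [volume3d] on `template_grid`.
#' @export
reconstruct_template_space <- function(result, transform, template_grid,
                                       config = result$config) {
  inliers <- Filter(function(sl) isTRUE(sl$inlier), result$slices)
  if (length(result$inlier_history) == 0L) inliers <- result$slices
  if (length(inliers) == 0L) stop("no-inliers: no inlier slices in the fit")
  inliers <- lapply(inliers, function(sl) {
    sl$transform <- rigid_compose(transform, sl$transform)
    sl
  })
  solve_srr(inliers, template_grid, alpha = config$alpha,
            lsq_max_iter = config$lsq_max_iter, lsq_tol = config$lsq_tol,
            config = config)
}
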