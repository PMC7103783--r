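#' P-Net architecture specification
#'
#' Declarative description of the compact 2D dilated-convolution dense
#' prediction network used for fetal-brain localization and segmentation:
#' six blocks, the first five with 2, 2, 3, 3 and 3 convolution layers and
#' dilation parameters 1, 2, 4, 8 and 16 at 64 channels each; multi-scale
#' features from those five blocks are concatenated into the sixth block, a
#' pixel-wise 1x1-convolution classifier followed by a softmax.  Dilated
#' convolutions preserve resolution, so output spatial shape equals input
#' spatial shape.
#'
#' @param n_blocks number of blocks (6).
#' @param convs_per_block convolutions in blocks 1-5.
#' @param dilations dilation parameter of blocks 1-5.
#' @param channels channel count of the dilated convolution layers.
#' @param kernel_size spatial kernel size of the dilated convolutions.
#' @param n_classes output classes of the softmax classifier.
#' @return An object of class `pnet_spec`.
#' @export
pnet_spec <- function(n_blocks = 6, convs_per_block = c(2, 2, 3, 3, 3),
                      dilations = c(1, 2, 4, 8, 16), channels = 64,
                      kernel_size = 3, n_classes = 2) {
  if (length(convs_per_block) != 5 || length(dilations) != 5)
    stop("invalid-architecture: convs_per_block and dilations must have length 5")
  structure(list(n_blocks = as.integer(n_blocks),
                 convs_per_block = as.integer(convs_per_block),
                 dilations = as.integer(dilations),
                 channels = as.integer(channels),
                 kernel_size = as.integer(kernel_size),
                 n_classes = as.integer(n_classes)),
            class = "pnet_spec")
}

#' Expand a P-Net specification into a validated layer table
#'
#' Produces the per-layer network description implied by a [pnet_spec]:
#' layer types, channels, dilations, cumulative receptive field and parameter
#' counts.  The declared receptive field follows from the dilation schedule
#' by construction; an inconsistent spec signals `invalid-architecture`.
#'
#' @param spec a [pnet_spec].
#' @param in_channels input image channels.
#' @return An object of class `pnet_description`: the layer data frame plus
#'   `receptive_field` and `n_parameters`.
#' @export
build_pnet <- function(spec = pnet_spec(), in_channels = 1) {
  if (spec$n_blocks != length(spec$convs_per_block) + 1L)
    stop("invalid-architecture: n_blocks must be one more than the dilated blocks")
  if (any(spec$convs_per_block < 1) || any(spec$dilations < 1))
    stop("invalid-architecture: non-positive layer counts or dilations")
  rows <- list()
  rf <- 1L
  cin <- in_channels
  k <- spec$kernel_size
  for (b in seq_along(spec$convs_per_block)) {
    for (l in seq_len(spec$convs_per_block[b])) {
      rf <- rf + (k - 1L) * spec$dilations[b]
      rows[[length(rows) + 1L]] <- data.frame(
        block = b, layer = l, type = "dilated_conv", kernel = k,
        dilation = spec$dilations[b], in_channels = cin,
        out_channels = spec$channels, receptive_field = rf,
        n_parameters = (k * k * cin + 1L) * spec$channels)
      cin <- spec$channels
    }
  }
  concat_ch <- spec$channels * length(spec$convs_per_block)
  rows[[length(rows) + 1L]] <- data.frame(
    block = 6, layer = 1, type = "concat_1x1_classifier", kernel = 1,
    dilation = 1, in_channels = concat_ch, out_channels = spec$n_classes,
    receptive_field = rf,
    n_parameters = (concat_ch + 1L) * spec$n_classes)
  layers <- do.call(rbind, rows)
  structure(list(spec = spec, layers = layers,
                 receptive_field = rf,
                 n_parameters = sum(layers$n_parameters),
                 output = "softmax probabilities, same spatial shape as input"),
            class = "pnet_description")
}

#' @export
print.pnet_description <- function(x, ...) {
  cat(sprintf("P-Net: %d layers, receptive field %d px, %s parameters\n",
              nrow(x$layers), x$receptive_field,
              format(x$n_parameters, big.mark = ",")))
  print(x$layers[, c("block", "layer", "type", "dilation", "in_channels",
                     "out_channels", "receptive_field")], row.names = FALSE)
  invisible(x)
}

# multi-scale image features for the pixelwise segmenter: the normalized
# image plus Gaussian-smoothed copies at dyadic scales, and a bias channel
segmenter_features <- function(img, sigmas = c(1, 2, 4, 8)) {
  s <- stats::sd(img)
  z <- if (s > 0) (img - mean(img)) / s else img * 0
  feats <- c(list(z), lapply(sigmas, function(sg) blur2d(z, sg)))
  array(unlist(feats), c(dim(img), length(feats)))
}

#' Train the pixelwise brain segmenter
#'
#' A lightweight trainable segmenter: each pixel is described by the
#' normalized intensity and its Gaussian-smoothed values at dyadic scales,
#' and classified by a small one-hidden-layer pixelwise neural network with a
#' sigmoid (two-class softmax) output.  Training minimizes the multi-scale
#' Dice loss ([multiscale_loss]) with Adam (learning rate `1e-3`, batch size
#' 10, weight decay `1e-7` by default).
#'
#' @param images list of 2D numeric arrays.
#' @param labels list of binary 2D arrays (same shapes).
#' @param spec a [multiscale_loss_spec] for the training loss.
#' @param hidden hidden units.
#' @param iterations Adam iterations.
#' @param batch_size mini-batch size.
#' @param lr initial learning rate.
#' @param weight_decay L2 weight decay.
#' @param sigmas feature smoothing scales (pixels).
#' @param seed RNG seed for initialization and batch sampling.
#' @return An object of class `brain_segmenter` with a `predict()` method
#'   returning per-pixel foreground probabilities.
#' @export
train_segmenter <- function(images, labels, spec = multiscale_loss_spec(),
                            hidden = 8, iterations = 300, batch_size = 10,
                            lr = 1e-3, weight_decay = 1e-7,
                            sigmas = c(1, 2, 4, 8), seed = 1) {
  stopifnot(length(images) == length(labels), length(images) >= 1)
  nf <- length(sigmas) + 1L
  feats <- lapply(images, segmenter_features, sigmas = sigmas)

  local_seed(seed, {
    W1 <- matrix(rnorm(nf * hidden, 0, 0.5), nf, hidden)
    b1 <- numeric(hidden)
    w2 <- rnorm(hidden, 0, 0.5)
    b2 <- 0
    pars <- list(W1 = W1, b1 = b1, w2 = w2, b2 = b2)
    mom <- lapply(pars, function(p) p * 0)
    vel <- lapply(pars, function(p) p * 0)
    beta1 <- 0.9; beta2 <- 0.999; eps <- 1e-8
    loss_trace <- numeric(iterations)

    for (it in seq_len(iterations)) {
      ids <- sample.int(length(images), min(batch_size, length(images)),
                        replace = length(images) < batch_size)
      grads <- lapply(pars, function(p) p * 0)
      lsum <- 0
      for (id in ids) {
        F <- feats[[id]]
        d <- dim(F)[1:2]
        X <- matrix(F, prod(d), nf)
        H <- tanh(sweep(X %*% pars$W1, 2, pars$b1, `+`))
        z <- drop(H %*% pars$w2) + pars$b2
        Y <- matrix(1 / (1 + exp(-z)), d[1], d[2])
        G <- labels[[id]]
        bw <- multiscale_dice_backward(Y, G, spec)
        lsum <- lsum + bw$loss
        dz <- as.numeric(bw$dY) * as.numeric(Y) * (1 - as.numeric(Y))
        dH <- outer(dz, pars$w2)
        dA <- dH * (1 - H^2)
        grads$W1 <- grads$W1 + crossprod(X, dA)
        grads$b1 <- grads$b1 + colSums(dA)
        grads$w2 <- grads$w2 + drop(crossprod(H, dz))
        grads$b2 <- grads$b2 + sum(dz)
      }
      for (nm in names(pars)) {
        gr <- grads[[nm]] / length(ids) + weight_decay * pars[[nm]]
        mom[[nm]] <- beta1 * mom[[nm]] + (1 - beta1) * gr
        vel[[nm]] <- beta2 * vel[[nm]] + (1 - beta2) * gr^2
        mhat <- mom[[nm]] / (1 - beta1^it)
        vhat <- vel[[nm]] / (1 - beta2^it)
        pars[[nm]] <- pars[[nm]] - lr * mhat / (sqrt(vhat) + eps)
      }
      loss_trace[it] <- lsum / length(ids)
    }
    structure(list(pars = pars, sigmas = sigmas, hidden = hidden,
                   loss_trace = loss_trace, spec = spec),
              class = "brain_segmenter")
  })
}

# multi-scale Dice loss and its gradient with respect to Y
multiscale_dice_backward <- function(Y, G, spec, eps = 1e-7) {
  S <- spec$n_scales
  Ys <- list(Y); Gs <- list(G)
  for (s in seq_len(S - 1)) {
    Ys[[s + 1]] <- downscale(Ys[[s]])
    Gs[[s + 1]] <- downscale(Gs[[s]])
  }
  loss <- 0
  dY <- Y * 0
  for (s in seq_len(S)) {
    y <- Ys[[s]]; g <- Gs[[s]]
    P <- sum(y * g); D <- sum(y^2) + sum(g^2)
    loss <- loss + 1 - (2 * P + eps) / (D + eps)
    dl <- -(2 * g * (D + eps) - (2 * P + eps) * 2 * y) / (D + eps)^2
    # chain back through the average-pooling stack to full resolution
    for (up in rev(seq_len(s - 1))) dl <- pool_backward(dl, dim(Ys[[up]]))
    dY <- dY + dl
  }
  list(loss = loss / S, dY = dY / S)
}

# distribute a pooled gradient back over its source blocks
pool_backward <- function(dP, fine_dim) {
  i_blk <- (seq_len(fine_dim[1]) + 1L) %/% 2L
  j_blk <- (seq_len(fine_dim[2]) + 1L) %/% 2L
  cnt <- tcrossprod(as.numeric(table(i_blk)), as.numeric(table(j_blk)))
  (dP / cnt)[i_blk, j_blk, drop = FALSE]
}

#' @export
print.brain_segmenter <- function(x, ...) {
  cat(sprintf("brain_segmenter: %d features -> %d hidden units; final training loss %.4f\n",
              length(x$sigmas) + 1, x$hidden, tail(x$loss_trace, 1)))
  invisible(x)
}

#' Predict per-pixel foreground probabilities
#'
#' @param object a `brain_segmenter`.
#' @param image 2D array, or 3D array / [volume3d] processed slice-by-slice.
#' @param ... unused.
#' @return Probability array of the same spatial shape.
#' @export
predict.brain_segmenter <- function(object, image, ...) {
  if (inherits(image, "volume3d")) image <- image$values
  d <- dim(image)
  if (length(d) == 3L) {
    out <- array(0, d)
    for (k in seq_len(d[3]))
      out[, , k] <- predict.brain_segmenter(object, image[, , k])
    return(out)
  }
  F <- segmenter_features(image, object$sigmas)
  X <- matrix(F, prod(d), length(object$sigmas) + 1L)
  H <- tanh(sweep(X %*% object$pars$W1, 2, object$pars$b1, `+`))
  z <- drop(H %*% object$pars$w2) + object$pars$b2
  matrix(1 / (1 + exp(-z)), d[1], d[2])
}

#' Synthetic noisy-ellipse benchmark images
#'
#' Generates 2D images of a bright, rotated ellipse on a noisy background with
#' its binary mask — the self-contained benchmark used to validate the
#' segmenter and the multi-scale loss.
#'
#' @param n number of images.
#' @param size image side, pixels.
#' @param noise_sd background/foreground noise standard deviation.
#' @param seed RNG seed.
#' @return List with `images` and `masks` (lists of 2D arrays).
#' @export
make_ellipse_images <- function(n, size = 64, noise_sd = 0.3, seed = 1) {
  local_seed(seed, {
    xs <- seq_len(size) - (size + 1) / 2
    X <- matrix(xs, size, size)
    Yc <- matrix(xs, size, size, byrow = TRUE)
    images <- vector("list", n)
    masks <- vector("list", n)
    for (i in seq_len(n)) {
      ctr <- runif(2, -0.2, 0.2) * size
      r <- runif(2, 0.15, 0.32) * size
      th <- runif(1, 0, pi)
      u <- (X - ctr[1]) * cos(th) + (Yc - ctr[2]) * sin(th)
      v <- -(X - ctr[1]) * sin(th) + (Yc - ctr[2]) * cos(th)
      m <- ((u / r[1])^2 + (v / r[2])^2 <= 1) * 1
      img <- 0.2 + 0.8 * m + matrix(rnorm(size^2, 0, noise_sd), size)
      images[[i]] <- img
      masks[[i]] <- m
    }
    list(images = images, masks = masks)
  })
}
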