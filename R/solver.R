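#' Forward-difference gradient and its exact adjoint
#'
#' `gradient_op()` returns the three spacing-scaled forward-difference
#' components of a volume (units 1/mm, so the regularization weight is
#' resolution independent), with a zero (Neumann) difference at the upper
#' boundary of each axis.  `adjoint_gradient_op()` is its exact adjoint
#' (negative divergence with matching boundary handling).
#'
#' @param x a [volume3d].
#' @param g list of three arrays as returned by `gradient_op()`.
#' @param grid the [image_grid] the gradient lives on.
#' @return `gradient_op()`: list of 3 arrays; `adjoint_gradient_op()`: a
#'   [volume3d] on `grid`.
#' @export
gradient_op <- function(x) {
  v <- x$values
  sp <- x$grid$spacing
  lapply(1:3, function(ax) {
    d <- dim(v)
    n <- d[ax]
    idx <- rep(list(quote(expr = )), 3)
    lo <- hi <- v
    idx_hi <- idx; idx_hi[[ax]] <- 2:n
    idx_lo <- idx; idx_lo[[ax]] <- 1:(n - 1)
    g <- array(0, d)
    gidx <- idx; gidx[[ax]] <- 1:(n - 1)
    g_sub <- (do.call(`[`, c(list(v), idx_hi)) - do.call(`[`, c(list(v), idx_lo))) / sp[ax]
    g <- do.call(`[<-`, c(list(g), gidx, list(g_sub)))
    g
  })
}

#' @rdname gradient_op
#' @export
adjoint_gradient_op <- function(g, grid) {
  out <- array(0, grid$shape)
  sp <- grid$spacing
  for (ax in 1:3) {
    y <- g[[ax]]
    d <- dim(y)
    n <- d[ax]
    idx <- rep(list(quote(expr = )), 3)
    # the last forward-difference row is identically zero: ignore y at n
    idx_last <- idx; idx_last[[ax]] <- n
    y <- do.call(`[<-`, c(list(y), idx_last, list(0)))
    idx_hi <- idx; idx_hi[[ax]] <- 1:(n - 1)
    ypad <- array(0, d)
    idx_to <- idx; idx_to[[ax]] <- 2:n
    ypad <- do.call(`[<-`, c(list(ypad), idx_to,
                             list(do.call(`[`, c(list(y), idx_hi)))))
    out <- out + (ypad - y) / sp[ax]
  }
  volume3d(out, grid)
}

# LSQR (Paige & Saunders) for min ||A x - b|| with matrix-free A.
# aprod(x) -> vector in data space; atprod(y) -> vector in model space.
# Returns x, per-iteration residual norms (monotone non-increasing), and the
# stopping reason.
lsqr_solve <- function(aprod, atprod, b, n_model, max_iter = 100, tol = 1e-6,
                       x0 = NULL) {
  x <- if (is.null(x0)) numeric(n_model) else as.numeric(x0)
  u <- b - if (is.null(x0)) 0 else aprod(x)
  beta <- sqrt(sum(u^2))
  rnorms <- beta
  if (beta == 0) return(list(x = x, rnorms = rnorms, iterations = 0L,
                             reason = "zero residual"))
  u <- u / beta
  v <- atprod(u)
  alpha <- sqrt(sum(v^2))
  if (alpha == 0) return(list(x = x, rnorms = rnorms, iterations = 0L,
                              reason = "normal equations satisfied"))
  v <- v / alpha
  w <- v
  phibar <- beta
  rhobar <- alpha
  bnorm <- max(beta, .Machine$double.eps)
  reason <- "iteration cap"
  it <- 0L
  for (it in seq_len(max_iter)) {
    u <- aprod(v) - alpha * u
    beta <- sqrt(sum(u^2))
    if (beta > 0) {
      u <- u / beta
      v <- atprod(u) - beta * v
      alpha <- sqrt(sum(v^2))
      if (alpha > 0) v <- v / alpha
    }
    rho <- sqrt(rhobar^2 + beta^2)
    c_ <- rhobar / rho
    s_ <- beta / rho
    theta <- s_ * alpha
    rhobar <- -c_ * alpha
    phi <- c_ * phibar
    phibar <- s_ * phibar
    x <- x + (phi / rho) * w
    w <- v - (theta / rho) * w
    rnorms <- c(rnorms, phibar)
    if (phibar <= tol * bnorm) { reason <- "residual tolerance"; break }
    if (beta == 0 || alpha == 0) { reason <- "exact solution"; break }
  }
  list(x = x, rnorms = rnorms, iterations = it, reason = reason)
}
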