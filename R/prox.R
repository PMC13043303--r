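# forward differences along one axis with Neumann (replicate) boundary,
# and its negative transpose (divergence); dimension generic (1-D to 3-D)
.fdiff <- function(x, axis) {
  d <- dim(x)
  n <- d[axis]
  idx <- lapply(d, seq_len)
  ip <- idx; ip[[axis]] <- c(2:n, n)
  do.call(`[`, c(list(x), ip)) - x
}

.fdiff_t <- function(g, axis) {
  # transpose of .fdiff (so that sum(fdiff(x) * g) == sum(x * fdiff_t(g)))
  d <- dim(g)
  n <- d[axis]
  idx <- lapply(d, seq_len)
  im <- idx; im[[axis]] <- c(1, 1:(n - 1))
  gm <- do.call(`[`, c(list(g), im))
  sel <- function(i) { ii <- idx; ii[[axis]] <- i; ii }
  out <- gm - g
  first <- do.call(`[`, c(list(g), sel(1)))
  lastm1 <- do.call(`[`, c(list(g), sel(n - 1)))
  out <- do.call(`[<-`, c(list(out), sel(1), list(-first)))
  out <- do.call(`[<-`, c(list(out), sel(n), list(lastm1)))
  out
}

#' Isotropic total-variation denoising (dual fast gradient projection)
#'
#' Solves `min_x 0.5 ||x - v||^2 + w TV(x)` (isotropic TV, optionally
#' subject to `x >= 0`) by accelerated gradient projection on the dual,
#' the standard approach for TV proximal maps which have no closed form.
#'
#' @param v input array (1-D vector, 2-D or 3-D array)
#' @param w TV weight (>= 0)
#' @param n_iter inner dual iterations (default 20)
#' @param nonneg project onto the non-negative orthant
#' @return denoised array of the same shape
#' @export
tv_denoise <- function(v, w, n_iter = 20, nonneg = TRUE) {
  if (w <= 0) return(if (nonneg) pmax(v, 0) else v)
  v <- as.array(v)
  d <- length(dim(v))
  axes <- seq_len(d)
  proj <- if (nonneg) function(x) pmax(x, 0) else identity
  q <- r <- lapply(axes, function(a) array(0, dim(v)))
  tk <- 1
  L <- 4 * d * w
  x <- v
  for (it in seq_len(n_iter)) {
    divr <- Reduce(`+`, lapply(axes, function(a) .fdiff_t(r[[a]], a)))
    x <- proj(v - w * divr)
    g <- lapply(axes, function(a) .fdiff(x, a))
    qn <- lapply(axes, function(a) r[[a]] + g[[a]] / L)
    nrm <- sqrt(Reduce(`+`, lapply(qn, function(z) z^2)))
    scale <- 1 / pmax(1, nrm)
    qn <- lapply(qn, function(z) z * scale)
    tn <- (1 + sqrt(1 + 4 * tk^2)) / 2
    r <- lapply(axes, function(a) qn[[a]] + ((tk - 1) / tn) * (qn[[a]] - q[[a]]))
    q <- qn
    tk <- tn
  }
  divq <- Reduce(`+`, lapply(axes, function(a) .fdiff_t(q[[a]], a)))
  proj(v - w * divq)
}

#' Proximal map of the composite regulariser
#'
#' Approximate proximal operator of `l1 * ||x||_1 + tv * TV(x)` plus the
#' indicator of the non-negative orthant: non-negative soft thresholding
#' followed by isotropic TV denoising under the same constraint. The step
#' scale tau must already be folded into the weights. The composition is
#' applied L1-first; the exact composite prox has no closed form.
#'
#' @param x input array
#' @param l1 soft-threshold level (l1 weight times step size)
#' @param tv TV weight times step size
#' @param nonneg constrain to x >= 0 (default TRUE)
#' @param n_inner_tv inner iterations of the TV dual solver
#' @return array of the same shape
#' @export
prox_composite <- function(x, l1 = 0, tv = 0, nonneg = TRUE, n_inner_tv = 20) {
  y <- if (nonneg) pmax(x - l1, 0) else sign(x) * pmax(abs(x) - l1, 0)
  if (tv > 0) y <- tv_denoise(y, tv, n_iter = n_inner_tv, nonneg = nonneg)
  y
}

#' Largest eigenvalue of the normal operator by power iteration
#'
#' Estimates `L = ||Op||^2`, the largest eigenvalue of `Op^T Op`, from which
#' the proximal-gradient step size `step_safety / L` is derived. Rayleigh
#' quotients are monotone non-decreasing for the symmetric positive
#' semi-definite normal operator.
#'
#' @param apply function mapping an image to data
#' @param adjoint function mapping data back to an image
#' @param shape image dimensions used to draw the random start vector
#' @param n_iter number of iterations (default 20)
#' @param seed RNG seed for the start vector
#' @return the eigenvalue estimate, with the per-iteration Rayleigh
#'   quotients in attribute `"trace"`
#' @export
power_iteration <- function(apply, adjoint, shape, n_iter = 20, seed = 1) {
  set.seed(seed)
  x <- array(stats::rnorm(prod(shape)), shape)
  x <- x / sqrt(sum(x^2))
  lam <- 0
  tr <- numeric(n_iter)
  for (i in seq_len(n_iter)) {
    y <- adjoint(apply(x))
    lam <- sum(x * y)
    tr[i] <- lam
    ny <- sqrt(sum(y^2))
    if (ny == 0) {
      warning("operator annihilated the iterate; returning 0")
      return(structure(0, trace = tr[seq_len(i)]))
    }
    x <- y / ny
  }
  structure(lam, trace = tr)
}
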