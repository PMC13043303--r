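# symmetric-padded separable convolution with a 1-D kernel along every axis
.conv1_sym <- function(x, kernel, axis) {
  d <- dim(x)
  n <- d[axis]
  hw <- (length(kernel) - 1L) %/% 2L
  pad_idx <- c(pmin(hw:1, n), 1:n, pmax(n - (1:hw) + 1L, 1))
  idx <- lapply(d, seq_len)
  ip <- idx; ip[[axis]] <- pad_idx
  xp <- do.call(`[`, c(list(x), ip))
  perm <- c(axis, setdiff(seq_along(d), axis))
  xp <- aperm(xp, perm)
  m <- matrix(xp, nrow = n + 2L * hw)
  out <- matrix(0, n, ncol(m))
  for (k in seq_along(kernel))
    out <- out + kernel[k] * m[(k - 1L) + seq_len(n), , drop = FALSE]
  out <- array(out, c(n, d[perm[-1]]))
  aperm(out, order(perm))
}

.gauss_kernel <- function(sigma, half_width = ceiling(3 * sigma)) {
  k <- stats::dnorm(seq(-half_width, half_width), sd = sigma)
  k / sum(k)
}

.gauss_blur <- function(x, sigma, half_width = ceiling(3 * sigma)) {
  if (sigma <= 0) return(x)
  k <- .gauss_kernel(sigma, half_width)
  for (a in seq_along(dim(x))) x <- .conv1_sym(x, k, a)
  x
}

#' Pair of images to compare
#'
#' @param test image under evaluation
#' @param reference ground-truth / skull-less reference image
#' @param normalization `"self-max"` (each image divided by its own maximum,
#'   as the comparison figures are presented) or `"none"`
#' @return object of class `image_pair`
#' @export
image_pair <- function(test, reference, normalization = c("self-max", "none")) {
  normalization <- match.arg(normalization)
  test <- as.array(test); reference <- as.array(reference)
  if (!identical(dim(test), dim(reference))) stop("images must have equal shape")
  if (normalization == "self-max") {
    if (max(reference) <= 0) stop("reference maximum must be positive for self-max")
    if (max(abs(test)) > 0) test <- test / max(test)
    reference <- reference / max(reference)
  }
  structure(list(test = test, reference = reference,
                 normalization = normalization),
            class = "image_pair")
}

.as_pair <- function(test, reference, ...) {
  if (inherits(test, "image_pair")) test else image_pair(test, reference, ...)
}

#' Pearson correlation coefficient between two images
#'
#' @param test image or an `image_pair`
#' @param reference reference image (ignored if `test` is a pair)
#' @return correlation in [-1, 1]
#' @export
image_correlation <- function(test, reference = NULL) {
  pair <- .as_pair(test, reference)
  a <- as.numeric(pair$test); b <- as.numeric(pair$reference)
  if (stats::sd(a) == 0 || stats::sd(b) == 0)
    stop("zero-variance image: correlation undefined")
  stats::cor(a, b)
}

#' Sliding correlation (maximum normalised cross-correlation over shifts)
#'
#' Maximum of the zero-mean normalised cross-correlation over all integer
#' shifts within `+-max_shift` voxels per axis, computed on the overlap
#' region with per-overlap means and variances. Insensitive to small
#' translations of otherwise similar images.
#'
#' @param test image or `image_pair`
#' @param reference reference image
#' @param max_shift maximum shift per axis (voxels, >= 0)
#' @return maximum correlation, with the best shift in attribute `"shift"`
#' @export
sliding_correlation <- function(test, reference = NULL, max_shift = 10) {
  pair <- .as_pair(test, reference)
  a <- pair$test; b <- pair$reference
  d <- dim(a)
  nd <- length(d)
  stopifnot(max_shift >= 0)
  if (any(d - max_shift < 0.5 * d))
    stop("max_shift leaves less than 25% overlap")
  shifts <- as.matrix(do.call(expand.grid,
                              rep(list(seq(-max_shift, max_shift)), nd)))
  best <- -Inf; best_sh <- rep(0L, nd)
  for (s in seq_len(nrow(shifts))) {
    sh <- shifts[s, ]
    ia <- lapply(seq_len(nd), function(k) {
      lo <- max(1L, 1L + sh[k]); hi <- min(d[k], d[k] + sh[k])
      lo:hi
    })
    ib <- lapply(seq_len(nd), function(k) ia[[k]] - sh[k])
    sa <- as.numeric(do.call(`[`, c(list(a), ia)))
    sb <- as.numeric(do.call(`[`, c(list(b), ib)))
    if (stats::sd(sa) == 0 || stats::sd(sb) == 0) next
    cc <- stats::cor(sa, sb)
    if (cc > best) { best <- cc; best_sh <- sh }
  }
  structure(best, shift = as.integer(best_sh))
}

#' Structural similarity index (mean local SSIM)
#'
#' Gaussian-window SSIM with the conventional constants: 11-tap window with
#' sigma 1.5, k1 = 0.01, k2 = 0.03, dynamic range defaulting to the
#' reference maximum.
#'
#' @param test image or `image_pair`
#' @param reference reference image
#' @param window window width in pixels (odd, default 11)
#' @param sigma Gaussian window sigma (default 1.5)
#' @param k1,k2 stabilisation constants
#' @param dynamic_range value range `L`; default `max(reference)`
#' @return mean SSIM in [-1, 1]
#' @export
image_ssim <- function(test, reference = NULL, window = 11, sigma = 1.5,
                       k1 = 0.01, k2 = 0.03, dynamic_range = NULL) {
  pair <- .as_pair(test, reference)
  a <- pair$test; b <- pair$reference
  if (any(dim(a) < window)) stop("window larger than the image")
  if (is.null(dynamic_range)) dynamic_range <- max(b)
  C1 <- (k1 * dynamic_range)^2
  C2 <- (k2 * dynamic_range)^2
  hw <- (window - 1) / 2
  kern <- .gauss_kernel(sigma, hw)
  blur <- function(x) { for (ax in seq_along(dim(x))) x <- .conv1_sym(x, kern, ax); x }
  mu1 <- blur(a); mu2 <- blur(b)
  s11 <- blur(a * a) - mu1^2
  s22 <- blur(b * b) - mu2^2
  s12 <- blur(a * b) - mu1 * mu2
  ssim_map <- ((2 * mu1 * mu2 + C1) * (2 * s12 + C2)) /
    ((mu1^2 + mu2^2 + C1) * (s11 + s22 + C2))
  mean(ssim_map)
}

#' Maximum amplitude projection of a volume
#'
#' Voxel-wise maximum over a slab of indices along one axis -- the standard
#' presentation of reconstructed volumes.
#'
#' @param volume 2-D or 3-D array
#' @param axis projection axis
#' @param slab index range along `axis` (default: all)
#' @return array with `axis` dropped
#' @export
map_projection <- function(volume, axis = 3, slab = NULL) {
  volume <- as.array(volume)
  d <- dim(volume)
  if (is.null(slab)) slab <- seq_len(d[axis])
  if (length(slab) == 0 || any(slab < 1) || any(slab > d[axis]))
    stop("slab out of bounds or empty")
  idx <- lapply(d, seq_len)
  idx[[axis]] <- slab
  sub <- do.call(`[`, c(list(volume), idx, list(drop = FALSE)))
  apply(sub, setdiff(seq_along(d), axis), max)
}

#' Line profile through an image
#'
#' Bilinear samples at uniformly spaced points on the segment from `p1` to
#' `p2` (physical coordinates, m).
#'
#' @param image 2-D array on `grid`
#' @param grid the image `pact_grid`
#' @param p1,p2 segment endpoints (m)
#' @param n_samples number of samples (default 100)
#' @return numeric vector of sampled values
#' @export
line_profile <- function(image, grid, p1, p2, n_samples = 100) {
  tseq <- seq(0, 1, length.out = n_samples)
  pts <- outer(1 - tseq, p1) + outer(tseq, p2)
  sample_field(image, grid, pts)
}
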