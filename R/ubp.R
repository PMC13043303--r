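#' Universal backprojection reconstruction
#'
#' Closed-form reconstruction assuming a homogeneous acoustic medium: each
#' channel's filtered signal `b(t) = 2 p(t) - 2 t dp/dt` is back-projected
#' over the sphere (circle in 2-D) `t = |r - r_s| / c` and accumulated with
#' solid-angle (arc-length in 2-D) weights. Through a skull this is the
#' aberrated baseline; in water it is exact up to the finite aperture and
#' band limit.
#'
#' @param data a `sensor_data`
#' @param sensors a `sensor_array` (defaults to the positions stored in
#'   `data`)
#' @param sos homogeneous sound speed (m/s), e.g. from [water_sos()]
#' @param roi target `pact_grid` for the image
#' @return numeric array on `roi` (negative values retained)
#' @export
ubp_reconstruct <- function(data, sensors = NULL, sos, roi) {
  stopifnot(inherits(data, "sensor_data"), inherits(roi, "pact_grid"))
  pos <- if (!is.null(sensors)) sensors$positions else data$positions
  if (is.null(pos)) stop("sensor positions required")
  nm <- nrow(pos); nt <- ncol(data$d)
  d <- roi$dim
  stopifnot(ncol(pos) == d)
  xyz <- grid_coords(roi)
  # coverage: farthest corner-of-ROI to sensor distance must fit the record
  rng <- apply(xyz, 2, range)
  corners <- as.matrix(do.call(expand.grid, lapply(seq_len(d), function(a) rng[, a])))
  dmax <- max(sqrt(outer(rowSums(pos^2), rowSums(corners^2), `+`) -
                     2 * pos %*% t(corners)))
  if (dmax / sos > data$t0 + nt * data$dt)
    stop(sprintf("time axis too short: need %d samples to cover %.3g s",
                 ceiling((dmax / sos - data$t0) / data$dt), dmax / sos))
  # backprojection term b(t) = 2 p - 2 t dp/dt
  tvec <- data$t0 + seq_len(nt) * data$dt
  dpdt <- t(apply(data$d, 1, function(x) {
    n <- length(x)
    c(x[2] - x[1], (x[3:n] - x[1:(n - 2)]) / 2, x[n] - x[n - 1]) / data$dt
  }))
  b <- 2 * data$d - 2 * sweep(dpdt, 2, tvec, `*`)
  centre <- colMeans(xyz)
  img <- numeric(nrow(xyz))
  wsum <- numeric(nrow(xyz))
  for (m in seq_len(nm)) {
    sv <- sweep(xyz, 2, pos[m, ])          # sensor -> voxel
    dist <- pmax(sqrt(rowSums(sv^2)), roi$spacing[1] * 1e-6)
    nrm <- centre - pos[m, ]               # inward element normal
    nrm <- nrm / sqrt(sum(nrm^2))
    costh <- pmax(as.numeric(sv %*% nrm) / dist, 0)
    w <- if (d == 3) costh / dist^2 else costh / dist
    fi <- (dist / sos - data$t0) / data$dt
    i0 <- floor(fi)
    fr <- fi - i0
    ok <- i0 >= 1 & i0 < nt
    bm <- b[m, ]
    val <- numeric(nrow(xyz))
    val[ok] <- bm[i0[ok]] * (1 - fr[ok]) + bm[i0[ok] + 1] * fr[ok]
    img <- img + w * val
    wsum <- wsum + w
  }
  img <- img / pmax(wsum, max(wsum) * 1e-12)
  array(img, roi$shape)
}
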