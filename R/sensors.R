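#' Transducer array
#'
#' @param positions N_m x dim matrix of element positions (m)
#' @param radius nominal array radius for canonical geometries (m), or NA
#' @param description free text
#' @return object of class `sensor_array`
#' @export
sensor_array <- function(positions, radius = NA_real_, description = "") {
  positions <- as.matrix(positions)
  stopifnot(all(is.finite(positions)), ncol(positions) %in% c(2L, 3L))
  structure(list(positions = positions, radius = radius,
                 description = description),
            class = "sensor_array")
}

#' @export
print.sensor_array <- function(x, ...) {
  cat(sprintf("<sensor_array> %d elements, %d-D%s%s\n",
              nrow(x$positions), ncol(x$positions),
              if (is.finite(x$radius)) sprintf(", radius %.3g m", x$radius) else "",
              if (nzchar(x$description)) paste0(" (", x$description, ")") else ""))
  invisible(x)
}

#' Hemispherical transducer array
#'
#' Models a hemispherical detection surface assembled from `n_arcs`
#' arc-shaped arrays of `n_elements_per_arc` elements each, rotated about the
#' z axis in `n_rotations` steps so that the azimuthal positions tile the
#' full circle uniformly. Elements along each arc sample the polar angle
#' uniformly between the pole and the equator (half-offset, so no element
#' sits exactly at the pole). All elements lie on the sphere of the given
#' radius; z >= 0 is the detection side.
#'
#' @param radius sphere radius (m)
#' @param n_arcs number of physical arcs
#' @param n_elements_per_arc elements per arc
#' @param n_rotations number of rotation steps
#' @return a `sensor_array` with `n_arcs * n_elements_per_arc * n_rotations`
#'   elements
#' @examples
#' arr <- make_hemispherical_array(0.13, 4, 128, 2)
#' range(sqrt(rowSums(arr$positions^2)))  # all 0.13
#' @export
make_hemispherical_array <- function(radius, n_arcs = 4, n_elements_per_arc = 128,
                                     n_rotations = 1) {
  stopifnot(radius > 0, n_arcs >= 1, n_elements_per_arc >= 1, n_rotations >= 1)
  theta <- (seq_len(n_elements_per_arc) - 0.5) * (pi / 2) / n_elements_per_arc
  base_phi <- (seq_len(n_arcs) - 1) * 2 * pi / n_arcs
  step <- 2 * pi / (n_arcs * n_rotations)
  phis <- as.vector(outer((seq_len(n_rotations) - 1) * step, base_phi, `+`))
  pos <- matrix(0, length(phis) * n_elements_per_arc, 3)
  k <- 1L
  for (phi in phis) {
    st <- sin(theta)
    pos[k:(k + n_elements_per_arc - 1L), ] <-
      cbind(radius * st * cos(phi), radius * st * sin(phi), radius * cos(theta))
    k <- k + n_elements_per_arc
  }
  sensor_array(pos, radius,
               sprintf("hemisphere %d arcs x %d elements x %d rotations",
                       n_arcs, n_elements_per_arc, n_rotations))
}

#' Circular transducer array (2-D)
#'
#' @param radius circle radius (m)
#' @param n_elements number of uniformly spaced elements
#' @param centre circle centre (m), default origin
#' @return a `sensor_array`
#' @export
make_circular_array <- function(radius, n_elements = 256, centre = c(0, 0)) {
  stopifnot(radius > 0, n_elements >= 1)
  ang <- (seq_len(n_elements) - 1) * 2 * pi / n_elements
  sensor_array(cbind(centre[1] + radius * cos(ang), centre[2] + radius * sin(ang)),
               radius, sprintf("circle %d elements", n_elements))
}

#' Multilinear interpolation weights for a set of points
#'
#' @return list with `idx` (n_points x 2^dim linear voxel indices) and `w`
#'   (matching weights, rows sum to 1)
#' @noRd
.interp_weights <- function(grid, positions) {
  positions <- as.matrix(positions)
  d <- grid$dim
  stopifnot(ncol(positions) == d)
  fi <- coord_to_index(grid, positions)
  for (a in seq_len(d)) {
    bad <- fi[, a] < 1 | fi[, a] > grid$shape[a]
    if (any(bad))
      stop(sprintf("position(s) %s outside grid along axis %d",
                   paste(utils::head(which(bad), 5), collapse = ", "), a))
  }
  i0 <- pmin(pmax(floor(fi), 1), matrix(grid$shape - 1L, nrow(fi), d, byrow = TRUE))
  fr <- fi - i0
  n <- nrow(fi)
  corners <- as.matrix(do.call(expand.grid, rep(list(0:1), d)))
  idx <- matrix(0L, n, nrow(corners))
  w <- matrix(0, n, nrow(corners))
  strides <- cumprod(c(1L, grid$shape[-d]))
  for (k in seq_len(nrow(corners))) {
    ik <- sweep(i0, 2, corners[k, ], `+`)
    lin <- 1 + as.vector((ik - 1) %*% strides)
    idx[, k] <- lin
    wk <- rep(1, n)
    for (a in seq_len(d))
      wk <- wk * (if (corners[k, a] == 1) fr[, a] else 1 - fr[, a])
    w[, k] <- wk
  }
  list(idx = idx, w = w)
}

#' Sample a field at arbitrary positions (the sampling operator S)
#'
#' Multilinear interpolation of a scalar field at physical positions; exact
#' at grid nodes and linear in the field.
#'
#' @param field numeric array on `grid`
#' @param grid a `pact_grid`
#' @param positions matrix of positions (m), one row per point
#' @return numeric vector of sampled values
#' @export
sample_field <- function(field, grid, positions) {
  field <- .as_field(field, grid)
  iw <- .interp_weights(grid, positions)
  rowSums(matrix(field[iw$idx], nrow(iw$idx)) * iw$w)
}

#' Multi-channel time-series sensor data
#'
#' @param d N_m x N_t numeric matrix of recorded pressure (Pa, arbitrary gain)
#' @param dt sampling interval (s)
#' @param t0 time of the first sample (s)
#' @param positions optional N_m x dim element positions (m)
#' @param meta provenance text
#' @return object of class `sensor_data`
#' @export
sensor_data <- function(d, dt, t0 = 0, positions = NULL, meta = "") {
  d <- as.matrix(d)
  storage.mode(d) <- "double"
  if (!all(is.finite(d))) stop("sensor data must be finite")
  if (!is.finite(dt) || dt <= 0) stop("dt must be positive")
  if (ncol(d) < 2) stop("need at least 2 time samples")
  if (!is.null(positions)) {
    positions <- as.matrix(positions)
    stopifnot(nrow(positions) == nrow(d))
  }
  structure(list(d = d, dt = dt, t0 = t0, positions = positions, meta = meta),
            class = "sensor_data")
}

#' @export
print.sensor_data <- function(x, ...) {
  cat(sprintf("<sensor_data> %d channels x %d samples, dt %.3g us%s\n",
              nrow(x$d), ncol(x$d), x$dt * 1e6,
              if (nzchar(x$meta)) paste0(" (", x$meta, ")") else ""))
  invisible(x)
}
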