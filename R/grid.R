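#' Regular simulation grid
#'
#' A `pact_grid` describes a regular 2-D or 3-D voxel grid: integer shape,
#' physical voxel spacing, and the physical coordinate of the centre of the
#' voxel with index 1 (R indexing). All units are SI (metres).
#'
#' @param shape integer vector of length 2 or 3, voxels per axis (each >= 8).
#' @param spacing voxel spacing in metres; a scalar (isotropic) or one value
#'   per axis.
#' @param origin physical coordinate (m) of the centre of the first voxel;
#'   defaults to placing the grid centre at the physical origin.
#' @return an object of class `pact_grid` with fields `shape`, `spacing`,
#'   `origin`, `dim`.
#' @examples
#' g <- make_grid(c(128, 128), 0.5e-3)
#' rng <- grid_axes(g)
#' @export
make_grid <- function(shape, spacing, origin = NULL) {
  shape <- as.integer(shape)
  d <- length(shape)
  if (!(d %in% c(2L, 3L))) stop("grid must be 2-D or 3-D")
  if (any(shape < 8L)) stop("grid shape must be >= 8 voxels per axis")
  spacing <- as.numeric(spacing)
  if (length(spacing) == 1L) spacing <- rep(spacing, d)
  if (length(spacing) != d) stop("spacing must be scalar or one value per axis")
  if (any(!is.finite(spacing)) || any(spacing <= 0)) stop("spacing must be positive")
  if (is.null(origin)) {
    # centre the grid on the physical origin
    origin <- -(shape - 1) * spacing / 2
  }
  origin <- as.numeric(origin)
  if (length(origin) == 1L) origin <- rep(origin, d)
  if (length(origin) != d || any(!is.finite(origin))) stop("bad origin")
  structure(list(shape = shape, spacing = spacing, origin = origin, dim = d),
            class = "pact_grid")
}

#' @export
print.pact_grid <- function(x, ...) {
  cat(sprintf("<pact_grid> %s voxels, spacing %s mm, origin %s mm\n",
              paste(x$shape, collapse = "x"),
              paste(signif(x$spacing * 1e3, 4), collapse = "/"),
              paste(signif(x$origin * 1e3, 4), collapse = ", ")))
  invisible(x)
}

#' Physical coordinates of grid voxel centres, one vector per axis
#' @param grid a `pact_grid`
#' @return list of numeric vectors, one per axis
#' @export
grid_axes <- function(grid) {
  lapply(seq_len(grid$dim), function(a)
    grid$origin[a] + (seq_len(grid$shape[a]) - 1) * grid$spacing[a])
}

#' Convert voxel indices (1-based) to physical coordinates
#' @param grid a `pact_grid`
#' @param idx integer matrix, one row per point, one column per axis
#' @return numeric matrix of coordinates (m)
#' @export
index_to_coord <- function(grid, idx) {
  idx <- rbind(idx)
  sweep(sweep(idx - 1, 2, grid$spacing, `*`), 2, grid$origin, `+`)
}

#' Convert physical coordinates to fractional voxel indices (1-based)
#' @param grid a `pact_grid`
#' @param xyz numeric matrix, one row per point
#' @return numeric matrix of (fractional) indices
#' @export
coord_to_index <- function(grid, xyz) {
  xyz <- rbind(xyz)
  sweep(sweep(xyz, 2, grid$origin, `-`), 2, grid$spacing, `/`) + 1
}

#' Coordinate arrays of all voxel centres
#' @param grid a `pact_grid`
#' @return matrix with one row per voxel (column-major voxel order) and one
#'   column per axis
#' @export
grid_coords <- function(grid) {
  ax <- grid_axes(grid)
  as.matrix(do.call(expand.grid, ax))
}

#' Squared distance field from a point
#' @noRd
.grid_r2 <- function(grid, centre) {
  ax <- grid_axes(grid)
  d <- grid$dim
  if (d == 2L) {
    outer((ax[[1]] - centre[1])^2, (ax[[2]] - centre[2])^2, `+`)
  } else {
    r2 <- array(0, grid$shape)
    r2 <- outer(outer((ax[[1]] - centre[1])^2, (ax[[2]] - centre[2])^2, `+`),
                (ax[[3]] - centre[3])^2, `+`)
    r2
  }
}

#' Grid spacing needed to resolve a given frequency
#'
#' Spacing that places a prescribed number of grid points per acoustic
#' wavelength at frequency `freq` in a medium with sound speed `sos`.
#' With the conventional six points per wavelength, water (1500 m/s) at a
#' 0.5 MHz cutoff gives 0.5 mm.
#'
#' @param freq frequency in Hz
#' @param sos sound speed in m/s (default nominal water, 1500)
#' @param points_per_wavelength grid points per wavelength (default 6)
#' @return spacing in metres
#' @export
wavelength_spacing <- function(freq, sos = 1500, points_per_wavelength = 6) {
  stopifnot(freq > 0, sos > 0, points_per_wavelength > 0)
  (sos / freq) / points_per_wavelength
}
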