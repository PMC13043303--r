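#' Convert density and wave speeds to Lame parameters
#'
#' For an isotropic solid with density `rho`, compression speed `cp` and shear
#' speed `cs`: `mu = rho*cs^2`, `lam = rho*(cp^2 - 2*cs^2)`. A fluid is the
#' special case `cs = 0`, giving `mu = 0`, `lam = rho*cp^2`.
#'
#' The pair is rejected when it implies a non-positive bulk modulus
#' (`lam + 2*mu/dim <= 0`), i.e. when `cs` is too large relative to `cp`.
#'
#' @param rho density, kg/m^3 (> 0)
#' @param cp compression wave speed, m/s (> 0)
#' @param cs shear wave speed, m/s (>= 0)
#' @param dim spatial dimension used for the bulk-modulus check (default 3)
#' @return list with elements `lam` and `mu` (Pa)
#' @seealso [lame_to_speeds()]
#' @examples
#' speeds_to_lame(1850, 2800, 1250)  # cranial bone, homogeneous model
#' speeds_to_lame(1000, 1500, 0)     # water
#' @export
speeds_to_lame <- function(rho, cp, cs, dim = 3) {
  stopifnot(all(is.finite(rho)), all(is.finite(cp)), all(is.finite(cs)))
  if (any(rho <= 0)) stop("density must be positive")
  if (any(cp <= 0)) stop("compression speed must be positive")
  if (any(cs < 0)) stop("shear speed must be non-negative")
  mu <- rho * cs^2
  lam <- rho * (cp^2 - 2 * cs^2)
  bulk <- lam + 2 * mu / dim
  if (any(bulk <= 0)) {
    i <- which(bulk <= 0)[1]
    stop(sprintf("speeds (cp = %g, cs = %g) imply non-positive bulk modulus",
                 cp[min(i, length(cp))], cs[min(i, length(cs))]))
  }
  list(lam = lam, mu = mu)
}

#' Convert Lame parameters and density back to wave speeds
#' @param rho density, kg/m^3
#' @param lam first Lame parameter, Pa
#' @param mu shear modulus, Pa
#' @return list with elements `cp` and `cs` (m/s)
#' @export
lame_to_speeds <- function(rho, lam, mu) {
  stopifnot(all(rho > 0), all(mu >= 0))
  list(cp = sqrt((lam + 2 * mu) / rho), cs = sqrt(mu / rho))
}

#' Elastic medium on a grid
#'
#' Holds the density and Lame parameter fields of an isotropic elastic medium
#' on a regular grid. Fluid regions are encoded by `mu = 0` exactly.
#'
#' @param rho,lam,mu arrays matching `grid$shape` (kg/m^3, Pa, Pa)
#' @param grid a `pact_grid`
#' @return object of class `elastic_medium`
#' @export
elastic_medium <- function(rho, lam, mu, grid) {
  stopifnot(inherits(grid, "pact_grid"))
  rho <- .as_field(rho, grid); lam <- .as_field(lam, grid); mu <- .as_field(mu, grid)
  if (any(rho <= 0)) stop("density must be positive everywhere")
  if (any(mu < 0)) stop("shear modulus must be non-negative")
  if (any(lam + 2 * mu / grid$dim <= 0)) stop("bulk modulus must be positive everywhere")
  structure(list(rho = rho, lam = lam, mu = mu, grid = grid),
            class = "elastic_medium")
}

.as_field <- function(x, grid) {
  if (length(x) == 1L) x <- array(x, grid$shape)
  x <- as.array(x)
  if (!identical(as.integer(dim(x)), grid$shape)) stop("field shape does not match grid")
  storage.mode(x) <- "double"
  x
}

#' @export
print.elastic_medium <- function(x, ...) {
  sp <- lame_to_speeds(x$rho, x$lam, x$mu)
  cat(sprintf("<elastic_medium> %s; cp range [%.0f, %.0f] m/s; %s solid voxels\n",
              paste(x$grid$shape, collapse = "x"),
              min(sp$cp), max(sp$cp), sum(x$mu > 0)))
  invisible(x)
}

#' Assign homogeneous elastic properties from a skull mask
#'
#' Bone voxels receive the skull property triple, all other voxels the
#' (fluid) background. Setting `cs = 0` in the skull triple yields the
#' acoustic-only model variant in which the skull supports only compression
#' waves.
#'
#' @param mask a `skull_mask` or logical array on `grid`
#' @param skull numeric vector `c(rho, cp, cs)` for bone
#' @param background numeric vector `c(rho, cp)` for the surrounding fluid
#'   (water)
#' @param grid the simulation grid (required when `mask` is a bare array)
#' @return an `elastic_medium`
#' @examples
#' g <- make_grid(c(32, 32), 1e-3)
#' m <- array(FALSE, g$shape); m[10:20, 10:12] <- TRUE
#' med <- assign_properties(m, c(1850, 2800, 1250), c(1000, 1500), g)
#' @export
assign_properties <- function(mask, skull, background, grid = NULL) {
  if (inherits(mask, "skull_mask")) {
    grid <- mask$grid
    mask <- mask$mask
  }
  stopifnot(inherits(grid, "pact_grid"))
  mask <- .as_field(mask, grid) > 0
  sk <- speeds_to_lame(skull[1], skull[2], if (length(skull) >= 3) skull[3] else 0,
                       dim = grid$dim)
  bg <- speeds_to_lame(background[1], background[2], 0, dim = grid$dim)
  rho <- array(background[1], grid$shape)
  lam <- array(bg$lam, grid$shape)
  mu <- array(0, grid$shape)
  rho[mask] <- skull[1]
  lam[mask] <- sk$lam
  mu[mask] <- sk$mu
  elastic_medium(rho, lam, mu, grid)
}
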