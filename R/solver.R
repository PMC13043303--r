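#' Perfectly matched layer configuration
#'
#' Split-field PML with a monotone power-law absorption profile rising from
#' zero at the inner PML edge to its maximum at the domain boundary.
#'
#' @param thickness PML thickness in voxels per side (>= 8, or 0 to disable
#'   and run a periodic domain)
#' @param profile_order exponent of the absorption profile (default 4,
#'   quartic)
#' @param target_reflection design reflection coefficient at normal
#'   incidence used to scale the profile (default 1e-4); ignored when
#'   `target_alpha` is given
#' @param target_alpha maximum absorption in nepers/s, overriding the
#'   reflection-based scaling
#' @return object of class `pml_config`
#' @export
pml_config <- function(thickness = 10, profile_order = 4,
                       target_reflection = 1e-4, target_alpha = NULL) {
  thickness <- as.integer(thickness)
  if (thickness != 0 && thickness < 8) stop("PML thickness must be >= 8 voxels (or 0)")
  stopifnot(profile_order >= 1)
  structure(list(thickness = thickness, profile_order = profile_order,
                 target_reflection = target_reflection,
                 target_alpha = target_alpha),
            class = "pml_config")
}

# decay factors exp(-alpha dt / 2) along one axis at integer (`half = FALSE`)
# or half-shifted voxel positions
.pml_decay_vec <- function(n, pml, dx, dt, c_ref, half = FALSE) {
  thick <- pml$thickness
  if (thick == 0) return(rep(1, n))
  alpha_max <- if (!is.null(pml$target_alpha)) pml$target_alpha else
    -(pml$profile_order + 1) * c_ref * log(pml$target_reflection) / (2 * thick * dx)
  u <- (seq_len(n) - 1) + if (half) 0.5 else 0
  depth <- pmax(thick - u, u - (n - 1 - thick)) / thick
  alpha <- alpha_max * pmax(depth, 0)^pml$profile_order
  exp(-alpha * dt / 2)
}

#' Courant number of a proposed time step
#'
#' Returns `c_max * dt / dx_min` for the medium and warns when it exceeds
#' the configured stability limit of the pseudo-spectral leapfrog scheme.
#'
#' @param medium an `elastic_medium`
#' @param grid the simulation grid (defaults to `medium$grid`)
#' @param dt time step (s)
#' @param limit CFL warning threshold (default 0.3)
#' @return the CFL number (invisibly warns above `limit`)
#' @examples
#' g <- make_grid(c(16, 16), 0.5e-3)
#' med <- assign_properties(array(TRUE, g$shape), c(1850, 2800, 1250),
#'                          c(1000, 1500), g)
#' check_stability(med, g, 50e-9)  # 0.28
#' @export
check_stability <- function(medium, grid = medium$grid, dt, limit = 0.3) {
  cp_max <- sqrt(max((medium$lam + 2 * medium$mu) / medium$rho))
  cfl <- cp_max * dt / min(grid$spacing)
  if (cfl > limit)
    warning(sprintf("CFL %.3f exceeds the stability limit %.2f", cfl, limit))
  cfl
}

#' Spectral derivative of a field with optional half-cell staggering
#'
#' Exact Fourier differentiation along one axis; `shift` of +-1/2 evaluates
#' the derivative on a grid staggered by half a cell (via a spectral phase
#' factor), as used between the velocity and stress grids of the solver.
#'
#' @param field numeric array (2-D or 3-D)
#' @param axis axis index (1-based)
#' @param spacing grid spacing along that axis (m)
#' @param shift one of 0, +0.5, -0.5 grid cells
#' @return array of the same shape
#' @export
spectral_derivative <- function(field, axis, spacing, shift = 0) {
  field <- as.array(field)
  if (any(!is.finite(field))) stop("field must be finite")
  d <- dim(field)
  n <- d[axis]
  f <- c(0:(n %/% 2), -((n - n %/% 2 - 1):1))[1:n]
  k <- 2 * pi * f / (n * spacing)
  m <- 1i * k * exp(1i * shift * k * spacing)
  if (shift == 0 && n %% 2 == 0) m[n %/% 2 + 1] <- 0  # odd symbol at Nyquist
  shp <- rep(1L, length(d)); shp[axis] <- n
  M <- array(rep(m, each = prod(d[seq_len(axis - 1)])), d)
  Re(fft(fft(field) * M, inverse = TRUE)) / prod(d)
}

#' Wave state (velocities and stresses) of the elastic solver
#'
#' Total velocity components `v` and unique stress components `sigma`
#' (`xx, yy[, zz], xy[, xz, yz]`) at one time level.
#'
#' @param grid a `pact_grid`
#' @param v list of velocity component arrays (default zeros)
#' @param sigma list of stress component arrays (default zeros)
#' @param t_index integer step count
#' @return object of class `wave_state`
#' @export
wave_state <- function(grid, v = NULL, sigma = NULL, t_index = 0L) {
  d <- grid$dim
  vn <- c("x", "y", "z")[seq_len(d)]
  sn <- if (d == 2) c("xx", "yy", "xy") else c("xx", "yy", "zz", "xy", "xz", "yz")
  zf <- function() array(0, grid$shape)
  if (is.null(v)) v <- stats::setNames(lapply(vn, function(i) zf()), vn)
  if (is.null(sigma)) sigma <- stats::setNames(lapply(sn, function(i) zf()), sn)
  stopifnot(identical(sort(names(v)), sort(vn)), identical(sort(names(sigma)), sort(sn)))
  for (f in c(v, sigma)) stopifnot(identical(as.integer(dim(f)), grid$shape))
  structure(list(v = v, sigma = sigma, grid = grid, t_index = as.integer(t_index)),
            class = "wave_state")
}

#' Initial wave state from an initial pressure distribution
#'
#' Realises the photoacoustic initial condition: diagonal stresses
#' `sigma_ii = -p0`, zero shear stress, zero velocity.
#'
#' @param p0 non-negative initial pressure array (Pa)
#' @param grid the simulation grid
#' @return a `wave_state`
#' @export
init_from_p0 <- function(p0, grid) {
  p0 <- .as_field(p0, grid)
  if (any(!is.finite(p0))) stop("p0 must be finite")
  if (any(p0 < 0)) stop("p0 must be non-negative (initial pressure)")
  st <- wave_state(grid)
  for (nm in c("xx", "yy", "zz")[seq_len(grid$dim)]) st$sigma[[nm]] <- -p0
  st
}

#' Pressure field of a wave state
#'
#' `p = -trace(sigma) / dim`, the fluid pressure recorded by the
#' transducers.
#'
#' @param state a `wave_state`
#' @return numeric array
#' @export
pressure_from_stress <- function(state) {
  d <- state$grid$dim
  s <- state$sigma$xx + state$sigma$yy
  if (d == 3) s <- s + state$sigma$zz
  -s / d
}

# split a total 2-D state into the 10 split fields (equal distribution; the
# splits only matter inside the PML, where initial data never lives)
.state_splits_2d <- function(state) {
  h <- function(x) x / 2
  list(vx_x = h(state$v$x), vx_y = h(state$v$x),
       vy_x = h(state$v$y), vy_y = h(state$v$y),
       sxx_x = h(state$sigma$xx), sxx_y = h(state$sigma$xx),
       syy_x = h(state$sigma$yy), syy_y = h(state$sigma$yy),
       sxy_x = h(state$sigma$xy), sxy_y = h(state$sigma$xy))
}

.splits_to_state_2d <- function(sp, grid, t_index) {
  wave_state(grid,
             v = list(x = sp$vx_x + sp$vx_y, y = sp$vy_x + sp$vy_y),
             sigma = list(xx = sp$sxx_x + sp$sxx_y, yy = sp$syy_x + sp$syy_y,
                          xy = sp$sxy_x + sp$sxy_y),
             t_index = t_index)
}

.decay_vectors <- function(grid, pml, dt, c_ref) {
  list(i = lapply(seq_len(grid$dim), function(a)
         .pml_decay_vec(grid$shape[a], pml, grid$spacing[a], dt, c_ref, half = FALSE)),
       h = lapply(seq_len(grid$dim), function(a)
         .pml_decay_vec(grid$shape[a], pml, grid$spacing[a], dt, c_ref, half = TRUE)))
}

.sensor_weights <- function(grid, sensors, pml) {
  if (is.null(sensors)) return(list(idx = matrix(0L, 0, 2^grid$dim),
                                    w = matrix(0, 0, 2^grid$dim)))
  pos <- if (inherits(sensors, "sensor_array")) sensors$positions else as.matrix(sensors)
  th <- if (is.null(pml)) 0L else pml$thickness
  if (th > 0) {
    lo <- grid$origin + th * grid$spacing
    hi <- grid$origin + (grid$shape - 1 - th) * grid$spacing
    bad <- rep(FALSE, nrow(pos))
    for (a in seq_len(grid$dim))
      bad <- bad | pos[, a] < lo[a] | pos[, a] > hi[a]
    if (any(bad))
      stop(sprintf("sensor channel(s) %s lie outside the non-PML interior",
                   paste(utils::head(which(bad), 8), collapse = ", ")))
  }
  .interp_weights(grid, pos)
}

#' Run the elastic solver for a number of steps
#'
#' Advances a `wave_state` through `nt` leapfrog steps of the
#' pseudo-spectral velocity-stress scheme (velocities at half-integer,
#' stresses at integer time levels; the first velocity update is a half
#' step when starting from `t_index = 0`). Optionally records pressure
#' and/or shear-stress traces at sensor positions and the total
#' (kinetic + strain) energy per step.
#'
#' @param state initial `wave_state` (2-D)
#' @param medium an `elastic_medium`
#' @param nt number of steps
#' @param dt time step (s)
#' @param pml a `pml_config`, or NULL for a periodic (PML-free) domain
#' @param sensors optional `sensor_array` or position matrix for recording
#' @param record which traces to record: subset of `c("p", "sxy")`
#' @param energy record the discrete energy per step
#' @return list with `state` (final `wave_state`), and any of `trace_p`,
#'   `trace_sxy` (channels x nt matrices), `energy` (length-nt vector)
#' @export
run_elastic <- function(state, medium, nt, dt, pml = pml_config(),
                        sensors = NULL, record = "p", energy = FALSE) {
  grid <- state$grid
  if (grid$dim != 2) stop("run_elastic state stepping is implemented for 2-D grids")
  if (is.null(pml)) pml <- pml_config(0)
  cp_max <- sqrt(max((medium$lam + 2 * medium$mu) / medium$rho))
  dec <- .decay_vectors(grid, pml, dt, cp_max)
  iw <- .sensor_weights(grid, sensors, pml)
  res <- .elastic_run_2d(.state_splits_2d(state), medium$rho, medium$lam,
                         medium$mu, grid$spacing[1], grid$spacing[2], dt,
                         as.integer(nt), dec$i[[1]], dec$h[[1]], dec$i[[2]],
                         dec$h[[2]], iw$idx, iw$w,
                         state$t_index == 0L, "p" %in% record,
                         "sxy" %in% record, energy, TRUE)
  out <- list(state = .splits_to_state_2d(res$state, grid, state$t_index + as.integer(nt)))
  if ("p" %in% record && nrow(iw$idx)) out$trace_p <- res$trace_p
  if ("sxy" %in% record && nrow(iw$idx)) out$trace_sxy <- res$trace_sxy
  if (energy) out$energy <- as.numeric(res$energy)
  out
}

#' Advance a wave state by one time step
#'
#' @inheritParams run_elastic
#' @return the updated `wave_state`
#' @export
step_elastic <- function(state, medium, dt, pml = NULL) {
  run_elastic(state, medium, 1L, dt, pml = pml, sensors = NULL,
              record = character(0))$state
}

#' Discrete forward/adjoint measurement operator
#'
#' Builds the composed linear measurement map `F S A`: elastic propagation
#' from an initial pressure (`A`), multilinear sampling at the transducer
#' positions (`S`), and optionally the causal Butterworth measurement
#' filter (`F`). The returned object carries `apply` (image -> channels x
#' time matrix) and `adjoint` (its exact transpose). The adjoint passes a
#' dot-product test to machine precision by construction.
#'
#' @param medium an `elastic_medium` (2-D or 3-D)
#' @param sensors a `sensor_array`
#' @param nt number of recorded time steps
#' @param dt time step and sampling interval (s)
#' @param pml a `pml_config` (NULL for periodic)
#' @param fc measurement-filter cutoff (Hz), or NULL for no filter
#' @param filter_order Butterworth order (default 2)
#' @param roi optional logical array restricting the image support
#' @return object of class `pact_operator` with elements `apply`,
#'   `adjoint`, `grid`, `nt`, `dt`, `n_channels`
#' @export
forward_operator <- function(medium, sensors, nt, dt, pml = pml_config(),
                             fc = NULL, filter_order = 2, roi = NULL) {
  grid <- medium$grid
  d <- grid$dim
  if (is.null(pml)) pml <- pml_config(0)
  cp_max <- sqrt(max((medium$lam + 2 * medium$mu) / medium$rho))
  dec <- .decay_vectors(grid, pml, dt, cp_max)
  iw <- .sensor_weights(grid, sensors, pml)
  nt <- as.integer(nt)
  if (!is.null(roi)) {
    roi <- .as_field(roi, grid) > 0
    if (!any(roi)) stop("empty ROI")
  }
  ap <- function(p0) {
    p0 <- .as_field(p0, grid)
    if (!is.null(roi)) p0 <- p0 * roi
    tr <- if (d == 2) {
      st <- list(sxx_x = -p0 / 2, sxx_y = -p0 / 2, syy_x = -p0 / 2, syy_y = -p0 / 2)
      .elastic_run_2d(st, medium$rho, medium$lam, medium$mu,
                      grid$spacing[1], grid$spacing[2], dt, nt,
                      dec$i[[1]], dec$h[[1]], dec$i[[2]], dec$h[[2]],
                      iw$idx, iw$w, TRUE, TRUE, FALSE, FALSE, FALSE)$trace_p
    } else {
      .elastic_run_3d(p0, medium$rho, medium$lam, medium$mu, grid$spacing,
                      dt, nt, dec, iw$idx, iw$w, TRUE)$trace_p
    }
    if (!is.null(fc)) tr <- butterworth_lowpass(tr, fc, filter_order, dt = dt)
    tr
  }
  adj <- function(dm) {
    dm <- as.matrix(dm)
    stopifnot(nrow(dm) == nrow(iw$idx), ncol(dm) == nt)
    if (!is.null(fc)) dm <- butterworth_lowpass(dm, fc, filter_order, dt = dt,
                                                adjoint = TRUE)
    img <- if (d == 2) {
      .elastic_adjoint_2d(dm, medium$rho, medium$lam, medium$mu,
                          grid$spacing[1], grid$spacing[2], dt, nt,
                          dec$i[[1]], dec$h[[1]], dec$i[[2]], dec$h[[2]],
                          iw$idx, iw$w, TRUE)
    } else {
      .elastic_adjoint_3d(dm, medium$rho, medium$lam, medium$mu, grid$spacing,
                          dt, nt, dec, iw$idx, iw$w, TRUE)
    }
    img <- array(img, grid$shape)
    if (!is.null(roi)) img <- img * roi
    img
  }
  structure(list(apply = ap, adjoint = adj, grid = grid, nt = nt, dt = dt,
                 n_channels = nrow(iw$idx), fc = fc, medium = medium,
                 sensors = sensors, pml = pml, roi = roi),
            class = "pact_operator")
}

#' @export
print.pact_operator <- function(x, ...) {
  cat(sprintf("<pact_operator> %s grid -> %d channels x %d steps (dt %.3g us)%s\n",
              paste(x$grid$shape, collapse = "x"), x$n_channels, x$nt, x$dt * 1e6,
              if (!is.null(x$fc)) sprintf(", filter %.2g MHz", x$fc / 1e6) else ""))
  invisible(x)
}

#' Simulate photoacoustic sensor data from an initial pressure
#'
#' Applies the forward measurement map to `p0` and wraps the result as a
#' `sensor_data` object.
#'
#' @param p0 non-negative initial pressure array
#' @param medium an `elastic_medium`
#' @param sensors a `sensor_array`
#' @param nt,dt recording length (steps) and time step (s)
#' @param pml,fc,filter_order see [forward_operator()]
#' @return a `sensor_data`
#' @export
elastic_forward <- function(p0, medium, sensors, nt, dt, pml = pml_config(),
                            fc = NULL, filter_order = 2) {
  op <- forward_operator(medium, sensors, nt, dt, pml, fc, filter_order)
  p0 <- .as_field(p0, medium$grid)
  if (any(p0 < 0)) stop("p0 must be non-negative")
  sensor_data(op$apply(p0), dt, 0, sensors$positions, "simulated")
}
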