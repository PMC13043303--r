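#' Vessel/wire phantom specification
#'
#' Describes the tube phantoms used as imaging targets: unions of smooth
#' random-walk tubes of fixed thickness (1-2 mm by default), confined to a
#' square region of at most 5 cm per side.
#'
#' @param kind `"tubes"` or `"wires"` (recorded provenance; both generate
#'   random-walk tubes)
#' @param thickness tube thickness (m), default 1.5 mm
#' @param extent side length of the confining square (m), <= 0.05
#' @param n_segments number of tubes
#' @param centre centre of the confining region (m)
#' @param seed RNG seed (generation is bit-reproducible given the seed)
#' @return object of class `phantom_spec`
#' @export
phantom_spec <- function(kind = c("tubes", "wires", "letters"),
                         thickness = 1.5e-3, extent = 0.04, n_segments = 5,
                         centre = NULL, seed = 1) {
  kind <- match.arg(kind)
  if (thickness < 0.5e-3 || thickness > 3e-3)
    stop("thickness outside the supported range")
  if (extent > 0.05 + 1e-12) stop("extent must be <= 0.05 m per side")
  structure(list(kind = kind, thickness = thickness, extent = extent,
                 n_segments = as.integer(n_segments), centre = centre,
                 seed = as.integer(seed)),
            class = "phantom_spec")
}

#' Generate a vessel-mimicking tube phantom
#'
#' Deterministic given the seed: each segment is a smooth random walk
#' rasterised as a tube of the specified thickness, amplitude 1, confined
#' to the requested extent.
#'
#' @param spec a [phantom_spec()]
#' @param grid target `pact_grid`
#' @return non-negative initial-pressure array on `grid`
#' @export
make_vessel_phantom <- function(spec, grid) {
  stopifnot(inherits(spec, "phantom_spec"), inherits(grid, "pact_grid"))
  d <- grid$dim
  img <- array(0, grid$shape)
  if (spec$n_segments == 0L) return(img)
  centre <- if (is.null(spec$centre)) rep(0, d) else spec$centre
  set.seed(spec$seed)
  half <- spec$extent / 2
  step <- min(grid$spacing) / 2
  n_steps <- ceiling(1.2 * spec$extent / step)
  pts <- NULL
  for (s in seq_len(spec$n_segments)) {
    p <- centre + stats::runif(d, -0.8 * half, 0.8 * half)
    dir <- stats::rnorm(d)
    dir <- dir / sqrt(sum(dir^2))
    seg <- matrix(0, n_steps, d)
    for (i in seq_len(n_steps)) {
      seg[i, ] <- p
      dir <- dir + stats::rnorm(d, sd = 0.25)
      dir <- dir / sqrt(sum(dir^2))
      p_new <- p + step * dir
      # reflect off the confinement box
      for (a in seq_len(d)) {
        if (p_new[a] > centre[a] + half || p_new[a] < centre[a] - half) {
          dir[a] <- -dir[a]
          p_new[a] <- p[a] + step * dir[a]
        }
      }
      p <- p_new
    }
    pts <- rbind(pts, seg)
  }
  idx <- round(coord_to_index(grid, pts))
  keep <- rep(TRUE, nrow(idx))
  for (a in seq_len(d)) keep <- keep & idx[, a] >= 1 & idx[, a] <= grid$shape[a]
  idx <- idx[keep, , drop = FALSE]
  path <- array(FALSE, grid$shape)
  strides <- cumprod(c(1L, grid$shape[-d]))
  path[1 + as.vector((idx - 1) %*% strides)] <- TRUE
  r_vox <- max((spec$thickness / 2) / min(grid$spacing), 0.5)
  tube <- .dilate(path, .ball_offsets(r_vox, d))
  img[tube] <- 1
  img
}

#' Skull-shell phantom specification
#'
#' Spherical (3-D) or annular (2-D) bone shell in water; the synthetic
#' stand-in for a registered cranium. Defaults follow the homogeneous
#' cranial-bone model: density 1850 kg/m^3, compression speed 2800 m/s,
#' shear speed 1250 m/s, wall thickness 6.5 mm.
#'
#' @param inner_radius cavity radius (m)
#' @param thickness wall thickness (m), default 6.5 mm
#' @param rho,cp,cs bone properties
#' @param centre shell centre (m)
#' @return object of class `skull_shell_spec`
#' @export
skull_shell_spec <- function(inner_radius = 14e-3, thickness = 6.5e-3,
                             rho = 1850, cp = 2800, cs = 1250,
                             centre = NULL) {
  stopifnot(inner_radius > 0, thickness > 0)
  speeds_to_lame(rho, cp, cs)  # validates the property triple
  structure(list(inner_radius = inner_radius, thickness = thickness,
                 rho = rho, cp = cp, cs = cs, centre = centre),
            class = "skull_shell_spec")
}

#' Build a skull-shell model (medium + mask) on a grid
#'
#' @param spec a [skull_shell_spec()]
#' @param grid simulation `pact_grid`
#' @param water background `c(rho, cp)` (default water at 20 C)
#' @param margin required clearance between the shell and the grid edge in
#'   voxels (default 10, one PML thickness)
#' @return object of class `skull_model`: list with `medium`
#'   (`elastic_medium`), `mask` (`skull_mask`), `skull`, `water`, `grid`
#' @export
make_skull_shell <- function(spec, grid, water = c(1000, water_sos(20)),
                             margin = 10) {
  stopifnot(inherits(spec, "skull_shell_spec"), inherits(grid, "pact_grid"))
  centre <- if (is.null(spec$centre)) rep(0, grid$dim) else spec$centre
  outer_r <- spec$inner_radius + spec$thickness
  lo <- grid$origin + margin * grid$spacing
  hi <- grid$origin + (grid$shape - 1 - margin) * grid$spacing
  if (any(centre - outer_r < lo) || any(centre + outer_r > hi))
    stop("shell does not fit inside the grid with the required margin")
  r <- sqrt(.grid_r2(grid, centre))
  mask <- r >= spec$inner_radius & r <= outer_r
  sm <- skull_mask(mask, grid, "synthetic")
  skull <- c(spec$rho, spec$cp, spec$cs)
  med <- assign_properties(sm, skull, water)
  structure(list(medium = med, mask = sm, skull = skull, water = water,
                 grid = grid, centre = centre),
            class = "skull_model")
}

#' @export
print.skull_model <- function(x, ...) {
  cat(sprintf("<skull_model> rho %.0f kg/m^3, cp %.0f m/s, cs %.0f m/s; %d bone voxels\n",
              x$skull[1], x$skull[2], x$skull[3], sum(x$mask$mask)))
  invisible(x)
}

#' Perturb a skull model (position, orientation, speeds, physics)
#'
#' Produces the model-mismatch variants of the perturbation study: rigid
#' translation and rotation of the skull mask, fractional rescaling of the
#' assigned compression/shear speeds, and the acoustic-only variant in
#' which the skull supports no shear waves (`cs = 0`). The original model
#' is left untouched.
#'
#' @param model a `skull_model`
#' @param kind one of `"translate"`, `"rotate"`, `"cp_scale"`, `"cs_scale"`,
#'   `"acoustic_only"`
#' @param magnitude translation vector (m); rotation angle (degrees, about
#'   `axis`); fractional speed change (e.g. -0.1 for -10 percent); ignored
#'   for `"acoustic_only"`
#' @param axis rotation axis (3-D only)
#' @return a new `skull_model`
#' @export
perturb_model <- function(model, kind = c("translate", "rotate", "cp_scale",
                                          "cs_scale", "acoustic_only"),
                          magnitude = NULL, axis = 3) {
  stopifnot(inherits(model, "skull_model"))
  kind <- match.arg(kind)
  grid <- model$grid
  mask <- model$mask
  skull <- model$skull
  if (kind == "translate") {
    stopifnot(length(magnitude) == grid$dim)
    if (sqrt(sum(magnitude^2)) > 0.015)
      warning("translation beyond the ~1 cm studied range")
    tr <- rigid_transform(diag(grid$dim), magnitude)
    mask <- rasterize_mask(mask, tr, grid)
  } else if (kind == "rotate") {
    stopifnot(length(magnitude) == 1)
    if (abs(magnitude) > 15) warning("rotation beyond the +-10 degree studied range")
    tr <- rigid_transform(rotation_about_axis(magnitude, axis, grid$dim),
                          rep(0, grid$dim))
    mask <- rasterize_mask(mask, tr, grid)
  } else if (kind == "cp_scale") {
    stopifnot(length(magnitude) == 1)
    if (abs(magnitude) > 0.15) warning("speed change beyond the +-10% studied range")
    skull[2] <- skull[2] * (1 + magnitude)
  } else if (kind == "cs_scale") {
    stopifnot(length(magnitude) == 1)
    if (abs(magnitude) > 0.15) warning("speed change beyond the +-10% studied range")
    skull[3] <- skull[3] * (1 + magnitude)
  } else if (kind == "acoustic_only") {
    skull[3] <- 0
  }
  med <- assign_properties(mask, skull, model$water)
  structure(list(medium = med, mask = mask, skull = skull, water = model$water,
                 grid = grid, centre = model$centre),
            class = "skull_model")
}

#' Simulate a sensor dataset from a phantom in a medium
#'
#' Forward-models the data and adds seeded white Gaussian noise.
#'
#' @param p0 ground-truth initial pressure array
#' @param medium an `elastic_medium`
#' @param sensors a `sensor_array`
#' @param nt,dt record length (steps) and time step (s)
#' @param noise_sigma standard deviation of the additive noise (data units)
#' @param seed noise seed
#' @param pml,fc,filter_order forwarded to [forward_operator()]
#' @return list with `data` (`sensor_data`) and `p0` (the ground truth)
#' @export
simulate_dataset <- function(p0, medium, sensors, nt, dt, noise_sigma = 0,
                             seed = 1, pml = pml_config(), fc = NULL,
                             filter_order = 2) {
  sd0 <- elastic_forward(p0, medium, sensors, nt, dt, pml, fc, filter_order)
  if (noise_sigma > 0) {
    set.seed(seed)
    sd0$d <- sd0$d + matrix(stats::rnorm(length(sd0$d), sd = noise_sigma),
                            nrow(sd0$d))
    sd0$meta <- paste0(sd0$meta, sprintf("|noise sd %.3g seed %d", noise_sigma, seed))
  }
  list(data = sd0, p0 = p0)
}

#' Photoacoustic emission of the skull itself
#'
#' Simulates the deterministic interference generated by optical absorption
#' in the bone under external illumination: a seeded non-negative random
#' texture supported on the shell, smoothed to the phantom feature scale,
#' forward-modelled through the same operator.
#'
#' @param model a `skull_model`
#' @param sensors a `sensor_array`
#' @param nt,dt record geometry
#' @param seed texture seed
#' @param feature_scale smoothing length of the texture (m), default 1.5 mm
#' @param pml,fc,filter_order forwarded to [forward_operator()]
#' @return `sensor_data` of the skull-only emission (unit texture amplitude)
#' @export
skull_background_signal <- function(model, sensors, nt, dt, seed = 1,
                                    feature_scale = 1.5e-3,
                                    pml = pml_config(), fc = NULL,
                                    filter_order = 2) {
  grid <- model$grid
  set.seed(seed)
  tex <- array(stats::runif(prod(grid$shape)), grid$shape)
  tex <- .gauss_blur(tex, feature_scale / min(grid$spacing))
  tex[!model$mask$mask] <- 0
  tex <- pmax(tex, 0)
  elastic_forward(tex, model$medium, sensors, nt, dt, pml, fc, filter_order)
}

#' Add skull-background interference to a dataset
#'
#' Adds the skull's own photoacoustic emission, scaled so that the RMS of
#' the added component equals `strength` times the RMS of the phantom data
#' (`strength > 1` emulates external illumination, where the skull
#' background dominates).
#'
#' @param data phantom `sensor_data`
#' @param model a `skull_model`
#' @param sensors a `sensor_array`
#' @param strength RMS ratio of background to phantom data (0 disables)
#' @param seed texture seed
#' @param ... forwarded to [skull_background_signal()]
#' @return `sensor_data` with interference added
#' @export
add_skull_background <- function(data, model, sensors, strength = 1, seed = 1,
                                 ...) {
  if (strength == 0) return(data)
  bg <- skull_background_signal(model, sensors, ncol(data$d), data$dt,
                                seed = seed, ...)
  scale <- strength * sqrt(mean(data$d^2)) / sqrt(mean(bg$d^2))
  data$d <- data$d + scale * bg$d
  data$meta <- paste0(data$meta, sprintf("|skull bg x%.3g seed %d", strength, seed))
  data
}

#' Standing transcranial 2-D test fixture
#'
#' A complete synthetic twin of a transcranial phantom acquisition, sized
#' for desk-scale computation: a 128^2 grid at 0.5 mm spacing, a 6.5 mm
#' thick annular skull shell (1850 kg/m^3, 2800 m/s, 1250 m/s) slightly
#' off-centre in 20 C water, a seeded tube phantom close to the inner
#' shell surface, a 256-element circular array of radius 25 mm, 50 ns
#' stepping and a 0.5 MHz second-order Butterworth measurement filter.
#'
#' @param seed phantom/noise seed
#' @param nt record length in steps (default 640)
#' @param noise_rel noise standard deviation relative to the peak signal
#'   (default 0.01, single-shot recording without averaging)
#' @param simulate also forward-simulate the noisy dataset (default TRUE)
#' @return list with `grid`, `model` (`skull_model`), `p0`, `sensors`,
#'   `nt`, `dt`, `fc`, `pml`, `config` (tuned `recon_config`), `sos_water`,
#'   and (when `simulate`) `data`
#' @export
transcranial_fixture <- function(seed = 7, nt = 640, noise_rel = 0.01,
                                 simulate = TRUE) {
  grid <- make_grid(c(128, 128), 0.5e-3)
  sos_w <- water_sos(20)
  model <- make_skull_shell(
    skull_shell_spec(inner_radius = 14e-3, thickness = 6.5e-3,
                     centre = c(1.5e-3, -1e-3)),
    grid, water = c(1000, sos_w))
  ph <- phantom_spec(thickness = 1.5e-3, extent = 22e-3, centre = c(0, 2e-3),
                     seed = seed)
  p0 <- make_vessel_phantom(ph, grid)
  # keep the phantom strictly inside the cranial cavity
  r <- sqrt(.grid_r2(grid, model$centre))
  p0[r > 14e-3 - 1.5e-3] <- 0
  sensors <- make_circular_array(25e-3, 256)
  dt <- 50e-9
  fc <- 0.5e6
  pml <- pml_config(10)
  # reconstruction region of interest: the central 32 x 32 mm imaging
  # region (the phantom area plus margin), aligned with the full grid
  roi_grid <- make_grid(c(64, 64), grid$spacing)
  roi_idx <- match(round(grid_axes(roi_grid)[[1]], 9),
                   round(grid_axes(grid)[[1]], 9))
  roi_mask <- array(FALSE, grid$shape)
  roi_mask[roi_idx, roi_idx] <- TRUE
  out <- list(grid = grid, model = model, p0 = p0, sensors = sensors,
              nt = as.integer(nt), dt = dt, fc = fc, pml = pml,
              sos_water = sos_w, phantom = ph, roi_grid = roi_grid,
              roi_idx = roi_idx, roi_mask = roi_mask)
  l1 <- tv <- 0
  if (simulate) {
    # raw (unfiltered) records, as acquired; the reconstruction applies the
    # measurement filter to both data and model predictions
    clean <- elastic_forward(p0, model$medium, sensors, nt, dt, pml, fc = NULL)
    sig <- noise_rel * max(abs(clean$d))
    set.seed(seed + 1)
    clean$d <- clean$d + matrix(stats::rnorm(length(clean$d), sd = sig), nrow(clean$d))
    clean$meta <- "transcranial fixture"
    out$data <- clean
    # regulariser weights tuned for this fixture: scaled to the gradient
    # magnitude at zero so they are invariant to the overall data gain
    gref <- max(abs(.fixture_gradient_scale(out)))
    l1 <- 0.02 * gref
    tv <- 0.02 * gref
  }
  out$config <- recon_config(l1_weight = l1, tv_weight = tv, n_outer = 10,
                             power_iters = 8, seed = seed)
  out
}

.fixture_gradient_scale <- function(fx) {
  adjoint_reconstruct(fx$data, fx$model$medium, fx$sensors, fx$pml, fx$fc)
}
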