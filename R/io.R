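#' Write sensor data to HDF5
#'
#' Layout: `/data` (channels x samples, float64), `/dt`, `/t0` (scalars, s),
#' `/positions` (channels x dim, m), and the provenance text as a JSON
#' string attribute `meta` on the root group. Round-trips are bit-exact.
#'
#' @param data a `sensor_data`
#' @param path output file path
#' @return `path`, invisibly
#' @export
write_sensor_h5 <- function(data, path) {
  stopifnot(inherits(data, "sensor_data"))
  pos <- if (is.null(data$positions)) matrix(0, 0, 0) else data$positions
  meta <- as.character(jsonlite::toJSON(list(meta = data$meta), auto_unbox = TRUE))
  .h5_write_sensor(path, data$d, data$dt, data$t0, pos, meta)
  invisible(path)
}

#' Read sensor data from HDF5
#'
#' @param path file path written by [write_sensor_h5()] (or following the
#'   same layout)
#' @return a `sensor_data`
#' @export
read_sensor_h5 <- function(path) {
  if (!file.exists(path)) stop(sprintf("no such file: %s", path))
  r <- .h5_read_sensor(path)
  meta <- tryCatch(jsonlite::fromJSON(r$meta)$meta, error = function(e) r$meta)
  if (is.null(meta)) meta <- ""
  sensor_data(r$d, r$dt, r$t0,
              positions = if (length(r$positions)) r$positions else NULL,
              meta = meta)
}

#' Write a volume (or mask) to NIfTI-1
#'
#' The grid spacing and origin are stored in the NIfTI affine (mm, as per
#' the NIfTI convention). Masks are stored as 8-bit integers.
#'
#' @param volume numeric or logical array
#' @param grid the `pact_grid` the volume lives on
#' @param path output path (`.nii` or `.nii.gz`)
#' @param mask write as 8-bit (for binary masks)
#' @return `path`, invisibly
#' @export
write_volume_nii <- function(volume, grid, path, mask = FALSE) {
  volume <- as.array(volume)
  if (mask) storage.mode(volume) <- "integer"
  d <- grid$dim
  aff <- diag(4)
  for (a in seq_len(d)) {
    aff[a, a] <- grid$spacing[a] * 1e3
    aff[a, 4] <- grid$origin[a] * 1e3
  }
  img <- RNifti::asNifti(volume)
  RNifti::pixdim(img) <- grid$spacing * 1e3
  RNifti::qform(img) <- structure(aff, code = 2L)
  RNifti::sform(img) <- structure(aff, code = 2L)
  RNifti::writeNifti(img, path, datatype = if (mask) "uint8" else "double")
  invisible(path)
}

#' Read a NIfTI volume and its grid
#'
#' @param path NIfTI file
#' @return list with `volume` (array) and `grid` (`pact_grid` from the
#'   affine, converted to metres)
#' @export
read_volume_nii <- function(path) {
  if (!file.exists(path)) stop(sprintf("no such file: %s", path))
  img <- RNifti::readNifti(path)
  aff <- RNifti::xform(img)
  vol <- as.array(img)
  d <- length(dim(vol))
  spacing <- abs(diag(aff)[seq_len(d)]) * 1e-3
  origin <- aff[seq_len(d), 4] * 1e-3
  list(volume = vol,
       grid = make_grid(dim(vol), spacing, origin))
}

# ---- run configuration -----------------------------------------------------

.config_schema <- function() {
  list(
    grid = list(shape = c(128L, 128L), spacing = 0.5e-3, origin = NULL),
    medium = list(skull_rho = 1850, skull_cp = 2800, skull_cs = 1250,
                  water_rho = 1000, water_temperature = 20,
                  shell_inner_radius = 14e-3, shell_thickness = 6.5e-3,
                  shell_centre = NULL, mask_file = NULL),
    sensors = list(type = "circle", radius = 25e-3, n_elements = 256L,
                   n_arcs = 4L, n_rotations = 1L),
    solver = list(dt = 50e-9, nt = 640L, pml_thickness = 10L,
                  pml_order = 4L),
    recon = list(method = "iterative", l1_weight = 0, tv_weight = 0,
                 n_outer = 10L, n_inner_tv = 20L, step_safety = 0.9,
                 power_iters = 20L, nonneg = TRUE, fc = 0.5e6,
                 filter_order = 2L, sos = NULL),
    perturb = list(kind = "cs_scale", magnitude = -0.1, axis = 3L),
    seeds = list(phantom = 7L, noise = 8L, power = 1L, background = 9L),
    paths = list(data = NULL, medium = NULL, truth = NULL, out = "out",
                 fiducials_src = NULL, fiducials_dst = NULL,
                 test = NULL, reference = NULL)
  )
}

.merge_config <- function(defaults, user, path = "") {
  for (key in names(user)) {
    full <- if (nzchar(path)) paste0(path, ".", key) else key
    if (!key %in% names(defaults))
      stop(sprintf("unknown configuration key '%s'", full))
    if (is.list(defaults[[key]]) && !is.null(names(defaults[[key]]))) {
      if (!is.list(user[[key]]))
        stop(sprintf("configuration key '%s' must be a block", full))
      defaults[[key]] <- .merge_config(defaults[[key]], user[[key]], full)
    } else {
      defaults[key] <- user[key]
    }
  }
  defaults
}

.validate_config <- function(cfg) {
  if (!is.null(cfg$solver$dt) && (cfg$solver$dt <= 0 || cfg$solver$dt > 1))
    stop("solver.dt implausible (must be in (0, 1] seconds)")
  if (cfg$grid$spacing <= 0 || cfg$grid$spacing > 1)
    stop("grid.spacing implausible")
  if (!is.null(cfg$recon$fc) && cfg$recon$fc >= 1 / (2 * cfg$solver$dt))
    stop("recon.fc at or above Nyquist for solver.dt")
  for (s in names(cfg$seeds))
    if (!is.numeric(cfg$seeds[[s]])) stop(sprintf("seeds.%s must be numeric", s))
  cfg
}

#' Load and validate a YAML run configuration
#'
#' Unknown keys are rejected by name; missing keys are filled with package
#' defaults; implausible values (e.g. a time step above one second) are
#' refused. All units are SI.
#'
#' @param path YAML file
#' @return validated configuration list (class `run_config`)
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop(sprintf("no such config file: %s", path))
  user <- yaml::read_yaml(path)
  if (is.null(user)) user <- list()
  cfg <- .validate_config(.merge_config(.config_schema(), user))
  class(cfg) <- "run_config"
  cfg
}

#' Save a run configuration as YAML
#' @param cfg configuration list
#' @param path output path
#' @export
save_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}
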