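#' Configuration of the iterative reconstruction
#'
#' @param l1_weight weight of the L1 penalty (image units; >= 0)
#' @param tv_weight weight of the isotropic TV penalty (>= 0)
#' @param n_outer outer accelerated proximal-gradient iterations (default 10)
#' @param n_inner_tv inner iterations of the TV proximal solver (default 20)
#' @param step_safety step size is `step_safety / L` with `L` from power
#'   iteration (default 0.9)
#' @param power_iters power iterations for the step-size estimate
#' @param seed RNG seed (power-iteration start vector)
#' @param nonneg constrain the image to be non-negative (default TRUE)
#' @return object of class `recon_config`
#' @export
recon_config <- function(l1_weight = 0, tv_weight = 0, n_outer = 10,
                         n_inner_tv = 20, step_safety = 0.9, power_iters = 20,
                         seed = 1, nonneg = TRUE) {
  stopifnot(is.finite(l1_weight), l1_weight >= 0,
            is.finite(tv_weight), tv_weight >= 0,
            n_outer >= 1, n_inner_tv >= 1,
            step_safety > 0, step_safety <= 1, power_iters >= 1)
  structure(list(l1_weight = l1_weight, tv_weight = tv_weight,
                 n_outer = as.integer(n_outer), n_inner_tv = as.integer(n_inner_tv),
                 step_safety = step_safety, power_iters = as.integer(power_iters),
                 seed = as.integer(seed), nonneg = isTRUE(nonneg)),
            class = "recon_config")
}

#' Adjoint reconstruction
#'
#' Applies the exact transpose of the discrete measurement map to the data
#' -- equivalent to a single unregularised gradient iteration from a zero
#' image (up to the step scale). Being linear and free of regularisation
#' parameters, it is the standard probe of the model's focusing quality
#' under perturbations.
#'
#' @param data a `sensor_data`
#' @param medium an `elastic_medium` (skull + water model)
#' @param sensors a `sensor_array`
#' @param pml,fc,filter_order forwarded to [forward_operator()]
#' @param roi optional logical support mask
#' @return image array on the medium grid
#' @export
adjoint_reconstruct <- function(data, medium, sensors, pml = pml_config(),
                                fc = NULL, filter_order = 2, roi = NULL) {
  op <- forward_operator(medium, sensors, ncol(data$d), data$dt, pml,
                         fc, filter_order, roi)
  if (op$n_channels != nrow(data$d))
    stop(sprintf("data has %d channels but the array has %d",
                 nrow(data$d), op$n_channels))
  op$adjoint(.filtered_data(data, fc, filter_order))
}

# the measurement filter is part of the measurement model: raw data enters
# the objective as F d, matching the F S A applied to predictions
.filtered_data <- function(data, fc, filter_order) {
  if (is.null(fc)) return(data$d)
  butterworth_lowpass(data$d, fc, filter_order, dt = data$dt)
}

#' Reconstruct an initial-pressure image from photoacoustic sensor data
#'
#' The central estimator. Three methods are available:
#' \describe{
#'   \item{`"iterative"`}{solves the non-negativity-constrained regularised
#'     least squares problem
#'     `argmin_{p0 >= 0} 0.5 ||S A p0 - d||^2 + l1 ||p0||_1 + tv TV(p0)`
#'     by a monotone accelerated proximal-gradient method: `A` solves the
#'     elastic initial value problem, `S` samples (and band-limits) the
#'     pressure at the transducers. With an elastic skull model in `medium`
#'     this is the de-aberrating reconstruction.}
#'   \item{`"adjoint"`}{a single application of the exact adjoint of `S A`
#'     (see [adjoint_reconstruct()]).}
#'   \item{`"ubp"`}{universal backprojection in a homogeneous medium at
#'     speed `sos`, ignoring the skull (the aberrated baseline).}
#' }
#'
#' @param data a `sensor_data`
#' @param sensors a `sensor_array`; defaults to positions stored in `data`
#' @param method `"iterative"` (default), `"adjoint"` or `"ubp"`
#' @param medium an `elastic_medium` (required for iterative/adjoint)
#' @param sos homogeneous sound speed for `"ubp"` (m/s)
#' @param roi a `pact_grid` for `"ubp"`, or a logical support mask on the
#'   medium grid otherwise (optional)
#' @param config a [recon_config()]
#' @param pml a [pml_config()]
#' @param fc measurement filter cutoff (Hz; NULL to disable)
#' @param filter_order Butterworth order of the measurement filter
#' @return an object of class `pact_recon` with elements `p0_hat` (the
#'   estimated initial pressure), `objective_trace`, `step_size`, `method`,
#'   `config`, `grid`
#' @seealso [coef.pact_recon()], [fitted.pact_recon()], [plot.pact_recon()]
#' @export
pact_reconstruct <- function(data, sensors = NULL,
                             method = c("iterative", "adjoint", "ubp"),
                             medium = NULL, sos = NULL, roi = NULL,
                             config = recon_config(), pml = pml_config(),
                             fc = NULL, filter_order = 2) {
  method <- match.arg(method)
  stopifnot(inherits(data, "sensor_data"))
  if (is.null(sensors) && !is.null(data$positions))
    sensors <- sensor_array(data$positions)
  if (method == "ubp") {
    if (is.null(sos) || is.null(roi)) stop("ubp needs `sos` and a `roi` grid")
    dataf <- data
    dataf$d <- .filtered_data(data, fc, filter_order)
    img <- ubp_reconstruct(dataf, sensors, sos, roi)
    return(.new_recon(img, method, NULL, NA_real_, config, roi, dataf$d))
  }
  if (is.null(medium)) stop(sprintf("method '%s' needs an elastic medium", method))
  op <- forward_operator(medium, sensors, ncol(data$d), data$dt, pml,
                         fc, filter_order, roi)
  if (op$n_channels != nrow(data$d))
    stop(sprintf("data has %d channels but the array has %d",
                 nrow(data$d), op$n_channels))
  d_used <- .filtered_data(data, fc, filter_order)
  if (method == "adjoint") {
    img <- op$adjoint(d_used)
    return(.new_recon(img, method, NULL, NA_real_, config, medium$grid,
                      d_used, op = op))
  }
  .fista(d_used, op, config)
}

.new_recon <- function(p0_hat, method, objective_trace, step_size, config,
                       grid, data_used, op = NULL) {
  structure(list(p0_hat = p0_hat, method = method,
                 objective_trace = objective_trace, step_size = step_size,
                 config = config, grid = grid, data_used = data_used, op = op),
            class = "pact_recon")
}

# monotone FISTA on the regularised least-squares objective; re-uses the
# linearity of the operator to avoid forward solves at the extrapolated
# points (Op(y) is a linear combination of cached Op(x) values)
.fista <- function(d, op, config) {
  shape <- op$grid$shape
  L <- as.numeric(power_iteration(op$apply, op$adjoint, shape,
                                  n_iter = config$power_iters,
                                  seed = config$seed))
  if (L <= 0) stop("operator norm estimate is zero; no signal path to sensors")
  tau <- config$step_safety / L
  obj_of <- function(Ax, x)
    0.5 * sum((Ax - d)^2) + config$l1_weight * sum(abs(x)) +
      config$tv_weight * .tv_value(x)
  x <- array(0, shape)
  Ax <- matrix(0, nrow(d), ncol(d))
  y <- x; Ay <- Ax
  tk <- 1
  obj <- obj_of(Ax, x)
  trace <- numeric(config$n_outer + 1)
  trace[1] <- obj
  x_prev <- x; Ax_prev <- Ax
  for (k in seq_len(config$n_outer)) {
    g <- op$adjoint(Ay - d)
    z <- prox_composite(y - tau * g, l1 = tau * config$l1_weight,
                        tv = tau * config$tv_weight, nonneg = config$nonneg,
                        n_inner_tv = config$n_inner_tv)
    Az <- op$apply(z)
    obj_z <- obj_of(Az, z)
    # monotone safeguard: keep the better of the candidate and the incumbent
    if (obj_z <= obj) {
      x_new <- z; Ax_new <- Az; obj_new <- obj_z
    } else {
      x_new <- x; Ax_new <- Ax; obj_new <- obj
    }
    tn <- (1 + sqrt(1 + 4 * tk^2)) / 2
    y <- x_new + (tk / tn) * (z - x_new) + ((tk - 1) / tn) * (x_new - x)
    Ay <- Ax_new + (tk / tn) * (Az - Ax_new) + ((tk - 1) / tn) * (Ax_new - Ax)
    x_prev <- x; Ax_prev <- Ax
    x <- x_new; Ax <- Ax_new; obj <- obj_new
    tk <- tn
    trace[k + 1] <- obj
    if (obj > 10 * trace[1] + .Machine$double.eps)
      stop(sprintf("objective diverged at iteration %d (step %.3g); reduce step_safety", k, tau))
  }
  .new_recon(x, "iterative", trace, tau, config, op$grid, d, op = op)
}

.tv_value <- function(x) {
  x <- as.array(x)
  axes <- seq_along(dim(x))
  sum(sqrt(Reduce(`+`, lapply(axes, function(a) .fdiff(x, a)^2))))
}

# ---- S3 methods ------------------------------------------------------------

#' @export
print.pact_recon <- function(x, ...) {
  cat(sprintf("<pact_recon> method '%s', %s image", x$method,
              paste(x$grid$shape, collapse = "x")))
  if (!is.null(x$objective_trace))
    cat(sprintf(", objective %.4g -> %.4g in %d iterations",
                x$objective_trace[1], utils::tail(x$objective_trace, 1),
                length(x$objective_trace) - 1))
  cat("\n")
  invisible(x)
}

#' @export
summary.pact_recon <- function(object, ...) {
  p0 <- object$p0_hat
  cat(sprintf("Reconstruction (%s)\n", object$method))
  cat(sprintf("  image: %s voxels, range [%.4g, %.4g]\n",
              paste(object$grid$shape, collapse = "x"), min(p0), max(p0)))
  cat(sprintf("  support (> 1%% of max): %.2f%%\n",
              100 * mean(p0 > 0.01 * max(p0))))
  if (!is.null(object$objective_trace)) {
    cat(sprintf("  step size: %.4g\n", object$step_size))
    cat("  objective trace:\n")
    print(signif(object$objective_trace, 5))
  }
  invisible(object)
}

#' Estimated initial pressure image
#' @param object a `pact_recon`
#' @param ... unused
#' @return the image array
#' @export
coef.pact_recon <- function(object, ...) object$p0_hat

#' Model-predicted sensor data of a reconstruction
#' @param object a `pact_recon` fitted with an elastic model
#' @param ... unused
#' @return channels x time matrix `S A p0_hat`
#' @export
fitted.pact_recon <- function(object, ...) {
  if (is.null(object$op))
    stop("fitted values require an operator-based method (iterative/adjoint)")
  object$op$apply(object$p0_hat)
}

#' Data residuals of a reconstruction
#'
#' Difference between the model-predicted measurements and the (filtered)
#' data the objective was fitted to.
#'
#' @param object a `pact_recon`
#' @param ... unused
#' @return channels x time matrix `F S A p0_hat - F d`
#' @export
residuals.pact_recon <- function(object, ...) {
  fitted(object) - object$data_used
}

#' Display a reconstructed image
#'
#' 2-D images are shown directly; 3-D volumes as a maximum amplitude
#' projection along `axis`.
#'
#' @param x a `pact_recon`
#' @param axis projection axis for 3-D volumes (default 3, the z axis)
#' @param ... passed to [graphics::image()]
#' @export
plot.pact_recon <- function(x, axis = 3, ...) {
  img <- x$p0_hat
  if (length(dim(img)) == 3) img <- map_projection(img, axis)
  ax <- grid_axes(x$grid)
  graphics::image(ax[[1]] * 1e3, ax[[2]] * 1e3, img, asp = 1,
                  xlab = "x (mm)", ylab = "y (mm)",
                  col = grDevices::hcl.colors(128, "inferno"),
                  main = sprintf("p0 (%s)", x$method), ...)
  invisible(x)
}
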