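#' Causal Butterworth low-pass filtering of sensor data
#'
#' Per-channel causal (single-pass) IIR filtering with zero initial
#' conditions, DC gain 1 and -3 dB at the cutoff. The same filter is applied
#' to measured data and to model predictions inside the measurement operator,
#' so the forward map and its adjoint remain exact companions. The adjoint of
#' the causal filter over a finite window is time-reversed filtering
#' (`adjoint = TRUE`).
#'
#' @param data a `sensor_data` object, or a plain channels-by-time matrix
#' @param fc cutoff frequency (Hz); must be below the Nyquist frequency
#' @param order filter order (default 2)
#' @param dt sampling interval (s); taken from `data` when it is a
#'   `sensor_data`
#' @param adjoint apply the transpose of the filtering operator instead
#' @return object of the same type as `data`
#' @export
butterworth_lowpass <- function(data, fc = 0.5e6, order = 2, dt = NULL,
                                adjoint = FALSE) {
  is_sd <- inherits(data, "sensor_data")
  d <- if (is_sd) data$d else as.matrix(data)
  if (is_sd) dt <- data$dt
  if (is.null(dt)) stop("dt required when data is a bare matrix")
  nyq <- 1 / (2 * dt)
  if (fc <= 0 || fc >= nyq)
    stop(sprintf("cutoff %g Hz must lie in (0, Nyquist = %g Hz)", fc, nyq))
  bf <- signal::butter(order, fc / nyq, type = "low")
  apply_one <- function(x) as.numeric(signal::filter(bf, x))
  out <- if (adjoint) {
    t(apply(d[, rev(seq_len(ncol(d))), drop = FALSE], 1, apply_one))[, rev(seq_len(ncol(d))), drop = FALSE]
  } else {
    t(apply(d, 1, apply_one))
  }
  if (nrow(d) == 1) out <- matrix(out, 1)
  if (is_sd) {
    data$d <- out
    data$meta <- paste0(data$meta, sprintf("|butter%d@%.3gMHz%s", order, fc / 1e6,
                                           if (adjoint) "^T" else ""))
    data
  } else out
}

#' Sound speed of pure water from temperature
#'
#' Fifth-order polynomial fit for pure water at atmospheric pressure
#' (Marczak 1997), valid for 0-95 degrees Celsius. Used to set the background
#' sound speed from the tank temperature measurement.
#'
#' @param temperature water temperature in degrees Celsius
#' @return sound speed in m/s
#' @examples
#' water_sos(20)  # ~1482.4 m/s
#' @export
water_sos <- function(temperature) {
  if (any(!is.finite(temperature)) || any(temperature < 0) || any(temperature > 95))
    stop("temperature must be within [0, 95] degrees Celsius")
  tt <- temperature
  1.402385e3 + 5.038813 * tt - 5.799136e-2 * tt^2 + 3.287156e-4 * tt^3 -
    1.398845e-6 * tt^4 + 2.787860e-9 * tt^5
}
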