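# First-order thermal-lag model of the tag's temperature sensor.

#' Advance a first-order thermal model
#'
#' A tag (or product) at `current_c` placed in an environment at `ambient_c`
#' relaxes exponentially: after `dt_min` minutes its temperature is
#' `ambient + (current - ambient) * exp(-k * dt_min)`.  The approach is
#' monotone and never overshoots the ambient.
#'
#' @param current_c Current temperature, degC.
#' @param ambient_c Environment temperature, degC.
#' @param k First-order rate constant, per minute (see [calibrate_rate()]).
#' @param dt_min Elapsed time, minutes (vectorised; must be non-negative).
#' @return Temperature(s) after `dt_min` minutes, degC.
#' @export
#' @examples
#' k <- calibrate_rate()
#' tag_temperature_step(23, 5, k, 30)
tag_temperature_step <- function(current_c, ambient_c, k, dt_min) {
  if (any(dt_min < 0)) stop("dt_min must be non-negative", call. = FALSE)
  if (k < 0) stop("rate constant k must be non-negative", call. = FALSE)
  ambient_c + (current_c - ambient_c) * exp(-k * dt_min)
}

#' Calibrate the thermal rate constant from a bench cooling run
#'
#' The sensor's thermal lag is summarised on the bench as a mean cooling speed
#' over an observation window: moved from `start_c` to an environment at
#' `ambient_c`, the tag cooled at `target_mean_rate` degC/min on average over
#' the first `window_min` minutes (0.42 degC/min over 30 min for a 23 -> 5 degC
#' transition by default).  This function recovers the first-order rate
#' constant `k` consistent with that summary by solving
#'
#' `|start - ambient| * (1 - exp(-k * window)) / window = target_mean_rate`
#'
#' with bisection to an absolute tolerance of 1e-9 on `k`.
#'
#' @param start_c Starting temperature, degC.
#' @param ambient_c Environment temperature, degC.
#' @param target_mean_rate Mean approach speed over the window, degC/min
#'   (positive).
#' @param window_min Observation window, minutes.
#' @return The rate constant `k`, per minute.
#' @export
#' @examples
#' k <- calibrate_rate()
#' # mean slope over the window reproduces the bench value:
#' (23 - tag_temperature_step(23, 5, k, 30)) / 30
calibrate_rate <- function(start_c = 23.0, ambient_c = 5.0,
                           target_mean_rate = 0.42, window_min = 30.0) {
  if (start_c == ambient_c) {
    stop("start_c must differ from ambient_c", call. = FALSE)
  }
  if (!is.finite(target_mean_rate) || target_mean_rate <= 0) {
    stop("target_mean_rate must be positive (a zero rate is degenerate)",
         call. = FALSE)
  }
  if (window_min <= 0) stop("window_min must be positive", call. = FALSE)
  gap <- abs(start_c - ambient_c)
  # The mean rate saturates at gap/window as k -> infinity.
  if (target_mean_rate >= gap / window_min) {
    stop(sprintf(
      "calibration error: target %.4g degC/min is unattainable (limit %.4g for a %.4g degC gap over %g min)",
      target_mean_rate, gap / window_min, gap, window_min), call. = FALSE)
  }
  f <- function(k) gap * (1 - exp(-k * window_min)) / window_min - target_mean_rate
  lo <- 0
  hi <- 1
  while (f(hi) < 0) hi <- hi * 2
  while (hi - lo > 1e-9) {
    mid <- (lo + hi) / 2
    if (f(mid) < 0) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

#' Thermal and sampling parameters of the tag sensor
#'
#' @param rate_constant_per_min First-order rate constant of the tag sensor;
#'   by default calibrated so the 30-min mean slope of a 23 -> 5 degC
#'   transition is 0.42 degC/min ([calibrate_rate()]).
#' @param sensor_bias_c Systematic offset of recorded values above the true
#'   temperature (bench comparison against a reference logger), degC.
#' @param quantization_c Resolution of recorded values, degC (0 disables
#'   quantization).
#' @param sampling_interval_min Minutes between successive temperature
#'   recordings.
#' @param product_rate_ratio Rate constant of the blood product itself relative
#'   to the tag's; products equilibrate more slowly than the tag, and only the
#'   tag temperature is observable.
#' @param initial_tag_c Tag temperature at activation (tags are handled at room
#'   temperature before being attached), degC.
#' @return An object of class `thermal_params`.
#' @export
thermal_params <- function(rate_constant_per_min = calibrate_rate(),
                           sensor_bias_c = 0.26,
                           quantization_c = 0.5,
                           sampling_interval_min = 8,
                           product_rate_ratio = 1 / 3,
                           initial_tag_c = 22.0) {
  if (rate_constant_per_min <= 0) stop("rate constant must be positive", call. = FALSE)
  if (sampling_interval_min <= 0) stop("sampling interval must be positive", call. = FALSE)
  if (quantization_c < 0) stop("quantization must be non-negative", call. = FALSE)
  structure(
    list(
      rate_constant_per_min = rate_constant_per_min,
      sensor_bias_c = sensor_bias_c,
      quantization_c = quantization_c,
      sampling_interval_min = sampling_interval_min,
      product_rate_ratio = product_rate_ratio,
      initial_tag_c = initial_tag_c
    ),
    class = "thermal_params"
  )
}

# Half-up quantization to a grid of width q (q = 0 disables).
quantize_temp <- function(x, q) {
  if (q <= 0) return(x)
  floor(x / q + 0.5) * q
}
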