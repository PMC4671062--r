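#' Construct a surface-temperature stimulus trace
#'
#' A stimulus trace is the sampled skin-surface temperature applied by the
#' heat electrode, as a tibble with columns `time_s` (seconds, strictly
#' increasing from 0 = stimulus onset) and `temp_C` (degrees Celsius).
#'
#' @param time_s Numeric vector of sample times in seconds; must start at 0
#'   and be strictly increasing.
#' @param temp_C Numeric vector of surface temperatures in degrees Celsius,
#'   same length as `time_s`; bounded in \[0, 100\].
#' @param ramp_duration_s,hold_duration_s Optional protocol metadata
#'   (seconds), stored as attributes.
#' @return A tibble of class `ncd_trace`.
#' @examples
#' tr <- stimulus_trace(c(0, 16, 26), c(32, 48, 48), 16, 10)
#' surface_temp_at(tr, 8)
#' @export
stimulus_trace <- function(time_s, temp_C, ramp_duration_s = NA_real_,
                           hold_duration_s = NA_real_) {
  if (length(time_s) != length(temp_C) || length(time_s) < 2) {
    abort("`time_s` and `temp_C` must have equal length >= 2.")
  }
  if (time_s[1] != 0) abort("`time_s` must start at 0 (stimulus onset).")
  if (any(diff(time_s) <= 0)) abort("`time_s` must be strictly increasing.")
  if (any(temp_C < 0 | temp_C > 100)) {
    abort("`temp_C` must lie within [0, 100] degrees Celsius.")
  }
  out <- tibble::tibble(time_s = as.numeric(time_s), temp_C = as.numeric(temp_C))
  attr(out, "ramp_duration_s") <- ramp_duration_s
  attr(out, "hold_duration_s") <- hold_duration_s
  class(out) <- c("ncd_trace", class(out))
  out
}

#' Surface temperature of a trace at arbitrary times
#'
#' Linear interpolation of the sampled trace; exact at the sample points.
#'
#' @param trace A [stimulus_trace()].
#' @param t Numeric vector of times in seconds, each within the trace support
#'   \[0, max(time_s)\].
#' @return Numeric vector of temperatures in degrees Celsius.
#' @export
surface_temp_at <- function(trace, t) {
  tmax <- trace$time_s[nrow(trace)]
  if (any(t < 0 | t > tmax)) {
    abort(sprintf("`t` outside trace support [0, %g] s.", tmax))
  }
  approx(trace$time_s, trace$temp_C, xout = t, ties = "ordered")$y
}

#' Trace duration in seconds
#' @param trace A [stimulus_trace()].
#' @return Scalar duration (seconds).
#' @export
trace_duration <- function(trace) trace$time_s[nrow(trace)]

#' Build the ramp-and-hold stimulation protocol
#'
#' Linear ramps from baseline `T0` to `T_peak` over each requested duration,
#' followed by a constant hold. The defaults reproduce the standard
#' skin-nerve protocol: three stimuli from 32 to 48 degrees Celsius with ramp
#' durations 16, 4 and 2 s and a 10 s hold.
#'
#' @param T0 Baseline temperature, degrees Celsius.
#' @param T_peak Peak surface temperature, degrees Celsius.
#' @param ramp_durations_s Numeric vector of ramp durations, seconds.
#' @param hold_s Hold duration at `T_peak` after the ramp, seconds (0 for no
#'   hold).
#' @param dt_s Sampling interval of the emitted traces, seconds.
#' @return A list of [stimulus_trace()] objects, one per ramp duration.
#' @examples
#' prot <- ramp_protocol()
#' vapply(prot, trace_duration, numeric(1)) # 26, 14, 12 s
#' @export
ramp_protocol <- function(T0 = 32, T_peak = 48, ramp_durations_s = c(16, 4, 2),
                          hold_s = 10, dt_s = 0.05) {
  if (T_peak <= T0) abort("`T_peak` must exceed `T0`.")
  if (any(ramp_durations_s <= 0)) abort("Ramp durations must be positive.")
  if (hold_s < 0) abort("`hold_s` must be nonnegative.")
  lapply(ramp_durations_s, function(dur) {
    total <- dur + hold_s
    tt <- sort(unique(c(seq(0, total, by = dt_s), dur, total)))
    temp <- ifelse(tt <= dur, T0 + (T_peak - T0) * tt / dur, T_peak)
    stimulus_trace(tt, temp, ramp_duration_s = dur, hold_duration_s = hold_s)
  })
}

#' Build constant-temperature (step) stimuli
#'
#' Step stimuli jump to a constant supra-threshold surface temperature at
#' onset and stay there; they are the idealized scenario for which the
#' classical intersection method has a closed-form threshold time.
#'
#' @param temps_C Numeric vector of constant surface temperatures, one trace
#'   per entry.
#' @param duration_s Trace duration, seconds.
#' @return A list of [stimulus_trace()] objects.
#' @export
step_protocol <- function(temps_C, duration_s = 30) {
  if (duration_s <= 0) abort("`duration_s` must be positive.")
  lapply(temps_C, function(Ts) {
    stimulus_trace(c(0, duration_s), c(Ts, Ts),
                   ramp_duration_s = 0, hold_duration_s = duration_s)
  })
}

#' Read / write a stimulus trace as CSV
#'
#' CSV with header `time_s,temp_C`, the on-disk interchange format for
#' traces.
#'
#' @param path File path.
#' @return `read_trace()` returns a [stimulus_trace()]; `write_trace()`
#'   returns `path` invisibly.
#' @export
read_trace <- function(path) {
  df <- readr::read_csv(path, col_types = readr::cols(
    time_s = readr::col_double(), temp_C = readr::col_double()
  ))
  stimulus_trace(df$time_s, df$temp_C)
}

#' @rdname read_trace
#' @param trace A [stimulus_trace()].
#' @export
write_trace <- function(trace, path) {
  readr::write_csv(trace[, c("time_s", "temp_C")], path)
  invisible(path)
}
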