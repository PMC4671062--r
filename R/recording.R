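#' Assemble a per-neuron recording
#'
#' A recording bundles, for one neuron, the stimulus traces applied to its
#' receptive field and the conduction-corrected first-spike latency observed
#' under each, plus the baseline temperature. It is stored as a tibble with
#' one row per stimulus (`stimulus`, `latency_s`, list-column `trace`) and
#' attributes `T0` and `neuron_id`.
#'
#' @param traces List of [stimulus_trace()] objects (>= 2).
#' @param latencies_s Numeric vector of first-spike latencies, seconds; each
#'   must be positive and within its trace support. `NA` marks a
#'   non-responsive stimulus.
#' @param T0 Baseline temperature, degrees Celsius.
#' @param neuron_id Label for the neuron.
#' @return A tibble of class `ncd_recording`.
#' @export
recording <- function(traces, latencies_s, T0, neuron_id = "neuron") {
  if (!is.list(traces) || length(traces) < 2) {
    abort("A recording needs at least 2 stimulus traces.")
  }
  if (length(latencies_s) != length(traces)) {
    abort("`latencies_s` must have one entry per trace.")
  }
  for (i in seq_along(traces)) {
    if (!inherits(traces[[i]], "ncd_trace")) {
      abort(sprintf("Stimulus %d: `traces` entries must be stimulus_trace objects.", i))
    }
    li <- latencies_s[i]
    if (!is.na(li) && (li <= 0 || li > trace_duration(traces[[i]]))) {
      abort(sprintf(
        "Stimulus %d: latency %g s outside the trace support (0, %g] s.",
        i, li, trace_duration(traces[[i]])
      ))
    }
  }
  out <- tibble::tibble(
    stimulus = seq_along(traces),
    latency_s = as.numeric(latencies_s),
    trace = traces
  )
  attr(out, "T0") <- T0
  attr(out, "neuron_id") <- neuron_id
  class(out) <- c("ncd_recording", class(out))
  out
}

#' Recording accessors
#' @param rec An [recording()] object.
#' @return `baseline_temp()`: the baseline temperature (degrees Celsius);
#'   `neuron_id()`: the neuron label; `n_stimuli()`: the number of stimuli.
#' @export
baseline_temp <- function(rec) attr(rec, "T0")

#' @rdname baseline_temp
#' @export
neuron_id <- function(rec) attr(rec, "neuron_id")

#' @rdname baseline_temp
#' @export
n_stimuli <- function(rec) nrow(rec)

# Stimuli with an observed (non-NA) latency.
responsive_idx <- function(rec) which(!is.na(rec$latency_s))

#' Write / read a recording bundle
#'
#' A bundle is a directory with one CSV per stimulus trace
#' (`trace_<i>.csv`, header `time_s,temp_C`) and a `manifest.json` holding
#' the latencies, baseline temperature and neuron id. The round trip
#' `read_recording(write_recording(rec, d))` reproduces the values.
#'
#' @param rec An [recording()].
#' @param dir Bundle directory (created if missing).
#' @return `write_recording()` returns `dir` invisibly; `read_recording()`
#'   returns the validated [recording()].
#' @export
write_recording <- function(rec, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- sprintf("trace_%d.csv", rec$stimulus)
  for (i in seq_len(nrow(rec))) {
    write_trace(rec$trace[[i]], file.path(dir, files[i]))
  }
  manifest <- list(
    neuron_id = neuron_id(rec),
    T0_C = baseline_temp(rec),
    stimuli = lapply(seq_len(nrow(rec)), function(i) {
      list(index = rec$stimulus[i], trace_file = files[i],
           latency_s = rec$latency_s[i])
    })
  )
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(dir)
}

#' @rdname write_recording
#' @export
read_recording <- function(dir) {
  mpath <- file.path(dir, "manifest.json")
  if (!file.exists(mpath)) abort(sprintf("No manifest.json in '%s'.", dir))
  manifest <- jsonlite::read_json(mpath)
  traces <- vector("list", length(manifest$stimuli))
  lat <- numeric(length(manifest$stimuli))
  for (i in seq_along(manifest$stimuli)) {
    st <- manifest$stimuli[[i]]
    fp <- file.path(dir, st$trace_file)
    if (!file.exists(fp)) {
      abort(sprintf("Stimulus %d: trace file '%s' is missing.", i, st$trace_file))
    }
    traces[[i]] <- tryCatch(read_trace(fp), error = function(e) {
      abort(sprintf("Stimulus %d: invalid trace '%s': %s", i, st$trace_file,
                    conditionMessage(e)))
    })
    lat[i] <- if (is.null(st$latency_s)) NA_real_ else st$latency_s
  }
  tryCatch(
    recording(traces, lat, T0 = manifest$T0_C,
              neuron_id = manifest$neuron_id %||% "neuron"),
    error = function(e) abort(sprintf("Invalid recording bundle: %s",
                                      conditionMessage(e)))
  )
}
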