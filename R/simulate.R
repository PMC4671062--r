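# Ground-truth simulator of the stimulation protocol: the generative model
# the estimators assume, plus a spontaneous (Poisson) outlier process.
# Recorded latency = threshold-crossing time + Exp(delay_rate) delay; when
# an outlier process is active, an independent Exp(outlier_rate) spontaneous
# spike competes and the earlier event is recorded (race model).

#' Define a ground-truth neuron
#'
#' @param depth_mm True receptor depth, mm (>= 0).
#' @param t_threshold True threshold temperature, degrees Celsius.
#' @param skin A [skin_params()]; fixes the diffusivity that maps depth to
#'   normalized depth.
#' @param delay_rate Rate of the exponential threshold-to-spike delay,
#'   s^-1 (`Inf` = zero delays, the noise-free limit).
#' @param outlier_rate Rate of the spontaneous Poisson spike process, s^-1,
#'   or `NULL` for no outlier process.
#' @param id Neuron label.
#' @return A list of class `ncd_neuron` (includes the implied `gamma`).
#' @export
ground_truth_neuron <- function(depth_mm, t_threshold, skin = skin_params(),
                                delay_rate = Inf, outlier_rate = NULL,
                                id = "sim") {
  if (depth_mm < 0) abort("`depth_mm` must be nonnegative.")
  structure(
    list(depth_mm = depth_mm, t_threshold = t_threshold,
         gamma = gamma_from_depth(depth_mm, skin), skin = skin,
         delay_rate = delay_rate, outlier_rate = outlier_rate, id = id),
    class = "ncd_neuron"
  )
}

#' Simulate a recording from a ground-truth neuron
#'
#' For each stimulus the threshold-crossing time is computed with
#' [threshold_time()] and an exponential delay added. With an active
#' outlier process, an independent spontaneous spike time is drawn and the
#' earlier of the two events is recorded; which one won is kept in the
#' `ground_truth` attribute. Latencies falling outside the trace support
#' (threshold never crossed and no earlier spontaneous spike) are recorded
#' as `NA` (non-responsive).
#'
#' @param neuron A [ground_truth_neuron()].
#' @param protocol List of [stimulus_trace()] objects (default: the
#'   standard [ramp_protocol()]).
#' @param T0 Baseline temperature, degrees Celsius.
#' @param seed Optional integer seed.
#' @return An [recording()] whose `ground_truth` attribute is a tibble with
#'   per-stimulus `t_star_s`, `delay_s`, `spont_s`, `is_outlier`.
#' @export
simulate_recording <- function(neuron, protocol = ramp_protocol(), T0 = 32,
                               seed = NULL) {
  sim <- function() {
    n <- length(protocol)
    tstar <- vapply(protocol, function(tr) {
      threshold_time(neuron$t_threshold, T0, neuron$gamma, tr)
    }, numeric(1))
    delays <- if (is.finite(neuron$delay_rate)) {
      rexp(n, neuron$delay_rate)
    } else {
      rep(0, n)
    }
    driven <- tstar + delays
    spont <- if (is.null(neuron$outlier_rate)) rep(Inf, n) else {
      rexp(n, neuron$outlier_rate)
    }
    lat <- pmin(driven, spont)
    dur <- vapply(protocol, trace_duration, numeric(1))
    lat[lat > dur | lat <= 0] <- NA_real_
    gt <- tibble::tibble(
      stimulus = seq_len(n), t_star_s = tstar, delay_s = delays,
      spont_s = spont, latency_s = lat,
      is_outlier = !is.na(lat) & spont < driven
    )
    rec <- recording(protocol, lat, T0 = T0, neuron_id = neuron$id)
    attr(rec, "ground_truth") <- gt
    attr(rec, "neuron") <- neuron
    rec
  }
  if (is.null(seed)) sim() else withr::with_seed(seed, sim())
}

#' Ground truth stored with a simulated recording
#' @param rec A recording from [simulate_recording()].
#' @return The per-stimulus ground-truth tibble (or `NULL`).
#' @export
ground_truth <- function(rec) attr(rec, "ground_truth")

#' Replace one latency by a spontaneous outlier spike
#'
#' Draws a spontaneous spike time from an exponential process with rate
#' `rate`, conditioned on preempting the currently recorded (stimulus-
#' driven) first spike — i.e. the race model of [simulate_recording()]
#' conditioned on the spontaneous process winning. Used to construct
#' recordings with exactly one outlier for recovery experiments.
#'
#' @param rec A recording (its `ground_truth` attribute, if any, is
#'   updated).
#' @param stimulus Index of the stimulus whose latency is replaced.
#' @param rate Spontaneous rate, s^-1.
#' @param seed Optional integer seed.
#' @return The modified recording.
#' @export
inject_outlier <- function(rec, stimulus, rate = 1, seed = NULL) {
  draw <- function() {
    lat0 <- rec$latency_s[stimulus]
    if (is.na(lat0)) abort("Cannot inject an outlier into a non-responsive stimulus.")
    # Exp(rate) truncated to (0, lat0): inverse-CDF draw.
    u <- runif(1)
    -log(1 - u * (1 - exp(-rate * lat0))) / rate
  }
  sp <- if (is.null(seed)) draw() else withr::with_seed(seed, draw())
  rec$latency_s[stimulus] <- sp
  gt <- attr(rec, "ground_truth")
  if (!is.null(gt)) {
    gt$spont_s[stimulus] <- sp
    gt$latency_s[stimulus] <- sp
    gt$is_outlier[stimulus] <- TRUE
    attr(rec, "ground_truth") <- gt
  }
  rec
}

#' Simulate a cohort of neurons drawn from the priors
#'
#' Depth is drawn from the scaled Beta prior and threshold from the Normal
#' prior (truncated to `(T0 + 1, 45)` degrees Celsius so that every
#' threshold is crossable under the default 32-48 protocol). Skin
#' parameters are fixed at the prior midpoints for the whole cohort by
#' default (`skin = "midpoint"`), so that depth-recovery error measures the
#' estimator rather than diffusivity uncertainty; `skin = "draw"` samples
#' them per neuron instead. A Bernoulli(`outlier_fraction`) coin decides
#' which neurons carry an active spontaneous outlier process.
#'
#' @param n_neurons Number of neurons.
#' @param prior A [prior_spec()].
#' @param protocol List of stimulus traces.
#' @param T0 Baseline temperature, degrees Celsius.
#' @param delay_rate Exponential delay rate shared by all neurons, s^-1.
#' @param outlier_fraction Fraction of neurons with an active outlier
#'   process (Bernoulli per neuron).
#' @param outlier_rate Spontaneous rate for outlier neurons, s^-1.
#' @param skin `"midpoint"`, `"draw"`, or a [skin_params()] shared by all.
#' @param seed Optional integer seed (applies to the whole cohort).
#' @param convention Diffusivity convention.
#' @return A tibble with one row per neuron: `id`, `depth_mm`,
#'   `t_threshold`, `has_outlier_process`, and list-columns `neuron`,
#'   `recording`.
#' @export
simulate_cohort <- function(n_neurons, prior = prior_spec(),
                            protocol = ramp_protocol(), T0 = 32,
                            delay_rate = 1, outlier_fraction = 0,
                            outlier_rate = 1, skin = "midpoint", seed = NULL,
                            convention = c("standard", "paper_sqrt")) {
  if (outlier_fraction < 0 || outlier_fraction > 1) {
    abort("`outlier_fraction` must be in [0, 1].")
  }
  convention <- match.arg(convention)
  sim <- function() {
    rows <- purrr::map(seq_len(n_neurons), function(i) {
      sk <- if (inherits(skin, "ncd_skin")) skin
      else if (identical(skin, "midpoint")) midpoint_skin(prior, convention)
      else if (identical(skin, "draw")) {
        sp <- sample_skin_params(prior, 1, convention = convention)
        skin_params(sp$k, sp$rho, sp$c, convention = convention)
      } else abort("`skin` must be 'midpoint', 'draw', or a skin_params object.")
      depth <- rbeta(1, prior$depth_shape1, prior$depth_shape2) *
        prior$depth_max_um / 1000
      repeat {
        thr <- stats::rnorm(1, prior$threshold_mean, prior$threshold_sd)
        if (thr > T0 + 1 && thr < 45) break
      }
      has_out <- runif(1) < outlier_fraction
      neuron <- ground_truth_neuron(
        depth, thr, sk, delay_rate = delay_rate,
        outlier_rate = if (has_out) outlier_rate else NULL,
        id = sprintf("sim_%03d", i)
      )
      rec <- simulate_recording(neuron, protocol, T0 = T0)
      tibble::tibble(id = neuron$id, depth_mm = depth, t_threshold = thr,
                     has_outlier_process = has_out,
                     neuron = list(neuron), recording = list(rec))
    })
    dplyr::bind_rows(rows)
  }
  if (is.null(seed)) sim() else withr::with_seed(seed, sim())
}

#' Parameter recovery over a simulated cohort
#'
#' Fits the requested estimator to every recording of a cohort and tabulates
#' estimated against true parameters.
#'
#' @param cohort Output of [simulate_cohort()].
#' @param method `"mle"` or `"classical"`.
#' @param skin A [skin_params()] used by the estimator (defaults to the
#'   cohort convention's midpoint skin).
#' @param ... Passed to [fit_mle()] / [fit_classical()].
#' @return A tibble with true values, estimates and signed errors
#'   (`err_depth_mm`, `err_t_threshold`).
#' @export
cohort_recovery <- function(cohort, method = c("mle", "classical"),
                            skin = NULL, ...) {
  method <- match.arg(method)
  skin <- skin %||% cohort$neuron[[1]]$skin
  rows <- purrr::map(seq_len(nrow(cohort)), function(i) {
    rec <- cohort$recording[[i]]
    est <- if (method == "mle") {
      f <- fit_mle(rec, skin = skin, ...)
      tibble::tibble(est_t_threshold = f$t_threshold, est_depth_mm = f$depth_mm,
                     est_gamma = f$gamma, status = if (f$converged) "ok" else "failed")
    } else {
      f <- fit_classical(rec, skin = skin, ...)
      tibble::tibble(est_t_threshold = f$t_threshold, est_depth_mm = f$depth_mm,
                     est_gamma = f$gamma, status = f$status)
    }
    dplyr::bind_cols(
      tibble::tibble(id = cohort$id[i], true_depth_mm = cohort$depth_mm[i],
                     true_t_threshold = cohort$t_threshold[i]),
      est
    )
  })
  out <- dplyr::bind_rows(rows)
  out$err_depth_mm <- out$est_depth_mm - out$true_depth_mm
  out$err_t_threshold <- out$est_t_threshold - out$true_t_threshold
  out
}
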