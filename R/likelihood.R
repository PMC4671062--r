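# Maximum-likelihood estimation of (T_threshold, gamma) with nonnegative,
# exponentially distributed delays between threshold crossing and first
# spike. The delay of stimulus i is Delta_i = latency_i - t*_i(T, gamma);
# any negative delay (or a threshold never crossed) makes the parameter
# pair infeasible.

#' Implied response delay for one stimulus
#'
#' Inverts the latency equation: `Delta = latency - t*(T_threshold, gamma)`,
#' where `t*` is the quasi-static threshold-crossing time of the stimulus.
#' Returns `-Inf`-free semantics via `NA`: `NA` means infeasible (threshold
#' never crossed within the trace, or the crossing happens after the
#' observed spike).
#'
#' @inheritParams threshold_time
#' @param latency_s Observed first-spike latency, seconds.
#' @return Scalar delay in seconds, or `NA` if infeasible.
#' @export
delay_of <- function(T_threshold, gamma, trace, latency_s, T0) {
  tstar <- threshold_time(T_threshold, T0, gamma, trace)
  d <- latency_s - tstar
  if (!is.finite(tstar) || d < 0) NA_real_ else d
}

#' Delay log likelihood at a parameter pair
#'
#' `sum_i (log lambda - lambda * Delta_i)` over the (retained) stimuli when
#' every implied delay is feasible; `-Inf` when any is not. With `lambda`
#' fixed, maximizing this likelihood is minimizing the total delay subject
#' to all delays being nonnegative, so the optimum sits on the feasibility
#' boundary and coincides with the classical intersection whenever that
#' exists.
#'
#' @param T_threshold Threshold temperature, degrees Celsius.
#' @param gamma Normalized depth, s^(1/2).
#' @param rec An [recording()].
#' @param rate_lambda Delay rate parameter, s^-1 (default 1).
#' @param retain Integer indices of stimuli to include (default: all
#'   responsive ones).
#' @return Scalar log likelihood (`-Inf` if infeasible).
#' @export
log_likelihood <- function(T_threshold, gamma, rec, rate_lambda = 1,
                           retain = responsive_idx(rec)) {
  if (rate_lambda <= 0) abort("`rate_lambda` must be positive.")
  T0 <- baseline_temp(rec)
  ll <- 0
  for (i in retain) {
    d <- delay_of(T_threshold, gamma, rec$trace[[i]], rec$latency_s[i], T0)
    if (is.na(d)) return(-Inf)
    ll <- ll + log(rate_lambda) - rate_lambda * d
  }
  ll
}

# Log-likelihood matrix over a (gamma, T) grid, using the vectorized
# interpolated threshold times. Rows = gamma, cols = T. -Inf at infeasible
# points.
loglik_grid <- function(rec, gamma_grid, T_grid, rate_lambda = 1,
                        retain = responsive_idx(rec)) {
  T0 <- baseline_temp(rec)
  ll <- matrix(0, nrow = length(gamma_grid), ncol = length(T_grid))
  for (i in retain) {
    tstar <- threshold_time_grid(rec$trace[[i]], T0, gamma_grid, T_grid)
    d <- rec$latency_s[i] - tstar
    term <- log(rate_lambda) - rate_lambda * d
    term[!is.finite(tstar) | d < 0] <- -Inf
    ll <- ll + term
  }
  ll
}

#' Search-control settings for [fit_mle()]
#'
#' The likelihood is maximized by exploiting its structure: for fixed
#' gamma, the log likelihood increases in `T_threshold` up to the
#' feasibility envelope `T_env(gamma) = min_i` (consistency curve of
#' stimulus i), and every envelope point is feasible, so the 2-D
#' constrained problem reduces exactly to a 1-D maximization along the
#' envelope. A coarse gamma grid locates the basin (ties broken toward
#' smaller gamma, i.e. shallower); [stats::optimize()] refines within one
#' grid spacing using exact root-finding. Deterministic.
#'
#' @param n_gamma Coarse gamma grid size (default 400).
#' @param refine_tol Gamma tolerance of the local refinement, s^(1/2).
#' @param T_max Upper end of the threshold search; `NULL` = maximum recorded
#'   surface temperature.
#' @param gamma_max Upper end of the gamma search; `NULL` = gamma of twice
#'   the assumed 1 mm skin thickness.
#' @return A list of class `ncd_mle_control`.
#' @export
mle_control <- function(n_gamma = 400L, refine_tol = 1e-7, T_max = NULL,
                        gamma_max = NULL) {
  structure(list(n_gamma = n_gamma, refine_tol = refine_tol, T_max = T_max,
                 gamma_max = gamma_max),
            class = "ncd_mle_control")
}

# Largest threshold consistent with stimulus i at normalized depth gamma:
# the running maximum of the quasi-static temperature-at-depth curve at the
# observed latency. For nondecreasing traces this is simply the attenuated
# surface temperature at the latency (the classical consistency curve).
envelope_T_one <- function(trace, latency_s, T0, gamma) {
  if (!is.unsorted(trace$temp_C)) {
    return(attenuated_temperature(surface_temp_at(trace, latency_s), T0,
                                  gamma, latency_s))
  }
  tg <- scan_times(trace)
  tg <- c(tg[tg < latency_s], latency_s)
  S <- surface_temp_at(trace, tg)
  vapply(gamma, function(g) {
    max(T0 + (S - T0) * erfc_(g / sqrt(tg)))
  }, numeric(1))
}

# Vectorized first-crossing times of level T_target[j] at gamma[j] for a
# nondecreasing trace (bisection on the monotone quasi-static curve).
# Assumes T_target <= running max at `latency` so a crossing exists.
tstar_bisect <- function(trace, T0, gamma, T_target, t_upper, iters = 52L) {
  lo <- rep(1e-12, length(gamma))
  hi <- t_upper
  for (k in seq_len(iters)) {
    mid <- (lo + hi) / 2
    v <- T0 + (surface_temp_at(trace, mid) - T0) * erfc_(gamma / sqrt(mid))
    up <- v >= T_target
    hi[up] <- mid[up]
    lo[!up] <- mid[!up]
  }
  hi
}

#' Maximum-likelihood fit of threshold and depth with exponential delays
#'
#' Jointly maximizes the delay log likelihood over
#' `T_threshold in (T0, T_max]` and `gamma in [0, gamma_max]` restricted to
#' the feasible region (all implied delays nonnegative). The optimum always
#' lies on the feasibility envelope (some delay is exactly zero), so the
#' search runs along the envelope; see [mle_control()]. For negligibly
#' small delays the optimum converges to the classical single-intersection
#' estimate.
#'
#' @param rec An [recording()].
#' @param skin A [skin_params()] used to report gamma as a physical depth.
#' @param rate_lambda Delay rate parameter, s^-1 (default 1; the optimum in
#'   `(T, gamma)` does not depend on it).
#' @param control An [mle_control()].
#' @param retain Stimulus indices to fit (default all responsive); used by
#'   the model-selection module to exclude suspected outliers.
#' @return An object of class `ncd_mle` with fields `t_threshold`, `gamma`,
#'   `depth_mm`, `delays` (tibble, one row per retained stimulus), `loglik`,
#'   `converged`, plus inputs. `converged = FALSE` with an all-`NA` estimate
#'   signals an empty feasible region (never silent).
#' @export
fit_mle <- function(rec, skin = skin_params(), rate_lambda = 1,
                    control = mle_control(), retain = responsive_idx(rec)) {
  if (length(retain) < 2) abort("`fit_mle()` needs >= 2 retained stimuli.")
  T0 <- baseline_temp(rec)
  traces <- rec$trace[retain]
  taus <- rec$latency_s[retain]
  T_max <- control$T_max %||%
    max(vapply(traces, function(tr) max(tr$temp_C), numeric(1)))
  gamma_max <- control$gamma_max %||% gamma_from_depth(2, skin)
  monotone <- vapply(traces, function(tr) !is.unsorted(tr$temp_C), logical(1))

  # Objective along the envelope: at gamma, T = min(T_env(gamma), T_max) and
  # loglik = sum_i log(lambda) - lambda * (tau_i - t*_i).
  obj_grid <- function(gg) {
    envs <- vapply(seq_along(traces), function(ii) {
      envelope_T_one(traces[[ii]], taus[ii], T0, gg)
    }, numeric(length(gg)))
    envs <- matrix(envs, nrow = length(gg))
    Tt <- pmin(apply(envs, 1, min), T_max)
    ok <- Tt > T0 + 1e-9
    val <- rep(-Inf, length(gg))
    if (any(ok)) {
      total_delay <- rep(0, length(gg))
      for (ii in seq_along(traces)) {
        ts <- if (monotone[ii]) {
          tstar_bisect(traces[[ii]], T0, gg[ok], Tt[ok], rep(taus[ii], sum(ok)))
        } else {
          vapply(which(ok), function(r) {
            threshold_time(Tt[r], T0, gg[r], traces[[ii]])
          }, numeric(1))
        }
        total_delay[ok] <- total_delay[ok] + (taus[ii] - pmin(ts, taus[ii]))
      }
      val[ok] <- length(traces) * log(rate_lambda) - rate_lambda * total_delay[ok]
    }
    list(T = Tt, value = val)
  }

  gg <- seq(0, gamma_max, length.out = control$n_gamma)
  coarse <- obj_grid(gg)
  if (all(!is.finite(coarse$value))) {
    return(structure(
      list(t_threshold = NA_real_, gamma = NA_real_, depth_mm = NA_real_,
           delays = tibble::tibble(stimulus = rec$stimulus[retain],
                                   delay_s = NA_real_),
           loglik = -Inf, converged = FALSE, feasible = FALSE,
           rate_lambda = rate_lambda, retain = retain,
           recording = rec, skin = skin, control = control,
           diagnostics = list(message = "empty feasible region: no threshold above baseline is consistent with any stimulus",
                              gamma_range = range(gg))),
      class = "ncd_mle"))
  }
  b <- which(coarse$value == max(coarse$value))[1]  # ties -> smaller gamma
  lo <- gg[max(1, b - 1)]
  hi <- gg[min(length(gg), b + 1)]
  obj_scalar <- function(g) obj_grid(g)$value
  opt <- stats::optimize(obj_scalar, lower = lo, upper = hi, maximum = TRUE,
                         tol = control$refine_tol)
  g_hat <- if (opt$objective >= coarse$value[b]) opt$maximum else gg[b]
  at <- obj_grid(g_hat)
  T_hat <- at$T

  delays <- vapply(seq_along(retain), function(ii) {
    ts <- threshold_time(T_hat, T0, g_hat, traces[[ii]])
    d <- taus[ii] - ts
    if (!is.finite(ts) || d < -1e-6) NA_real_ else max(d, 0)
  }, numeric(1))
  ll_exact <- if (anyNA(delays)) at$value else {
    sum(log(rate_lambda) - rate_lambda * delays)
  }
  structure(
    list(t_threshold = T_hat, gamma = g_hat,
         depth_mm = depth_from_gamma(g_hat, skin),
         delays = tibble::tibble(stimulus = rec$stimulus[retain],
                                 delay_s = delays),
         loglik = ll_exact,
         converged = TRUE, feasible = TRUE,
         rate_lambda = rate_lambda, retain = retain,
         recording = rec, skin = skin, control = control,
         diagnostics = list()),
    class = "ncd_mle"
  )
}

#' @export
print.ncd_mle <- function(x, ...) {
  cat("Probabilistic (delay) ML estimate (", neuron_id(x$recording), ")\n", sep = "")
  if (!x$converged) {
    cat("  estimation failed:", x$diagnostics$message, "\n")
    return(invisible(x))
  }
  cat(sprintf("  T_threshold: %.2f C   depth: %.3f mm (gamma %.4f s^1/2)\n",
              x$t_threshold, x$depth_mm, x$gamma))
  cat(sprintf("  log lik: %.4f   delays (s): %s\n", x$loglik,
              paste(sprintf("%.3g", x$delays$delay_s), collapse = ", ")))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.ncd_mle <- function(x, ...) x$delays

#' @exportS3Method generics::glance
glance.ncd_mle <- function(x, ...) {
  tibble::tibble(
    neuron_id = neuron_id(x$recording),
    t_threshold = x$t_threshold, gamma = x$gamma, depth_mm = x$depth_mm,
    loglik = x$loglik, converged = x$converged,
    n_retained = length(x$retain), rate_lambda = x$rate_lambda
  )
}
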