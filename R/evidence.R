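# Marginal-likelihood model selection. Candidates: the full model (all
# first spikes stimulus-driven) and one exclusion model per stimulus, in
# which that stimulus's first spike is a spontaneous Poisson-process event.
# Evidence = E_prior[likelihood], computed by trapezoidal integration over
# the (T_threshold, gamma) plane; the excluded spike contributes a
# separable factor: the exponential density at its latency, averaged over
# the lambda_s prior (the Dirac treatment of the outlier component makes
# the factor exact).

trapz2d <- function(x, y, F) {
  # F: length(x) rows, length(y) cols
  inner <- vapply(seq_along(x), function(i) pracma::trapz(y, F[i, ]),
                  numeric(1))
  pracma::trapz(x, inner)
}

#' Log marginal likelihood of a candidate model
#'
#' Integrates `exp(log_likelihood(T, gamma)) * p(T) * p(gamma)` over the
#' grid by the trapezoidal rule (log-evidence accumulated with a max-shift
#' for numerical safety); infeasible points contribute zero. For an
#' exclusion model, the retained stimuli enter the likelihood and the
#' excluded latency contributes the separable spontaneous-spike factor
#' `E_{lambda_s}[lambda_s exp(-lambda_s tau)]` under the uniform
#' `lambda_s` prior, integrated by trapezoid.
#'
#' @param rec An [recording()].
#' @param exclude Stimulus index treated as a spontaneous outlier, or `NULL`
#'   for the full model.
#' @param prior A [prior_spec()] (threshold prior and lambda_s prior).
#' @param gamma_prior An `ncd_gamma_prior` from [fit_gamma_prior()].
#' @param rate_lambda Delay rate parameter, s^-1.
#' @param grid A list with `n_T`, `n_gamma`, `T_max`, `gamma_max`,
#'   `n_lambda_s` as produced by [evidence_grid()].
#' @param skin A [skin_params()] (anchors the default `gamma_max`).
#' @return Scalar log evidence (`-Inf`, with a warning, if the grid carries
#'   no feasible mass).
#' @export
marginal_likelihood <- function(rec, exclude = NULL, prior = prior_spec(),
                                gamma_prior, rate_lambda = 1,
                                grid = evidence_grid(), skin = skin_params()) {
  idx <- responsive_idx(rec)
  retain <- if (is.null(exclude)) idx else setdiff(idx, exclude)
  if (length(retain) < 2) abort("Need >= 2 retained stimuli for the evidence.")
  T0 <- baseline_temp(rec)
  T_max <- grid$T_max %||%
    max(vapply(rec$trace[idx], function(tr) max(tr$temp_C), numeric(1)))
  gamma_max <- grid$gamma_max %||% gamma_from_depth(2, skin)
  T_grid <- grid$T_grid %||% seq(T0 + 1e-3, T_max, length.out = grid$n_T)
  g_grid <- grid$gamma_grid %||% seq(0, gamma_max, length.out = grid$n_gamma)

  ll <- loglik_grid(rec, g_grid, T_grid, rate_lambda, retain)
  m <- suppressWarnings(max(ll[is.finite(ll)]))
  if (!is.finite(m)) {
    warn("Evidence grid carries no feasible likelihood mass; returning -Inf.")
    return(-Inf)
  }
  W <- exp(ll - m)
  W[!is.finite(ll)] <- 0
  F <- W * (dgamma_mixture(g_grid, gamma_prior) %o% dprior_threshold(T_grid, prior))
  log_ev <- m + log(trapz2d(g_grid, T_grid, F))
  if (!is.null(exclude)) {
    log_ev <- log_ev + log(outlier_factor(rec$latency_s[exclude], prior,
                                          n_lambda_s = grid$n_lambda_s))
  }
  log_ev
}

#' Spontaneous-spike evidence factor
#'
#' Expectation of the exponential first-spike density at the excluded
#' latency over the uniform `lambda_s` prior:
#' `(b - a)^-1 integral_a^b lambda exp(-lambda tau) dlambda`, computed by
#' trapezoid. Independent of the `(T, gamma)` grid.
#'
#' @param latency_s Excluded first-spike latency, seconds.
#' @param prior A [prior_spec()] (its `lambda_s` range is used).
#' @param n_lambda_s Number of trapezoid points.
#' @return Scalar factor (units s^-1).
#' @export
outlier_factor <- function(latency_s, prior = prior_spec(), n_lambda_s = 200L) {
  ls <- seq(prior$lambda_s[1], prior$lambda_s[2], length.out = n_lambda_s)
  pracma::trapz(ls, ls * exp(-ls * latency_s)) / diff(prior$lambda_s)
}

#' Integration-grid settings for the evidence
#'
#' @param n_T,n_gamma Trapezoid grid sizes over threshold and gamma
#'   (default 150 x 150).
#' @param T_max,gamma_max Upper integration limits; `NULL` = maximum
#'   recorded surface temperature and gamma of twice the assumed 1 mm skin
#'   thickness.
#' @param n_lambda_s Trapezoid points for the lambda_s expectation.
#' @param T_grid,gamma_grid Optional explicit grids overriding the automatic
#'   ones (used e.g. to concentrate quadrature under a near-degenerate
#'   prior).
#' @return A list.
#' @export
evidence_grid <- function(n_T = 150L, n_gamma = 150L, T_max = NULL,
                          gamma_max = NULL, n_lambda_s = 200L,
                          T_grid = NULL, gamma_grid = NULL) {
  list(n_T = n_T, n_gamma = n_gamma, T_max = T_max, gamma_max = gamma_max,
       n_lambda_s = n_lambda_s, T_grid = T_grid, gamma_grid = gamma_grid)
}

#' Model selection over full and stimulus-exclusion models
#'
#' Computes the marginal likelihood of the full model and of every
#' single-stimulus exclusion model, normalizes them to weights summing to
#' 1, selects the maximum-evidence candidate, and reports the
#' maximum-likelihood estimate under the selected model (outliers, if any,
#' excluded from the fit).
#'
#' @inheritParams marginal_likelihood
#' @param mle_ctrl An [mle_control()] for the reported estimate.
#' @return An object of class `ncd_selection`: `evidence` tibble (one row
#'   per candidate: `model`, `excluded`, `log_evidence`, `weight`),
#'   `selected`, `weight_full` (the normalized full-model evidence), and
#'   `fit` (the `ncd_mle` under the selected model). [tidy()] returns the
#'   evidence table; [glance()] a one-row summary.
#' @export
fit_selection <- function(rec, prior = prior_spec(), gamma_prior,
                          rate_lambda = 1, grid = evidence_grid(),
                          skin = skin_params(), mle_ctrl = mle_control()) {
  idx <- responsive_idx(rec)
  if (length(idx) < 3) {
    abort("Model selection needs >= 3 responsive stimuli (exclusions must leave >= 2).")
  }
  cand <- tibble::tibble(
    model = c("full", sprintf("exclude_%d", rec$stimulus[idx])),
    excluded = c(NA_integer_, rec$stimulus[idx])
  )
  log_ev <- vapply(seq_len(nrow(cand)), function(r) {
    ex <- if (is.na(cand$excluded[r])) NULL else cand$excluded[r]
    marginal_likelihood(rec, exclude = ex, prior = prior,
                        gamma_prior = gamma_prior, rate_lambda = rate_lambda,
                        grid = grid, skin = skin)
  }, numeric(1))
  if (all(!is.finite(log_ev))) {
    abort("Selection failure: all candidate evidences are zero.")
  }
  w <- exp(log_ev - max(log_ev[is.finite(log_ev)]))
  w[!is.finite(log_ev)] <- 0
  w <- w / sum(w)
  cand$log_evidence <- log_ev
  cand$weight <- w
  sel <- which.max(log_ev)
  retain <- if (is.na(cand$excluded[sel])) idx else setdiff(idx, cand$excluded[sel])
  fit <- fit_mle(rec, skin = skin, rate_lambda = rate_lambda,
                 control = mle_ctrl, retain = retain)
  structure(
    list(evidence = cand, selected = cand$model[sel],
         excluded = cand$excluded[sel],
         weight_full = w[cand$model == "full"],
         fit = fit, prior = prior, gamma_prior = gamma_prior,
         grid = grid, recording = rec, skin = skin),
    class = "ncd_selection"
  )
}

#' @export
print.ncd_selection <- function(x, ...) {
  cat("Marginal-likelihood model selection (", neuron_id(x$recording), ")\n",
      sep = "")
  cat("  selected:", x$selected,
      sprintf("(normalized full-model weight %.3f)\n", x$weight_full))
  print(x$evidence)
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.ncd_selection <- function(x, ...) x$evidence

#' @exportS3Method generics::glance
glance.ncd_selection <- function(x, ...) {
  tibble::tibble(
    neuron_id = neuron_id(x$recording), selected = x$selected,
    excluded = x$excluded, weight_full = x$weight_full,
    t_threshold = x$fit$t_threshold, gamma = x$fit$gamma,
    depth_mm = x$fit$depth_mm, converged = x$fit$converged
  )
}
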