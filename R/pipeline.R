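# Configuration and the one-call analysis pipeline: classical, full-MLE
# and model-selection estimates for one recording, with the effective
# configuration echoed into every report.

#' Analysis configuration
#'
#' Collects every tunable of the analysis with its documented default.
#' Unspecified fields take the defaults; the effective configuration (and
#' its hash) is echoed into every report written by [run_pipeline()].
#'
#' @param prior A [prior_spec()].
#' @param rate_lambda Delay rate parameter lambda, s^-1.
#' @param convention Diffusivity convention, see [alpha_from_krc()].
#' @param skin A [skin_params()] or `NULL` for the prior midpoints.
#' @param mle An [mle_control()].
#' @param grid An [evidence_grid()].
#' @param point_tol,triangle_tol Classical classification tolerances,
#'   `(degrees Celsius, mm)`.
#' @param gamma_prior_n,gamma_prior_seed Sample size and seed of the
#'   Gaussian-mixture gamma-prior fit.
#' @param seed Master seed recorded in reports.
#' @return A list of class `ncd_config`.
#' @export
analysis_config <- function(prior = prior_spec(), rate_lambda = 1,
                            convention = c("standard", "paper_sqrt"),
                            skin = NULL, mle = mle_control(),
                            grid = evidence_grid(),
                            point_tol = c(0.2, 0.02), triangle_tol = c(2, 0.2),
                            gamma_prior_n = 5e4, gamma_prior_seed = 20151207,
                            seed = 1L) {
  convention <- match.arg(convention)
  skin <- skin %||% midpoint_skin(prior, convention)
  structure(list(prior = prior, rate_lambda = rate_lambda,
                 convention = convention, skin = skin, mle = mle, grid = grid,
                 point_tol = point_tol, triangle_tol = triangle_tol,
                 gamma_prior_n = gamma_prior_n,
                 gamma_prior_seed = gamma_prior_seed, seed = seed),
            class = "ncd_config")
}

#' Read an analysis configuration from YAML
#'
#' Every field is optional; unspecified fields keep the documented
#' defaults. Recognized top-level keys: `rate_lambda`, `convention`,
#' `seed`, `gamma_prior_n`, `gamma_prior_seed`, `point_tol`, `triangle_tol`,
#' and the nested blocks `prior` (fields of [prior_spec()]), `skin`
#' (`k`, `rho`, `c`), `mle` (fields of [mle_control()]) and `grid` (fields
#' of [evidence_grid()]).
#'
#' @param path YAML file path.
#' @return An [analysis_config()].
#' @export
read_config <- function(path) {
  y <- yaml::read_yaml(path)
  take <- function(block, builder) {
    if (is.null(y[[block]])) return(builder())
    do.call(builder, y[[block]])
  }
  conv <- y$convention %||% "standard"
  prior <- take("prior", prior_spec)
  skin <- if (is.null(y$skin)) NULL else {
    skin_params(y$skin$k, y$skin$rho, y$skin$c, convention = conv)
  }
  analysis_config(
    prior = prior, rate_lambda = y$rate_lambda %||% 1, convention = conv,
    skin = skin, mle = take("mle", mle_control),
    grid = take("grid", evidence_grid),
    point_tol = unlist(y$point_tol) %||% c(0.2, 0.02),
    triangle_tol = unlist(y$triangle_tol) %||% c(2, 0.2),
    gamma_prior_n = y$gamma_prior_n %||% 5e4,
    gamma_prior_seed = y$gamma_prior_seed %||% 20151207,
    seed = y$seed %||% 1L
  )
}

config_hash <- function(config) rlang::hash(unclass(config))

#' Run the full analysis pipeline on one recording
#'
#' Runs the classical intersection method, the full probabilistic MLE and
#' marginal-likelihood model selection, and assembles one report.
#' Estimator failures are captured per method and never abort the others.
#'
#' @param rec An [recording()].
#' @param config An [analysis_config()].
#' @param gamma_prior Optionally a pre-fitted `ncd_gamma_prior` (otherwise
#'   fitted from `config`, the expensive step).
#' @return An object of class `ncd_report`: a list with `classical`, `mle`,
#'   `selection` (each either a fit object or an error message), a
#'   `summary` tibble of the three estimates, `attenuated` (the stimulus
#'   traces at each method's estimated depth) and `config_echo`.
#' @export
run_pipeline <- function(rec, config = analysis_config(), gamma_prior = NULL) {
  if (!inherits(rec, "ncd_recording")) abort("`rec` must be an `ncd_recording`.")
  if (length(responsive_idx(rec)) < 2) {
    abort("Recording has fewer than 2 responsive stimuli; nothing to estimate.")
  }
  skin <- config$skin
  gamma_prior <- gamma_prior %||% fit_gamma_prior(
    config$prior, n = config$gamma_prior_n, seed = config$gamma_prior_seed,
    convention = config$convention)

  run <- function(expr) tryCatch(expr, error = function(e) conditionMessage(e))
  classical <- run(fit_classical(rec, skin, point_tol = config$point_tol,
                                 triangle_tol = config$triangle_tol))
  mle <- run(fit_mle(rec, skin, rate_lambda = config$rate_lambda,
                     control = config$mle))
  selection <- run(fit_selection(rec, prior = config$prior,
                                 gamma_prior = gamma_prior,
                                 rate_lambda = config$rate_lambda,
                                 grid = config$grid, skin = skin,
                                 mle_ctrl = config$mle))

  row <- function(method, fit) {
    if (is.character(fit)) {
      return(tibble::tibble(method = method, status = "error",
                            t_threshold = NA_real_, gamma = NA_real_,
                            depth_mm = NA_real_, depth_um = NA_real_))
    }
    g <- glance(fit)
    tibble::tibble(method = method,
                   status = if ("status" %in% names(g)) g$status
                            else if (isTRUE(g$converged)) "ok" else "failed",
                   t_threshold = g$t_threshold, gamma = g$gamma,
                   depth_mm = g$depth_mm, depth_um = g$depth_mm * 1000)
  }
  summary <- dplyr::bind_rows(row("classical", classical), row("mle", mle),
                              row("selection", selection))

  atten <- purrr::map_dfr(seq_len(nrow(summary)), function(r) {
    g <- summary$gamma[r]
    if (is.na(g)) return(tibble::tibble())
    purrr::map_dfr(responsive_idx(rec), function(i) {
      tr <- rec$trace[[i]]
      tt <- tr$time_s[tr$time_s > 0]
      tibble::tibble(method = summary$method[r], stimulus = rec$stimulus[i],
                     time_s = tt,
                     temp_C = attenuated_temperature(
                       surface_temp_at(tr, tt), baseline_temp(rec), g, tt))
    })
  })

  structure(
    list(classical = classical, mle = mle, selection = selection,
         summary = summary, attenuated = atten,
         neuron_id = neuron_id(rec),
         config_echo = list(hash = config_hash(config), seed = config$seed,
                            rate_lambda = config$rate_lambda,
                            convention = config$convention,
                            lambda_s_prior = config$prior$lambda_s)),
    class = "ncd_report"
  )
}

#' @export
print.ncd_report <- function(x, ...) {
  cat("Pipeline report (", x$neuron_id, ")\n", sep = "")
  print(x$summary)
  invisible(x)
}

#' Write a pipeline report to JSON
#'
#' Serializes the estimate summary, the per-candidate evidence weights (for
#' audit), the per-stimulus delays and the effective configuration echo.
#'
#' @param report An `ncd_report` from [run_pipeline()].
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path) {
  ev <- if (inherits(report$selection, "ncd_selection")) {
    report$selection$evidence
  } else NULL
  delays <- if (inherits(report$mle, "ncd_mle")) report$mle$delays else NULL
  out <- list(
    neuron_id = report$neuron_id,
    estimates = report$summary,
    evidence = ev,
    mle_delays_s = delays,
    config = report$config_echo
  )
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       null = "null", dataframe = "rows")
  invisible(path)
}
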