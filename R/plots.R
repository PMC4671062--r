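# ggplot2 visualizations: the depth-threshold plane of the classical
# method, attenuated stimulus traces at an estimated depth, and evidence
# weights of the model-selection candidates.

#' @exportS3Method ggplot2::autoplot
autoplot.ncd_classical <- function(object, max_depth_mm = 1.5, ...) {
  curves <- object$curves
  curves$depth_mm <- depth_from_gamma(curves$gamma, object$skin)
  curves <- curves[curves$depth_mm <= max_depth_mm, ]
  p <- ggplot2::ggplot(curves,
                       ggplot2::aes(x = .data$depth_mm, y = .data$t_threshold,
                                    colour = factor(.data$stimulus))) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "depth (mm)", y = "threshold temperature (°C)",
                  colour = "stimulus",
                  title = sprintf("Classical intersection: %s", object$status)) +
    ggplot2::theme_minimal()
  if (nrow(object$intersections)) {
    p <- p + ggplot2::geom_point(
      data = object$intersections,
      ggplot2::aes(x = .data$depth_mm, y = .data$t_threshold),
      inherit.aes = FALSE, shape = 4, size = 3)
  }
  p
}

#' Attenuated stimulus traces at an estimated depth
#'
#' Plots each surface trace together with the quasi-static temperature at
#' the estimated receptor depth, with the observed first-spike latencies
#' marked.
#'
#' @param fit An `ncd_mle` (or any object with `gamma` and `recording`).
#' @return A ggplot.
#' @export
plot_attenuation <- function(fit) {
  rec <- fit$recording
  T0 <- baseline_temp(rec)
  df <- purrr::map_dfr(responsive_idx(rec), function(i) {
    tr <- rec$trace[[i]]
    tt <- tr$time_s[tr$time_s > 0]
    dplyr::bind_rows(
      tibble::tibble(stimulus = i, time_s = tt,
                     temp_C = surface_temp_at(tr, tt), where = "surface"),
      tibble::tibble(stimulus = i, time_s = tt,
                     temp_C = attenuated_temperature(surface_temp_at(tr, tt),
                                                     T0, fit$gamma, tt),
                     where = "at estimated depth")
    )
  })
  lat <- tibble::tibble(stimulus = responsive_idx(rec),
                        latency_s = rec$latency_s[responsive_idx(rec)])
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time_s, y = .data$temp_C,
                                   linetype = .data$where)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(data = lat,
                        ggplot2::aes(xintercept = .data$latency_s),
                        colour = "grey50") +
    ggplot2::facet_wrap(~stimulus, scales = "free_x") +
    ggplot2::labs(x = "time (s)", y = "temperature (°C)", linetype = NULL) +
    ggplot2::theme_minimal()
}

#' @exportS3Method ggplot2::autoplot
autoplot.ncd_mle <- function(object, ...) plot_attenuation(object)

#' @exportS3Method ggplot2::autoplot
autoplot.ncd_selection <- function(object, ...) {
  ggplot2::ggplot(object$evidence,
                  ggplot2::aes(x = .data$model, y = .data$weight)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = NULL, y = "normalized evidence weight",
                  title = sprintf("Selected: %s", object$selected)) +
    ggplot2::theme_minimal()
}
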