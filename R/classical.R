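# Classical intersection method: each stimulus constrains (gamma, T) to a
# curve; the estimate is read off the curves' common intersection.

#' Consistency curve of one stimulus in the depth-threshold plane
#'
#' Given the observed latency, every pair (gamma, T) with
#' `T = T0 + (S(latency) - T0) * erfc(gamma / sqrt(latency))` is consistent
#' with the measurement under the zero-delay assumption. The curve starts at
#' the surface temperature at the latency (gamma = 0) and decays to `T0`.
#'
#' @param trace A [stimulus_trace()].
#' @param latency_s First-spike latency, seconds, within the trace support.
#' @param T0 Baseline temperature, degrees Celsius.
#' @param gamma_grid Sorted nonnegative grid of normalized depths.
#' @param stimulus Integer label carried into the output.
#' @return A tibble with columns `stimulus`, `gamma`, `t_threshold`.
#' @export
threshold_curve <- function(trace, latency_s, T0,
                            gamma_grid = default_gamma_grid(),
                            stimulus = 1L) {
  if (latency_s <= 0 || latency_s > trace_duration(trace)) {
    abort("`latency_s` outside the trace support.")
  }
  if (is.unsorted(gamma_grid) || any(gamma_grid < 0)) {
    abort("`gamma_grid` must be sorted and nonnegative.")
  }
  S <- surface_temp_at(trace, latency_s)
  tibble::tibble(
    stimulus = stimulus,
    gamma = gamma_grid,
    t_threshold = attenuated_temperature(S, T0, gamma_grid, latency_s)
  )
}

#' Default normalized-depth grid for the classical method
#'
#' 2000 points: zero plus a geometric sequence up to the gamma of
#' `depth_max_mm` (default 5 mm), dense near the surface where the curves
#' are steep. Intersections are refined by linear interpolation between grid
#' points.
#'
#' @param skin A [skin_params()] used to anchor the upper end.
#' @param depth_max_mm Upper end of the grid, as a physical depth.
#' @param n Number of grid points.
#' @return Sorted numeric vector starting at 0.
#' @export
default_gamma_grid <- function(skin = skin_params(), depth_max_mm = 5,
                               n = 2000L) {
  g_max <- gamma_from_depth(depth_max_mm, skin)
  c(0, exp(seq(log(g_max * 1e-4), log(g_max), length.out = n - 1L)))
}

#' Intersection of two consistency curves
#'
#' Finds the gamma at which the signed threshold difference between two
#' curves (on a common gamma grid) changes sign, refined by linear
#' interpolation. Returns `NULL` when the curves do not cross on the grid.
#' Intersecting a curve with itself (the same stimulus twice) is degenerate
#' and raises an error.
#'
#' @param curve_a,curve_b Tibbles from [threshold_curve()] on the same
#'   `gamma` grid.
#' @return A list `(gamma, t_threshold)`, or `NULL` if no crossing.
#' @export
pairwise_intersection <- function(curve_a, curve_b) {
  if (!isTRUE(all.equal(curve_a$gamma, curve_b$gamma))) {
    abort("Curves must share a common `gamma` grid.")
  }
  d <- curve_a$t_threshold - curve_b$t_threshold
  if (max(abs(d)) < 1e-12) {
    abort("Degenerate intersection: the two curves are identical (same stimulus?).")
  }
  # Sub-nanokelvin differences are ties: far in the tail both curves sit
  # numerically at T0 and the sign of their difference is noise. A crossing
  # is a sign change between the surrounding nonzero differences.
  d[abs(d) < 1e-9] <- 0
  s <- sign(d)
  nz <- which(s != 0)
  if (length(nz) < 2) return(NULL)
  flip <- which(s[nz][-1] * s[nz][-length(nz)] < 0)
  if (!length(flip)) return(NULL)
  i <- nz[flip[1]]
  j <- nz[flip[1] + 1]
  w <- d[i] / (d[i] - d[j])
  g <- curve_a$gamma[i] + w * (curve_a$gamma[j] - curve_a$gamma[i])
  Ta <- curve_a$t_threshold[i] + w * (curve_a$t_threshold[j] - curve_a$t_threshold[i])
  list(gamma = g, t_threshold = Ta)
}

#' Classical depth/threshold estimate with four-outcome classification
#'
#' Computes all pairwise intersections of the per-stimulus consistency
#' curves and classifies the outcome:
#' \describe{
#'   \item{`single`}{all pairs intersect and the points coincide within
#'     `point_tol`; estimate = mean of the points.}
#'   \item{`triangle`}{all pairs intersect and the points' diameter is below
#'     `triangle_tol`; estimate = centroid of the points.}
#'   \item{`partial`}{exactly one pairwise intersection exists; that point is
#'     returned as a provisional, non-final estimate.}
#'   \item{`none`}{anything else; no estimate.}
#' }
#' Tolerances are `(temperature, depth)` pairs in (degrees Celsius, mm); the
#' depth component is compared after conversion with `skin`.
#'
#' @param rec An [recording()].
#' @param skin A [skin_params()] used to convert gamma to depth.
#' @param gamma_grid Grid passed to [threshold_curve()].
#' @param point_tol,triangle_tol Numeric length-2 `(T, D)` tolerances.
#' @return An object of class `ncd_classical`: a list with `status`,
#'   `t_threshold`, `gamma`, `depth_mm`, the `intersections` tibble, the
#'   per-stimulus `curves` tibble and the inputs. [tidy()] returns the
#'   intersections, [glance()] a one-row summary, [autoplot()] the
#'   depth-threshold plane.
#' @examples
#' skin <- skin_params()
#' prot <- step_protocol(c(43, 45, 47, 49))
#' g <- gamma_from_depth(0.3, skin)
#' lat <- vapply(prot, function(tr) threshold_time(38.8, 32, g, tr), numeric(1))
#' fit <- fit_classical(recording(prot, lat, T0 = 32), skin)
#' glance(fit)
#' @export
fit_classical <- function(rec, skin = skin_params(),
                          gamma_grid = default_gamma_grid(skin),
                          point_tol = c(0.2, 0.02),
                          triangle_tol = c(2, 0.2)) {
  idx <- responsive_idx(rec)
  if (length(idx) < 2) abort("The classical method needs >= 2 responsive stimuli.")
  T0 <- baseline_temp(rec)
  curves <- purrr::map_dfr(idx, function(i) {
    threshold_curve(rec$trace[[i]], rec$latency_s[i], T0, gamma_grid,
                    stimulus = rec$stimulus[i])
  })
  pairs <- utils::combn(idx, 2)
  pts <- purrr::map(seq_len(ncol(pairs)), function(p) {
    a <- pairs[1, p]; b <- pairs[2, p]
    ca <- curves[curves$stimulus == rec$stimulus[a], ]
    cb <- curves[curves$stimulus == rec$stimulus[b], ]
    hit <- pairwise_intersection(ca, cb)
    if (is.null(hit)) return(NULL)
    tibble::tibble(stimulus_a = rec$stimulus[a], stimulus_b = rec$stimulus[b],
                   gamma = hit$gamma, t_threshold = hit$t_threshold,
                   depth_mm = depth_from_gamma(hit$gamma, skin))
  })
  inter <- dplyr::bind_rows(pts)
  n_pairs <- ncol(pairs)
  n_int <- nrow(inter)

  diameter <- function(df) {
    c(Td = max(df$t_threshold) - min(df$t_threshold),
      Dd = max(df$depth_mm) - min(df$depth_mm))
  }
  status <- "none"
  est <- c(gamma = NA_real_, t_threshold = NA_real_, depth_mm = NA_real_)
  if (n_int == n_pairs && n_int > 0) {
    dia <- diameter(inter)
    if (dia["Td"] <= point_tol[1] && dia["Dd"] <= point_tol[2]) {
      status <- "single"
    } else if (dia["Td"] <= triangle_tol[1] && dia["Dd"] <= triangle_tol[2]) {
      status <- "triangle"
    }
    if (status %in% c("single", "triangle")) {
      est <- c(gamma = mean(inter$gamma), t_threshold = mean(inter$t_threshold),
               depth_mm = mean(inter$depth_mm))
    }
  }
  if (status == "none" && n_int == 1) {
    status <- "partial"
    est <- c(gamma = inter$gamma[1], t_threshold = inter$t_threshold[1],
             depth_mm = inter$depth_mm[1])
  }
  structure(
    list(status = status,
         t_threshold = unname(est["t_threshold"]),
         gamma = unname(est["gamma"]),
         depth_mm = unname(est["depth_mm"]),
         final = status %in% c("single", "triangle"),
         intersections = inter, curves = curves,
         recording = rec, skin = skin,
         point_tol = point_tol, triangle_tol = triangle_tol),
    class = "ncd_classical"
  )
}

#' @export
print.ncd_classical <- function(x, ...) {
  cat("Classical intersection estimate (", neuron_id(x$recording), ")\n", sep = "")
  cat("  status:", x$status, "\n")
  if (!is.na(x$t_threshold)) {
    cat(sprintf("  T_threshold: %.2f C   depth: %.3f mm (gamma %.4f s^1/2)%s\n",
                x$t_threshold, x$depth_mm, x$gamma,
                if (x$final) "" else "  [provisional]"))
  }
  cat("  pairwise intersections:", nrow(x$intersections), "\n")
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.ncd_classical <- function(x, ...) x$intersections

#' @exportS3Method generics::glance
glance.ncd_classical <- function(x, ...) {
  tibble::tibble(
    neuron_id = neuron_id(x$recording), status = x$status,
    t_threshold = x$t_threshold, gamma = x$gamma, depth_mm = x$depth_mm,
    n_stimuli = n_stimuli(x$recording), n_intersections = nrow(x$intersections)
  )
}
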