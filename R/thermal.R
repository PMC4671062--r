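# Quasi-static Henriques forward model of heat conduction into skin.
# All inference happens in the normalized depth gamma = x / (2 sqrt(alpha))
# (units s^(1/2)); physical depth enters only through the diffusivity.

erfc_ <- function(x) 2 * pnorm(x * sqrt(2), lower.tail = FALSE)

erfc_inv_ <- function(p) qnorm(p / 2, lower.tail = FALSE) / sqrt(2)

#' Thermal diffusivity from conductivity, density and specific heat
#'
#' Two conventions are supported. `"standard"` is the textbook definition
#' alpha = k / (rho c) (m^2/s). `"paper_sqrt"` takes the square root of that
#' ratio, a convention that appears in parts of the bioheat literature; it is
#' dimensionally nonstandard and kept only for comparability. The package
#' default everywhere is `"standard"`.
#'
#' @param k Thermal conductivity, W m^-1 K^-1.
#' @param rho Density, kg m^-3.
#' @param c Specific heat, J kg^-1 K^-1.
#' @param convention `"standard"` or `"paper_sqrt"`.
#' @return Diffusivity (m^2/s under `"standard"`).
#' @export
alpha_from_krc <- function(k, rho, c, convention = c("standard", "paper_sqrt")) {
  convention <- match.arg(convention)
  if (any(k <= 0) || any(rho <= 0) || any(c <= 0)) {
    abort("`k`, `rho` and `c` must be strictly positive.")
  }
  ratio <- k / (rho * c)
  if (convention == "paper_sqrt") sqrt(ratio) else ratio
}

#' Bundle skin thermal parameters
#'
#' @inheritParams alpha_from_krc
#' @param D_e_mm,D_d_mm Optional epidermis / dermis thicknesses, mm.
#' @return A list of class `ncd_skin` with fields `k`, `rho`, `c`, `alpha`,
#'   `convention` and the optional thicknesses.
#' @examples
#' skin_params() # Table-midpoint mouse/primate skin
#' @export
skin_params <- function(k = 0.095, rho = 1158, c = 825,
                        convention = c("standard", "paper_sqrt"),
                        D_e_mm = NULL, D_d_mm = NULL) {
  convention <- match.arg(convention)
  structure(
    list(k = k, rho = rho, c = c,
         alpha = alpha_from_krc(k, rho, c, convention),
         convention = convention, D_e_mm = D_e_mm, D_d_mm = D_d_mm),
    class = "ncd_skin"
  )
}

#' Convert between physical depth and normalized depth
#'
#' `gamma_from_depth()` maps a physical depth D (mm) to the normalized depth
#' gamma = D / (2 sqrt(alpha)); `depth_from_gamma()` inverts it,
#' D = 2 gamma sqrt(alpha). The two are exact inverses for any diffusivity
#' convention.
#'
#' @param depth_mm Physical depth, mm.
#' @param gamma Normalized depth, s^(1/2).
#' @param skin A [skin_params()] object (its `alpha` is used).
#' @return Numeric vector.
#' @export
gamma_from_depth <- function(depth_mm, skin = skin_params()) {
  if (any(depth_mm < 0)) abort("`depth_mm` must be nonnegative.")
  (depth_mm / 1000) / (2 * sqrt(skin$alpha))
}

#' @rdname gamma_from_depth
#' @export
depth_from_gamma <- function(gamma, skin = skin_params()) {
  if (any(gamma < 0)) abort("`gamma` must be nonnegative.")
  2 * gamma * sqrt(skin$alpha) * 1000
}

#' Temperature at depth under the Henriques approximation
#'
#' For a semi-infinite solid initially at `T0` whose surface is held at
#' `T_surface`, the temperature at normalized depth `gamma` after time `t` is
#' `T0 + (T_surface - T0) * erfc(gamma / sqrt(t))`, equivalently
#' `T0 + (T_surface - T0) * 2 * (1 - Phi(sqrt(2) * gamma / sqrt(t)))` with
#' Phi the standard normal CDF. Time-varying surface temperatures are
#' handled quasi-statically by evaluating this expression with the
#' instantaneous surface temperature (see [threshold_time()]).
#'
#' @param T_surface Surface temperature, degrees Celsius (vectorized).
#' @param T0 Baseline (initial, far-field) temperature, degrees Celsius.
#' @param gamma Normalized depth, s^(1/2), nonnegative.
#' @param t Time since onset, seconds, strictly positive.
#' @return Temperature at depth, degrees Celsius.
#' @examples
#' attenuated_temperature(48, 32, 0, 1)    # surface neuron: 48
#' attenuated_temperature(48, 32, 0.5, 4)  # attenuated
#' @export
attenuated_temperature <- function(T_surface, T0, gamma, t) {
  if (any(t <= 0)) abort("`t` must be strictly positive.")
  if (any(gamma < 0)) abort("`gamma` must be nonnegative.")
  T0 + (T_surface - T0) * erfc_(gamma / sqrt(t))
}

#' Time at which the temperature at depth first reaches a threshold
#'
#' Evaluates the quasi-static temperature-at-depth curve
#' `g(t) = T0 + (S(t) - T0) * erfc(gamma / sqrt(t))`, with `S(t)` the
#' interpolated surface trace, and returns the smallest `t > 0` with
#' `g(t) >= T_threshold`. The crossing is bracketed by scanning a dense time
#' grid and refined with [stats::uniroot()]. If the threshold is never
#' reached within the trace support, the sentinel `Inf` is returned (never an
#' error: the likelihood must evaluate parameter regions with no crossing).
#'
#' For a constant (step) surface temperature `Ts` the closed form is
#' `t* = (gamma / u)^2` with `erfc(u) = (T_threshold - T0) / (Ts - T0)`.
#'
#' @param T_threshold Threshold temperature, degrees Celsius; must exceed
#'   `T0`.
#' @inheritParams attenuated_temperature
#' @param trace A [stimulus_trace()].
#' @param tol Absolute time tolerance of the root refinement, seconds.
#' @return Scalar crossing time in seconds, or `Inf` if never crossed.
#' @export
threshold_time <- function(T_threshold, T0, gamma, trace, tol = 1e-11) {
  if (T_threshold <= T0) {
    abort("`T_threshold` must exceed the baseline temperature `T0`.")
  }
  if (gamma < 0) abort("`gamma` must be nonnegative.")
  tmax <- trace_duration(trace)
  tg <- scan_times(trace)
  S <- surface_temp_at(trace, tg)
  g <- T0 + (S - T0) * erfc_(gamma / sqrt(tg))
  hit <- which(g >= T_threshold)
  if (!length(hit)) return(Inf)
  i <- hit[1]
  f <- function(t) {
    T0 + (surface_temp_at(trace, t) - T0) * erfc_(gamma / sqrt(t)) - T_threshold
  }
  lo <- if (i == 1) tmax * 1e-12 else tg[i - 1]
  if (f(lo) >= 0) return(lo)
  uniroot(f, lower = lo, upper = tg[i], tol = tol)$root
}

# Dense scan grid over the trace support: geometric points resolve the fast
# early-time variation of erfc(gamma/sqrt(t)); uniform points plus the trace's
# own sample times resolve the ramp.
scan_times <- function(trace, n_uniform = 1024L, n_geom = 256L) {
  tmax <- trace_duration(trace)
  tg <- c(10^seq(log10(tmax) - 8, log10(tmax), length.out = n_geom),
          seq(tmax / n_uniform, tmax, length.out = n_uniform),
          trace$time_s[-1])
  sort(unique(pmin(tg, tmax)))
}

# Vectorized threshold times on a (gamma, T) grid via interpolation of the
# running maximum of the quasi-static temperature-at-depth curve. Returns a
# length(gamma) x length(T_levels) matrix; Inf where never crossed. Used by
# the likelihood and evidence grids where per-point root finding would be
# prohibitive; accuracy on the smooth protocol curves is ~1e-5 s.
threshold_time_grid <- function(trace, T0, gamma, T_levels) {
  tg <- scan_times(trace, n_uniform = 2048L)
  S <- surface_temp_at(trace, tg)
  n <- length(tg)
  out <- matrix(Inf, nrow = length(gamma), ncol = length(T_levels))
  for (j in seq_along(gamma)) {
    v <- T0 + (S - T0) * erfc_(gamma[j] / sqrt(tg))
    m <- cummax(v)
    idx <- findInterval(T_levels, m)  # largest i with m[i] <= T
    tt <- rep(Inf, length(T_levels))
    exact <- idx >= 1 & idx <= n
    exact[exact] <- m[idx[exact]] == T_levels[exact]
    tt[exact] <- tg[idx[exact]]
    cross <- !exact & idx < n
    if (any(cross)) {
      i0 <- pmax(idx[cross], 1L)
      below <- idx[cross] >= 1
      v0 <- ifelse(below, v[i0], if (gamma[j] > 0) T0 else v[1])
      t0 <- ifelse(below, tg[i0], 0)
      i1 <- idx[cross] + 1L
      frac <- (T_levels[cross] - v0) / (v[i1] - v0)
      frac[!is.finite(frac)] <- 0  # crossing at onset (step stimulus, gamma = 0)
      tt[cross] <- pmax(t0 + frac * (tg[i1] - t0), 0)
    }
    out[j, ] <- tt
  }
  out
}

#' Finite-difference oracle for the one-layer skin heat equation
#'
#' Explicit (FTCS) solution of `dT/dt = alpha_eff d2T/dx2` on `[0, x_max]`
#' with the surface trace as a Dirichlet boundary at `x = 0`, and the
#' baseline `T0` as both initial condition and far-field boundary. This
#' solver exists to validate the quasi-static Henriques approximation; it is
#' not used by any estimator.
#'
#' @param trace A [stimulus_trace()]; its first temperature is taken at
#'   `t = 0+`.
#' @param alpha_eff Diffusivity of the diffusion equation, m^2/s (i.e. the
#'   standard-convention alpha = k/(rho c), whatever convention is used for
#'   reporting).
#' @param T0 Baseline temperature, degrees Celsius.
#' @param x_max_mm Domain depth, mm (far-field boundary held at `T0`).
#' @param nx Number of grid intervals in depth.
#' @param t_end_s Final time, seconds (defaults to the trace duration).
#' @param safety Fraction of the explicit stability limit
#'   `dx^2 / (2 alpha_eff)` used as the time step; must be in (0, 1).
#' @return A list with `x_mm` (depth grid), `t_s` (output times = every step)
#'   and `temp_C` (matrix, rows = times, cols = depths).
#' @export
solve_heat_pde <- function(trace, alpha_eff, T0, x_max_mm = 10, nx = 200L,
                           t_end_s = NULL, safety = 0.4) {
  if (safety <= 0 || safety >= 1) {
    abort("`safety` must be in (0, 1): the explicit scheme is unstable otherwise.")
  }
  t_end_s <- t_end_s %||% trace_duration(trace)
  L <- x_max_mm / 1000
  dx <- L / nx
  dt <- safety * dx^2 / (2 * alpha_eff)
  nt <- ceiling(t_end_s / dt)
  dt <- t_end_s / nt
  r <- alpha_eff * dt / dx^2
  x <- seq(0, L, length.out = nx + 1)
  Tn <- rep(T0, nx + 1)
  times <- seq_len(nt) * dt
  keep <- unique(pmin(nt, round(seq(1, nt, length.out = min(nt, 400L)))))
  out <- matrix(NA_real_, nrow = length(keep), ncol = nx + 1)
  ki <- 1L
  for (s in seq_len(nt)) {
    Tn[1] <- surface_temp_at(trace, min(times[s], trace_duration(trace)))
    interior <- 2:nx
    Tn[interior] <- Tn[interior] +
      r * (Tn[interior + 1] - 2 * Tn[interior] + Tn[interior - 1])
    Tn[1] <- surface_temp_at(trace, min(times[s], trace_duration(trace)))
    Tn[nx + 1] <- T0
    if (ki <= length(keep) && s == keep[ki]) {
      out[ki, ] <- Tn
      ki <- ki + 1L
    }
  }
  list(x_mm = x * 1000, t_s = times[keep], temp_C = out)
}
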