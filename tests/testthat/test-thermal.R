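test_that("attenuated temperature matches the erfc solution and its limits", {
  # zero depth returns the surface temperature; infinite depth the baseline
  expect_equal(attenuated_temperature(48, 32, 0, 1), 48)
  expect_equal(attenuated_temperature(48, 32, 100, 1), 32, tolerance = 1e-9)

  # gamma* with erfc(gamma*) = 0.5 gives the midpoint 40 C at t = 1 s,
  # with gamma* obtained by an independent root-finder
  g_star <- uniroot(function(g) 2 * pnorm(g * sqrt(2), lower.tail = FALSE) - 0.5,
                    c(0.1, 1), tol = 1e-12)$root
  expect_equal(attenuated_temperature(48, 32, g_star, 1), 40, tolerance = 1e-8)

  # strictly decreasing in gamma, strictly increasing in t
  gs <- seq(0, 2, length.out = 50)
  expect_true(all(diff(attenuated_temperature(48, 32, gs, 2)) < 0))
  ts <- seq(0.1, 20, length.out = 50)
  expect_true(all(diff(attenuated_temperature(48, 32, 0.5, ts)) > 0))

  expect_error(attenuated_temperature(48, 32, 0.5, 0), "positive")
  expect_error(attenuated_temperature(48, 32, -0.1, 1), "nonnegative")
})

test_that("diffusivity conventions and depth round trips are consistent", {
  expect_equal(alpha_from_krc(1, 1, 1, "paper_sqrt"), 1)
  a <- alpha_from_krc(0.09, 1150, 800, "standard")
  expect_equal(a, 0.09 / (1150 * 800), tolerance = 1e-12)
  expect_equal(a, 9.78e-8, tolerance = 1e-3)
  expect_equal(alpha_from_krc(0.09, 1150, 800, "paper_sqrt"), sqrt(a))
  expect_error(alpha_from_krc(-1, 1, 1), "positive")

  for (conv in c("standard", "paper_sqrt")) {
    skin <- skin_params(convention = conv)
    D <- c(0, 0.05, 0.3, 1.7)
    expect_equal(depth_from_gamma(gamma_from_depth(D, skin), skin), D,
                 tolerance = 1e-12)
  }
  # D == 0 <=> gamma == 0
  expect_identical(gamma_from_depth(0), 0)
  expect_identical(depth_from_gamma(0), 0)
})

test_that("trace interpolation is linear and range-checked", {
  tr <- stimulus_trace(c(0, 16, 26), c(32, 48, 48), 16, 10)
  expect_equal(surface_temp_at(tr, 0), 32)
  expect_equal(surface_temp_at(tr, 16), 48)
  expect_equal(surface_temp_at(tr, 8), 40)
  expect_error(surface_temp_at(tr, 27), "support")
  expect_error(surface_temp_at(tr, -1), "support")
  expect_error(stimulus_trace(c(1, 2), c(32, 40)), "start at 0")
  expect_error(stimulus_trace(c(0, 0), c(32, 40)), "increasing")
  expect_error(stimulus_trace(c(0, 1), c(32, 140)), "100")
})

test_that("threshold time matches the step closed form and handles sentinels", {
  skin <- test_skin()
  tr <- step_protocol(48, duration_s = 30)[[1]]
  for (g in c(0.1, 0.4756754, 1.2)) {
    for (Tth in c(34, 38.8, 44)) {
      u <- qnorm(((Tth - 32) / 16) / 2, lower.tail = FALSE) / sqrt(2)
      t_closed <- (g / u)^2
      expect_equal(threshold_time(Tth, 32, g, tr), t_closed,
                   tolerance = 1e-8)
    }
  }
  # surface neuron fires at onset of a supra-threshold step
  expect_lt(threshold_time(32.01, 32, 0, tr), 1e-6)
  # threshold above the reachable temperature is never crossed
  expect_identical(threshold_time(49, 32, 0.1, tr), Inf)
  expect_identical(threshold_time(40, 32, 50, tr), Inf)
  expect_error(threshold_time(31, 32, 0.1, tr), "exceed")
})

test_that("vectorized grid threshold times agree with the root-finder", {
  traces <- c(ramp_protocol(), step_protocol(c(45, 49)))
  gg <- c(0, 0.05, 0.3, 0.7, 1.5)
  TT <- c(33, 36, 40, 44, 47.5)
  for (tr in traces) {
    grid <- nocidepth:::threshold_time_grid(tr, 32, gg, TT)
    exact <- outer(gg, TT, Vectorize(function(g, Tt) threshold_time(Tt, 32, g, tr)))
    fin <- is.finite(exact)
    expect_identical(is.finite(grid), fin)
    expect_lt(max(abs(grid[fin] - exact[fin])), 1e-4)
  }
})

test_that("the finite-difference oracle validates the Henriques approximation", {
  skin <- test_skin()
  al <- skin$alpha

  # boundary is reproduced exactly; interior approaches steady state
  tr <- step_protocol(48, duration_s = 16)[[1]]
  sol <- solve_heat_pde(tr, al, T0 = 32, x_max_mm = 10, nx = 200)
  expect_equal(sol$temp_C[, 1], rep(48, length(sol$t_s)))
  shallow <- which(sol$x_mm <= 1)
  expect_true(all(diff(sol$temp_C[, shallow[5]]) > -1e-9))

  # step problem: numerical solution vs analytic erfc within 1% of the rise
  it <- which.min(abs(sol$t_s - 8))
  x_m <- sol$x_mm / 1000
  eta <- x_m / (2 * sqrt(al * sol$t_s[it]))
  exact <- 32 + 16 * (2 * pnorm(eta * sqrt(2), lower.tail = FALSE))
  sel <- sol$x_mm <= 2
  expect_lt(max(abs(sol$temp_C[it, sel] - exact[sel]) / 16), 0.01)

  # unstable configuration is refused
  expect_error(solve_heat_pde(tr, al, 32, safety = 1.5), "unstable")
})

test_that("quasi-static ramp crossing times track the PDE, degrading with depth", {
  # The quasi-static evaluation is exact for steps; for ramps its error
  # grows with normalized depth. Assert the documented discrepancy bounds
  # on the 16 s ramp at threshold 40 C.
  skin <- test_skin()
  tr <- ramp_protocol()[[1]]
  sol <- solve_heat_pde(tr, skin$alpha, T0 = 32, x_max_mm = 10, nx = 400)
  bound <- list(c(0.05, 0.02), c(0.12, 0.05), c(0.5, 0.15))
  for (b in bound) {
    ix <- which.min(abs(sol$x_mm - depth_from_gamma(b[1], skin)))
    g <- gamma_from_depth(sol$x_mm[ix], skin)
    f <- approxfun(sol$t_s, sol$temp_C[, ix])
    t_pde <- uniroot(function(t) f(t) - 40, c(0.5, 25))$root
    t_hen <- threshold_time(40, 32, g, tr)
    expect_lt(abs(t_hen - t_pde) / t_pde, b[2])
  }
})
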