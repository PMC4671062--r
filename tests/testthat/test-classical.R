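test_that("consistency curves start at the surface temperature and decay to baseline", {
  tr <- ramp_protocol()[[1]]
  gg <- default_gamma_grid()
  cv <- threshold_curve(tr, latency_s = 8, T0 = 32, gamma_grid = gg)
  expect_equal(cv$t_threshold[1], surface_temp_at(tr, 8))
  expect_lt(cv$t_threshold[nrow(cv)] - 32, 0.01)
  expect_true(all(diff(cv$t_threshold) <= 0))
  expect_error(threshold_curve(tr, 30, 32), "support")
})

test_that("all step-scenario curves pass through the generating point", {
  skin <- test_skin()
  rec <- fig1b_recording(skin)
  g_true <- gamma_from_depth(0.3, skin)
  for (i in 1:4) {
    cv <- threshold_curve(rec$trace[[i]], rec$latency_s[i], 32,
                          gamma_grid = g_true)
    expect_equal(cv$t_threshold, 38.8, tolerance = 1e-6)
  }
})

test_that("pairwise intersections recover ground truth and detect degeneracy", {
  skin <- test_skin()
  rec <- fig1b_recording(skin)
  gg <- default_gamma_grid(skin)
  c1 <- threshold_curve(rec$trace[[1]], rec$latency_s[1], 32, gg, stimulus = 1L)
  c2 <- threshold_curve(rec$trace[[2]], rec$latency_s[2], 32, gg, stimulus = 2L)
  hit <- pairwise_intersection(c1, c2)
  expect_equal(hit$gamma, gamma_from_depth(0.3, skin), tolerance = 1e-3)
  expect_equal(hit$t_threshold, 38.8, tolerance = 1e-2)

  expect_error(pairwise_intersection(c1, c1), "Degenerate")

  # inflating one latency so its curve dominates removes the crossing
  lat2 <- rec$latency_s[2] * 3
  c2b <- threshold_curve(rec$trace[[2]], lat2, 32, gg, stimulus = 2L)
  expect_null(pairwise_intersection(c2b, c1))
})

test_that("noise-free recordings classify as single and recover the truth", {
  skin <- test_skin()
  # step scenario
  fit <- fit_classical(fig1b_recording(skin), skin)
  expect_identical(fit$status, "single")
  expect_equal(fit$t_threshold, 38.8, tolerance = 0.1)
  expect_equal(fit$depth_mm, 0.3, tolerance = 0.01)

  # ramp protocol, several depths/thresholds
  for (par in list(c(0.15, 41), c(0.42, 39.5), c(0.55, 37))) {
    rec <- simulate_recording(ground_truth_neuron(par[1], par[2], skin))
    fit <- fit_classical(rec, skin)
    expect_identical(fit$status, "single")
    expect_equal(fit$depth_mm, par[1], tolerance = 0.01)
    expect_equal(fit$t_threshold, par[2], tolerance = 0.1)
  }
})

test_that("classification is perturbation-sensitive and order-invariant", {
  skin <- test_skin()
  rec <- simulate_recording(ground_truth_neuron(0.42, 39.5, skin))

  # a 5% inflation of one latency must break the single intersection
  lat <- rec$latency_s
  lat[2] <- lat[2] * 1.05
  fitp <- fit_classical(recording(rec$trace, lat, T0 = 32), skin)
  expect_false(fitp$status == "single")

  # a small perturbation leaves three close points: a triangle
  lat <- rec$latency_s
  lat[2] <- lat[2] * 1.01
  fitt <- fit_classical(recording(rec$trace, lat, T0 = 32), skin)
  expect_identical(fitt$status, "triangle")
  expect_equal(fitt$t_threshold, 39.5, tolerance = 1)

  # permuting the stimuli does not change the estimate
  perm <- c(3, 1, 2)
  fit0 <- fit_classical(rec, skin)
  fit1 <- fit_classical(recording(rec$trace[perm], rec$latency_s[perm], T0 = 32),
                        skin)
  expect_equal(fit1$status, fit0$status)
  expect_equal(fit1$t_threshold, fit0$t_threshold, tolerance = 1e-9)
  expect_equal(fit1$depth_mm, fit0$depth_mm, tolerance = 1e-9)
})

test_that("partial and none outcomes are reported as in the failure taxonomy", {
  skin <- test_skin()
  prot <- ramp_protocol()
  # dominated curves (each later curve starts lower and decays faster): none
  fit_none <- fit_classical(recording(prot, c(6, 1, 0.3), T0 = 32), skin)
  expect_identical(fit_none$status, "none")
  expect_true(is.na(fit_none$t_threshold))

  # an early outlier latency typically leaves exactly one crossing: partial
  rec <- simulate_recording(ground_truth_neuron(0.42, 39.5, skin,
                                                delay_rate = 1), seed = 8)
  rec <- inject_outlier(rec, 1, rate = 1, seed = 99)
  fit_part <- fit_classical(rec, skin)
  expect_identical(fit_part$status, "partial")
  expect_false(fit_part$final)
  expect_identical(nrow(fit_part$intersections), 1L)
})

test_that("reported thresholds stay within the physical bracket", {
  skin <- test_skin()
  for (seed in 1:5) {
    coh <- simulate_cohort(1, delay_rate = 5, seed = seed)
    fit <- fit_classical(coh$recording[[1]], skin)
    if (!is.na(fit$t_threshold)) {
      expect_gt(fit$t_threshold, 32)
      expect_lte(fit$t_threshold, 48)
    }
  }
})

test_that("classical fit tidiers expose intersections and summary", {
  skin <- test_skin()
  fit <- fit_classical(fig1b_recording(skin), skin)
  td <- tidy(fit)
  expect_s3_class(td, "tbl_df")
  expect_identical(nrow(td), 6L)  # 4 choose 2
  gl <- glance(fit)
  expect_identical(gl$status, "single")
  expect_identical(gl$n_intersections, 6L)
  expect_s3_class(autoplot(fit), "ggplot")
})
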