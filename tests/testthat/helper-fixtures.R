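# Shared fixtures, all generated in code.

test_skin <- function() midpoint_skin()

# Worked example: neuron at 0.3 mm depth, threshold 38.8 C, probed with four
# constant supra-threshold surface temperatures, zero delays.
fig1b_recording <- function(skin = test_skin(), temps = c(43, 45, 47, 49)) {
  g <- gamma_from_depth(0.3, skin)
  prot <- step_protocol(temps, duration_s = 30)
  lat <- vapply(prot, function(tr) threshold_time(38.8, 32, g, tr), numeric(1))
  recording(prot, lat, T0 = 32, neuron_id = "fig1b")
}

# Gamma-prior mixture is expensive to fit; cache one per test session.
cached_gamma_prior <- local({
  gp <- NULL
  function() {
    if (is.null(gp)) gp <<- fit_gamma_prior(seed = 42, n = 2e4)
    gp
  }
})

expect_close <- function(object, expected, tol) {
  expect_true(abs(object - expected) <= tol,
              label = sprintf("|%g - %g| <= %g", object, expected, tol))
}
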