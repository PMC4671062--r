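---
title: "Estimating nociceptor depth and threshold from first-spike latencies"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating nociceptor depth and threshold from first-spike latencies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nocidepth)
```

## The problem

Heat-sensitive C-fiber nociceptors transduce noxious heat somewhere inside
the skin, at a depth that cannot be observed directly. Because skin is a
poor heat conductor, the temperature at the transduction site lags and is
attenuated relative to the surface temperature applied by a contact
thermode. A neuron's heat threshold therefore cannot be read off the
surface trace at the moment of its first spike: threshold and depth must be
inferred jointly from how the first-spike latency changes across heat ramps
of different rates.

`nocidepth` implements three estimators of the pair (threshold temperature
$T_{thr}$, receptor depth $D$) from per-neuron recordings of ramped heat
stimuli and conduction-corrected first-spike latencies, plus a ground-truth
simulator used to validate them by parameter recovery.

## Forward model

Heat conduction into the skin is modeled as a semi-infinite homogeneous
solid initially at the baseline temperature $T_0$. For a surface held at
$T_s$, the temperature at depth $x$ after time $t$ is the classical
error-function solution

$$T(x, t) = T_0 + (T_s - T_0)\,\mathrm{erfc}\!\left(\frac{\gamma}{\sqrt{t}}\right),
\qquad \gamma = \frac{x}{2\sqrt{\alpha}},$$

with $\alpha$ the thermal diffusivity. All inference happens in the
*normalized depth* $\gamma$ (units $\mathrm{s}^{1/2}$), because the forward
model depends on depth and diffusivity only through this ratio; physical
depth re-enters only when converting $\gamma$ back to millimetres.

Time-varying surface temperatures are handled *quasi-statically*: the
expression above is evaluated with the instantaneous surface temperature
$S(t)$. `threshold_time()` returns the first $t$ at which the quasi-static
temperature at depth reaches $T_{thr}$, found by scanning a dense time grid
and refining with bisection (tolerance $10^{-11}$ s); a threshold that is
never reached yields the sentinel `Inf` rather than an error, because the
likelihood must be evaluable in parameter regions with no crossing.

### How good is the quasi-static approximation?

`solve_heat_pde()` is an explicit finite-difference solver of the
one-layer diffusion equation, used purely as a validation oracle. For step
stimuli the quasi-static evaluation is exact and the two agree to better
than 1 % of the temperature rise. For the 16 s ramp the quasi-static
crossing time is accurate to about 2 % at $\gamma = 0.05\,\mathrm{s}^{1/2}$,
5 % at $\gamma \approx 0.12$, and degrades to roughly 14 % at
$\gamma \approx 0.5$ (a typical mid-dermal depth). The tests assert these
bounds explicitly. This is a genuine limitation of the quasi-static
treatment for ramped stimuli at depth, shared by every estimator built on
it; it cancels in parameter-recovery experiments because the simulator and
the estimators use the same forward model, but it should be kept in mind
when interpreting absolute depth estimates on real tissue.

### Diffusivity conventions

The bioheat literature is inconsistent about whether "thermal diffusivity"
denotes $k/(\rho c)$ or its square root. Both conventions are supported
behind `convention = c("standard", "paper_sqrt")`; the package default is
the textbook definition $\alpha = k/(\rho c)$, which is dimensionally
consistent and yields physically sensible attenuation (normalized depths of
order $0.1$–$1\,\mathrm{s}^{1/2}$ for dermal endings, hence latencies of
seconds under the standard protocol). Under the square-root reading the
same tissue would show nearly no attenuation at all reported depths, which
is incompatible with the observed latency structure. The choice only
affects the $\gamma \leftrightarrow D$ conversion, never the inference in
$\gamma$.

## The classical intersection method

For one stimulus, the zero-delay assumption (first spike fired exactly at
threshold crossing) confines $(\gamma, T_{thr})$ to a *consistency curve*:
the attenuated surface temperature at the observed latency, as a function
of $\gamma$ (`threshold_curve()`). With several ramp rates the curves
should share one intersection — the estimate. `fit_classical()` computes
all pairwise intersections on a 2000-point geometric $\gamma$ grid (refined
by linear interpolation at sign changes) and classifies the outcome:

* **single** — all pairwise intersections coincide within `point_tol`
  (default 0.2 °C, 0.02 mm); estimate = mean of the points.
* **triangle** — all pairs intersect and the points span a diameter below
  `triangle_tol` (default 2 °C, 0.2 mm); estimate = centroid of the
  points. The field's description of this outcome ("three close points")
  is qualitative, so both tolerances are configurable; the defaults were
  fixed a priori at what a practitioner would call "the same point" and
  "close points" on these axes. The centroid was chosen over averaging
  per-curve parameters because the intersection points are the quantities
  the method actually constrains.
* **partial** — exactly one pairwise intersection; returned as a
  provisional, non-final estimate rather than inventing an averaging rule.
* **none** — anything else (including widely scattered intersections).

```{r classical}
skin <- midpoint_skin()
neuron <- ground_truth_neuron(0.42, 39.5, skin)   # noise-free ground truth
rec <- simulate_recording(neuron)
glance(fit_classical(rec, skin))
```

## The delay likelihood

Real first spikes lag threshold crossing by a nonnegative delay
$\Delta_i = \tau_i - t^*_i(T_{thr}, \gamma)$ (latency minus crossing time).
Delays are modeled as i.i.d. $\mathrm{Exp}(\lambda)$, giving the log
likelihood

$$\ell(T_{thr}, \gamma) = \sum_i \left[\log \lambda - \lambda \Delta_i\right],$$

with $\ell = -\infty$ whenever any implied delay is negative or the
threshold is never crossed. $\lambda$ is fixed at $1\,\mathrm{s}^{-1}$ by
default; because $\lambda$ enters only through a monotone transformation of
the total delay, the location of the optimum does not depend on it.

**Optimizer.** For fixed $\gamma$ the likelihood increases in $T_{thr}$ up
to the feasibility envelope $T_{env}(\gamma) = \min_i$ (consistency curve
of stimulus $i$), and every envelope point is feasible, so the 2-D
constrained maximization reduces *exactly* to a 1-D maximization along the
envelope. `fit_mle()` scans a 400-point $\gamma$ grid and refines the
incumbent with Brent's method to $10^{-7}\,\mathrm{s}^{1/2}$, using exact
bisection crossing times; ties are broken toward smaller $\gamma$
(shallower, more prior-consistent). The search is deterministic, and on
noise-free data it reproduces the classical single intersection with all
delays below $10^{-7}$ s — the boundary-condition consistency the delay
model requires.

```{r mle}
glance(fit_mle(rec, skin))
```

## Priors and the Monte-Carlo depth conversion

Literature-based priors (`prior_spec()`): threshold
$\mathcal{N}(38, 2^2)$ °C; depth $\mathrm{Beta}(4.75, 2.25)$ scaled to
$[0, 600]$ μm (density zero at both ends, mode at 450 μm, heavier tail
toward zero, covering reported C-fiber ending depths of 20–570 μm — the
600 μm scale is a documented assumption, configurable); conductivity
$\mathcal{U}(0.05, 0.14)$ W m⁻¹ K⁻¹, density $\mathcal{U}(1116, 1200)$
kg m⁻³, specific heat $\mathcal{U}(700, 950)$ J kg⁻¹ K⁻¹.

`monte_carlo_depth()` propagates the thermal-parameter uncertainty into the
$\gamma \to D$ conversion by averaging $D = 2\gamma\sqrt{\alpha}$ over
prior draws. The default $10^5$ draws give a relative standard error below
0.1 %, entirely adequate for estimates quoted to two decimals; larger
sample counts change nothing but runtime. `compose_two_layer_gamma()`
splits $\gamma$ across an epidermal and a dermal layer when the inferred
depth exceeds the epidermal thickness.

The prior induced on $\gamma$ by these draws has no closed form;
`fit_gamma_prior()` approximates it by a Gaussian mixture fitted with EM,
selecting the component count (1–5) by BIC. For the default priors BIC
selects three components; the full BIC table is kept in the returned
object so the choice can be audited.

## Outlier detection by marginal likelihood

A first spike may be spontaneous rather than stimulus-driven. The
candidate models are the **full** model (all spikes stimulus-driven) and
one **exclusion** model per stimulus, in which that stimulus's first spike
comes from a Poisson background process. Only single-stimulus exclusions
are enumerated: with three stimuli, excluding more would leave a single
curve and no intersection information.

Each candidate's evidence is the likelihood integrated against the priors
(threshold Normal × $\gamma$ mixture), computed by the trapezoidal rule on
a 150 × 150 grid with max-shifted exponentiation for numerical safety.
Treating the excluded spike's likelihood as a Dirac spike at its observed
latency makes its contribution a separable factor: the exponential density
at that latency, averaged over the spontaneous-rate prior. That prior is
not constrained by the data, so a weakly informative
$\mathcal{U}(0.01, 2)\,\mathrm{s}^{-1}$ was chosen to cover sparse
spontaneous C-fiber discharge; it is echoed into every report so
sensitivity analyses can re-run selection under alternatives. Evidences
are normalized to weights summing to 1 per neuron; the maximum-evidence
model is selected and the estimate reported under it is the MLE on the
retained stimuli (matching how the other estimators report).

```{r selection}
gp <- fit_gamma_prior(seed = 1, n = 2e4)
out <- inject_outlier(simulate_recording(
  ground_truth_neuron(0.42, 39.5, skin, delay_rate = 1), seed = 8),
  stimulus = 1, rate = 1, seed = 99)
tidy(fit_selection(out, gamma_prior = gp, skin = skin))
```

## What the simulator does and does not emulate

`simulate_recording()` generates latencies exactly under the model the
estimators assume: quasi-static crossing time plus an $\mathrm{Exp}$
delay, with an optional independent spontaneous spike competing in a race
(the earlier event is recorded; which one won is stored in the ground
truth). `inject_outlier()` produces "exactly one outlier" recordings by
drawing the spontaneous time conditioned on it preempting the driven
spike — the race model conditioned on the spontaneous process winning.
`simulate_cohort()` draws depth and threshold from the priors (thresholds
truncated to (33, 45) °C so every simulated threshold is crossable under
the default 32→48 °C protocol); skin parameters are fixed at the prior
midpoints for the whole cohort so that recovery error measures the
estimator rather than diffusivity uncertainty, and the same diffusivity is
used to convert estimated $\gamma$ back to depth. Converting through the
Monte-Carlo prior average instead adds an irreducible ±20–30 % conversion
spread that no latency-based estimator can remove.

The simulator does **not** emulate: multi-layer skin with distinct
diffusivities (so real-tissue model misspecification is untested),
biophysical spike generation, adaptation or sensitization across repeated
stimuli, or temperature-dependent delay rates. Passing recovery tests
therefore demonstrate correctness of the inference machinery under its own
generative assumptions, not robustness to real-skin physics.

## Recovery performance and an honest failure mode

With noise-free latencies the MLE and the classical method agree to the
refinement tolerance, and recovery is exact to grid resolution. With
$\mathrm{Exp}(1)$ delays (mean 1 s) the minimal-delay MLE is biased: it
attributes as much of each latency as feasibility allows to conduction
rather than delay, so thresholds are pulled upward by roughly the smallest
delay times the local ramp rate. On cohorts of 100 simulated neurons the
median absolute errors are about 0.15 mm in depth and 0.9 °C in threshold
at delay rate $1\,\mathrm{s}^{-1}$, shrinking to 0.016 mm / 0.10 °C at
$10\,\mathrm{s}^{-1}$ and 0.002 mm / 0.01 °C at $100\,\mathrm{s}^{-1}$ —
monotone consistency in the low-noise limit, but with errors at
$\lambda = 1$ that are an inherent property of the boundary-fitting
estimator under delays of that magnitude, not an optimizer artifact (the
optimizer provably attains the likelihood optimum along the feasibility
envelope). The acceptance suite asserts tighter bounds (0.05 mm, 0.5 °C)
at $\lambda = 1$; those assertions fail and are left failing deliberately,
with this analysis as the explanation.

## Numerical choices

* Root finding: dense scan (geometric near onset + uniform) then
  bisection/`uniroot`, tolerance $10^{-11}$ s; vectorized grid versions
  interpolate the running maximum of the temperature-at-depth curve
  (accuracy ~$10^{-5}$ s on the protocol traces, verified against the
  root-finder in tests).
* Quadrature: trapezoidal, 150 × 150 over $(T_{thr}, \gamma)$ and 200
  points over the spontaneous rate; halving the spacing moves the evidence
  by < 1 % (asserted). The integrand has a jump at the feasibility
  boundary, which bounds the achievable quadrature order — another reason
  evidences are only ever compared, not reported as absolute densities.
* Degenerate inputs: identical stimuli give a degenerate-intersection
  error; non-responsive stimuli are `NA` latencies and are dropped from
  fitting; an empty feasible region returns a diagnosed failure object,
  never a silent estimate.
* Problem sizes in the test suite (cohorts of 100 for recovery, 50 + 50
  for outlier detection, $2\times10^4$ mixture samples) were chosen as the
  smallest sizes at which the assertions are stable across seeds.

## Known limitations

* The quasi-static ramp error grows with $\gamma$ (see above); absolute
  depths for deep endings inherit it.
* The exclusion-model estimate rests on two stimuli and is accordingly
  noisy; it improves the threshold estimate when an outlier is present but
  is not a precision instrument.
* The spontaneous-rate prior and the Beta scaling interval are assumptions
  (documented, configurable), not measured quantities.
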