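# nocidepth

Estimation of the depth and heat-activation threshold of C-fiber
nociceptor endings in skin, from first-spike latencies recorded under
ramped heat stimulation.

## The problem

Heat-sensitive C-fibers (C-MH nociceptors) transduce noxious heat at free
nerve endings embedded somewhere in the epidermal/dermal layers. The
temperature at the transduction site cannot be measured: thermocouples are
too large, infrared imaging cannot locate the ending, and skin attenuates
and delays the applied surface temperature. Both the ending's **depth**
*D* and its **threshold temperature** *T*<sub>thr</sub> must therefore be
inferred from how the first-spike latency varies across heat ramps of
different rates.

The forward model is the error-function solution of heat conduction into a
semi-infinite solid, evaluated quasi-statically for time-varying surface
temperatures *S*(*t*):

```
T(x, t) = T0 + (S(t) − T0) · erfc(γ / √t),     γ = x / (2√α)
```

where *T0* is the baseline temperature, α = *k*/(ρ*c*) the thermal
diffusivity, and γ the *normalized depth* (s<sup>1/2</sup>) — the natural
inference coordinate, since the model depends on depth and diffusivity
only through γ.

Three estimators are provided:

1. **Classical intersection method** (`fit_classical()`) — each stimulus
   confines (γ, *T*<sub>thr</sub>) to a consistency curve; the estimate is
   the curves' common intersection, classified as
   `single` / `triangle` / `partial` / `none`.
2. **Delay maximum likelihood** (`fit_mle()`) — allows a nonnegative
   Exp(λ) delay Δ<sub>i</sub> = τ<sub>i</sub> − t*<sub>i</sub> between
   threshold crossing and first spike and maximizes
   ℓ = Σ<sub>i</sub> (log λ − λΔ<sub>i</sub>) subject to all Δ<sub>i</sub> ≥ 0;
   reduces to the classical solution as delays vanish, and still returns
   estimates when the curves fail to intersect.
3. **Marginal-likelihood model selection** (`fit_selection()`) — compares
   the full model against models that treat one stimulus's first spike as
   a spontaneous Poisson event (Bayesian evidence with literature-based
   priors, trapezoidal integration, evidence weights normalized to 1),
   detecting and discarding outlier responses.

A ground-truth simulator (`simulate_recording()`, `simulate_cohort()`)
reproduces the standard stimulation protocol (three 32→48 °C ramps of
16/4/2 s with a 10 s hold) and validates every estimator by parameter
recovery. Monte-Carlo propagation of skin thermal-parameter uncertainty
(`monte_carlo_depth()`) and a Gaussian-mixture approximation of the
induced γ prior (`fit_gamma_prior()`) connect normalized depth back to
millimetres.

## Worked example

Simulate a neuron 0.42 mm deep with a 39.5 °C threshold, Exp(1) response
delays, and one spontaneous (outlier) first spike, then run all three
estimators:

```r
library(nocidepth)

skin   <- midpoint_skin()                       # Table-midpoint k, rho, c
neuron <- ground_truth_neuron(depth_mm = 0.42, t_threshold = 39.5,
                              skin, delay_rate = 1)
rec    <- simulate_recording(neuron, seed = 8)
rec$latency_s
#> [1] 10.656975  3.451999  2.876427

fit_classical(rec, skin)      # delays break the intersection
#> Classical intersection estimate (sim)
#>   status: none
#>   pairwise intersections: 3

fit_mle(rec, skin)            # the delay model still estimates
#> Probabilistic (delay) ML estimate (sim)
#>   T_threshold: 40.04 C   depth: 0.456 mm (gamma 0.7233 s^1/2)
#>   log lik: -0.5526   delays (s): 3.55e-15, 1.26e-10, 0.553

gp  <- fit_gamma_prior(seed = 1, n = 2e4)       # mixture prior on gamma
out <- inject_outlier(rec, stimulus = 1, rate = 1, seed = 99)
fit_selection(out, gamma_prior = gp, skin = skin)
#> Marginal-likelihood model selection (sim)
#>   selected: exclude_1 (normalized full-model weight 0.000)
#> # A tibble: 4 × 4
#>   model     excluded log_evidence    weight
#>   <chr>        <int>        <dbl>     <dbl>
#> 1 full            NA       -13.1  0.0000502
#> 2 exclude_1        1        -3.20 1.000
#> 3 exclude_2        2       -13.1  0.0000479
#> 4 exclude_3        3       -13.3  0.0000414
```

Reading the output: with mean-1 s delays the classical curves no longer
meet (`none`), while the delay MLE recovers the parameters to within the
method's sampling error (here 40.04 °C / 0.456 mm against a truth of
39.5 °C / 0.42 mm). After replacing the long-ramp latency with a
spontaneous spike, the evidence overwhelmingly selects the model that
excludes exactly that stimulus. Every fitted object supports `tidy()`,
`glance()` and `autoplot()`; `run_pipeline()` runs all three estimators
and writes a single JSON report with the effective configuration echoed.

A thin command-line wrapper lives at `inst/cli/nocidepth.R`
(`simulate | fit-classical | fit-mle | select-model | run-all`).

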