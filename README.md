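# flimion

Fluorescence-lifetime photometry analysis and ion/pump modeling for
stimulus-evoked neuronal metabolism experiments.

Two-photon fluorescence-lifetime imaging (FLIM) of genetically encoded
biosensors — Peredox for cytosolic NADH:NAD⁺, RCaMP for Ca²⁺ — together with
the intensity-mode Na⁺ dye SBFI lets one follow, in single neurons in brain
slices, the chain that couples electrical activity to glycolysis: stimulation
drives Na⁺ and Ca²⁺ influx; Ca²⁺ is exported by the Na⁺/Ca²⁺ exchanger (NCX)
at a cost of 3 Na⁺ imported per Ca²⁺; the summed Na⁺ load activates the
Na⁺/K⁺-ATPase, whose ATP consumption stimulates glycolytic NADH production.
`flimion` implements the complete analysis path for such experiments, plus a
mechanistic synthetic-data generator so that every stage can be exercised and
validated without microscope data.

## What the package computes

* **TCSPC lifetime fitting (`tcspc`)** — photon-arrival histograms from an
  80 MHz pulsed laser (12.5 ns period) are modeled as exponential decays
  convolved with a Gaussian instrument response, with periodic wrap-around of
  the decay tail. `fit_lifetime()` performs a Poisson maximum-likelihood
  (or weighted least-squares) fit of a mono- or biexponential model,
  restricted to the window from the histogram peak to 8 ns after it; the
  scalar readout is **tau8**, the amplitude-weighted mean lifetime
  `Σ aᵢτᵢ` of that windowed fit. `simulate_histogram()` generates photon
  realizations of the same model.
* **Spectral unmixing (`unmixing`)** — green-emitting dyes bleed a fraction
  of their photons into the red channel. `estimate_bleedthrough()` recovers
  the ratio from control ROIs (mean of per-ROI red/green ratios, e.g. 0.053
  for SBFI into the red channel) and `unmix_red()` subtracts
  `ratio × green`, per TCSPC bin or per frame.
* **Transient quantification (`traces`)** — `delta_f_over_f()`,
  `transient_metrics()` (baseline, signed peak, time-to-peak, interpolated
  half-decay time), exclusion rules for noisy recordings (ΔRCaMP < 0.2 ns or
  RCaMP half-decay ≥ 35 s), ΔPeredox/ΔRCaMP response ratios,
  `bin_and_average()` cohort averaging on a common binned time axis (1 s
  bins outside the stimulus, 10 ms inside), and `compare_groups()`, a
  Shapiro–Wilk-gated choice of t-test vs Wilcoxon/Mann–Whitney.
* **Ion models (`ionmodels`)** — the SBFI single-site quench calibration
  `ΔF/F = −a·(f(Na) − f(Na₀))/(1 − a·f(Na₀))` with `f(x) = x/(K_d + x)`,
  `K_d = 26` mM, baseline `Na₀ = 13` mM and quench amplitude `a = 0.74`,
  invertible in closed form (`na_from_dff()`); Hill activation of the
  Na⁺/K⁺ pump `Naⁿ/(Naⁿ + K½ⁿ)` with `n = 3`, `K½ = 13` mM for α1β1
  (`hill_fraction()`, `fold_activation()`); and NCX/NKA/PMCA/SERCA
  transport stoichiometry (`ncx_na_load()`, `atp_cost()`).
* **Synthetic experiments (`synthexp`)** — `simulate_cell()` integrates a
  minimal Ca²⁺/Na⁺/NADH model (fixed-step RK4, 10 ms) under stimulation
  protocols (control, Ca²⁺-channel block, Ca²⁺ puff, ion substitution) and
  renders noisy sensor traces; `render_photons()` goes all the way down to
  photon-level TCSPC histograms; `generate_cohort()` builds paired cohorts
  with log-normal cell-to-cell variability.
* **Pipeline (`run_pipeline()`)** — validated JSON configuration in, result
  bundle (metrics JSON, averaged-trace CSVs, log) out, reproducible from a
  single seed.

## Worked example

```r
library(flimion)

## a Peredox-like biexponential decay, tau8 = 0.7*0.4 + 0.3*4.5 = 1.63 ns
m   <- decay_model(list(c(0.7, 0.4), c(0.3, 4.5)))
irf <- irf_model(center_time = 1.0, width_sigma = 0.2)
h   <- simulate_histogram(m, irf, n_photons = 5e5, seed = 11)
fit <- fit_lifetime(h, irf = irf, n_components = 2)
fit
#> Lifetime fit (poisson, window 1.17-9.17 ns, converged):
#>   a = 0.6995  tau = 0.4000 ns
#>   a = 0.3005  tau = 4.4834 ns
#>   background = 0.0008181, tau8 = 1.6270 ns, red. chi2 = 1.04
```

The fit recovers the generating parameters; `tau8_from_fit(fit)` returns
1.627 ns, within 0.003 ns of the ground truth.

```r
## sodium and pump activation implied by a peak SBFI quench of -25.6%
calib <- sbfi_calibration()        # Kd 26 mM, baseline 13 mM, a = 0.74
na_from_dff(-0.256, calib)
#> [1] 25.03088                     # mM above the 13 mM baseline

pump_activation_report(13, 38, hill_pump())
#> $percent_peak ... 96.2  (rounded: 95 % of maximal activity)
#> $fold         ... 1.92  (rounded: 2-fold over baseline)
```

A 25 mM sodium rise nearly saturates the α1β1 pump (≈95 % of maximal,
≈2-fold over its half-activated baseline); repeating the calculation for the
−11.5 % quench seen when Ca²⁺ entry is blocked gives +8 mM, ≈80 % and
≈1.5-fold — the nonlinear compression that makes the NCX contribution to the
sodium load visible.

## Layout

```
R/                  implementation (tcspc, unmixing, traces, ionmodels,
                    synthexp, io, pipeline)
tests/testthat/     unit, property and acceptance tests with independent
                    oracles (quadrature/FFT decay oracles, closed forms)
vignettes/          methods vignette: models, assumptions, parameter choices
inst/extdata/       example run configuration
scripts/            acceptance script
```
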