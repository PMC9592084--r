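---
title: "Models and methods behind flimion"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind flimion}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(flimion)
```

`flimion` analyses fluorescence-lifetime photometry of neuronal biosensors
and models the ion-transport chain that links stimulation to glycolytic NADH
production. This vignette documents the models, their assumptions, the
tunable parameters and the numerical choices, so that a user can judge what
a passing test suite does — and does not — establish about real recordings.

## 1. TCSPC decay model

A fluorophore excited by a pulsed laser (period $T = 12.5$ ns at 80 MHz)
emits photons whose arrival times, measured modulo $T$, follow a mixture of
wrapped exponential decays blurred by the timing spread of the instrument.
We model the instrument response (IRF) as a Gaussian with centre $t_0$ and
width $\sigma$, so each decay component with lifetime $\tau$ contributes an
exponentially-modified Gaussian (EMG), and the periodic excitation means
every observation window inherits the residue of all previous pulses:

$$p(t) \;=\; (1-b)\sum_i a_i \sum_{j\ge0} \mathrm{EMG}(t + jT;\, t_0, \sigma, \tau_i) \;+\; \frac{b}{T},$$

with amplitude fractions $a_i$ summing to one and a uniform background
fraction $b$ (dark counts, ambient light). Bin probabilities are exact
differences of the EMG CDF, evaluated in log space to avoid overflow of the
$\exp(\lambda^2\sigma^2/2 - \lambda x)$ factor. Pulse shifts near the
observation window are summed explicitly; once all bin edges clear the
Gaussian region ($x > t_0 + 10\sigma$) the EMG pdf is a pure exponential and
the remaining infinite sum collapses to a geometric factor. The tests verify
this construction against two independent oracles: numerical integration of
the un-convolved wrapped exponential (narrow-IRF limit) and a quadrature
convolution over the Gaussian excitation-time density, both to better than
$10^{-6}$ relative error.

**Binning.** Histograms default to 256 uniform bins over the period
(~49 ps), a standard TCSPC depth that resolves IRF widths of 0.1–0.3 ns.

**Lifetimes near or above 100 periods** make the decay indistinguishable
from flat background over one period; the package warns that such fits are
ill-conditioned rather than refusing them.

## 2. Lifetime fitting and the tau8 readout

`fit_lifetime()` fits the model to the counts restricted to the window from
the peak-count bin (earliest bin at the maximum, a deterministic tie-break)
to 8 ns after it. Windowing concentrates the fit on the region that carries
decay information and makes the readout insensitive to acquisition-window
differences between instruments. The default objective is the Poisson
negative log-likelihood — photon counts are Poisson — with the overall scale
profiled out analytically ($\hat S = \sum c_w / \sum q_w$); Pearson-weighted
least squares is available as an option since either weighting is defensible
for the count levels involved. Parameters are optimised on transformed
scales (log lifetimes, logistic amplitude and background) by Nelder–Mead
with up to three restarts followed by a BFGS polish; the restarts matter
because the windowed likelihood has a flat valley trading uniform background
against the long-lifetime tail, and a single simplex run can stall there.
Convergence tolerance is $10^{-8}$ on the relative objective change with at
most 500 iterations per run. Two-component fits whose lifetimes agree within
2% are collapsed to one component with a warning.

**tau8.** For a biexponential fit the scalar readout is defined as the
amplitude-weighted mean lifetime $\sum_i a_i\tau_i$ of the windowed fit. It
reduces to the single lifetime for mono-exponential fits and is the natural
scalar summary of a two-state sensor whose occupancy shifts with analyte
binding.

**IRF handling.** IRF parameters are normally supplied (from configuration
or a calibration measurement) and held fixed. Co-fitting ($t_0$ initialised
at the histogram peak, $\sigma$ at 0.2 ns) is supported but ill-constrained
when the fit window starts at the peak; treat co-fitted IRFs as a fallback,
not a calibration.

## 3. Spectral unmixing

With two detection channels, a green-emitting dye contributes
`ratio × green` counts to the red channel. The ratio is estimated from
control ROIs expressing only the green fluorophore as the **mean of per-ROI
red/green ratios** (rather than the ratio of summed counts), so each ROI
contributes equally regardless of brightness, and the spread across ROIs is
reported as its SD. Correction subtracts `ratio × green` per bin *before*
lifetime fitting — lifetimes are computed from photon histograms, so the
contamination must be removed at the histogram level — and is also exposed
for scalar intensity traces. Poisson noise makes small negative corrected
counts inevitable; they are clamped to zero and counted, and the clamp count
is reported, since silent clamping would hide a mis-estimated ratio. The
Peredox↔RCaMP unmixing ratio is instrument-specific and configurable
(default 0).

## 4. Transient quantification

* **Baseline**: mean of all samples in the 60 s before the stimulus. The
  window length is a package choice; it spans several coarse sampling
  intervals and is configurable via `analysis_thresholds()`.
* **Peak**: extremum of (value − baseline) after the stimulus — minimum for
  downward transients (SBFI quench), maximum for upward ones. The search
  window defaults to stimulus-to-end and is configurable.
* **Half-decay**: time from the peak until the signal first returns halfway
  to baseline, linearly interpolated between samples; recordings that never
  cross halfway are flagged rather than assigned a value. The estimator is
  applied to the raw samples, not the binned averages.
* **Exclusion rules**: response ratios ΔPeredox/ΔRCaMP are only computed
  when ΔRCaMP ≥ 0.2 ns (small denominators make the ratio noise-dominated)
  and the RCaMP half-decay is below 35 s (slow Ca²⁺ clearance indicates an
  unhealthy cell). Every recording yields exactly one of {ratio, exclusion
  record naming the failed rule}.
* **Cohort averaging**: traces are aligned on the stimulus, binned to 1 s
  outside the stimulation window and 10 ms inside it (acquisition is
  interleaved: samples every 10–60 s at rest, ~4 Hz during stimulation),
  then linearly interpolated onto the union grid with no extrapolation —
  each grid point averages only the traces that span it, and `n` per point
  is reported. SEM is SD/√n per point.
* **Group comparison**: Shapiro–Wilk at α = 0.05 on each group gates
  parametric (paired/two-sample t) versus nonparametric (paired
  Wilcoxon/Mann–Whitney) tests. Constant groups are routed to the
  nonparametric branch (the Shapiro–Wilk statistic is undefined for them),
  and identical paired samples report the null result (statistic 0, p = 1)
  rather than erroring. Box summaries use linear-interpolation percentiles
  (`quantile` type 7) for the 5–95% range.

## 5. SBFI calibration

SBFI fluorescence excited at 790 nm is quenched by Na⁺ binding. We adopt a
single-site binding quench model,

$$F(\mathrm{Na}) = F_\mathrm{free}\,\bigl(1 - a\, f(\mathrm{Na})\bigr),
\qquad f(x) = \frac{x}{K_d + x},$$

with the in-situ $K_d = 26$ mM and baseline $[\mathrm{Na}^+]_0 = 13$ mM, and
ΔF/F referenced to $F([\mathrm{Na}^+]_0)$. The quench amplitude $a = 0.74$
is a package constant fixed once so that the isotherm reproduces the paired
worked conversions −25.6 % → +25 mM *and* −11.5 % → +8 mM simultaneously
(the second conversion serves as the independent check; both are asserted in
the test suite). The inversion is algebraic and exact: the round trip
`na_from_dff(dff_from_na(x))` is the identity to below $10^{-9}$ mM across
0–200 mM. Inputs outside the achievable range (below the saturation quench,
or implying negative dye occupancy) are rejected rather than extrapolated.
Because $f$ saturates, equal ratios of ΔF/F correspond to *smaller* ratios
of Δ[Na⁺]: a 0.449 ratio of quenches maps to a ≈0.33 ratio of sodium
increases. This nonlinear compression is exactly why a calibration, not a
linear scale, is needed.

## 6. Hill model of pump activation

Na⁺/K⁺-pump activation by intracellular Na⁺ is cooperative with Hill
coefficient ~3 (three transported Na⁺). We use
$h(\mathrm{Na}) = \mathrm{Na}^n/(\mathrm{Na}^n + K_{1/2}^n)$ with $n = 3$
and $K_{1/2} = 13$ mM for the α1β1 isozyme — numerically equal to the
resting sodium concentration, which places the resting pump at
half-activation and makes it maximally sensitive to sodium loads. No
reliable $K_{1/2}$ exists for α3 at this model's level of abstraction, so
`hill_pump("alpha3")` requires an explicit value instead of shipping a
default. Fold-activation is the ratio of Hill fractions at peak versus
baseline. Reported values follow the precision the biology supports — mM to
the nearest integer, percent of maximal to the nearest 5 points, fold to the
nearest 0.5 — with raw values always retained.

## 7. The synthetic-experiment generator

`simulate_cell()` integrates a deliberately minimal latent model:

$$\frac{d\mathrm{Ca}}{dt} = J_\mathrm{Ca}(t)\,\beta -
  (k_\mathrm{NCX}\,[\mathrm{Na}^+_e] + k_\mathrm{other})(\mathrm{Ca} - \mathrm{Ca}_0)$$
$$\frac{d\mathrm{Na}}{dt} = J_\mathrm{Na}(t) +
  \phi\,k_\mathrm{NCX}\,[\mathrm{Na}^+_e](\mathrm{Ca} - \mathrm{Ca}_0) -
  V_\mathrm{max}\bigl(h(\mathrm{Na}) - h(\mathrm{Na}_0)\bigr)$$
$$\frac{d\mathrm{NADH}}{dt} = g\,V_\mathrm{max}\bigl(h(\mathrm{Na}) - h(\mathrm{Na}_0)\bigr)
  - k_\mathrm{NADH}\,\mathrm{NADH}$$

where $\beta$ is the fraction of Ca²⁺ influx remaining (1 normally, 0.145
under channel block), $[\mathrm{Na}^+_e]$ gates forward NCX transport (0/1),
and $\phi$ (`ca_to_na_volume_factor`, 22.1 mM/µM) lumps the strict 3:1 molar
NCX stoichiometry with the cytosolic Ca²⁺ buffering ratio and volume terms —
free-Ca changes understate the total Ca²⁺ flux the exchanger moves, so the
molar bookkeeping (tracked separately and checked to 0.1 %) and the
free-concentration coupling constant must differ. Linear clearances and a
linear NADH production term make this a *data generator embodying the
mechanistic narrative*, not a biophysical model: it exists so the pipeline
has ground truth to recover.

**Default conditions.** Defaults were tuned once, before the acceptance
tests were written, to the study conditions the pipeline targets: control
stimulation (2 s, emulating a 100-pulse 50 Hz train) peaks at +25 mM sodium
and the Ca²⁺-blocked condition at +8 mM (channel influx 3.16 mM/s and
$\phi = 22.1$ solve those two constraints); Ca²⁺ decays with ~1 s half-time,
sodium over tens of seconds ($V_\mathrm{max} = 1.2$ mM/s), NADH peaks about
a minute after the stimulus ($k_\mathrm{NADH} = 0.01\,\mathrm{s}^{-1}$).
Sensor baselines are 1.63 ns (Peredox) and 0.88 ns (RCaMP) with 0.05 ns
Gaussian sample noise — the across-condition spread of lifetime
measurements — and 1 % relative noise on SBFI intensity. Cell-to-cell
variability is log-normal with CV 0.2 on rates and gains, applied per cell
and shared between paired protocols.

**Integration** is fixed-step RK4 at 10 ms, written as an inline loop (the
system is non-stiff at these rates, and a fixed step makes runs bitwise
reproducible; the loop form avoids per-step closure overhead at 40 000+
steps). Negative concentrations abort with advice to reduce the step.

**Sampling** mimics interleaved acquisition: 10 s spacing at rest, 0.25 s
from 2 s before to 5 s after the stimulus. Simulations in the test suite use
recordings of 150–420 s; cohorts use n = 13 cells, matching the paired
designs the analysis targets.

**Photon rendering.** `render_photons()` maps each lifetime sample to a
biexponential decay with two fixed component lifetimes (0.4/4.5 ns for
Peredox, 0.3/2.5 ns for RCaMP) whose amplitudes are solved so the
amplitude-weighted mean equals the sensor lifetime — a two-state-sensor
picture — then draws a multinomial photon realisation per frame and leaks a
binomially thinned 5.3 % of green photons into the red channel.
`fit_photon_frames()` unmixes and refits every frame; it defaults to the
full-period window with the background fixed at zero because rendered frames
contain no dark counts and the pre-peak bins carry real information about
the long-lifetime tail (the windowed, background-free readout remains the
default for `fit_lifetime()` itself, where those assumptions cannot be
made).

**What the generator does not emulate.** Photobleaching, motion, focus
drift, pile-up and afterpulsing, sensor saturation (the RCaMP map is linear
by default), mitochondrial Ca²⁺ handling, the malate–aspartate shuttle, and
any pharmacology beyond what parameter changes can express. Passing
recovery tests therefore demonstrates that the *analysis* is correct and
self-consistent at realistic signal and noise scales — not that real tissue
obeys the generator's kinetics.

## 8. Randomness and reproducibility

Every stochastic operation takes an explicit integer seed and restores the
caller's RNG state afterwards. Cohorts derive per-cell noise seeds from the
cohort seed by fixed offsets, so any cell can be regenerated in isolation.
`run_pipeline()` is byte-reproducible for a fixed configuration.

## 9. Known limitations

* The windowed biexponential fit's background/long-tail degeneracy limits
  per-frame tau8 precision to roughly 0.01–0.03 ns at $10^5$ photons;
  averaging across frames is the intended remedy.
* Co-fitting the IRF together with two components from peak-windowed data is
  weakly identified (see §2).
* The α3 pump isozyme is supported only parametrically; no default
  half-activation is shipped.
* `compare_groups()` implements a fixed normality-gated two-group procedure;
  it is not a general statistics interface.
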