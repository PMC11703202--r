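---
title: "Temperature scaling of the embryonic cell-cycle oscillator: models and methods"
author: "oscitemp"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Temperature scaling of the embryonic cell-cycle oscillator: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", fig.width = 6)
library(oscitemp)
```

## The scientific problem

Early embryonic cell cycles of ectotherms (frog, zebrafish, nematodes, fly)
are driven by a biochemical relaxation oscillator built around the cyclin
B--Cdk1 kinase complex. Empirically the cycle duration scales with
temperature roughly like a single activated process: an Arrhenius plot
(log duration against inverse absolute temperature) is close to a straight
line over most of the viable range, with an apparent activation energy of
roughly 75 kJ/mol (a Q10 near 2.8 at 20 degC), and it bends upward at both
thermal extremes, where the cycle first slows and then stops.

`oscitemp` packages the quantitative machinery needed to study this
behaviour end to end:

* the four empirical duration-versus-temperature laws and their fitting
  pipeline (per-degree median binning, least squares on log durations,
  stratified bootstrap of apparent activation energies);
* a two-variable cyclin B--Cdk1 oscillator with Hill-type regulatory
  responses, temperature-scaled kinetic rates, nullcline/fixed-point
  analysis and arrest classification;
* limit-cycle period detection, period-versus-temperature sweeps with
  bisected thermal limits, and synthesis/degradation titration scans;
* likelihood-free (ABC-SMC) inference of per-rate activation energies from
  phase-duration summaries;
* pipelines that turn droplet FRET-ratio recordings and in-vitro assay
  time series into phase durations and rates;
* synthetic-data generators for all three input classes with known ground
  truth, so every stage is testable without external downloads.

## Scaling laws

All laws are expressed as durations in minutes; rates are their
reciprocals. Temperatures enter in kelvin, and activation energies are
reported in kJ/mol with R = 8.314 J mol^-1 K^-1.

* **SE (Arrhenius)**: `dt(T) = (1/A) exp(+Ea/RT)`; the rate is
  `A exp(-Ea/RT)`.
* **DE (double exponential)**:
  `dt(T) = A1 exp(-Ea1/RT) + A2 exp(-Ea2/RT)`, four parameters.
* **QE (quadratic exponential)**: `dt(T) = A exp(-(Ea/R)(1/T + B/T^2))`.
* **PE (power law--exponential)**: `dt(T) = A T^B exp(-Ea/RT)`.

The sign conventions follow the printed forms exactly: the SE duration
carries `+Ea/RT` while the DE/QE/PE terms carry `-Ea/RT`. Consequently a
U-shaped DE duration has `Ea1 < 0 < Ea2`, and the nested-model identities
map parameters with a sign flip (`a2 = 0` reduces DE to SE with
`Ea = -Ea1`, `A = 1/A1`). To make laws comparable, `apparent_ea()` reports
the local slope of log duration against inverse temperature (times R) for
any law, in the SE convention where a process that speeds up with warming
has positive apparent energy.

The local Q10 is defined on a 10-degree interval,
`Q10(T) = dt(T)/dt(T+10)`; for an Arrhenius law this equals the closed
form `exp((Ea/R)(1/T_K - 1/(T_K+10)))` implemented in `q10_from_ea()`
(75 kJ/mol at 20 degC gives 2.76, i.e. 2.8 at the reported precision).
An instantaneous-derivative definition would differ by a few percent at
strongly curved points; the interval form is used throughout and matches
the reported Q10--Ea correspondence.

```{r q10}
q10_from_ea(75, 20)
ea_summary(c(87, 51, 46, 56))  # the four in-vitro regulator energies
```

## Fitting pipeline

Measurements (one duration per embryo/droplet/cycle) are binned at integer
temperatures (round-half-to-even) and the per-bin **median** is the unit
of fitting; medians make the pipeline robust to the right-skewed duration
noise, and the synthetic generator's multiplicative lognormal noise is
median-preserving by construction, so binned medians are unbiased for the
generating law.

SE, QE and PE are linear in their parameters on the log scale and are fit
by ordinary least squares on log durations. DE is fit in three steps: an
SE fit on a caller-chosen Arrhenius interval; an SE fit to the positive
residual durations outside it; then a full nonlinear least-squares
refinement on durations (Levenberg--Marquardt, amplitudes kept positive
through a log parameterisation) seeded by the first two steps. If the
refinement fails to improve the seed it is discarded. Model comparison
always uses the mean squared error on log durations (`mse_log`), which is
invariant to the duration unit; the DE refinement itself minimises error
on durations, and the two choices are deliberately kept distinct.

Bootstrap distributions of the apparent activation energy resample
individual measurements with replacement *within* each integer bin
(stratified), preserving the temperature design; resamples leaving fewer
than two usable bins are redrawn and counted. The 90% interval is the
5th/95th percentile of the resampled energies. Dataset-specific outlier
exclusions (for example a suspect lowest-temperature bin) are passed as an
explicit `exclude_bins` argument, never hard-coded.

## The two-ODE oscillator

State variables are total cyclin B (`cyc`, nM) and active Cdk1 (`cdk1a`,
nM):

```
dcyc/dt      = ks - kd * d(cdk1a) * cyc
eps dcdk1a/dt = ka * a(cdk1a) * (cyc - cdk1a) - ki * i(cdk1a) * cdk1a
```

`d`, `a`, `i` are Hill responses of APC/C-mediated degradation, Cdc25 and
Wee1 to active Cdk1, obtained by a quasi-steady-state elimination of the
fast phosphorylation reactions. The bistable switch (Cdc25 positive
feedback, Wee1 double-negative feedback) plus the slow cyclin turnover
negative feedback produce relaxation oscillations for `eps` well below 1:
slow cyclin build-up, abrupt Cdk1 activation, APC/C-driven cyclin
destruction, abrupt inactivation.

### Reference parameterisation

`oscitemp_defaults()` is the single source of truth for numeric defaults.
Hill shapes follow steady-state response measurements in frog egg
extracts: a sharply ultrasensitive degradation response (EC50 32 nM, Hill
coefficient 17, basal 0.01, amplitude 0.06), an ultrasensitive Cdc25
response (EC50 35 nM, n = 11, range 0.16--0.96) and a shallower Wee1
response (EC50 30 nM, n = 3.5, range 0.48 down to 0.08). With `kd = 1.5`
per min, `ka = ki = 1` per min and `eps = 0.1`, the cyclin synthesis rate
was calibrated once to `ks = 2.2` nM/min so that the reference set
oscillates with a period near 30 min, with the rising (interphase-like)
phase occupying roughly three quarters of the cycle — the qualitative
phenotype seen in extract recordings. Simulations use a stiff-capable
solver (`lsoda`; a compiled right-hand side is the default, with a pure-R
reference implementation tested against it) at tolerances `rtol = 1e-8`,
`atol = 1e-10` — tighter than typical defaults because period detection
differentiates peak positions — over a standard 1000-minute horizon from
the origin state.

### Phase-plane analysis

The cyclin nullcline `cyc = ks/(kd d(cdk1a))` depends only on `ks/kd`;
the S-shaped Cdk1 nullcline
`cyc = cdk1a (1 + ki i(cdk1a)/(ka a(cdk1a)))` only on `ki/ka`.
`fixed_points()` brackets all intersections along the Cdk1 nullcline,
classifies stability from the analytic Jacobian, and labels stable states
as interphase-like (active Cdk1 below the Cdc25 half-activation point) or
M-phase-like (above it). Starving the oscillator of synthesis produces the
former; excess synthesis the latter; the reference set has a single
unstable state encircled by the limit cycle.

## Temperature maps and scaling scenarios

A `temperature_map` attaches a rate curve to each of `ks`, `kd`, `ka`,
`ki` and the inverse time-scale separation (`1/eps` scales like a rate, so
the switch speeds up with warming); Hill shapes stay
temperature-independent. Rate curves are reciprocal duration laws anchored
at a reference temperature: an Arrhenius curve for single-activated
scaling, or a biphasic curve (U-shaped DE duration with a stated optimum
and a steep, denaturation-like decline above it) for thermally fragile
processes.

Four canonical scenarios organise the analysis:

1. **All energies equal.** Rescaling all four rates by a common factor and
   time by its inverse maps orbits onto orbits, so the period is exactly
   Arrhenius with the shared energy. The sweep-and-refit check recovers
   the input energy to a fraction of a percent.
2. **Pairwise-equal energies** (synthesis/degradation vs
   activation/inactivation), fast switch: both nullclines are
   temperature-invariant and the period follows the synthesis/degradation
   energy; the mismatch contributed by the switch phases scales with
   `eps`.
3. **Synthesis/degradation imbalance.** `ks/kd` then drifts with
   temperature, the cyclin nullcline slides across the S-shaped nullcline,
   and oscillations fail at both extremes: finite `t_min` and `t_max`
   bracket a concave-up (bowed) Arrhenius plot.
4. **Biphasic synthesis.** A thermal optimum in `ks` alone produces a
   high-temperature upturn and a hot limit while remaining Arrhenius-like
   on the cold side.

`extract_map()` packages the extract-like configuration inferred from
droplet phase durations: biphasic synthesis (cold-side energy 113 kJ/mol,
optimum near 30 degC, 300 kJ/mol decline above it — a typical
denaturation-scale slope), weakly scaling degradation (40 kJ/mol) and a
60 kJ/mol switch-speed energy. Both failure mechanisms are then active at
once, as the data require.

## Period detection, thermal limits, titration

Peaks of the cyclin variable are local maxima with a minimum prominence of
10% of the series range and a minimum separation of 5 minutes of model
time (robust against solver output density and conservative for sawtooth
shapes); peak times are refined by a local quadratic so periods are not
quantised to the output step. The period is the spacing of the **last two
peaks** of the horizon; if their heights differ by more than 5% (relative)
the trajectory is classed as damped, not oscillating. The 5% figure is a
documented default, exposed as `amp_tol`. Rising/falling durations are
measured on the active-Cdk1 variable over the final full
trough--peak--trough cycle.

`temperature_sweep()` applies this at each grid temperature and refines
the outermost oscillating/non-oscillating brackets by bisection to
0.1 degC (matching the integer-degree resolution of the experimental
binning); `t_opt` interpolates the period minimum. `titration_scan()`
rescales the reference-temperature anchors of synthesis (and, to a lesser
extent, degradation) while leaving their temperature dependence intact,
emulating morpholino knock-down of cyclin translation. Under the
extract-like map, lowering synthesis narrows the viable range from both
ends; raising it speeds the cycle, broadens the range, and at high factors
produces failure that begins at intermediate temperatures.

## ABC-SMC inference

Observed summaries are binned median durations per temperature — either
the period or the rising/falling phase pair. Distances are mean squared
differences of log durations over shared bins (both phase channels
averaged with equal weight); bins where the model fails to oscillate but
the data cycle add a fixed penalty of 10 to the pool (the value is a
config knob; it simply has to dominate any plausible squared-log error).

The sampler is a standard sequential population Monte Carlo: generation
one keeps the best half of twice the population drawn from the prior;
subsequent generations resample by weight, perturb with a Gaussian kernel
(per-parameter sd equal to sqrt(2x) the weighted population variance),
and accept below an epsilon set to the median of the previous generation's
accepted distances, stopping when epsilon stalls (relative change below
1%), the generation budget is reached, or a generation yields nothing.
Weights follow the usual prior/kernel ratio. The sampler is sequential and
fully determined by its seed. Default priors are uniform on
[-100, 250] kJ/mol for energies (negative values express declining
branches) and log-uniform within a factor of ten of the reference for
anchors; both are documented stand-ins for unpublished fitting settings.
`posterior_summary()` reports the weighted mean, a weighted-kernel mode
(Silverman bandwidth) and the central 90% interval — mean and mode are
both reported because the degradation-energy posterior is strongly
right-skewed. `fit_sweep_direct()` offers the non-Bayesian counterpart (a
Nelder--Mead point fit of the same distance) for quick optimal fits.

At desk scale (population 200, at most 8 generations, observations from
the package's own generator at 16--26 degC) the sampler recovers a
113 vs 40 kJ/mol synthesis/degradation imbalance with the synthesis energy
within about 5% and essentially all posterior mass on the correct sign of
the imbalance.

## Droplet and assay pipelines

Droplet quality control keeps radii under 100 um and track starts within
the first 60 minutes, logging a reason per rejection. Cycle segmentation
deserves detail because phase durations must be read off series sampled
every ~5 minutes:

* Raw peaks/troughs are local extrema of a lightly despiked copy (3-point
  running median) with prominence at least 20% of the droplet's range and
  15-minute separation (extract periods are 30 minutes or more);
  alternation is enforced by keeping the highest peak per
  trough-to-trough cycle.
* Raw extremum samples would quantise durations to the sampling lattice,
  so extremum times are refined by anchoring on the waveform's fast
  edges, pooling shape information across the droplet's own cycles: the
  M-phase decline slope (common-slope fit with per-cycle intercepts),
  bias-corrected ceiling and fold levels (order-statistic correction of
  the observed extremes), the destruction-drop duration estimated from
  how often a sample lands mid-drop, and interpolation of mid-drop
  samples down to the floor. Every refinement is clamped to its
  bracketing samples, and waveforms without fast edges (the gates test
  for a dominant step adjacent to the raw extremum) fall back to local
  quadratic refinement, so smooth signals are segmented sensibly too.
* Sub-sample accuracy requires each phase to span a few sampling
  intervals; with 5-minute sampling, median phase durations are recovered
  to a few percent for phases of 15 minutes and longer, while phases
  comparable to the sampling interval are only determined to about one
  interval. Closure tests are designed accordingly.

Cycle selection implements both reported windows: cycles 2--4 (1-based
from the first complete trough-to-trough cycle) or all cycles whose
starting trough falls within the first 300 minutes. The interphase slope
(a direct proxy for the cyclin synthesis rate) is the least-squares slope
over the central 10--90% of a rising segment; the average waveform
rescales each selected cycle to trough-to-trough phase in [0, 1],
resamples linearly and averages pointwise, leaving amplitude in native
units (alignment details of the original analysis are unpublished; the
trough-anchored rescaling used here is stated explicitly for that
reason).

In-vitro assay series are reduced to rates as follows: synthesis, kinase
and phosphatase signals take the least-squares slope over an initial
linear window grown greedily while the running R^2 stays at or above 0.95
(a documented stand-in for unpublished assay-fitting details; the
threshold is an argument); degradation series estimate the plateau from
the final 10% of samples, fit log excess against time, and refine
baseline, amplitude and decay constant jointly by nonlinear least squares
seeded by that log fit. `rates_to_ea()` then applies the standard
median-binning Arrhenius fit to per-series rates and bootstraps over
series within temperature bins.

## Synthetic data

Three generators emulate the input classes with known ground truth.
Embryo timing tables draw durations from a stated law with multiplicative
lognormal noise (median-preserving, so binned medians are unbiased).
Droplet recordings simulate the two-ODE model through a temperature map,
map active Cdk1 affinely onto a FRET-ratio-like range of 0.9--1.4 (only
shape and timing matter downstream), optionally stretch successive cycles
geometrically (`1 + drift` per completed cycle, emulating the slowing of
extract cycles over time), sample every 5 minutes (within the reported
3--7 minute acquisition cadence) from a random track start, and add
Gaussian observation noise (default sd 0.01 ratio units, about 2% of the
waveform amplitude — typical for ratiometric imaging). Radii are
lognormal around 50 um so a realistic fraction fails quality control.
Assay series are exact lines or exponentials with Gaussian noise.

What the generators do **not** emulate is worth stating: droplet-to-
droplet biochemical variability beyond observation noise and drift,
photobleaching, imaging gaps, segmentation errors upstream of the FRET
trace, and the gradual amplitude run-down of ageing extracts. Passing
closure tests therefore demonstrates the correctness of the pipeline's
computations, not the behaviour of every real-data pathology.

## Problem sizes and numerical choices

Simulation-based checks use the sizes at which the reported behaviour is
comfortably resolved: sweeps over 7--9 temperatures at the 1000-minute
horizon; ABC at population 200 and at most 8 generations with a shortened
(400-minute, 0.25-minute output, 1e-6 tolerance) sweep inside the
sampler, which leaves at least a dozen cycles per evaluation; closure runs
with 10--16 droplets per temperature. Degenerate inputs are handled
explicitly: fewer than two peaks means "not oscillating" rather than an
error, empty segmentations are valid results, zero-overlap distances are
infinite, and a generation with no ABC acceptances returns the last
completed generation with a warning. Ties in peak selection resolve
toward earlier time through the stable order of detection.

## Known limitations

* The reference parameterisation is a transcription of the published
  response-curve lineage with a single calibrated synthesis rate, not a
  fit to any particular extract; its oscillatory `ks/kd` window spans
  about a four-fold range, which is narrower than the fitted models used
  for some published scans. One visible consequence: rescaling synthesis
  by 1.6 and degradation by 0.7 (the extract-to-embryo correction) drives
  this calibration past its M-phase-arrest boundary above ~20 degC, so
  the direction of that correction is demonstrated at 18 degC.
* Phase durations shorter than about two sampling intervals cannot be
  recovered to better than roughly one interval per cycle; median-level
  accuracy then rests on pooling many cycles.
* The ABC distance treats temperature bins as independent; correlated
  drift within droplets is not modelled in the distance.
* Only the two-variable oscillator is implemented; the map/scenario
  interfaces accept any parameter set expressed through the same rate
  names, which is where a higher-dimensional model would plug in.
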