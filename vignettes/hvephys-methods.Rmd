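---
title: "Methods: models and estimators in hvephys"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models and estimators in hvephys}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hvephys)
```

`hvephys` characterizes voltage-gated proton (Hv1) channels from
macro-patch current ensembles. This vignette documents the generative
model behind the simulator, each estimator and its assumptions, the
numerical choices, and what the recovery tests do and do not demonstrate
about real recordings.

Units are fixed package-wide: mV, ms, pA, nS; unitary quantities are
reported in fA and fS. The default temperature is 294.15 K (~21 °C room
temperature); every function that involves RT/F accepts a `temperature`
argument. Physical constants are CODATA 2018 values in `hv_constants`.

## Conventions

**Boltzmann sign.** All activation curves use
$A(V) = A_\mathrm{max} / (1 + e^{-z\delta F (V - V_{0.5})/RT})$, which
increases with depolarization for $z\delta > 0$ and equals
$A_\mathrm{max}/2$ at $V_{0.5}$. (The alternative sign convention that
appears in parts of the literature produces curves that fall with
depolarization; plotted proton-channel GV data rise, so the package
standardizes on the rising form.)

**ΔpH.** `ph_condition(pH_in, pH_out)` defines
$\Delta pH = pH_{out} - pH_{in}$. With this convention the proton Nernst
potential is $V_{rev} = -\ln(10)\,(RT/F)\,\Delta pH$, i.e. −58.4 mV per
unit at 294.15 K: an outward-acidic gradient (pH_in 6 / pH_out 7,
ΔpH = +1) gives a negative reversal potential, as observed for
proton-selective channels.

## The generative model

`channel_model` describes N independent channels, each a two-state
(closed/open) Markov chain with voltage-dependent opening rate
$\alpha(V)$ and closing rate $\beta(V)$ chosen so that

* the equilibrium open probability is
  $p_\infty(V) = P_\mathrm{max} \cdot \mathrm{Boltz}(V; z\delta, V_{0.5})$, and
* the relaxation time is $\tau(V) = 1/(\alpha + \beta)$, derived from a
  symmetric charge split (each rate carries $z\delta/2$) and scaled so the
  opening rate at 0 mV equals `rate_scale`.

Design choices worth stating explicitly:

* **`tau_min`** (default 0.5 ms) floors $\tau(V)$. The symmetric
  exponential rate law diverges far from $V_{0.5}$, which is unphysical
  (conformational rates saturate) and would force sub-microsecond time
  steps at ordinary holding potentials. The floor changes kinetics only
  where $\tau$ would be unrealistically fast; equilibrium behavior is
  untouched. Models meant to keep their activation state through a fast
  ramp (the reversal-potential protocol) should set `tau_min` to tens of
  ms, matching the slow deactivation of real Hv1 channels.
* **`P_open_max`** multiplies the Boltzmann equilibrium as a
  voltage-independent factor. Measured maximal open probabilities of Hv1
  are below 1 with no established mechanism; a voltage-independent
  blocked fraction is the simplest generative structure that reproduces
  the observation.
* **`n_gating_steps`** ≥ 2 replaces the single activation step by that
  many identical sequential transitions (per-step rates $m\alpha$,
  $m\beta$), producing the sigmoidal activation delay characteristic of
  dimeric Hv1 gating. Any scheme with a delay would do; this one has one
  parameter and collapses to the two-state model at 1.
* **`dV_half_per_pH`** (default −40 mV per ΔpH unit) shifts $V_{0.5}$
  linearly when `shift_condition` re-references a model to a new
  gradient, emulating the observed hyperpolarizing shift of activation
  with increasing outward proton gradient.

**Simulation scheme.** `simulate_ensemble` propagates aggregate state
counts with binomial draws: per step, movers are drawn with probability
$1 - e^{-(f+b)\Delta t}$ and split between directions by the rate shares
$f/(f+b)$, $b/(f+b)$; at boundary states the disallowed share stays put.
For the two-state chain this matches the exact propagator (stationary
ratio $f/b$, relaxation $e^{-(f+b)\Delta t}$) at any step size; for
multi-step chains the error is $O(\Delta t^2)$, and the simulator refuses
steps with rate·Δt ≥ 1 and warns above a per-step transition probability
of 0.2. Aggregate updating keeps desk-scale runtimes for N up to 10⁶,
unlike per-channel Gillespie simulation. A `deterministic` mode
propagates expected occupancies (exact for the two-state chain),
providing noiseless reference traces for estimator validation.

The measured current is
$I = n_\mathrm{open}\,\gamma\,(V - V_{rev}) + G_{Leak}(V - V_{Leak}) +
I_\mathrm{const} + \varepsilon$, with white Gaussian $\varepsilon$
(`thermal_noise_sd`) and optional multiplicative rundown across sweeps.
Proton depletion during large currents is deliberately not modeled: the
variable-duration protocols the analyses assume exist precisely to avoid
it, and the simulator emulates the depletion-free regime those protocols
target.

**What the generator does not emulate.** Series-resistance and
liquid-junction errors, capacitive transients (only a constant remnant is
modeled), proton depletion and intracellular pH dynamics, open-channel
noise and 1/f noise, and zinc or arachidonic-acid pharmacology. Parameter
recovery on these synthetic ensembles therefore validates the estimators'
statistical behavior under the model's assumptions — it cannot certify
robustness to artifacts the generator lacks.

## Estimators

### IV and tail-GV Boltzmann fits

`extract_iv` averages the last 5 % (configurable) of each depolarizing
pulse; `extract_tail_gv` reads tail amplitudes isochronally 0.5 ms after
the step to the common tail potential (past the capacitive settle) and
converts to conductance by $G = I_{tail}/(V_{tail} - V_{rev})$, removing
driving-force differences. Neither window is canonical in the
literature; both defaults are configurable. Fits are unweighted
Levenberg–Marquardt least squares (`minpack.lm`), with starting values
from the data (half-maximum crossing, logit-linear slope); an optional
`weights` argument enables SE-weighted fits. A midpoint fitted outside
the sampled voltage range triggers an identifiability warning rather
than an error. GV curves for cross-condition comparison are normalized
by the fitted $G_\mathrm{max}$.

### Leak subtraction

`subtract_leak` fits $I = G_{Leak}(V - V_{Leak})$ to end-pulse currents
at subthreshold voltages (≥ 2 required; singular otherwise), subtracts
it via the command voltage, and re-baselines each sweep on its pre-pulse
holding segment, which absorbs the residual constant offset.

### Nonstationary noise analysis

`ensemble_moments` offers the direct pointwise variance (n−1
denominator) and the pairwise-difference estimator
$\hat\sigma^2(t) = \langle (I_{k+1}(t) - I_k(t))^2 \rangle / 2$, which
cancels slow drift (rundown) and is the default. The baseline
(closed-channel) variance is estimated on the pre-pulse segment and
subtracted — the acquisition chain is assumed already low-pass filtered,
and no further digital filtering is applied.

`fit_variance_parabola` fits $\sigma^2 = i\langle I\rangle - \langle
I\rangle^2/N$, which is linear in $(i, 1/N)$, by iteratively reweighted
linear least squares with weights $\propto 1/\sigma^4$ (the sampling
variance of a sample variance scales with $\sigma^4$). $P_\mathrm{max} =
I_\mathrm{end}/(iN)$ and $\gamma = i/(V - V_{rev})$ follow. A
band-averaged comparison of mid-range and top-range variances flags
non-biphasic data (monotone variance means the open probability never
passed 0.5 and the curvature is weakly constrained); a negative fitted N
is an error. Optional equal-mean binning is available but the default
fits raw time points.

A statistical caveat documented deliberately: with a single activation
rise per sweep, the interior of the variance–mean parabola is crossed
once per sweep, so the curvature information saturates at the sweep
count. At 128 sweeps the sampling dispersion of $\hat i$ is ~10 % (and
of $\hat N$ ~15 %, anticorrelated, since $iN$ is pinned by the steady
current). Published per-patch estimates carry comparable uncertainty.
Recovery tests at a fixed seed should be read with that dispersion in
mind.

### Reversal potential from fast-ramp crossings

With sweeps carrying different activation levels into a fast ramp, every
channel current vanishes at $V = V_{rev}$ regardless of its gating
state, so the traces cross and the across-sweep variance is minimal
there. `estimate_vrev_crossing` discards the first 5 % of ramp samples
(residual capacitive transient at the ramp corner), smooths the variance
profile with a centered moving average (0.5 mV default width), and takes
the minimizing voltage; exact ties resolve to the sample closest to the
median of the minimizing set, and a minimum at the ramp edge raises a
boundary warning. Flat profiles (indistinguishable sweeps) are an error,
not a value. The method needs gating to be slow relative to the ramp —
that is what preserves distinct activation levels across the ramp — so
simulated ensembles for this protocol use a `tau_min` of tens of ms.
`nernst_regression` then regresses $\hat V_{rev}$ on ΔpH by OLS; a
proton-selective channel gives −58.4 mV per unit, while any
leak-like conductance pulls the slope toward zero (conductance-weighted
mixing of reversal potentials).

### Limiting slope

`preprocess_ramp` takes the rising limb of a slow symmetric ramp
(0.5–1 mV/s keeps gating at equilibrium; > 2 mV/s warns), optionally
low-pass filters at 10 Hz (4-pole digital filter run forward–backward
for zero phase), block-averages five points, converts to conductance
with the known $V_{rev}$, and mean-bins into 100 equal-voltage bins.
`fit_limiting_slope` computes $z\delta(V) = (kT/e_0)\, d\ln G/dV$ by
central differences on the binned curve and reports three numbers: the
plateau estimate $z\delta_\mathrm{eff}$ (median of $z\delta(V)$ over
bins with $G/G_\mathrm{max}$ below the 0.01 default threshold — the
median is used because no canonical reduction of the plateau to a single
number exists), the slope of the log-linear exponential fit
$G = G_0 e^{z\delta F V/RT}$ over the same region, and the steepness of
a Boltzmann fit of the full curve. For an exact two-state curve all
three agree; on real data they bracket the estimate. Fewer than 10
sub-threshold bins warns; non-positive conductance in the fit region is
a log-domain error.

### Kinetics

`fit_activation_tau` fits $I(t) = a\,e^{-(t - t_0)/\tau} + C$ from the
time of 20 % rise (configurable), skipping the sigmoidal delay of
multi-step gating; fitting from $t = 0$ instead biases $\tau$ high, and
the package keeps both options because the bias itself is informative.
For a two-state channel the fitted $\tau$ equals $1/(\alpha + \beta)$;
for the sequential multi-step scheme it approaches the slowest
eigenvalue of the chain where eigenvalues are separated (near the
midpoint), and overestimates it where they degenerate (strong
depolarization) — a limitation of single-exponential reduction, not of
the fit. `tau_v_curve` applies the fit per step voltage of a family.

`decompose_exponentials` fits sums of exponentials by separable least
squares: amplitudes and offset are solved linearly for any candidate
time constants, and the constants are optimized on a log scale
(L-BFGS-B) from 20 multi-starts — one log-spaced, the rest randomized
under a fixed seed, so results are deterministic given the seed. Bounds
default to [0.1 ms, 10 × trace length]. Time constants closer than a
factor 1.5 trigger a merged-component warning; three-component fits are
reliable when the constants are separated ≥ 4-fold, which is the regime
the mixed-isoform decomposition targets.

## Trace formats and the pipeline

`write_atf`/`read_atf` implement a text ATF dialect: signature line,
record counts, quoted `Key=Value` header records (units, sample
interval, pH condition, temperature, JSON-encoded protocol), a title
line, then tab-delimited time + one column per sweep at 9 significant
digits. CSV files carry the same metadata in a single `#`-prefixed JSON
line. Format errors report the offending line. Time is stored in ms,
0-based at sweep start.

`run_pipeline` validates the stage list before executing anything, runs
stages in order against a simulated or loaded ensemble, and writes
`results.json` plus `manifest.json` (package version, seed, config MD5).
Stage failures exit with the stage name and preserve earlier results.

## Problem sizes in the tests

The recovery studies in the test suite use the sizes above: 128 sweeps
for noise analysis (400 ms pulses at 0.2 ms sampling), 5-sweep
variable-duration ramp families at 0.05 ms sampling for reversal
estimation, single 200 s slow-ramp limbs at 20 ms sampling for the
limiting slope, and 10⁴–10⁵-channel patches. These match the scale of
the experiments the analyses come from while keeping the whole suite
inside a coffee break on one core.
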