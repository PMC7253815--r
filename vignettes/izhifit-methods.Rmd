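---
title: "Models and methods behind izhifit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind izhifit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(izhifit)
```

## The neuron model

izhifit simulates the two-variable quadratic spiking-neuron model

$$\dot v = 0.04 v^2 + 5 v + 140 - u + I, \qquad \dot u = a (b v - u),$$

with the discontinuous after-spike rule: when $v$ reaches $+30$ mV, $v
\leftarrow c$ and $u \leftarrow u + d$. The membrane potential $v$ is in mV,
$u$ is a dimensionless recovery variable aggregating ionic-current
activation, and $I$ is the injected current in the equation's own input
units. The four parameters have direct biophysical readings: $a$ is the
recovery time scale (smaller = slower recovery), $b$ the sensitivity of
recovery to subthreshold voltage (it moves the resting potential between
roughly $-70$ and $-60$ mV), $c$ the after-spike reset voltage, and $d$ the
after-spike jump of $u$.

**Integration.** The equations are integrated with forward Euler. The
published convention for this model is a 1 ms step; the package defaults to
`dt_ms = 0.1`, trading speed for accuracy, and exposes the step in
`sim_config()`. A property test checks grid robustness: halving `dt`
changes the spike count of the canonical tonic simulation by at most one.
The inner loop is compiled (Rcpp) because the genetic algorithm evaluates
on the order of $10^4$ full traces per fit; `step_update()` is pure R and a
test pins the compiled path against repeated R steps (to near machine
precision — compiled arithmetic may use fused multiply-adds).

**Spike rendering.** A spike sample is stored clipped at the apex
(`peak_cutoff = +30` mV) while the carried state takes the reset values.
This matches the standard way the model's traces are plotted and makes
`max(v)` testable: every clipped trace peaks at exactly $+30$.

**Fixed points.** `equilibria()` solves $0.04 v^2 + (5-b) v + (140+I) = 0$,
with $u^* = b v^*$, and classifies each root by the eigenvalues of the
Jacobian. With $b = 0.2$ and no input the stable root is $-70$ mV and the
saddle $-50$ mV; with $b = 0.25$ the stable root is $\approx -64.41$ mV; at
$I = 20$ no fixed point remains and the cell fires repetitively.

**Initial conditions.** Simulations start at the stable equilibrium under
the holding current when one exists, else at $(c, b c)$. One registry
entry overrides this: the integrator cell ($b = -0.1$) has its stable
equilibrium near $-87.5$ mV, far below the operating point at which the
pattern is conventionally demonstrated, so its registry entry starts at
$-60$ mV like the published gallery.

## The canonical pattern registry

`canonical_registry()` holds the eight patterns with their published
quadruples and a protocol that elicits each:

| pattern | (a, b, c, d) | protocol |
|---|---|---|
| tonic spiking | 0.02, 0.2, −65, 6 | step I = 10 from 20 ms |
| mixed spiking | 0.02, 0.2, −55, 4 | step I = 10 from 20 ms |
| integrator | 0.02, −0.1, −55, 6 | paired pulses (40 × 2 ms, 2 ms gap) + wide control pair |
| depolarizing (DAP) | 1, 0.2, −60, −21 | single pulse 12 × 2 ms |
| phasic spiking | 0.02, 0.25, −65, 6 | step I = 0.5 from 20 ms |
| rebound spiking | 0.03, 0.25, −60, 4 | pulse −15 × 5 ms |
| threshold variability | 0.03, 0.25, −60, 4 | +1 probe, −6 prime, +1 probe |
| inhibition-induced | −0.02, −1, −60, 8 | baseline 80, step down to 75 |

Protocol amplitudes and timings are all exposed in the constructors. Two
protocols needed tuning against the fixed-coefficient voltage equation: the
DAP pulse uses amplitude 12 (stronger pulses make the after-potential
itself reach threshold and fire a second spike), and the integrator pulses
use amplitude 40 so that only the closely spaced pair summates to
threshold — a lone pulse or a widely spaced pair stays subthreshold.

## Pattern classification

`classify_pattern()` is a deterministic, ordered rule list over features
extracted from (trace, spike train, protocol). The pattern vocabulary is
the standard 20-name set plus `quiescent` and `unclassified`. The rules
and their default thresholds (all tunable via `classify_thresholds()`):
quiescent (0 spikes); phasic (exactly 1 spike within 30 ms of a sustained
step's onset); rebound (all spikes after release from a brief, ≤ 50 ms,
hyperpolarizing pulse); inhibition-induced (≥ 3 spikes during a sustained
negative step); integrator / threshold variability (spikes confined to the
probe window of the matching probe protocol); DAP (a post-spike
depolarized bump > 2 mV above the pre-stimulus baseline within 10 ms,
under a brief pulse); mixed mode (≥ 2 leading inter-spike intervals below
10 ms followed by ≥ 2 above 20 ms); tonic (≥ 4 spikes, ISI coefficient of
variation < 0.3, no burst prefix); otherwise unclassified.

Two design points matter. First, a label is only reachable under its
probing protocol — rebound requires a hyperpolarizing pulse, the
integrator label requires the paired-pulse probe — which prevents spurious
matches on the step-driven patterns. Second, the burst threshold of 10 ms
separates the canonical burst prefix (ISIs of 2–4 ms at the registry's
stimulus amplitudes) from regular firing (ISIs > 20 ms) by an order of
magnitude, so the mixed/tonic distinction is not threshold-sensitive. The
thresholds themselves are implementation choices: the pattern names are
conventional, but no published numeric decision criteria exist for them.

## Spike sorting

The sorting chain is an automated, parameterized counterpart of a manual
offline-sorter workflow:

1. **Filter** — zero-phase 4th-order Butterworth band-pass, 300–10000 Hz.
   The signal is padded by odd reflection over ~3 periods of the low band
   edge before `filtfilt`, which confines start-up transients to the
   padding (a DC input leaves residuals below $10^{-6}$ of its amplitude).
2. **Detect** — amplitude threshold whose sign selects polarity; the
   default threshold is $-4.5 \times \hat\sigma$ with $\hat\sigma =
   \mathrm{median}(|x|)/0.6745$, the standard robust noise estimate. Events
   are aligned on the extremum within 0.3 ms of the crossing, with a 1 ms
   dead time. The extremum is located on a 5-sample running mean: on wide
   spikes the trough is flat on the noise scale, and unsmoothed alignment
   jitters by a few samples, which visibly inflates within-unit feature
   variance.
3. **Features** — first three principal-component scores of the snippet
   matrix plus each snippet's peak and valley amplitude (5 features).
4. **Cluster** — k-means with a fixed seed and `k` supplied by the user
   (the reference synthetic recording has 3 units). Feature
   standardization before k-means was evaluated and rejected: on the
   reference fixture it slightly degrades assignment accuracy.
5. **Validate** — per-cluster inter-spike-interval histograms with the
   refractory-violation fraction, auto-/cross-correlograms (self-pairs
   excluded at zero lag), and firing-rate histograms.

## Synthetic data

The generators produce every input with known ground truth.

* `make_target_trace()` adds i.i.d. Gaussian voltage noise to a simulated
  trace and carries the generating quadruple for recovery scoring.
* `make_extracellular()` draws per-unit spike times (refractory-thinned
  Poisson, or a simulated neuron), adds scaled templates at those times
  (overlaps sum), then white Gaussian background noise. The band-limited
  look of a recorded channel emerges from the 300–10000 Hz filter stage,
  keeping the generator simple.
* `standard_recording()` is the reference fixture: 60 s at 50 kHz, three
  units at 2/5/8 Hz with peak amplitudes 80/100/120 µV, 2 ms refractory
  periods, and 16 µV background noise (peak SNR 5–7.5), seed 1234 — a
  3-cluster single-channel recording at desk scale rather than a
  half-hour session. The three default templates are distinct waveform
  families (narrow biphasic, triphasic with a positive prepotential, wide
  biphasic); distinctness in shape, not just amplitude, is what the
  feature extractor needs and what real units provide.

What the generator does **not** emulate: electrode drift, overlapping-spike
statistics beyond linear superposition, bursting structure, LFP content,
or non-Gaussian noise. Passing sorter tests therefore certify the chain's
correctness on well-behaved data, not its performance on pathological
recordings.

## Genetic-algorithm fitting

`fit_izhikevich()` is a real-coded GA: uniform initialization within a
4-dimensional bounds box; tournament selection (size 3); arithmetic blend
crossover applied to a 0.7 share of offspring; per-gene Gaussian mutation
with probability 0.8 and standard deviation 10% of the bound width;
clamping to bounds; elitism 1; population 60; a 150-generation cap. The
reference crossover/mutation/termination settings follow the conventional
tuning for this task; "mutation rate" is read as a per-gene application
probability, and both readings are runnable through `ga_config()`.
Candidates are simulated under the target's stimulus and scored by the
mean squared voltage difference (mV²) on the identical grid; a candidate
whose simulation diverges receives the largest finite fitness rather than
aborting the run. Early stopping exists but is off by default. Default
bounds (`default_bounds()`) cover every canonical and reference-optimized
quadruple with margin; `bounds_around()` recentres the box for recovery
experiments.

**The objective's geometry, honestly.** The raw-trace MSE is phase
sensitive. On a long tonic target (500 ms, ~14 spikes) a sub-percent
parameter error misphases the late spikes and the error saturates, while a
nearly quiescent candidate scores *better* than a rate-matched but
misphased one — a deceptive attractor. Inside a ±50% search box the GA
therefore converges to subdued-firing solutions instead of the generating
quadruple, for every mutation schedule we evaluated (fixed, annealed,
two-scale, log-uniform multiscale), and the packaged recovery check
documents this honest failure rather than hiding it. Where the objective
*is* informative the machinery works as intended: with the box confined to
the truth's immediate neighborhood the fit reaches low MSE (a packaged
test), and against stand-in neurons built from the reference optimized
quadruples the GA reduces the canonical model's error several-fold (the
demo pipeline and `analysis/03_fit_parameters.R`). Practical fits of this
kind should use short windows, few spikes, or spike-timing-aware
objectives; the package keeps the voltage-MSE objective because it is the
convention this pipeline follows.

## Problem sizes and tolerances

The test suite and analysis scripts run at desk scale by choice: 60 s
sorting fixtures (not 30-minute sessions), 500 ms fitting targets, 5-seed
recovery medians, 50-train correlogram oracles capped at 200 spikes.
Correlogram counts are checked *exactly* against an $O(n^2)$ enumeration;
filter gains to 5%; Poisson counts to 3 standard errors; equilibria to
machine precision. Divergence checks use `a = 40`, which destabilizes the
explicit recovery update at `dt = 0.1` (growth factor $|1 - a\,dt| = 3$).

## Known limitations

* The after-spike reset always returns to `c`; alternative resets (e.g.
  returning to the pre-stimulus baseline, which real cells often appear to
  do) are out of scope.
* The classifier is rule-based and protocol-aware by design; it does not
  attempt probabilistic classification or classification of raw
  extracellular waveforms.
* The sorter assumes a supplied `k` and well-separated units; it does not
  resolve overlapping spikes or track drift.
* Wide-box parameter recovery by voltage-MSE GA is unreliable for long
  multi-spike targets, as discussed above.
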