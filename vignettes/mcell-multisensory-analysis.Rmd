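---
title: "Quantifying multisensory integration in Mauthner-cell recordings"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying multisensory integration in Mauthner-cell recordings}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mcellmsi)
```

## The analysis problem

The goldfish Mauthner (M-) cell is a paired reticulospinal command neuron: one
action potential triggers the C-start escape. It receives auditory input on
its lateral dendrite (a fast electrotonic EPSP riding on a slow depolarizing
envelope) and visual input — here emulated by direct electrical stimulation of
the optic tectum — on its ventral dendrite (per-pulse phasic EPSPs riding on a
slowly building tonic envelope). Both pathways also recruit feed-forward
inhibition (FFI) onto the perisomatic membrane through interneurons that open
chloride channels, producing a *shunt* rather than a hyperpolarization.

`mcellmsi` implements the quantification pipeline for such intracellular
recordings:

* **Windowed response amplitudes.** Every response is summarized as the mean
  (and peak) depolarization above a pre-stimulus baseline inside a 12-ms
  half-open window `[t0, t0 + 12)` anchored at sound onset (auditory trials)
  or at the last tectal pulse (tectal-only and multisensory trials).
* **Phasic/tonic decomposition** of train responses at the last pulse: tonic =
  membrane potential one sample before the last pulse minus baseline; phasic =
  window peak minus that pre-pulse potential. The two add up exactly to the
  window's peak-above-baseline.
* **Multisensory indices.** `MSI/Max = M / max(T, A)` (enhancement when > 1)
  and `MSI/Sum = M / (T + A)` (supra/sub-linearity), computed per cell on
  trial-averaged responses (5–10 subthreshold repetitions) and then aggregated.
* **Sequence integration.** For stimulus pairs 50 ms apart,
  `S1–S2 Int./Sum = Resp(1+2) / (Resp1 + Resp2)`, with `Resp1` measured in a
  12-ms window starting 50 ms after S1 onset *on S1-only trials* (measured,
  never model-extrapolated), `Resp2` at S2 onset on S2-only trials.
* **FFI time courses.** Shunting inhibition is probed by an antidromic test
  action potential at delays 2–80 ms after a conditioning stimulus;
  `%SI = 100 − 100·APtest/APcontrol`. Per-modality time courses yield peak
  %SI, time of peak, half-decay time and the trapezoidal 0–70 ms area under
  the curve.
* **Group statistics** are thin wrappers over base R tests (`wilcox.test`,
  `kruskal.test`, `lm`/`anova`, `t.test`) that pin zero/tie handling,
  exact-vs-approximate thresholds and undefined-case flagging. No
  multiple-testing correction is applied.

## The synthetic M-cell

Because archived raw recordings cannot ship with the package, a
single-compartment conductance-based simulator generates traces with the
statistical and biophysical structure the analysis assumes. The membrane
equation (leak conductance 1, all synaptic conductances relative to it) is

$$\tau_m \frac{dV}{dt} = -(V - V_\mathrm{rest}) - g_\mathrm{exc}(t)\,(V - E_\mathrm{exc}) - g_\mathrm{ffi}(t)\,(V - V_\mathrm{rest}),$$

integrated sample-by-sample with an exponential-Euler update at the
acquisition rate (25 kHz by default). The FFI reversal equals the resting
potential, so inhibition divides depolarization without ever hyperpolarizing —
the defining property of a somatic shunt. Under constant drive the equation
has the closed-form fixed point
$V = V_\mathrm{rest} + g\,(E_\mathrm{exc} - V_\mathrm{rest})/(1 + g)$, which
the tests use as an oracle, and it makes summation *sublinear* by
construction: the response to a sum of conductances never exceeds the sum of
responses. That sublinearity, growing with drive, is the mechanistic seed of
the inverse-effectiveness regression; in the weak-drive limit the ratio tends
to 1 (near-linear integration).

Synaptic drive is built from unit-peak kernels per stimulus event:

| component | shape | defaults (rise/decay, ms) | role |
|---|---|---|---|
| auditory fast | difference of exponentials | 0.3 / 1, gain 0.28 | electrotonic club-ending EPSP |
| auditory slow | difference of exponentials | 3 / 45, gain 0.044 | chemical slow EPSP envelope |
| tectal phasic | difference of exponentials | 0.4 / 2, gain 0.14 | per-pulse EPSP |
| tectal tonic | per-pulse saturating state | decay 80, inc 0.016, sat 0.13 | building envelope |
| FFI auditory | rise × two-exponential decay | 3 / (17, 400), w=0.76, latency 4 | slow-recovering shunt |
| FFI tectal | rise × single exponential | 3 / 7.2, latency 4 | fast-recovering shunt |

The tonic state increments at every tectal pulse as
`s ← s + inc·(1 − s/sat)` and decays exponentially between pulses, producing
an envelope that builds during a train, saturates, and relaxes back to rest a
few hundred milliseconds after train end.

All calibration constants live in one file,
`inst/extdata/default_params.yaml`. They were set once so that noise-free
default traces land in the response ranges the analysis is designed for: an
auditory pip peaking near 5 mV with ~1.5 mV lingering at 50 ms; tonic
amplitudes that grow with 60-Hz train duration while the phasic component
stays flat within ~10%; comparable auditory/tectal FFI peaks (~14 %SI) at
~8–11 ms, with tectal %SI decaying to half of peak in ~8 ms but auditory in
~30 ms on a slow plateau. One published description puts the late auditory
plateau near 50% of peak while the same source's ~4% %SI at 50 ms would imply
~29%; the defaults follow the 50%-of-peak description (noted in the config
comments). Mind that these are *design targets of the generator*, not
empirical claims: passing tests show that the pipeline recovers what the
generator put in, under the generator's assumptions.

What the generator deliberately does **not** emulate: dendritic cable
filtering (a single compartment has no electrotonic distance), presynaptic
inhibition (the dominant source of the strong auditory prepulse suppression in
vivo — the simulator's AA suppression is therefore milder than recorded data
show, and only the AA-below-TT ordering is asserted), active spike currents
(the "fired" flag is a threshold crossing at rest + 25 mV, not an AP
waveform), and electrode/stimulus artifacts (artifact blanking in the
quantifier is available but off for synthetic data).

Noise model: per-trial lognormal gain jitter (sd 0.1 on the log scale,
independently for excitation and FFI) plus white Gaussian voltage noise
(sd 0.2 mV). One root seed governs a run; children are derived by a fixed
folding rule `child_seed(root, stage, cell, condition, trial)` so any trial or
stage can be re-simulated in isolation and reordering cannot change results.
The optional dendritic "boost" conductance (proportional to depolarization
above 5 mV) is off by default; it exists to probe how a voltage-dependent
nonlinearity would bend weak-stimulus integration toward supralinearity, and
it voids the sublinearity guarantee when enabled.

## Numerical and design choices

* **Windows** are half-open `[start, start + len)` and anchored at the event
  time itself; at 25 kHz "immediately before the last pulse" is one sample
  (0.04 ms) before the pulse time. In the multisensory condition the pip
  onset coincides with the last train pulse, so the T and M windows coincide.
* **Baseline** is the mean over `[-50, 0)` ms; traces must carry at least
  that much pre-stimulus data. All quantities are invariant to adding a
  constant to the trace.
* **Half-decay time** of an FFI time course is the first post-peak crossing
  of 50% of peak, linearly interpolated between sampled delays; ties for the
  peak resolve to the earliest delay. Both the absolute delay of the crossing
  and the time elapsed since the peak are reported, since published values of
  this kind are quoted in the elapsed convention. A curve that never falls
  below half-peak within the sampled range is *undefined-flagged*, not an
  error.
* **AUC 0–70 ms** uses the trapezoid rule; if delay 0 is unsampled the curve
  is extended with %SI = 0 there (inhibition cannot precede the stimulus) and
  the value at 70 ms is interpolated from the bracketing samples. On the
  2–80 ms probe grid the trapezoid carries a small positive bias for convex
  decaying curves (~4% for the fast tectal kernel against the analytic
  ground truth); the recovery tests therefore check the deterministic
  estimator and the mean over noisy replicates rather than every single noisy
  sweep, whose half-crossing estimate for the slowly decaying auditory kernel
  has a sampling sd of a few ms.
* **Averaging before statistics**: per condition, trials with a suprathreshold
  crossing are excluded (they are counted separately for firing incidence),
  the remaining 5–10 subthreshold trials are averaged pointwise, and indices
  are computed on the averages. Undefined indices (non-positive
  denominators) raise errors at the record level and are excluded — never
  imputed — by callers.
* **Inclusion rule**: trials with resting potential outside the closed
  interval \[-90, -70\] mV load with an `included = FALSE` flag.
* **Stimulus protocols**: a tectal train of frequency `f` and duration `d`
  places pulses at `0, 1000/f, …` up to and including `d` (closed endpoint;
  `d` of 0 or 1 ms gives a single pulse), so the event count is
  `floor(d·f/1000) + 1`. The default condition menu offers 60-Hz trains of
  {1, 33, 66, 100, 200} ms and 100-ms trains of {30, 60, 100, 200} Hz; other
  menus (e.g. a {1, 33, 100, 200} Hz frequency series) are constructible, as
  the menu is a configuration value, not a constant.
* **File formats**: trial bundles are plain CSV (RFC-4180, "." decimal,
  UTF-8) plus protocol JSON and a manifest with md5 content hashes, verified
  on read. The ABF importer covers episodic ABF version-1 files (int16 or
  float32 data, per-channel scale/gain/offset and unit strings, including
  prefixed units like "0.1 mV"); ABF2 is out of scope. Sweep-to-protocol
  mapping is caller-supplied because deposit layouts are not standardized,
  and skipped sweeps are counted, never silently dropped.

## Problem sizes

The packaged study-scale runs use populations matching the recorded data sets
they emulate: 17 cells for the condition-menu MSI experiment, 19 fish for the
FFI probe sweeps (12 delays × 10 repeats per modality), 29 cells for the
50-ms sequence experiment, and 10 cells × 20 stimulus-strength levels for the
inverse-effectiveness sweep. The test suite exercises the same code paths on
2–10 cells with 2–5 trials each; these sizes are the package's choices for
desk-scale reproducibility and are stated here so that reruns are comparable.

## A worked example

```{r example, eval = FALSE}
library(mcellmsi)

params <- sim_params()           # calibrated defaults
train <- build_tectal_train(60, 100)        # 7 pulses, 0..100 ms
msi_trial <- simulate_trial(build_multisensory(train), params, seed = 1)

b <- compute_baseline(msi_trial$trace)
window_response(msi_trial$trace, 100, 12, b)  # 12-ms window at the last pulse

cfg <- run_config(seed = 1, n_cells = 10, trials_per_condition = 5)
msi <- run_msi_experiment(cfg)
msi$group                          # per-condition MSI/Max, MSI/Sum, Wilcoxon p

ffi <- run_ffi_experiment(cfg)
ffi$metrics                        # per-fish peak %SI, t_half, AUC by modality
```

## Known limitations

* The simulator is a minimal stand-in: quantitative agreement with recorded
  group values is expected only for the features it was calibrated on;
  everything else (e.g. the depth of auditory prepulse suppression) is
  qualitative.
* `MSI/Sum` of the weakest stimuli stays slightly below 1 with the boost
  disabled, because a passive single compartment cannot integrate
  supralinearly; recorded data can exceed 1 there.
* The inverse-effectiveness fits are ordinary least squares on pooled
  cell × level records; mixed-effects refinements are out of scope.
* ABF import reads version-1 files only and maps one voltage channel per
  call.
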