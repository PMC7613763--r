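---
title: "cardiopore: models, conventions and limitations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{cardiopore: models, conventions and limitations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cardiopore)
```

This vignette is the package's own account of its science: the models it
assumes, the parameters that matter (with units and defaults), the numerical
conventions, and what a green test does — and does not — establish. Nothing
here states an empirical result that the test suite or the acceptance script
does not itself compute.

## 1. The action-potential template

The simulator's membrane voltage for one beat is a product of an upstroke
factor and a repolarization factor,

$$V(t) = A \cdot r(t) \cdot f(t), \qquad
  f(t) = \frac{1}{1 + e^{(t - m)/w}}, \quad m = \mathrm{APD}_{90} - w\ln 9 ,$$

with the upstroke $r$ a cubic smoothstep $s(u) = 3u^2 - 2u^3$ rescaled so
that $r = 0.1$ at $t = 0$ and $r = 1$ at $t = t_\mathrm{dep}$. Time zero is
therefore the **AP onset in the 10%-of-peak sense**, the peak is reached
exactly $t_\mathrm{dep}$ after onset, and because $f$ crosses $0.1$ at
$t = \mathrm{APD}_{90}$ while $r \approx 1$ there, APD90 is an exact,
testable property of the waveform rather than an approximate one.

Two design choices deserve justification:

* **Smoothstep, not a logistic, for the upstroke.** A logistic rise
  multiplied by a slowly falling sigmoid has no well-defined peak: the
  product keeps creeping upward for tens of milliseconds after the rise
  saturates, so "onset-to-peak" ceases to be the rise-time parameter and
  APD90 extraction inherits an onset bias of $\approx 0.28\,t_\mathrm{dep}$.
  The smoothstep reaches its ceiling at finite time, which pins the peak at
  $t_\mathrm{dep}$ and makes the feature-recovery loop exact (APD90 error
  < 0.3 ms over the tested grid).
* **Onset anchoring at the 10% crossing.** APD90 and depolarization time
  share one onset definition (the last upward crossing of 10% of peak before
  the peak, linearly interpolated). Anchoring the template at that same
  crossing means generator parameters and extracted features live on the
  same clock, so recovery tolerances test the pipeline, not a convention
  mismatch.

Defaults: $A = 100$ mV, $t_\mathrm{dep} = 10$ ms, APD90 $= 300$ ms,
$w = 20$ ms — typical for spontaneously beating human iPSC-derived
cardiomyocyte cultures. Beats are scheduled at 30 bpm with a 5% coefficient
of variation (Gaussian inter-beat intervals, rejection-sampled above a 0.5 s
floor so beats never overlap); cultures beat synchronously, so one schedule
drives all electrodes. Drug effects multiply each cell's APD90 and
$t_\mathrm{dep}$ by preset factors with per-cell lognormal dispersion
(`cell_sd`, default 0.05): multiplicative because the reported compound
effects are percent changes of strictly positive durations. The presets
carry the reference mean effects (APD90 ×0.631 and $t_\mathrm{dep}$ ×1.155
for the L-type calcium blocker nifedipine; ×1.327 and ×1.464 for the sodium/
hERG blocker quinidine; identity for the DMSO vehicle).

## 2. The electrode interface

The recorded trace (µV) is a linear mix

$$y(t) = 10^3\, g(t)\, k_\mathrm{ic}\, V(t) \; + \; k_\mathrm{ec}\,
  \frac{dV}{dt} \; + \; \mathrm{offset}(t) \; + \; \eta(t),$$

clipped at $\pm V_\mathrm{sat}$. With pore coupling $g = 0$ only the
derivative term remains — the extracellular field potential; after a
successful electroporation $g$ jumps to $g_0$ and decays as
$g_0 e^{-(t - t_\mathrm{end})/\tau}$ (resealing), superposing across
repeated porations and clipped at 1. No nonlinear membrane or ionic model
is attempted: mixed waveforms during resealing emerge naturally from the
linear mix, which is all the downstream analysis assumes.

| parameter | default | units | rationale |
|---|---|---|---|
| `k_ec` | 25 | µV per mV/ms | FP peaks ≈ 300 µV for the default template |
| `k_ic` | 0.5 | – | max recordable amplitude ≈ 50 mV |
| `tau_reseal_s` | 900 | s | intracellular-like signals persisting tens of minutes, with ~75 min as a distribution tail |
| `v_sat_uv` | ±50,000 | µV | amplifier saturation |
| `noise_sd_uv` | 10 | µV | white noise floor |
| `offset_mv`, `offset_tau_s` | 10, 2 | mV, s | post-stimulation amplifier offset and settling |

**Electroporation success** is logistic in the log of a delivered-charge
proxy: $V_\mathrm{eff} = V_\mathrm{pp} / (1 + c_\mathrm{load}(n_\mathrm{unit}
- 1))$ derates the pulse amplitude for every extra electrode sharing a
stimulation unit (slew-rate loss from capacitive loading), $Q =
V_\mathrm{eff}\, t_\mathrm{phase}\, N_\mathrm{pulses} / A_\mathrm{el}$, and

$$p = \mathrm{logistic}\!\left(a_0 + a_1 \ln(1 + Q/Q_\mathrm{ref}) +
  a_2\,\mathrm{seal}\right),$$

with $Q_\mathrm{ref}$ the charge of the optimized reference protocol (1 Vpp,
200 µs phase, 25,000 pulses, 12.6 µm² electrode). `log1p` rather than a bare
logarithm so that a zero-pulse train degrades gracefully to the seal-only
lower bound (< 5% at the defaults) instead of $-\infty$. Defaults $a_0 = -6$,
$a_1 = 8.8$, $a_2 = 3$, $c_\mathrm{load} = 0.05$ put the reference protocol
near 80% success for typical seals — the regime reported for optimized
protocols on a few hundred electrodes — while preserving every qualitative
ordering the tests assert: success increases with pulse amplitude, phase
duration and pulse count, and decreases with electrode area and unit
loading. On success the initial coupling is $g_0 = g_\mathrm{max}
(Q/Q_\mathrm{ref})^{\gamma}$ ($g_\mathrm{max} = 0.3$, $\gamma = 0.5$) with
30% lognormal jitter, so milder effective pulses also give smaller
amplitudes. These constants are stated-world choices, not fits.

**Routing.** 32 on-chip stimulation units. A *random* electrode selection is
shuffled and assigned round-robin — balanced loads. A *high-amplitude*
selection is spatially clustered, and the switch matrix can only route
nearby electrodes to a few local units (`units_local = 8`): sorted by
position and chunked, the load concentrates, $V_\mathrm{eff}$ drops, and
yield falls — which is why balanced random selections porate at least as
well as clustered ones at equal electrode count.

## 3. Waveform pipeline conventions

* **Detection**: running-median detrend (1 s window; computed on a decimated
  copy, ~100 points per window, and interpolated back — the trend is sub-Hz,
  the speedup ~10×), robust noise $\hat\sigma = 1.4826 \cdot
  \mathrm{MAD}$, threshold $\max(6\hat\sigma, 50\,\mu V)$, candidates merged
  within a 100 ms refractory window.
* **Peak-plateau timing convention**: the peak of an event (and of a
  waveform in feature extraction) is the *first* sample reaching 98% of the
  maximum. For sharp FP spikes this coincides with the argmax; on the
  near-flat early plateau of an AP — where the repolarization sigmoid falls
  by less than the noise floor over ~150 ms — an argmax would wander by tens
  of milliseconds of pure noise. The convention is exactly linear under time
  scaling, so drug-induced *ratios* of depolarization time are recovered
  unbiased even though the absolute value reads ~10% short of the generator
  parameter (e.g. a 0→1 ramp over 50 ms followed by a plateau reads 44 ms,
  not 45). Amplitudes always use the true maximum.
* **Offset correction**: each snippet subtracts the median of a 25 ms
  baseline window that *precedes* the snippet window (so the upstroke foot
  never contaminates it). Offset drift is measured across consecutive
  beats' baseline medians (µV/s); a single 25 ms window is too short for a
  noise-robust slope. The first beat of a channel gets infinite drift —
  conservative, it can never be selected.
* **Classification**: intracellular-like iff peak amplitude **strictly**
  exceeds 500 µV *and* full width at half maximum **strictly** exceeds
  25 ms (the width level is configurable since only "peak width" is
  specified by the published rule). Snippets whose window contains a
  poration instant record the stimulation transient, not a beat, and are
  labelled `mixed_reject` and excluded.
* **Selection**: the first three *consecutive* intracellular-like beats at
  least 9 s after poration end with drift below 200 µV/s, aligned at the
  peak sample (nearest-sample alignment: 50 µs at 20 kHz is negligible
  against the 25 ms width scale) and averaged pointwise. Channels with
  fewer than three qualifying beats are excluded with a reason, never an
  error.

## 4. Statistics

Pulse trains are biphasic: duration $= N (2\,t_\mathrm{phase} +
\mathrm{IPI})$, which reproduces the 35 s reference train exactly (25,000 ×
(2×200 µs + 1 ms)). The AC-frequency of such a train is convention-dependent
(one full cycle vs one phase pair) and is deliberately not reported as a
single number. Electrode areas are geometric; the 5.5 × 9.3 µm rectangle is
51.15 µm² geometrically even though datasheets print 50.7 µm² (rounded
corners, presumably) — the printed figure belongs in metadata.

The Mann–Whitney U test uses midranks; for $\min(n, m) \le 8$ without ties
the two-sided p is exact, $p = \min(1, 2\min(P(U \le u), P(U \ge u)))$, from
the exact null counts (dynamic program over the rank-partition recurrence);
otherwise a normal approximation with tie correction and continuity
correction. The exact path is verified in the tests against brute-force
enumeration over all $\binom{n+m}{n}$ group assignments. Drug reports
compute per-electrode percent changes against the *last* baseline (ctrl3),
test postdose vs ctrl3 distributions across electrodes (the published N are
electrode counts, so electrodes — not beats — are the experimental units),
and report ctrl1 vs ctrl3 as a stability check. No multiple-testing
correction is applied, matching the assay convention.

## 5. What the synthetic world does and does not establish

The generator emulates: synchronized spontaneous beating, FP spikes of a
few hundred µV, post-poration intracellular-like waveforms of ~1–45 mV
decaying with resealing, saturating amplifier offsets after stimulation,
load-dependent electroporation yield, and multiplicative drug modulation
with per-cell dispersion. It does **not** emulate ionic-current dynamics
(no notch/dome morphology, no rate-dependent APD adaptation), arrhythmic
events (EADs/DADs), conduction across the array, electrode impedance
spectra, or amplitude drift of the FP between repeats. A green drug-recovery
test therefore establishes that the *pipeline* recovers known multiplicative
effects through realistic measurement artifacts — not that the simulator
reproduces any particular compound's electrophysiology.

Two statistical caveats are inherent and accepted rather than tuned away:
the vehicle arm's Mann–Whitney p is a draw from an approximately uniform
null (a "p > 0.05" check has an irreducible ~5% false-alarm rate at any
fixed seed), and the protocol-ordering properties are stochastic orderings
of means over 20 replicate simulations, not per-replicate guarantees.

## 6. Scale-downs and budgets

Heavy simulation tests run at 1 kHz sampling (the template's stated floor;
linear interpolation at the 10% crossings keeps APD90 errors far below the
±2 ms tolerance) and 20–30 s recordings; the repeat-stability study uses 60
electrodes per repeat. Electrode counts for the yield orderings (200 vs 500)
and the replicate count (20) are kept at their stated values. The full test
suite runs in about 8 minutes on one CPU.

## 7. Known limitations

* The resealing time-constant distribution is a stated assumption (single
  exponential, τ = 900 s); only anecdotal long recordings constrain it.
* Poration success is independent across repeats; sensitization or fatigue
  across repeated porations is not modelled.
* The success model's constants are calibrated to orderings and one
  operating point, not fitted to dose-response data; absolute yields should
  not be over-interpreted.
* FP amplitude is modelled as stationary per electrode; drug effects on FP
  amplitude are out of scope.
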