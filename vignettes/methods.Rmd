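---
title: "From vesicles to behavior: models and estimators in retinfo"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From vesicles to behavior: models and estimators in retinfo}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(retinfo)
```

`retinfo` quantifies the chain from vesicular glutamate release at retinal
bipolar-cell synapses to the optomotor response (OMR) of larval zebrafish.
This vignette explains the models the package implements, the estimator
design choices that were genuinely open, what the synthetic-data generator
does and does not emulate, and the numerical conventions used throughout.

## The synthetic release model

A synapse regime describes one experimental condition by nine parameters.
Spontaneous release is a homogeneous Poisson process in *event* time whose
vesicle rate is `spont_rate` (vesicles s⁻¹); stimulus-locked release adds,
in every cycle of a 5 Hz stimulus, a Poisson number of events whose
expected total quanta equal a Hill function of contrast,

  m(C) = `evoked_max` · C^h / (C^h + C₅₀^h).

Each event carries an integer number of vesicles (multivesicular release)
drawn from a configurable weight vector; the default is a geometric law
truncated to 1–5 quanta with p = 0.55 (mean ≈ 1.7 vesicles per event). The
literature establishes that multivesicular events occur and that their
amplitudes are integer multiples of a quantum, but not their size law, so
the truncated geometric is a stand-in chosen for realism (mostly
uniquantal, a thin tail of large events) and is exposed as a parameter.
Stimulus-locked events sit at a single preferred phase per cycle, jittered
with SD 10 ms; the phase distribution of real release is not specified
beyond being phase-locked, and a single jittered phase is the simplest
model consistent with that.

Two consequences of this model matter for interpretation. First, total
quanta per cycle are compound-Poisson, so the generator's Fano factor is
E[K²]/E[K] ≈ 2.3 with the default weights — synthetic synapses are noisier
than a Poisson counter. Second, events jittered into near-coincidence
within a cycle are genuinely inseparable in the rendered fluorescence;
the decomposition handles them as merged integer-amplitude events (see
below).

The renderer places each event's transient — amplitude
`quanta × quantal_dff`, convolved with the reporter kernel
h(t) = A·e^(−t/τ_f)(1 − e^(−t/τ_r)), τ_r = 1 ms, τ_f = 60 ms, peak-
normalised — on the resting fluorescence of its spatial Gaussian
component, applies mono-exponential bleaching (default τ = 300 s; the
source recordings are described only as bleach-corrected, so a single
slow exponential is assumed) and adds Gaussian recording noise. The
default `quantal_dff` = 0.5 and `noise_sd` = 0.1 give a quantal
signal-to-noise ratio of 5. The generator does **not** emulate detector
shot noise statistics, scan-line jitter, motion, or out-of-focus
contamination; passing recovery tests on these renders shows the
estimator chain is correct under its stated assumptions, not that it is
robust to every artifact of real two-photon data.

## Quantal decomposition

The six steps mirror standard practice for iGluSnFR linescans:

1. *Spatial components.* The time-averaged profile is fitted with a sum
   of Gaussians on a constant offset by Levenberg–Marquardt least
   squares; the number of components grows while BIC improves by more
   than 10, capped at four. The strict margin exists because a noise
   Gaussian admitted here produces a baseline-free trace downstream.
   Flat profiles (peak < 3 spatial-noise SDs) yield no components.
2. *Trace extraction.* Each time point is fitted with a weighted sum of
   the fixed Gaussians plus a constant; the weight series is the trace.
   Components closer than half their width are merged (their weights are
   not separable) with a warning.
3. *ΔF/F₀.* Bleaching is fitted to per-segment 5 % quantiles of the
   trace — the lower envelope — because release transients occupy most
   of a stimulated recording and any fit to the raw trace chases
   stimulus structure. The exponential is accepted only when it explains
   at least 60 % of the envelope variance and implies a plausible decay;
   otherwise the trace is left untouched (a few percent of residual
   trend costs far less than a spurious correction, which can distort
   the trace several-fold). Bleach correction precedes baseline
   estimation. F₀ is the mode of the trace from a Freedman–Diaconis
   histogram with parabolic refinement of the peak bin.
4. *Wiener deconvolution.* The frequency-domain Wiener inverse of the
   kernel turns transients into approximate impulses. The noise power is
   estimated from the trace spectrum above 100 Hz and the prior signal
   power from the kernel spectrum scaled to the remaining trace power;
   an `snr` override is exposed (infinite SNR gives the pure inverse
   filter). The output is calibrated on the filter's own response to a
   unit kernel-shaped transient, so a unit event yields a unit-height
   impulse at the transient onset.
5. *Event detection.* The baseline SD is the median absolute deviation
   of the deconvolved trace (robust to the sparse impulses); events are
   supra-threshold runs at `k_sd` = 3.5 SDs (the usual working range is
   3–4), merged when closer than 5 ms. Each event reports its peak and a
   calibrated-area amplitude: the integral over the event extent divided
   by the matching integral of the unit response. Deconvolution is
   linear, so the area of a merged run equals the sum of its constituent
   event amplitudes regardless of partial overlap — the peak of a
   half-resolved pair does not. Detections whose area falls below half
   their peak are rejected as single-sample noise spikes (a real
   transient has area ≈ peak under the same calibration).
6. *Quantal clustering.* Event amplitudes are fitted by maximum
   likelihood with a mixture whose component means are k·q, k = 1..5,
   with a shared relative width (SD = CV·k·q, CV bounded to 2–40 %), ten
   restarts. A population of pure k-quantum events is equally well
   described by q/m with quanta m·k; among likelihood ties the largest
   unitary size wins. Amplitudes beyond the mixture range (chains of
   merged stimulus-locked events) are assigned as extrapolated integer
   multiples of q rather than clipped — clipping would bias release
   rates down by ~10 % at afternoon stimulation levels. Below 50 events
   the mixture is not reliably identifiable and the unitary size falls
   back to the amplitude density mode (sparse spontaneous activity is
   dominated by single-quantum events).

On noise-free renders the pipeline returns ground-truth quanta exactly;
at quantal SNR 5 event recall exceeds 0.9 and total quanta are recovered
within a few percent.

## Information metrics

Quanta are counted in 20 ms bins, each labeled with its trial's
contrast; at physiological rates a bin almost never holds two events,
and when it does the quanta are summed with a warning. p(Q|S) is
estimated by counting bins of amplitude 0, 1, 2, … per stimulus
(alphabet capped at 5, larger counts clipped with a warning), the joint
follows by the chain rule with a uniform stimulus prior, and
I(S;Q) = H(S) − H(S|Q) in bits with 0·log 0 ≡ 0. The information rate is
I divided by the bin width (bits s⁻¹) — the alternative reading, bits
per presentation, is rejected because rates are paired against vesicles
s⁻¹ throughout — and efficiency is the rate divided by the vesicle
release rate.

The plug-in estimator is used as-is by default. Its positive
small-sample bias is estimated, behind a flag, by permuting the
trial-to-contrast assignment and averaging the residual information;
at the narrow contrast windows used for gain measurements this bias is a
substantial fraction of the raw estimate, so the cohort-level analyses
in this package enable the correction. The Fano factor of vesicles per
stimulus cycle uses the sample (n − 1) variance.

## Swim kinematics

Speed is differentiated from position after a ~33 ms running mean
(tracking noise is white frame to frame; bouts last ~200 ms). The
detection threshold is the speed-density mode plus 3 per-axis noise SDs —
the per-axis velocity components are Gaussian while speed itself is
Rayleigh-like, so the SD comes from the robust MAD of the axis
velocities. Bouts are supra-threshold excursions merged within 100 ms;
the turn angle is the heading change across the bout (±50 ms margin),
signed toward the grating drift; |angle| < 0.1 rad classifies a scoot,
and the sign separates correct turns from errors. Trial summaries use
the sum of signed bout angles as the cumulative angle, which makes
turning speed = bout frequency × mean signed angle an exact identity.

The behavior generator emits bouts from two superposed Poisson
processes: spontaneous bouts at the regime's base rate with unbiased
turn direction, and stimulus-evoked bouts at (max − base)·Hill(C) signed
toward the drift with probability `p_correct`. This split reconciles
contrast-dependent steering with the observation that turns are equally
probable leftward and rightward without a stimulus. Bouts cannot
overlap (dead time = bout duration + 100 ms); the generating rate is
inflated by 1/(1 − λ·dead) so the *realised* bout rate matches the
configured one — without this the strongest conditions would be
compressed nonlinearly. Turn-angle statistics (|angle| ~ N(0.45, 0.15)
rad, scoot fraction 0.4, p_correct 0.85) are shared across all
conditions: modulation acts on bout frequency, not amplitude.
Between-fish variability is not separately modeled (fish differ only by
sampling); the defaults were chosen so 30-fish cohorts resolve the
1.7-fold diurnal effect.

## Cross-level models

Contrast-response functions are fitted with
R = R_max·S^h/(S^h + S₁/₂^h) by bounded Levenberg–Marquardt
(h ∈ (0.1, 10], C₅₀ ∈ (1, 200] %), initialised at the half-max crossing
and weighted by 1/SEM² when SEMs are available. The maximum contrast
gain is the unweighted OLS slope over 11 contrasts spanning a 20 %
window; behavior uses 15–35 %, synapses place the window at ±10 % around
a coarsely estimated C₅₀ (11 steps over 0–100 %), clamped into 0–100
with its width preserved. Efficiency-rate laws are fitted as OLS of
log E on log R. Pooled points sort synapses by rate into blocks of 4–8
(trailing fragments merge into the last block), and the
afternoon/morning efficiency ratio curve is the ratio of the two fitted
laws, not of raw points. Condition-level correlations report Pearson r
on values and Spearman ρ on ranks (exact small-n permutation p-values
via `cor.test`), with behavioral gains normalised to the morning
control.

## The default cohort

The two diurnal controls carry the printed physiology: morning synapses
release 2.7 vesicles per cycle at 100 % contrast (C₅₀ 45 %, h 1.6) with
3.6 vesicles s⁻¹ of spontaneous noise; afternoon synapses 4.3 per cycle
(C₅₀ 35 %, h 1.5) with 0.8 s⁻¹. `evoked_max` is the Hill scale, so it is
set to the printed response divided by Hill(100). The four drug
conditions move along the morning↔afternoon modulation axis — dopamine
and substance P act in push–pull, so potentiation lowers spontaneous
noise and raises gain while suppression does the reverse — with their
evoked gains calibrated once, by Monte Carlo on ground-truth trains
(`calibrate_evoked_gain`), so the six mean bias-corrected information
rates sit on a line against relative behavioral gain with endpoints
spanning exactly 4-fold in information and 2.4-fold in gain. The
calibration targets sit on the line through the two measured controls
(morning ≈ 0.021 bits s⁻¹ at relative gain 1, afternoon ≈ 0.051 at
1.7); the afternoon control's own point lies slightly off the final
line, which is the realistic scatter any measured cohort shows. The
information rate is not monotone in evoked gain — at extreme rates the
20 ms bins saturate the quanta alphabet — so the calibration searches
the rising branch of a gain grid rather than bisecting.

Absolute information rates of the synthetic cohort are lower than real
synapses achieve, because the compound-Poisson generator is noisier
(Fano ≈ 2.3) than biological ribbon synapses over the same narrow
contrast windows; the cohort is designed to reproduce the *relative*
structure — spans, collinearity, efficiency exponents — not absolute
bits.

## Problem sizes and numerical conventions

The bundled analyses and tests use desk-scale cohorts chosen to keep
estimator noise well inside the effects being measured: 10–20 synapses
per condition with 50–100 presentations per contrast, and 24–30 fish
with 30–50 presentations per contrast. Seeds flow from a single master
seed through fixed per-stage offsets, and identical configurations
reproduce byte-identical outputs. Degenerate inputs are handled
explicitly: zero-duration protocols, silent synapses, flat spatial
profiles, traces without a positive baseline, zero release rates and
empty bout lists all either return well-defined empty results or raise
informative errors, as documented on each function.
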