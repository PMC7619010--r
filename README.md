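# retinfo

Tools for quantifying how the information that retinal bipolar-cell
synapses transmit about stimulus contrast relates to a visually guided
behavior — the optomotor response (OMR) of larval zebrafish — across
diurnal and pharmacological states of the retina.

Bipolar cells are the bottleneck between photoreceptors and the inner
retina. Their output can be counted vesicle by vesicle with the
fluorescent glutamate reporter iGluSnFR, and the OMR of free-swimming
larvae can be factorised into discrete swim bouts. `retinfo` implements
the full quantitative chain between those two levels:

1. **Quantal decomposition** of linescan recordings: the spatial profile
   is unmixed into Gaussian point sources (active zones); each source's
   trace is converted to ΔF/F₀ (baseline = mode of the trace, after
   mono-exponential bleach correction); release events are recovered by
   Wiener deconvolution with the reporter kernel
   h(t) = A·e^(−t/τ_f)·(1 − e^(−t/τ_r)) (τ_r = 1 ms, τ_f = 60 ms),
   thresholded at 3.5 robust SDs, and partitioned into integer numbers of
   vesicles by a maximum-likelihood mixture whose component means are
   integer multiples of the unitary amplitude.
2. **Information metrics**: vesicle counts in 20 ms bins against the
   contrast ensemble give the joint p(S,Q); mutual information
   I(S;Q) = H(S) − H(S|Q) (plug-in, with an optional shuffle-subtraction
   bias correction), information rate (bits/s), efficiency (bits per
   vesicle) and the Fano factor of vesicles per stimulus cycle.
3. **Swim kinematics**: bouts detected from the speed trace (threshold
   from a Gaussian fit to the tracking-noise mode), signed turn angles,
   and the exact factorisation
   turning speed = bout frequency × mean angle per bout.
4. **Cross-level models**: Hill contrast-response fits
   R = R_max·S^h/(S^h + S₁/₂^h); maximum contrast gain (MCG, the OLS slope
   over 11 contrasts spanning a 20 % window around C₁/₂); efficiency-rate
   power laws E = a·R^b; pooled efficiency points; and the correlation of
   synaptic information rate with behavioral gain across conditions.
5. **A synthetic-data generator** that emulates the study's recordings
   with known ground truth: stimulus-locked multivesicular release (5 Hz
   cycles, Poisson spontaneous events, integer quantal amplitudes,
   reporter kernel, bleaching, noise) and optomotor swimming (contrast-
   dependent bout rates via a Hill function, scoots/turns/errors), under
   six condition regimes — morning and afternoon controls carrying the
   study's printed physiology (3.6 vs 0.8 vesicles s⁻¹ spontaneous;
   2.7 vs 4.3 vesicles per cycle at full contrast) plus four
   neuromodulator manipulations (NK1R antagonist, D1R agonist, substance
   P, D1R antagonist).

## Worked example

```r
library(retinfo)

# an afternoon-regime synapse, 100 cycles of full-contrast stimulation
reg  <- configure_cohort("pm_control")$pm_control$synapse
prot <- protocol_constant(100, 20)            # 20 s at 5 Hz
train <- simulate_release(reg, prot, seed = 1)
scan  <- render_linescan(train, regime = reg, seed = 2)
qs    <- quantal_decompose(scan)[[1]]

sum(train$quanta) / 100   # ground-truth quanta per cycle
#> [1] 4.37
sum(qs$quanta) / 100      # recovered by the full pipeline
#> [1] 4.4
attr(qs, "quantal_size")  # estimated unitary amplitude (dF/F0)
#> [1] 0.432
```

The regime was configured so a full-contrast cycle releases 4.3 vesicles
on average; a single 20-s recording fluctuates around that value, and the
pipeline's estimate tracks the realised ground truth within a few
percent.

The numbered scripts under `analysis/` run the study-style workflow end
to end (simulate → decompose → information metrics → kinematics →
cross-level models), writing tables under `results/`. At the bundled
demo sizes (10 synapses and 12 fish per condition) stage 5 prints the
six-condition linkage — an information-rate span near 4-fold against a
behavioral-gain span near 2.4-fold with a strong positive correlation
(Pearson r ≈ 0.93) — and recovers the morning and afternoon efficiency
power laws (exponents ≈ −0.74 and −1.11) from law-generated synapse
populations, pooled and unpooled. The acceptance script below runs the
same analyses at full scale.

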