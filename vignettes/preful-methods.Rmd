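---
title: "Phase-resolved functional lung MRI: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Phase-resolved functional lung MRI: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(prefulr)
```

## The measurement problem

Free-breathing spoiled gradient-echo lung MRI acquired at ~288 ms per frame
for about a minute per coronal section carries two physiological signals in
every parenchymal voxel: a slow modulation at the respiratory rate
(~0.2–0.4 Hz), because proton density falls as the lung inflates, and a
faster modulation at the cardiac rate (~1 Hz, still below the 1.74 Hz
Nyquist limit of 288 ms sampling), because pulsatile blood volume raises
the signal in systole. Phase-resolved functional lung (PREFUL) analysis
separates the two by temporal filtering, estimates a respiratory and a
cardiac phase for every frame, and re-sorts the frames of the registered
series into one high-temporal-resolution respiratory cycle (60 phases) and
one cardiac cycle (30 phases) per voxel. From these cycles it derives:

* **RVent**, regional fractional ventilation:
  $RVent = (S_{ex} - S_{in})/S_{ex}$ from the cycle extrema, plus the full
  RVent time series over the cycle;
* **FVL-CM**, the flow-volume-loop correlation map: each voxel's loop of
  RVent ("volume") against its symmetric-difference-quotient derivative
  ("flow") is correlated at zero lag with an individualized healthy
  reference loop;
* **Q**, quantitative perfusion:
  $Q = A_Q / S_b \cdot HR \cdot 100$ mL/min/100 mL from the cardiac cycle
  amplitude $A_Q$, the full-blood vessel signal $S_b$ and the heart rate;
* defect percentages (VDP, QDP) by fixed thresholds, and the
  ventilation-perfusion match **VQM**, the fraction of voxels whose two
  binary defect labels agree.

The treatment-effect layer estimates LS-means treatment differences from
two-period crossover tables with `value ~ treatment + period + patient`.

## Signal model of the synthetic phantom

Patient data of this kind are not publicly deposited, so the package ships
a generator whose defaults define the study conditions for all tests:

$$S(x,t) = S_0(x)\,\bigl[1 - FV(x)\, v(\phi_r(t) - lag(x))\bigr]\,
           \bigl[1 + A'(x)\, q(\phi_c(t))\bigr] + \varepsilon(t)$$

with $v$ a raised cosine rising 0→1 from end-expiration to
end-inspiration (optionally duty-asymmetric), $q$ a half-rectified sine
peaking at cardiac phase 0.25, and $A'(x) = A(x) S_b / S_0(x)$ so that the
cardiac peak-to-peak amplitude in signal units is exactly $A(x) S_b$ and
ground-truth perfusion is $Q = A \cdot HR \cdot 100$. Vessel voxels carry
$S_b(1 - 0.3\,(1 - q))$, i.e. a full-blood level modulated predominantly by
the cardiac waveform.

Key defaults and why:

| parameter | default | rationale |
|---|---|---|
| grid | 64×64×3 sections | desk-scale stand-in for the acquisition matrix |
| frame interval / duration | 288 ms / 60 s (208 frames) | matches the acquisition protocol |
| respiratory / cardiac rate | 0.30 Hz / 1.0 Hz | resting adult rates; cardiac below Nyquist |
| $S_0$, $S_b$ | 100, 200 a.u. | blood roughly twice parenchymal signal |
| FV | 0.08–0.14 (smooth gradient) | tidal fractional ventilation range; gradient keeps the RVent percentile band non-degenerate |
| $A$ | 1/60 ± 20% | gives Q ≈ 80–120 mL/min/100 mL at 60 bpm |
| noise | SNR 50 ($\sigma = S_0/50$) | plausible parenchymal SNR |
| defects | FV = 0.03; lag = 0.15 cycles; $A$ = 1/400 (Q = 15) | each ≥ 2 decision-widths from its cutoff |

The three defect types are deliberately orthogonal: a reduced-FV region is
a static-RVent defect but keeps a normal loop *shape* (FVL-CM ≈ 1, since
the correlation is scale-invariant); a phase-lag region keeps its static
RVent but shifts the loop, degrading FVL-CM by $\approx\cos(2\pi\,lag)$;
a reduced-amplitude region is a pure perfusion defect. This lets the tests
separate what each metric can and cannot see — the point of the dynamic
loop metric over the static one.

What the phantom does **not** emulate: breathing-motion deformation and
registration error (the pipeline consumes registered input by contract),
B0/B1 inhomogeneity and MR physics, partial-volume mixing at lung borders,
through-plane motion, and heart-rate/breathing-rate variability beyond what
phase estimation tolerates. Passing recovery tests therefore demonstrate
correctness of the *analysis*, not robustness to acquisition artifacts.

## Numerical and design choices

**Filters.** The cutoffs (0.6 Hz low-pass for ventilation, 0.8 Hz
high-pass for perfusion) are conventions of the method; the realization is
ours: a zero-phase frequency-domain filter applied to an even (mirror)
extension of each voxel time course, with a raised-cosine transition band
of half-width 0.15 Hz and gain 0.5 at the cutoff. A low-order IIR filter
run forward and backward cannot simultaneously pass 1 Hz within a few
percent and stop 0.4 Hz (and vice versa) with cutoffs this close; the
frequency-domain realization meets both band contracts exactly and is
exactly zero-phase, so phase sorting is not biased by group delay. The
even extension suppresses wrap-around transients; linearity is exact.

**Respiratory phase.** End-expiratory peaks are detected on the smoothed
parenchymal mean (lung signal is maximal at end-expiration, which anchors
phase 0), peak times and extrema are refined by quadratic interpolation,
and within each breath the phase is the normalized angular position of the
cosine model, $\phi = \arccos(2u-1)/2\pi$ on the descending half and its
mirror on the ascending half, with $u$ the signal normalized to the
breath's refined extrema. This tolerates variable breath lengths and gives
sub-frame resolution; on noiseless phantoms the circular RMS phase error
is < 0.02 cycles. Frames before the first (after the last) detected peak
are phased by extrapolation at the mean breathing rate.

**Cardiac phase.** At 288 ms a 1 Hz beat contains ~3.5 samples, so
independent per-beat fits are ill-posed. The heart rate is located as the
dominant periodogram peak above 0.5 Hz of the high-passed vessel-mean
signal and refined by maximizing the $R^2$ of a sinusoid regression; the
regression phase anchors the pulsatility maximum at phase 0.25; beats are
segmented at the fitted oscillation's cycle boundaries, and a bounded
(±0.1 cycle) per-beat offset re-fit is applied only where a segment has at
least 5 samples, accommodating rate drift when the sampling supports it.

**Sorting.** Frames are pooled to their nearest of $n$ equidistant phase
bins and averaged; empty bins are filled by circular linear interpolation.
Pooling (rather than two-point interpolation between phase neighbours)
uses all ~208 frames, which matters because cardiac amplitudes are only
1–2% of the signal. The nominal grid resolution is
$\lfloor 1000/(rate \cdot n)\rfloor$ ms — 55 ms for 60 phases at the
conventional 0.3 Hz reference, 33 ms for 30 phases at 1 Hz.

**Loops and FVL-CM.** Flow uses the circular symmetric difference
quotient over the nominal grid spacing, so flows are nominal (comparable
within and between maps, not absolute airflow). The reference region is
the per-section [P80, P90) band of static RVent (linearly interpolated
quantiles; values equal to P80 included, equal to P90 excluded; a
degenerate band is an error rather than a silent empty region). The loop
similarity is the zero-lag Pearson correlation of the concatenated
standardized volume and flow sequences (120 points), which equals the mean
of the volume-wise and flow-wise correlations and makes $r$ invariant to
affine rescaling of the voxel signal; `standardize = FALSE` exposes the
raw normalized inner product since the choice is not fixed by convention.
Zero-variance loops get $r = 0$, are flagged, and appear as NA so they can
never enter summaries or defect denominators.

**Perfusion.** $S_b$ is the 95th percentile of the vessel-region mean over
its sorted cardiac cycle — a robust proxy for a fully blood-filled voxel;
the amplitude is the raw peak-to-peak of the 30-phase cycle (a
first-harmonic option exists; for sinusoid-like waveforms the two agree).
The vessel reference is taken from the middle (tracheal-bifurcation)
section when it contains vessel voxels. Heart rates outside 30–180
beats/min are rejected.

**Defects and VQM.** Strict `<` at every threshold (a value equal to the
cutoff is normal), defaults FVL-CM 0.90, RVent 0.075, Q 20 mL/min/100 mL.
Defect and match percentages pool voxels across sections (each voxel
counted once) rather than averaging per-section percentages, reading
"relative area" as a pooled fraction.

**Crossover estimation.** Patient enters the estimating regression as a
fixed factor: for balanced complete two-period data the treatment-effect
point estimate coincides with the random-intercept formulation the design
calls for, while the within-patient error df ($n-2$) gives the correct t
inference — and the closed form (half the difference of the sequence
groups' period-1 minus period-2 means) provides an independent oracle that
the tests check to numerical tolerance. Baselines are kept for
descriptive change summaries but not used as covariates. p values are not
multiplicity-adjusted, matching the post hoc character of the correlation
analyses. Patients missing a period are excluded with a warning.

## What the tests and scripts compute

Problem sizes are chosen at desk scale: the full-grid phantom is
64×64×3 with 208 frames; module tests use 32×32×1 phantoms; the
Monte-Carlo study uses 200 simulated trials of 50 patients. On the
noiseless default phantom the pipeline recovers static RVent within
0.0011 of the generating FV, Q within 6.3% of truth, FVL-CM ≥ 0.991 in
lag-free parenchyma, and all three defect regions with Dice 1.0; the
crossover estimator's bias is below twice its Monte-Carlo SE with ~95% CI
coverage. These numbers are recomputed, not quoted, by
`scripts/acceptance.R` and the test suite.

## Known limitations

* At the default SNR of 50 the cardiac modulation (~1.7% of $S_0$) is
  comparable to the post-filter noise floor, so peak-to-peak amplitudes —
  an extreme-value statistic — are biased upward and Q is overestimated;
  the flow channel of the loops likewise amplifies noise and lowers
  FVL-CM. This mirrors the intrinsic noise sensitivity of
  signal-pulsatility perfusion mapping; the recovery contracts are
  therefore stated (and tested) on noiseless phantoms, and noisy-phantom
  behaviour is reported as-is.
* A single global sinusoid dominates cardiac phase estimation; strong
  heart-rate variability within an acquisition would degrade it, and only
  the bounded per-beat refinement addresses drift.
* The healthy-reference selection assumes high static RVent marks healthy
  lung; in severe disease that assumption, inherited from the method, may
  fail.
* Sections are assumed simultaneously acquired by the phantom, while real
  protocols acquire them sequentially; since all processing after phase
  estimation is per-section, this affects nothing downstream.
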