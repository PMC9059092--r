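# prefulr

Phase-resolved functional lung (PREFUL) MRI analysis in R: ventilation
dynamics, quantitative perfusion, and ventilation-perfusion match from
free-breathing, non-contrast dynamic proton MRI, plus the crossover
treatment-effect statistics used to evaluate such biomarkers in
two-period trials. It is written for imaging scientists who have a
registered 2D+time lung series (4D NIfTI), lung-parenchyma and
large-vessel masks, and want reproducible regional ventilation/perfusion
maps and defect metrics — and for methodologists who want a fully
synthetic, ground-truthed test bed for this class of pipeline.

## What it computes

Every parenchymal voxel of a free-breathing series oscillates with
breathing (signal falls as the lung inflates) and with the heartbeat
(signal rises with pulsatile blood volume). The pipeline:

1. splits the two components with zero-phase temporal filters
   (low-pass 0.6 Hz → ventilation branch; high-pass 0.8 Hz → perfusion
   branch);
2. assigns each frame a respiratory phase (cosine model of the
   parenchymal mean) and a cardiac phase (sinusoid fit to the
   large-vessel mean), then sorts frames into one 60-phase respiratory
   and one 30-phase cardiac cycle per voxel (nominal resolutions 55 ms
   and 33 ms);
3. derives regional ventilation `RVent = (S_ex − S_in)/S_ex`, flow-volume
   loops (RVent vs its symmetric-difference-quotient derivative), and the
   flow-volume-loop correlation map **FVL-CM** — each voxel's loop
   correlated at zero lag with an individualized healthy reference loop
   (per-section RVent 80–90th percentile region);
4. quantifies perfusion `Q = A_Q/S_b · HR · 100` (mL/min/100 mL) from the
   cardiac-cycle amplitude, the full-blood vessel signal and the heart
   rate;
5. thresholds the maps into defects (FVL-CM < 0.90, RVent < 0.075,
   Q < 20 mL/min/100 mL), yielding VDP/QDP and the ventilation-perfusion
   match **VQM** (fraction of voxels whose two defect labels agree);
6. estimates crossover treatment effects as LS-means differences from
   `value ~ treatment + period + patient`, with Pearson correlation for
   post hoc comparisons.

A synthetic-phantom module (`phantom_spec()`, `generate_series()`)
generates registered series with known FV, Q, phase-lag and defect ground
truth, and `generate_crossover_table()` simulates the 2×2 trial design —
these define the conditions under which everything here is tested.

## Worked example

```r
library(prefulr)

spec <- phantom_spec(seed = 1, noise_sd = 0)   # 64 x 64 x 3, 208 frames
res  <- run_pipeline(spec)
print(res)
#> <pipeline_result>
#>   mean FVL-CM 0.967 | mean RVent 0.106 | mean Q 96 mL/min/100 mL
#>   VDP(CM) 7.9% | VDP(RVent) 7.9% | QDP 8.1%
#>   VQM_CM 0.841 | VQM_RVent 0.841 | HR 60 bpm | resp 0.30 Hz
```

The phantom contains three planted defect regions, each ~8% of the
parenchyma: a low-FV region (caught by RVent, invisible to FVL-CM because
the loop correlation is scale-invariant), a respiratory phase-lag region
(caught by FVL-CM, invisible to static RVent — the reason the dynamic
metric exists), and a low-amplitude perfusion region (caught by Q). All
three are recovered with Dice 1.0 against the generating masks, RVent
matches the generating FV within 0.0011, and Q is within 6.3% of truth.

The crossover layer on a simulated 50-patient trial with a true effect of
0.05:

```r
tab <- generate_crossover_table(50, true_effect = 0.05, seed = 1)
estimate_crossover_effect(tab)
#> <crossover_estimate> effect 0.05916 (95% CI 0.03996, 0.07837), p = 1.27e-07, n = 50
```

The numbered drivers under `analysis/` run the same steps as a narrative
workflow (simulate → ventilation → perfusion → defects/VQM → statistics),
writing maps and tables under `results/`.

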