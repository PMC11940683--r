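# hrvbal

Heart-rate-variability (HRV) preprocessing, spectral feature extraction and
**bidimensional autonomic-balance analysis** for three-phase stress/recovery
protocols — the kind of recording collected when a subject sits through a
baseline, performs under pressure (a live interview, a talk, an exam), and
recovers. It is aimed at psychophysiology researchers who work from
chest-strap RR-interval exports and want a reproducible path from raw
intervals to phase-by-group statistics.

## What it computes

Starting from beat-to-beat (RR) intervals in milliseconds, the pipeline

1. **detects and corrects artifacts** (ectopic, missed, extra, misaligned
   beats) with adaptive thresholds — beat *i* is suspect when the successive
   difference dRR_i or the deviation from an 11-beat running median exceeds
   5.2 × the local quartile deviation (91-beat windows) — and corrects
   suspects so that total elapsed time is conserved exactly, warning when
   corrections reach the 5 % quality gate;
2. **regularizes** the series: cubic-spline resampling to a 4 Hz tachogram
   and smoothness-priors detrending, `trend = (I + λ² D₂ᵀD₂)⁻¹ x` with
   λ = 500 (a tunable high-pass filter that removes slow non-stationary
   trends and passes the 0.04–0.4 Hz HRV bands essentially untouched);
3. **extracts features** per centered 5-minute phase segment (3-minute
   fallback): mean RR/HR, HR range, SDNN, and Welch band powers
   (VLF 0.003–0.04, LF 0.04–0.15, HF 0.15–0.40 Hz, in ms²) with a
   Parseval-calibrated estimator (300 s Hann windows, 50 % overlap);
4. **maps autonomic balance to two dimensions**:

   ```
   LHFP  = LF + HF                 (combined oscillatory power, ms²)
   LHFND = (LF − HF) / (LF + HF)   (bounded balance index in [−1, 1])
   ```

   a normalized 45° rotation of the HF–LF plane. `LHFND` equals
   `(LFnu − HFnu)/100` and, unlike the LF/HF ratio, is symmetric and robust
   to extreme values. `classify_state()` turns positions relative to a
   baseline into the interpretive vocabulary of the plane (physical /
   emotional / mental stress, flow, rest, recovery–rebound);
5. **tests effects**: repeated-measures ANOVA of phase with between-subject
   factors and covariates (Pillai's trace for the multivariate tests,
   Greenhouse–Geisser–corrected univariate tests, covariate-adjusted
   Bonferroni pairwise contrasts, partial η²), varimax-rotated PCA of jury
   judgment panels, exact one-dimensional two-cluster K-means for high/low
   performance grouping, plus paired-t, chi-square and correlation
   utilities.

Because real recordings of this kind are rarely shareable, the package
includes a first-class **synthetic-data module**: an integral pulse frequency
modulation (IPFM) generator that emits beats from a modulator with known
LF/HF sinusoids (band power a²/2 for amplitude a), labelled artifact
injection, a two-latent-factor jury-rating simulator, and a cohort simulator
whose default phase targets are calibrated to published group values
(mean RR 680/586/708 ms; LF 643/449/1088 ms²; HF 295/232/373 ms² across
pre/interview/post).

## Worked example

```r
library(hrvbal)

sim <- simulate_cohort(cohort_config(), seed = 42)   # 24 subjects, 2 clusters
res <- run_pipeline(sim, pipeline_config(seed = 42))

res$trajectory
#>  group     phase  n     lf    hf   lhfp    lhfnd
#>   high       pre 12  571.9 242.9  814.8  0.40229
#>   high interview 12  614.7 216.7  831.4  0.47716
#>   high      post 12  566.2 303.3  869.4  0.29654
#>    low       pre 12 1038.7 329.3 1368.0  0.51860
#>    low interview 12  249.5 266.4  515.9 -0.03317
#>    low      post 12 1789.3 399.5 2188.8  0.63431
```

The low-performance cluster collapses in combined power during the stressor
(LHFP 1368 → 516 ms²) and rebounds past baseline afterwards (2189 ms²),
while the high cluster stays in a narrow "flow" band (815–869 ms²) — exactly
the trajectory contrast the simulator encodes. The statistics layer picks
this up as a Phase × Cluster interaction on LF:

```r
subset(res$anova$lf, test == "multivariate")
#>         effect      F df1 df2        p eta_p2
#>          phase 78.345   2  18 1.31e-09 0.8970
#>  phase:cluster 57.874   2  18 1.45e-08 0.8654
#>   phase:gender  0.106   2  18 9.00e-01 0.0116
#>      phase:age  0.200   2  18 8.21e-01 0.0217
#>  phase:log_pub  1.751   2  18 2.02e-01 0.1628

res$contrasts$lhfp   # covariate-adjusted pairwise phase differences
#>         contrast   md   se      t df        p    p_adj
#>  pre - interview  419 43.5   9.62 19 9.81e-09 2.94e-08
#>       pre - post -437 41.0 -10.64 19 1.91e-09 5.72e-09
#> interview - post -855 64.6 -13.24 19 4.85e-11 1.46e-10
```

The plane transform itself is one line:

```r
to_bidim(643, 295)
#> $lhfp  938      $lhfnd  0.3710
```

## Documentation

The methods vignette (`vignettes/autonomic-balance.Rmd`) explains the model
assumptions, every tunable parameter with its default and rationale, what
the synthetic generator does and does not emulate, and the package's
numerical choices and known limitations.
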