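---
title: "Methods: from RR intervals to bidimensional autonomic balance"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from RR intervals to bidimensional autonomic balance}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hrvbal)
```

## The analysis problem

`hrvbal` analyses beat-to-beat (RR) interval recordings collected over a
three-phase stress/recovery protocol: an anticipation baseline (*pre*), a
stressor (*interview*), and a recovery baseline (*post*). The scientific
questions it serves are (a) how spectral HRV indices move across phases,
(b) whether subject groups — e.g. communicators judged high vs low in
authoritativeness by a rating panel — differ in those trajectories, and
(c) how to read autonomic state off a two-dimensional summary of the LF and
HF band powers rather than a single ratio.

The pipeline assumes input at the RR-interval level (a chest-strap export,
one interval per beat), not raw ECG; R-peak detection is out of scope. It
also assumes the phase annotation is trusted metadata.

## The bidimensional balance coordinates

All spectral analysis reduces to the LF (0.04–0.15 Hz) and HF (0.15–0.40 Hz)
band powers of the tachogram, in ms². The package's central coordinates are

$$\mathrm{LHFP} = \mathrm{LF} + \mathrm{HF}, \qquad
  \mathrm{LHFND} = \frac{\mathrm{LF} - \mathrm{HF}}{\mathrm{LF} + \mathrm{HF}}.$$

Geometrically `(LHFP, LHFND)` is a normalized 45° rotation of the (HF, LF)
plane: LHFP is the radius-like combined oscillatory power, LHFND the bounded
(−1 to +1), symmetric balance coordinate. It equals the difference of
normalized units divided by 100, so the two common formulations of
"normalized balance" coincide. Compared with the LF/HF ratio, LHFND does not
explode when HF is small, and it is antisymmetric under swapping LF and HF.
The transform is an exact bijection on the positive quadrant
(`to_bidim()` / `from_bidim()`), which the tests verify to 1e−9.

When averaging over subjects (`phase_trajectory()`), the LHFND centroid is
the **mean of per-subject LHFND values**, not the LHFND of mean powers. The
two differ whenever power varies across subjects, and only the former is
consistent with treating LHFND as a per-subject index that gets its own
group statistics.

### Qualitative state labels

`classify_state()` maps a point's LF and HF, each rated high / neutral / low
against a baseline with a ±20 % dead zone (`dead_zone = 0.2`), onto the
plane's interpretive vocabulary: high-LF/low-HF → physical stress,
low-LF/low-HF → emotional stress, high-LF/high-HF → recovery–rebound,
both neutral → rest, neutral-LF with moderately suppressed HF (ratio in
[0.5, 0.8)) → flow. Published descriptions pin only those cells; the
remaining combinations are this package's decisions: a strongly suppressed
HF (< 0.5×) with neutral LF is labelled mental stress, a lone LF excursion
falls to the stress label of its LF side, and an HF at or above baseline
without elevated LF is rest. The rule uses power ratios only, so it is
scale-invariant; the dead zone is configurable because the regions have no
canonical boundaries. These labels are interpretive vocabulary, **not**
claims about measured sympathetic/parasympathetic drive.

## Preprocessing

### Artifact detection and correction

Beat *i* is *suspect* when |dRR_i| (successive difference) or |mRR_i|
(deviation from an 11-beat running median) exceeds 5.2 × the local quartile
deviation (QD = IQR/2) of the respective series, computed over 91-beat
windows truncated (not mirrored) at the edges. Suspects are classified:

* **missed** — RR_i ≈ 2 × local median (ratio 1.7–2.3): split into halves;
* **extra** — RR_i + RR_{i+1} ≈ local median (ratio 0.7–1.3): merged;
* **ectopic** — antisymmetric short/long alternation (neighbouring
  deviations of opposite sign that largely cancel): the pair is replaced by
  spline-interpolated values;
* **misaligned** — any remaining suspect *that has an antisymmetric
  cancelling partner* (|dev_i + dev_j| < 0.7 × max|dev|): corrected like an
  ectopic pair. Suspects without such a partner are left unchanged — a lone
  threshold excursion is genuine rhythm, and correcting it would make the
  procedure non-idempotent (each pass would keep "fixing" tail values of the
  natural variability).

Two numerical choices matter. First, **every correction conserves total
elapsed time exactly**: splits and merges redistribute the same
milliseconds, and interpolated pairs are rescaled to their original pair
sum. Reference implementations of interpolation-based correction do not
guarantee this; we treat conservation as a contract because downstream
segment boundaries are defined in absolute time. Second, the quartile
deviations are evaluated every 5 beats and linearly interpolated in between
(`qd_stride`); the threshold field varies slowly by construction, and this
cuts the detector's cost roughly five-fold in the simulation studies.
A warning is raised when corrections reach 5 % of beats, the conventional
quality gate; the feature table flags such segments `excluded` rather than
dropping them silently.

After a pair correction, the *next* beat's dRR necessarily jumps (its
predecessor changed); a trailing suspect that deviates in dRR only is
consumed as part of the same event rather than corrected separately.

### Resampling and detrending

Spectral estimation needs even sampling, so the corrected intervals are
interpolated with a cubic spline against their beat times and evaluated on
a 4 Hz grid spanning the observed beats (no extrapolation). The tachogram
convention plots RR_i at the *i*-th beat's occurrence; since RR_i is the
average of the underlying modulation over the preceding interval, the
reconstruction trails the true modulator by about half a mean interval, and
frequency component f is attenuated by roughly sinc²(π f T̄) in power
(T̄ = mean RR in seconds). At 4 Hz and typical heart rates this costs a few
percent in LF and ~10 % in HF; the recovery tests account for it.

Slow trends are removed with the smoothness-priors operator
`trend = (I + λ² D₂ᵀ D₂)⁻¹ x` (D₂ = second differences), with λ = 500 at
4 Hz. Straight lines lie in the null space of D₂ and are removed exactly;
a 0.25 Hz component retains ≥ 95 % of its variance, so the HRV bands pass
through. λ = 0 is the identity. The solve uses a sparse banded Cholesky
(`Matrix`), which the tests require to match a dense inverse to 1e−8
(relative) on ≤ 2000 samples. The operator assumes even spacing, so
detrending is applied **after** resampling; a smoothness-priors operator on
raw unevenly spaced beats is not well defined, and the high-pass test
(residual power below 0.01 Hz under 5 % of input) bounds the numerical
impact of this ordering.

### Segment policy

Epoch length strongly affects HRV features, so all phases are analysed over
equal-length windows: 300 s when the phase allows, otherwise a 180 s
fallback (flagged), otherwise the segment is reported missing. The window is
centered in the phase — placement is not prescribed by convention, and
centering minimizes boundary transients from phase transitions.

## Spectral features

`welch_psd()` averages Hann-tapered, 50 %-overlapped periodograms over 300 s
windows, each demeaned. The binding normalization contract is Parseval's
identity — the integral of the one-sided density equals the input variance —
so band integrals (trapezoidal, with interpolated band edges) are powers in
ms²; the taper identity itself is cosmetic. Segments shorter than the window
use one full-length window and are flagged. The VLF lower edge defaults to
0.003 Hz, the short-term convention; all edges are configurable.

Two reporting ambiguities are resolved explicitly rather than silently:
the feature table emits both the max−min instantaneous heart rate
(`hr_range`) and mean HR, because published "HR range" columns sometimes
track mean HR (≈ 60000 / mean RR) rather than a literal range; and
"normalized HR" phrasing in source material is presumed to mean normalized
HF. Downstream analyses can choose either column.

## The synthetic-data module

The generator exists so every downstream stage has ground truth; it is
tested code, not a fixture.

* **IPFM beats.** A beat is emitted each time the integral of the
  instantaneous rate 1000/rr(t) crosses an integer; crossing times are
  interpolated linearly on the integration grid (threshold 1.0, grid-free
  beat placement). A sinusoidal modulator of amplitude *a* ms contributes
  band power a²/2, the closed-form target used by the recovery tests.
  Broadband noise is white on the modulator at 4 Hz (then interpolated), not
  on the intervals, so its spectral footprint is flat and interpretable.
* **Artifacts.** Injection draws per-category binomial counts at the
  configured rates (default 3 % total: ectopic 1 %, missed 0.75 %, extra
  0.75 %, misaligned 0.5 %) at positions ≥ 3 beats apart, and conserves
  total time exactly. Misaligned jitter is a fixed ±50 ms antisymmetric
  shift; ectopic prematurity is 25–40 % of the interval.
* **Jury ratings.** rating = dimension mean + Λ · factor score + rater bias
  + noise, clipped to [1, 5]; the default 6 × 2 loading pattern has a
  *Content* factor (Interest, Agreement) and a *Performance* factor
  (Authoritativeness, Learning, Clarity) with Engagement split. Ratings are
  continuous by default (`round_likert = FALSE`) because analyses operate on
  communicator means, which are continuous anyway.
* **Cohort.** Default phase targets are calibrated to published group
  values: mean RR 680/586/708 ms and HF 295/232/373 ms² for everyone;
  LF 900 → 208 → 1552 ms² for the low-performance cluster (pre-to-interview
  change −692 ms², interview-to-post +1344 ms²) and a flat 643 ms² for the
  high cluster. Between-subject variability is a shared log-normal amplitude
  multiplier (sdlog 0.20), a per-phase jitter (sdlog 0.05) and a mean-RR
  offset (sd 30 ms) — published group means come without per-subject
  variance components, so these are calibrated choices, not estimates.

What the generator does **not** emulate: respiratory coupling and
respiratory-frequency drift (HF is a fixed-frequency sinusoid), circadian or
posture trends beyond what detrending removes, non-stationarity within a
phase, non-Gaussian covariates, rater × communicator interactions, and any
ECG-level morphology. Passing tests therefore demonstrate the pipeline's
correctness on signals with known spectral content and labelled corruption —
they do not certify performance on pathological rhythms or poor-contact
recordings.

## Statistics

`rm_anova()` transforms the k = 3 phase responses by k−1 orthonormal
polynomial contrasts and regresses them on the between-subject design:
intercept, sum-to-zero coded factors, mean-centered covariates. With this
coding the intercept row *is* the phase main effect evaluated at the
covariate means — the printed "covariates evaluated at ..." convention.
Within-subject effects are reported multivariately with Pillai's trace
V = tr(H(H+E)⁻¹) and its standard F approximation (preferred at small n for
robustness to covariance heterogeneity), and univariately with the
Greenhouse–Geisser ε = (tr Σ̂)²/((k−1) tr Σ̂²) applied to the degrees of
freedom **unconditionally** — sphericity is not tested first, so no
diagnostic gate decides which p value is real. ε is clamped to its
theoretical range [1/(k−1), 1]. Between-subject effects are tested on
subject means. Partial η² is V/s for multivariate rows and
SS_h/(SS_h+SS_e) = F·df1/(F·df1+df2) univariately. When the error degrees
of freedom cannot support the multivariate approximation (df2 ≤ 0), the F
and p are NA rather than numeric noise. Pairwise phase contrasts are
estimated at the covariate means with Bonferroni adjustment — the common
default when no rule is stated.

Supporting primitives: Pearson chi-square (no continuity correction) with an
optional exact p by full enumeration of fixed-margin tables (feasible to
n = 200); correlations with t-transform p values; PCA on the correlation
matrix retaining eigenvalues strictly greater than 1 (ties at exactly 1 are
not retained) with varimax + Kaiser row normalization, reporting variance
before and after rotation (rotation conserves retained variance, which the
tests assert); and an **exact** one-dimensional two-cluster K-means — in 1-D
the optimum is a split of the sorted values, so scanning all n−1 splits
finds the global optimum deterministically, with no seed sensitivity; the
tests confirm it coincides with multi-start `stats::kmeans`. log(pub)
covariates are natural logarithms.

## Problem sizes and reproducibility

The simulation studies shipped with the package use: 50 seeds × 600 s
recordings for spectral recovery and artifact-detection fidelity, 500
replications (n = 20) for the null size of the multivariate phase test, and
200 replications of the full 24-subject pipeline for the pattern-recovery
study. These sizes give binomial standard errors comfortably inside the
asserted margins while keeping a complete test run in the minutes range.
Every stochastic function takes an explicit seed; identical (configuration,
seed) pairs give byte-identical outputs, and `run_pipeline()` writes a JSON
manifest recording the seed and configuration of each run.

## Known limitations

* Band-power estimates inherit the tachogram's sampling attenuation
  (strongest for HF at long mean RR) and the spline's edge behaviour.
* The artifact detector's constants (5.2, 91, 11) are tuned for short-term
  recordings at rest-to-moderate heart rates; atrial fibrillation or
  exercise data violate its local-stationarity premise.
* With very small cohorts the multivariate within-subject tests run out of
  error degrees of freedom quickly (n must exceed the design rank by at
  least k−1).
* State labels summarize position in the LF–HF plane relative to a chosen
  baseline; they are not validated clinical constructs.
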