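---
title: "Mapping the cerebellar dot fraction: models, choices and limitations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping the cerebellar dot fraction: models, choices and limitations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dotfrac)
```

## The signal model and its two regimes

Spherical tensor encoding (STE) sensitises the measurement to diffusion in
all directions within a single acquisition. Under the assumption of multiple
non-exchanging, effectively isotropic compartments, the STE signal is a sum
of exponentials,

$$S(b) = S_0 \sum_i f_i \, e^{-b D_i},$$

with the b-value stored in s/mm² and converted once, at the model boundary,
to ms/µm² (1000 s/mm² = 1 ms/µm²), so that diffusivities are expressed in
µm²/ms throughout. `forward_signal()` implements this and is the generative
core of every phantom.

Two regimes of the decay are informative about different compartments, and
the pipeline fits them separately per voxel (`fit_voxelwise()`):

* **High b (b ≥ 10 000 s/mm², `highb_min`).** Any compartment with
  appreciable diffusivity has decayed away; the residual signal is modelled
  as $S_{0s} e^{-b D_s}$ (`fit_highb_monoexp()`), giving the sphere ("dot")
  compartment's signal and diffusivity. Bounds: $S_{0s} \ge 0$,
  $D_s \in [0, 1]$ µm²/ms.
* **Low b (b ≤ 1500 s/mm², `lowb_max`).** CSF partial volume inflates naive
  diffusivity estimates, so the low-b signal is modelled bi-exponentially
  with a fixed free-water compartment,
  $S_0 [f_t e^{-b \cdot MD} + (1 - f_t) e^{-b D_{fw}}]$ with $D_{fw} = 3$
  µm²/ms (`fit_lowb_freewater()`). Bounds: $f_t \in [0, 1]$,
  $MD \in [0, 3]$ µm²/ms, $S_0 > 0$.

The tissue sphere signal fraction combines both regimes:
$f_s = S_{0s} / (f_t S_0)$ (`compute_fs()`); voxels with $f_t S_0 \le 0$ are
marked undefined rather than erroring, so maps compute wholesale.

Both fits use bounded Levenberg–Marquardt least squares (`minpack.lm`),
initialised from log-linear regression (high b) or from the b0 mean, a
log-linear slope and $f_t = 0.9$ (low b). On data generated by the fitted
model both fits recover parameters to machine precision; the test suite
asserts this, and checks the tri-exponential case against brute-force
grid-search oracles instead, since there the least-squares solution is not
the generating parameter set (see "What recovery means", below).

## The acquisition scheme

The default protocol (`build_scheme()`) uses eleven STE shells, b = 250 to
15 000 s/mm², with per-shell repetition counts rising with b
(`default_repeats()`: 1, 2, 6, 10, 12, 13, 17, 20, 31, 45, 47 — 204 weighted
volumes) to counter the decaying SNR, the shell order randomised
(seed-reproducible) to decouple b from scanner drift, and a b0 reference
opening every 15-volume block. Repetition counts are configurable; the
default is the package's reconstruction of a realistic ultra-high-b
protocol and fixes the conditions used by all validation phantoms.

## Preprocessing choices

**Noise level.** `estimate_sigma()` uses the repeats of the highest shell,
where true signal is smallest: the repeat standard deviation, rescaled by
$1/\sqrt{2 - \pi/2}$ where the repeat mean falls below twice the SD
(noise-floor-dominated voxels, where the magnitude SD understates the
underlying Gaussian σ).

**Noise floor.** Magnitude MRI noise is Rician; near the floor the mean
magnitude plateaus above the true signal, flattening the apparent decay and
biasing the sphere fit. Two corrections are provided, and the distinction is
deliberate:

* `rician_correct()` applies the elementwise method-of-moments map
  $\hat A = \sqrt{\max(M^2 - 2\sigma^2, 0)}$. It is exactly the identity at
  σ = 0, removes the plateau ($M = \sigma\sqrt2 \mapsto 0$), and is the
  right tool above SNR ≈ 10. But at the top STE shells the working SNR is
  0.9–1.4, and there the *expectation* of the corrected magnitude sits well
  below the true signal (Jensen's inequality on the square root): in
  Monte-Carlo under the default protocol, an elementwise-corrected high-b
  fit underestimates $S_{0s}$ by ~30%.
* `fit_voxelwise()` therefore applies the same moment logic one level up:
  after outlier exclusion it collapses each high-b shell to
  $\sqrt{\max(\overline{M^2} - 2\sigma^2, 0)}$ over its surviving repeats.
  Because $E[M^2] = A^2 + 2\sigma^2$ holds exactly at every SNR, the shell
  representative is asymptotically unbiased in the many-repeat shells that
  dominate the high-b regime (Monte-Carlo: $S_{0s}$ +3%, $D_s$ +0.2%).
  Low-b and b0 values, at SNR ≥ 10, receive the elementwise correction.
  Datasets already passed through `rician_correct()` are flagged and not
  re-corrected.

**Drift.** Slow signal drift over the ~36-minute protocol is modelled as a
polynomial gain (default order 2, matching a 1 → 0.95 decay) fitted to the
spatial-mean intensity of the interleaved b0s and divided out of every
volume, normalised to the first b0 (`drift_correct()`; requires ≥ 3 b0s
unless explicitly skipped).

**Outliers.** The modified Z-score $0.6745 (x - \tilde x)/\text{MAD}$ with
threshold 3.5 (`modified_zscore()`), falling back to the mean absolute
deviation with constant 0.7979 when the MAD degenerates. Scoring is applied
per voxel per shell across repeats — the exchangeable unit the fits consume;
whether the original analysis pooled across all volumes instead is not
determinable, so the unit is a documented choice here. Exclusion runs once,
before both fits, not iterated.

## The synthetic generator

`generate_phantom()` builds a concentric "cerebellum": a white-matter core,
a grey-matter shell carved into ten lobule labels (label 10 a deliberately
tiny polar cap, so the small-region exclusion rule is exercisable), and a
CSF rim, on a configurable grid. Each voxel's noiseless signal is the
forward model of its class mixture; drift multiplies it; Rician corruption
$|S + \epsilon_1 + i\epsilon_2|$ adds the floor. Defaults: S0 = 100, σ =
S0/50 (SNR 50 at b0 — not reported for the original data, chosen as
realistic for 4-mm isotropic voxels and recorded in the spec object), the
grey matter the tri-exponential f = (0.2, 0.72, 0.08), D = (3, 1, 0.1)
µm²/ms whose first and last compartments mimic free water and the sphere.

`generate_cohort()` layers between-subject structure on top: per group,
target overall medians for (MD, fs, Ds) and MAD-scale spreads; per subject a
log-normal factor per metric (log-normal keeps parameters positive and
medians on target); per lobule a fixed anatomical lobe profile (anterior MD
highest, inferior-posterior fs highest, scaled from the control-group lobe
medians) and a 3% log-normal lobule jitter; mixtures are then solved from
the targets (`mixture_from_targets()`), erroring on unreachable
combinations. The default groups encode the published control vs SCA6
contrasts: MD 0.60 (0.03) vs 0.54 (0.07) µm²/ms, fs 0.11 (0.01) vs 0.14
(0.03), Ds 0.12 (0.02) vs 0.13 (0.02), cerebellar volume 115.94 (21.02) vs
89.60 (12.90) cm³ — the printed per-group spreads, taken as given even
though the patient columns' MADs at n = 5 are themselves noisy. With
`voxels = FALSE` the generator returns the per-lobule truth table without
materialising grids (every voxel of a lobule shares its mixture, so lobule
medians are exact); this keeps thousand-replicate calibration runs cheap.

**What the phantoms do not emulate:** anatomy beyond concentric shells,
partial-volume mixing at tissue boundaries, spatially varying noise,
motion/eddy/susceptibility artefacts (accepted as corrected upstream),
exchange between compartments, and any LTE signal. Passing tests bound
estimator behaviour under the stated noise and drift models, not under real
scanner physics.

## What recovery means on tri-exponential tissue

Two conventions coexist and the tests name them explicitly:

* When the generating model lies inside the fit family (the two-compartment
  "exact" classes of `exact_tissue_classes()`, free water + one
  low-diffusivity compartment), the voxelwise round trip recovers every
  map — $D_s$, $S_{0s}$, $f_s$, $f_t$, MD — to 10⁻⁶ relative, and the
  acceptance suite asserts it.
* On the realistic tri-exponential grey matter the least-squares solution
  differs from the generating mixture by construction. The high-b fit is
  contaminated by the D = 1 µm²/ms compartment at the ~10⁻³ level (slope
  and intercept within 2% of the sphere values — the worked example the
  acceptance script recomputes). The low-b fit projects bi-exponential
  tissue onto a single tissue compartment: the projection has
  $f_t \approx 0.749$, MD ≈ 0.79, not the generating 0.8 and 0.91. Fits are
  therefore compared against brute-force grid-search oracles (the same
  least-squares problem solved by exhaustive search), and $f_s$ — built
  from the fitted $f_t$ — carries a +7% projection offset even at σ = 0.

Under noise at the default SNR, the noise-*induced* median bias (estimate
vs its own noiseless projection, ~1400 GM voxels) is within 10% for both
$f_s$ (+3–8%, driven by ratio skew: the low-b regime has only 1 + 2 repeats
at 250 and 1500 s/mm², so $f_t$ is the least precise parameter and
$1/\hat f_t$ is right-skewed) and $D_s$ (within 4%). Measured against the
generating truth instead, $f_s$ lands at +11–15% — projection offset and
ratio skew compounding — which is worth knowing when interpreting absolute
fs values from this protocol; group *comparisons* are unaffected, since the
offset is common to groups.

## ROI aggregation

`filter_voxels()` implements the grey-matter inclusion rule: labelled voxels
with finite parameters and $f_t > 0.3$; then fs and Ds are trimmed at the
per-subject 99th percentile, computed *after* the ft gate (so CSF-dominated
voxels cannot distort the percentile) and per subject rather than per
lobule (per-lobule percentiles would destabilise small regions). "Within
the 99th percentile" is read as an upper-tail trim (≤ the percentile).

`summarize_rois()` reports per-lobule medians and per-lobe medians over
*pooled* voxels — never a median or mean of lobule medians; the test suite
pins the distinction on a constructed counterexample ({1,1,1} ∪ {9}: pooled
median 1, mean-of-medians 5). Regions under `min_voxels = 5` are flagged
excluded, the rule that removes the flocculonodular lobe in practice. The
default lobule→lobe table follows standard cerebellar anatomy (I–V anterior,
VI–VII superior posterior, VIII–IX inferior posterior, X flocculonodular)
and is a configurable data frame, since only the lobe names are fixed by
convention.

## Group statistics

`mann_whitney()` (exact enumeration for combined n ≤ 20 without ties, tie-
and continuity-corrected normal approximation otherwise), `icc()` — the
two-way random-effects, absolute-agreement, single-measure ICC(2,1), the
standard scan–rescan form, computed from the ANOVA mean squares —
`anova_tukey()` (omnibus F plus studentized-range-adjusted pairwise
comparisons), `adjusted_group_regression()` (OLS on group indicators plus
total cerebellar volume, reference = control), and `bonferroni_threshold()`.
With α = 0.05 and m = 15 (three metrics across five region-level analyses)
the adjusted threshold is 0.0033 — the operative "p < 0.003"; m is a
parameter, not a constant.

Two analysis units appear in the validation suite, on purpose. Type-I error
is calibrated at the *subject* level (one pooled-cerebellum median per
subject), where observations are exchangeable and the Mann-Whitney rejects
at its nominal rate. The cohort power check instead pools *per-lobule*
medians across subjects (nine lobules × subjects per group, flocculonodular
excluded), the unit the original region-wise analysis plots and tests; this
treats correlated within-subject observations as independent and is
therefore anti-conservative as an inferential procedure — a limitation
inherited from the analysis design it emulates, and the reason the
subject-level unit is used wherever calibration matters. Under the default
two-group targets at n = 20/group and α = 0.003, directionally correct
separation of both MD and fs occurs in ~88% of replicates; the fs contrast
alone separates in ~98%, the MD contrast is the binding one because the
SCA6 column's printed MD spread (MAD 0.07) is large relative to its 0.06
µm²/ms effect.

## Numerical choices and degenerate inputs

* Levenberg–Marquardt tolerances 10⁻¹³ (cost and parameters), ≤ 200
  iterations; bounds as above; ties between flagging and fitting resolved by
  running exclusion once, before both fits.
* b0 volumes are averaged (post-drift-correction) into one b = 0 datum; the
  surviving-repeat mean is used if outlier exclusion empties the b0 set.
* High-b initialisation falls back to (smallest positive signal, Ds = 0.1)
  when log-linear initialisation is impossible (noise-floor zeros).
* Voxels with all-zero or single-shell regimes are flagged non-converged,
  never thrown; `fs` is set iff both fits converged and $f_t S_0 > 0$.
* Schemes lacking either regime are rejected up front, naming the regime.
* The label volume and parameter maps must share the voxel grid; no
  resampling or registration is implemented, by scope.

## Problem sizes used in validation

Phantom round trips run on 8³–18³ grids (≈ 200–1400 grey-matter voxels) with
the full 219-volume protocol; the noise-robustness measurement uses ≈ 1400
voxels; cohort calibration uses 1000 table-only replicates (type-I) and 100
voxel-grid replicates at n = 20/group (power). These sizes were chosen so
the whole validation suite completes in a few minutes while keeping median
standard errors a few percent.

## Known limitations

* Exchange between compartments is not modelled; at long encoding times the
  sphere fraction conflates restriction and exchange.
* The MD reported is the free-water-eliminated tissue diffusivity of the
  bi-exponential fit; on multi-compartment tissue it is a projection, and
  absolute fs inherits a positive offset (quantified above).
* The elementwise Rician correction is the right tool only above SNR ≈ 10;
  the shell-moment path exists because the top shells sit near the floor.
* Lobule geometry is schematic; no claims are made about atlas accuracy or
  partial-volume behaviour at real lobule boundaries.
* The region-level group comparison inherits the anti-conservative pooling
  of the analysis it reproduces.
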