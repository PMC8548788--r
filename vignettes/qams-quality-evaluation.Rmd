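---
title: "Single-marker quantification and fingerprint chemometrics: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Single-marker quantification and fingerprint chemometrics: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(qamskit)
```

## The problem

Quality control of herbal material (here: dandelion, *Taraxacum
mongolicum*) from HPLC-DAD data usually combines three views of the same
chromatograms:

1. **Quantification** of a panel of marker phenolics — chlorogenic acid,
   caffeic acid, p-coumaric acid, cichoric acid, luteolin, apigenin — in
   mg per g of dry material.
2. **Fingerprint similarity**: the whole multi-peak profile of a batch
   compared holistically against a reference chromatogram.
3. **Chemometric evaluation** of the batch-by-compound content matrix:
   clustering, factor analysis and a composite quality score used to rank
   batches.

The quantification step contrasts two routes. The *external standard
method* (ESM) calibrates every compound against its own standard series,
`A = a·x + b`, and back-calculates `x = (A − b)/a`. *Quantitative analysis
of multi-components by a single marker* (QAMS) calibrates only one marker
(cichoric acid, the dominant and most stable constituent) and converts the
other peaks through fixed **relative correction factors**

    f_si = f_s / f_i = (A_s / C_s) / (A_i / C_i),

so that an analyte's concentration in the injected extract is

    C_i = f_si · C_s · A_i / A_s.

QAMS needs one standard instead of six; its validity is established by
showing the two routes agree (relative error `RE = 100·(QAMS − ESM)/ESM`
within a few percent, correlation near 1, paired *t*-test non-significant)
and that `f_si` is robust to instrument conditions (flow rate, column
temperature).

## What the synthetic generator emulates

Real raw chromatograms for such studies are rarely deposited; only the
printed summary tables are available (they ship with this package as
checksummed fixtures, see `load_fixture()`). The generator therefore
recreates the *statistical structure* of the study so the whole pipeline is
testable with known ground truth:

* 15 batches, 6 quantified compounds plus 4 unidentified common peaks
  (10 common peaks), on a 0–27 min gradient;
* linear detector response per compound with the published regression
  constants (slope, intercept, R², linear range);
* Gaussian peaks of sigma 0.08 min — a realistic analytical peak width
  that also gives a closed-form area `h·σ·√(2π)` for tests;
* extraction dilution 1 g of powder into 30 ml of solvent, so a content of
  `c` mg/g injects `c·1000/30` µg/ml;
* a low-order polynomial baseline drift (default amplitude 1 mAU) to
  exercise baseline correction without dominating peaks;
* multiplicative per-peak detector noise `1 + N(0, cv)`;
* replicate/spike designs (precision, stability, repeatability, recovery)
  with the same multiplicative noise model.

Retention times and peak widths are **generator parameters, not data
claims**: publications of this kind rarely print them, so fixed values
spread over 2–25 min with ≥ 0.8 min spacing were chosen once, which makes
retention-time matching at the default 0.2 min tolerance unambiguous by
construction. Consequently, passing tests demonstrate correctness of the
signal processing and statistics — not robustness to co-elution, peak
tailing, retention drift or detector saturation, none of which are
modelled.

Two generator details are worth flagging:

* **Contents vs linear range.** The published content envelope for some
  compounds extends below their calibration linear range (luteolin can be
  as low as 0.003 mg/g ≈ 0.1 µg/ml against a 2.0 µg/ml range floor); with
  a negative intercept the fitted response is then negative. The generator
  follows the linear response everywhere, clips negative predicted areas
  to zero and flags the record. `sample_contents(range = "linear")`
  restricts draws to the calibration range (and above the concentration
  where the response turns positive), which is what the end-to-end
  round-trip checks use: a batch whose peak is genuinely absent cannot be
  recovered by any integrator.
* **Planted structure.** `structure = "factors"` plants three orthogonal
  latent quality factors driving the compound pairs
  (luteolin, apigenin), (cichoric, chlorogenic), (p-coumaric, caffeic) —
  the grouping reported for real material. The factor scores are
  orthonormalized in-sample: with only 15 batches, raw independent draws
  are routinely correlated at |r| ≈ 0.3, and the factor-recovery property
  is a statement about *orthogonal* planted factors, not about chance
  collinearity. `structure = "clusters"` plants three batch groups at
  low/mid/high content for cluster-recovery checks.

## Why the method-agreement properties use a proportional response

Eq. `C_i = f_si·C_s·A_i/A_s` is a *ratio* model: it is exact when the
detector response is proportional (`b = 0`) and biased otherwise, by the
factor `(1 + b_i/(a_i x_i)) / (1 + b_s/(a_s x_s))` relative to ESM. With
the published intercepts this bias is large at sample concentrations far
from the standard level (chlorogenic acid: `b = 48.25` against
`a·x ≈ 270` at a typical 25 µg/ml — about +15 %). Real studies report
sub-percent agreement, which tells us their actual responses are
effectively proportional in the working range; the printed intercepts are
artifacts of fitting a straight line to a wide calibration series. The
package therefore exposes `default_design(proportional = TRUE)` and states
the agreement properties (QAMS = ESM within 0.5 % noise-free; |RE| < 5 %
for ≥ 95 % of cells at 2 % detector noise) under that variant. The
intercept-bearing design remains the default everywhere else, and the bias
is observable with it — an instructive negative control.

Relatedly, the pipeline's calibration series is simulated noise-free: the
calibration relation is an *input* of the study. If per-point noise is
added to a series spanning a wide range, the fitted intercept's
uncertainty dominates relative error at the bottom of the range for *any*
method, which says nothing about QAMS. `fit_curve()`'s behaviour under
noisy series (R² near the published 0.999) is tested separately.

## Signal processing choices

* **Baseline**: piecewise-linear interpolation through per-window minimum
  anchors (1 min windows, wide against the 0.08 min peak sigma), linearly
  extrapolated at the ends. Removes offsets and linear drifts exactly.
* **Detection**: local maxima above 1 mAU with topographic prominence
  above 1 mAU; bounds at the nearest valley or where the signal falls
  below 0.1 % of apex height.
* **Integration**: trapezoid between the bounds minus the local chord —
  standard drop-baseline practice; agreement with a fine-grid oracle is
  tested to 0.5 %.
* **Matching**: each reference retention time claims the nearest unclaimed
  peak within 0.2 min; contested peaks go to the closer reference, ties to
  the earlier one. Common peaks are those matched in **all** samples (the
  fraction is configurable).

## Chemometrics choices

* **HCA** comes in the two published flavours: squared Euclidean distance
  on raw contents with between-groups (average) linkage, and a
  heatmap-style mode using per-feature z-scoring, `1 − Pearson` between
  sample rows and average linkage. The second mode is under-specified in
  the literature; these settings are declared, not asserted as anyone
  else's.
* **KMO / Bartlett** follow the textbook formulas (anti-image partial
  correlations from the inverse correlation matrix; the determinant-based
  chi-squared). No base-R implementation exists, so they are authored here
  and tested against a regression-residual partial-correlation oracle.
* **Factor extraction** is principal-component based: eigenvalues of the
  correlation matrix, loadings `v·√λ`, retention rule eigenvalue > 0.8
  (configurable; Kaiser's 1.0 available). Published tables of this kind
  report exactly this arithmetic, e.g. the cumulative variance of the
  first three components, `100·(2.717 + 1.836 + 0.804)/6 = 89.283 %`.
* **Varimax** uses `stats::varimax` (Kaiser normalization) restarted from
  eight fixed orthogonal matrices, keeping the best criterion value — the
  single-start iteration can stall on a stationary point (reproduced in
  the test suite with a 4×2 simple-structure matrix under a reflection).
  Column order (decreasing sum of squared loadings) and sign (largest
  |loading| positive) are fixed for determinism. Communalities are
  preserved to 1e−8 by construction and asserted.
* **Scores and composite**: regression-method scores `Z R⁻¹ L` (unit
  variance on principal components, asserted to 1e−6); composite score
  `F = Σ w_k F_k / Σ w_k` with the rotated percent-variance contributions
  as weights — invariant to rescaling all weights. Ranking is
  competition-style (ties share the smaller rank).
* The published KMO (0.542), Bartlett (45.487) and loading matrices are
  **fixtures, not recomputation targets**: they require the unpublished
  raw peak-area matrix. Factor analysis here takes the 6 quantified
  compounds as variables, matching the published factor tables (the
  accompanying text mentions 10 peak areas; with only 15 samples and the
  4 unidentified peaks tied to the marker in our generator, the 6-variable
  mode is the defensible default and the 10-column peak table remains
  available).

## Orthogonal-design range analysis

For the L9(3⁴) extraction screen, `k[level, factor]` is the mean response
at a level and `R = max(k) − min(k)`. `R` is computed from raw level
means; a 3-dp-rounded variant is also reported because published tables
round (and occasionally truncate) `k` before differencing — the run sheet
fixture's printed `R` for solvent concentration (3.465) mixes a truncated
`k2` (19.597 from 19.5977) with a rounded `k3` (16.132 from 16.1317) and
is not reproducible under any single convention; the raw value is 3.466.
Factor ranking and best-level selection (70 % solvent, 30 min, 1:30
ratio choices in the packaged sheet) are unaffected.

## Fingerprint similarity

Similarity is the congruence (cosine) coefficient on baseline-corrected
traces resampled to a common 0.01 min grid, with Pearson correlation as an
option; whether reference software computes it on full traces or on
common-peak area vectors is unstated in the field, so both inputs are
possible (full traces by default, the peak table otherwise). The reference
profile is a designated good batch (or the point-wise mean). The 0.82
quality bar is configurable. Cosine similarity is scale-invariant, equals
1 for noiseless replicates, and decreases in expectation with independent
noise — all asserted by the suite.

## Reporting conventions

Contents print at 3 dp (4 dp for means), RE and RSD at 2 dp, `f_si` at
4 dp. All RSDs use the sample (n−1) standard deviation. The paired
*t*-test is two-sided; 0.05 is reported against, never enforced.

## Problem sizes

The test and acceptance runs use the study's native scale — 15 batches ×
10 peaks on a 0.005 min grid (5401 points per trace) — plus 1000-seed
Monte-Carlo loops for the sampling-distribution checks; a full pipeline
run takes well under a second.

## Limitations

* No gradient-elution physics, co-elution, tailing, retention drift or
  saturation; matching tolerance conclusions do not transfer to real data.
* No weighted or nonlinear calibration; no LOD/LOQ estimation.
* No time-warping alignment (COW/DTW).
* No oblique rotations or maximum-likelihood factor extraction; no
  bootstrap intervals on loadings.
* No ANOVA on the orthogonal design (range analysis only).
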