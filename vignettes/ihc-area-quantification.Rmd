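---
title: "Quantifying immunostained area: point counting, color-range selection, and their agreement"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying immunostained area: point counting, color-range selection, and their agreement}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ihcquant)
```

## The measurement problem

Immunohistochemistry marks antibody-bound cells with the brown DAB
chromogen against a blue hematoxylin counterstain. For inflammatory
lesions around teeth (periodontitis, PD) and dental implants
(peri-implantitis, PI), the quantity of interest per
400×-magnification field is the **area fraction**: the percentage of the
field occupied by specifically stained tissue, measured for lineage
markers such as CD3 (T cells), CD4, CD8, CD15 (neutrophils), CD20
(B cells), CD68 (macrophages), and CD138 (plasma cells).

`ihcquant` implements the two estimation routes used in practice and the
statistical machinery needed to ask whether they agree:

* **MC (manual counting)**: a systematic grid of $n$ points is overlaid
  on the field; if $h$ points fall on stained tissue, $\hat{A} = 100\,h/n$.
  The default grid is $27 \times 22 = 594$ points, so the estimate has a
  granularity of $100/594 \approx 0.17$ percentage points.
* **DC (digital counting)**: a reference stain color is sampled from a
  marked cell; every pixel within a *fuzziness* tolerance $F$ of a
  sampled color is selected, and $\hat{A} = 100 \cdot
  \mathrm{selected}/\mathrm{total}$ pixels. The default is $F = 100$.

Because real patient images are not public, the package ships a
synthetic image generator with exact ground truth. Every downstream
claim in the test suite is made against that known truth.

## The synthetic field model

`generate_field()` renders an 8-bit RGB raster (default $512 \times
512$; the physical pixel size of a 400× field is scanner-dependent, so
extent is a free simulation parameter) containing:

* **stain blobs**: random ellipses (semi-axes 5–16 px) stamped until the
  stained pixel count reaches the target exactly — the last ellipse is
  trimmed farthest-from-center-first, so `true_fraction` equals the
  requested fraction to pixel granularity. Blob pixels get the DAB
  reference color RGB (120, 66, 18) with ±10 per-channel jitter.
  Morphological realism (membrane rings, marker-specific cell shapes) is
  deliberately out of scope: exact area control is the design goal.
* **background**: a pale hematoxylin wash (205, 205, 230) with darker
  nucleus ellipses (80, 80, 140) and eosin-pink patches (230, 185, 205),
  each with small jitter.

The palette is constructed so that every background color stays more
than 100 Chebyshev units away from the stain color even after jitter.
Consequently, in the clean **GOOD** regime, color-range selection at the
default fuzziness recovers the truth mask *exactly* — a deliberate
property that lets tests attribute any DC error to the contamination
model rather than to palette accidents.

`add_background_noise()` produces the paired **NOISE** regime: a smooth
brown haze (a sum of random Gaussian bumps, plus sparse near-stain
speckles) is alpha-blended into *background pixels only*. Ground truth
is never altered — the mask and `true_fraction` are untouched — so the
regimes differ exclusively in how misleading the color channel is. This
emulates diffuse non-specific DAB background on real slides. What
passing tests on these images do **not** show: robustness to real
histology variation (stain batch effects, tissue folds, out-of-focus
regions, marker-specific morphology), since none of these are modeled.

Synthetic study sets draw true fractions uniformly from 1–30%, a range
chosen to represent sparse inflammatory-marker staining; all randomness
flows through one integer seed per call, and no function touches the
global RNG state.

## Numerical conventions

* **Coordinates** are continuous $(row, col)$ pairs, 0-based, origin at
  the top-left corner. Pixel $i$ spans $[i, i+1)$ with its center at
  $i + 0.5$. A sampling point maps to the pixel *containing* it (equivalently,
  the nearest pixel center), and a coordinate exactly on an integer
  boundary resolves down to the lower pixel. Under this rule every
  pixel's preimage has width exactly 1, which is what makes the
  uniform-random point estimator exactly unbiased; a
  nearest-integer-coordinate rule would give border pixels half or
  one-and-a-half weight and introduce a small but measurable bias.
* **Systematic grids** place point $(i, j)$ at
  $((i + 0.5)\,H/n_{rows},\ (j + 0.5)\,W/n_{cols})$: half-cell margins,
  no points on the image border. The 594-point default is arranged
  $27 \times 22$, approximating a 4:3 field; any factorization can be
  requested.
* **Color distance** defaults to Chebyshev (maximum per-channel absolute
  difference) in RGB, the closest published analogue of per-channel
  fuzziness semantics in commercial color-range tools; Euclidean is
  available. The exact proprietary algorithm is unpublished, so the
  contract is the declared metric, not bit-compatibility with any
  particular editor.
* **Selection falloff** defaults to `hard` (binary), matching a pixel
  count read off a histogram. A `linear` mode (weight 1 up to $F/2$,
  decaying to 0 at $F$) exists for sensitivity analysis, since graded
  (anti-aliased) selections are plausible in interactive tools; with
  $F = 0$ the linear mode degenerates to exact color equality.
* **Degenerate inputs** fail loudly: ICC on constant data, correlation
  of zero-variance vectors, a signed-rank test whose differences are all
  zero, and normality testing below $n = 8$ are errors (or, inside
  `compare_cohort()`, explicitly labeled degenerate rows), never silent
  zeros.

## Agreement statistics

`icc_oneway()` is the one-way random-effects, single-measure ICC:
$\mathrm{ICC} = (MS_B - MS_W)/(MS_B + (k-1) MS_W)$ with $k = 2$, between
and within mean squares from the explicit ANOVA sums, variance
components $\sigma^2_b = (MS_B - MS_W)/k$ and $\sigma^2_e = MS_W$, and a
$MS_B/MS_W$ F-test. The one-way form was chosen because each paired
design here (two timepoints, or two observers) is analysed separately
and rater identity is not modeled; a two-way absolute-agreement variant
(`icc_twoway_agreement()`) is provided as an option. Qualitative labels
follow the Fleiss-style cutpoints: ICC > 0.75 *excellent*, 0.40–0.75
*good*, < 0.40 *poor* (both boundaries belong to *good* — the only
mapping consistent with labeling 0.65 good and 0.76–0.88 excellent).

`bland_altman()` uses differences $d_i = B_i - A_i$ (sign convention
DC − MC, or T2 − T1, recorded in every output), bias $\bar d$, sample SD
with $n-1$ denominator, limits $\bar d \pm 1.96\,s_d$ (multiplier
configurable), and coverage = the percentage of differences inside the
limits, boundaries counted as inside. Under normal differences the
1.96-SD interval contains about 95% of points, which is exactly what the
calibration tests assert.

`pearson_r()` offers the plain product-moment correlation and a
`diff_vs_mean` mode (correlating $B - A$ with $(A + B)/2$), the
proportional-bias companion to a Bland–Altman plot. Both are exposed
because a near-zero "correlation between methods" reported alongside an
otherwise good agreement analysis is consistent only with the
difference-versus-mean usage — two agreeing methods are always strongly
positively correlated in the plain sense — and the package takes no
position on which a given study meant.

## Cohort comparison

`compare_cohort()` aggregates the 4 field values to one mean per patient
per marker per method (the patient is the experimental unit; a
field-level alternative exists but ignores within-patient clustering and
is labeled as such), then runs per marker: two-sided Mann–Whitney PI vs
PD within each method, and the Wilcoxon signed-rank test MC vs DC across
patients. The D'Agostino–Pearson $K^2$ omnibus statistic (transformed
skewness + kurtosis, $\chi^2_2$) is reported per marker and method but
never used as a gate — the pipeline is non-parametric throughout, and no
multiple-testing correction is applied across the seven markers by
default. Significance is assessed at $\alpha = 0.05$.

Exactness policy: Mann–Whitney p-values come from the exact rank
distribution when the pooled sample has at most 12 tie-free
observations; the signed-rank test enumerates all $2^n$ sign assignments
on the observed midranks whenever at most 15 nonzero differences remain
(so tied ranks are handled exactly too); larger samples use the normal
approximation with tie and continuity corrections. The path taken is
always reported.

The default cohort generator plants additive effects of +4 percentage
points on CD68 and CD138 in the PI group (patient SD 1.5, field SD 1.0,
method noise SD 0.5) — an effect size around 2.5 patient-level SDs,
large enough that the 11-vs-11 Mann–Whitney flags those two markers with
high power while the five null markers reject at the nominal rate.

## The in-silico agreement study

`run_study()` replays the full design: `n_good + n_noise` fields, each
measured by 2 emulated observers at 2 timepoints with both methods
(1600 measurements at the default 100 + 100). Human variability must be
injected explicitly, and its magnitude is a simulation knob, not a
fitted quantity:

* **DC observers** re-sample their reference color with per-channel
  Gaussian jitter (SD 4) at each observer–timepoint pass. On GOOD fields
  this is inconsequential by construction (the palette margin swallows
  it); on NOISE fields the jitter moves the selection boundary through
  the haze's color continuum, so DC agreement degrades exactly where the
  color channel is ambiguous.
* **MC observers** default to the oracle mask with a 1% per-point
  misclassification rate — a regime-independent model of human counting
  slips. This default (rather than a color-rule observer with jittered
  tolerance, which is also available via `mc_mode = "color_rule"`) keeps
  the MC arm's agreement statistically indistinguishable between
  regimes, isolating the noise effect in the DC arm; a color-rule MC
  observer would conflate the two.

The report contains the intraobserver ICC (T1 vs T2, per observer and
method), interobserver ICC (observer 1 vs 2 at T1, per method and
regime), Bland–Altman DC − MC per regime (observer 1, T1), and Pearson
correlations per regime. Per-image wall-clock time is logged as
informational metadata only — timing comparisons are hardware-bound and
make no scientific claim. Identical configuration and seed give
byte-identical CSV outputs.

## Problem sizes used in the test suite

The suite generates all fixtures in code at run time. Estimator
Monte-Carlo checks use $10^4$ replicates of the 594-point grid on
128-pixel fields; calibration checks use $10^4$ simulated pairs;
oracle-equivalence checks enumerate exhaustively at $n \le 6$ subjects
(ICC), $\le 12$ pooled observations (Mann–Whitney), and $\le 15$
differences (signed-rank); the cohort power pattern uses 200 replicates
of the 11 + 11 design; study-level regime comparisons average 5 master
seeds of a 12 + 12-field study at 96-pixel extent. These sizes are the
package's declared simulation conditions; enlarging them sharpens the
Monte-Carlo tolerances but changes no conclusion.

## Known limitations

* The synthetic images are area-controlled abstractions, not
  photorealistic histology; no stain-separation (color deconvolution) or
  learned segmentation is attempted, and per-marker morphology is not
  modeled.
* The DC contract is the declared distance metric and falloff, not
  bit-compatibility with any commercial editor's selection bitmask.
* ICC generalization beyond two measurements per subject is out of
  scope, as is mixed-effects modeling of field-within-patient
  correlation.
* Wall-clock timing is reported but carries no scientific weight.
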