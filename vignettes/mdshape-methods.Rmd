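---
title: "Moment-distance shape indices and the object-based classification pipeline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Moment-distance shape indices and the object-based classification pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mdshape)
```

## The moment-distance framework

A hyperspectral pixel is a reflectance curve $\rho_i$ sampled at
positions $x_i$ along the spectrum. Broadband vegetation indices
compress that curve into two or three band averages; classes whose
curves differ only in fine structure (small absorption features,
slightly shifted shoulders) then become indistinguishable. The
moment-distance family instead integrates the raw curve shape. Two
anchor points ("pivots") are placed on the abscissa, a left pivot
$\lambda_{LP}$ at the short-wavelength end of the analysis window and a
right pivot $\lambda_{RP}$ at the long-wavelength end, and the curve is
summarized by the summed hypotenuse lengths from each pivot to every
sample point:

$$
MD_{LP} = \sum_{i=\lambda_{LP}}^{\lambda_{RP}}
  \sqrt{\rho_i^2 + (x_i - \lambda_{LP})^2},
\qquad
MD_{RP} = \sum_{i=\lambda_{LP}}^{\lambda_{RP}}
  \sqrt{\rho_i^2 + (\lambda_{RP} - x_i)^2}.
$$

Four shape indices are built from the two sums:

* `MDI` $= MD_{RP} - MD_{LP}$ — the original, unbounded difference;
* `MDIN` $= (MD_{RP} - MD_{LP})/(MD_{RP} + MD_{LP})$ — normalized to
  $(-1, 1)$ for positive curves, comparable across sensors;
* `MDRLR` $= MD_{LP}/MD_{RP}$ and `MDRRL` $= MD_{RP}/MD_{LP}$ — the two
  pivot ratios, reciprocals of one another.

Because every retained band contributes, a localized absorption feature
shifts the two sums asymmetrically (its distance to the two pivots
differs), so the ratios respond to *where* on the curve the feature
sits — which is exactly what distinguishes, say, two tillage regimes
with nearly identical broadband reflectance.

```{r md-example}
sc <- spectral_curve(c(0.1, 0.5, 0.2))
md_metrics(sc)
```

### Units and the abscissa

The sums mix the reflectance ordinate with abscissa distances, so the
two units must be chosen together. The package default is the
retained-band ordinal index (0, 1, 2, ...) with reflectance as stored —
this keeps results comparable between sensors with the same band count
and is the convention used throughout the tests. Wavelength-nm abscissa
(`abscissa = "wavelength"`) and an ordinate multiplier
(`reflectance_scale`, e.g. for DN-scaled products) are available;
changing either changes MD values materially, so the choice is echoed
into every provenance record.

The default pivots are the first and last retained band (the full
spectrum); `md_sweep()` provides the moving-pivot diagnostic — fix one
pivot, advance the other band by band, and watch where two curves'
cumulative sums diverge — used to localize the spectral region where
two classes actually differ.

Degenerate cases are explicit: a single-band window returns
$MD = \rho$ (keeping the sweep defined at its start); an all-zero
degenerate window makes the ratios 0/0, which is reported as `NaN`
with a warning, never silently replaced; missing reflectance fails
fast unless `na_skip = TRUE`, and then the number of samples actually
summed is reported.

## Comparison indices

Six conventional indices serve as the baseline feature set
(`spectral_index_stack()`). Broadband means are taken over NIR
750–850 nm, red 600–700 nm, green 500–600 nm and blue 400–500 nm;
NDII (819/1649 nm) and PRI (529/580 nm) use the single retained band
nearest the target wavelength, with ties resolved toward the shorter
wavelength and an error when the cube does not cover the target at all.
Two printed-form quirks are preserved deliberately:

* `NDVI` is computed as $(\mathrm{Red}-\mathrm{NIR})/(\mathrm{Red}+\mathrm{NIR})$ —
  the reverse of the textbook orientation. A `standard_orientation`
  flag flips it; tree-based classifiers are insensitive to the sign,
  which the test suite checks.
* `PSRI` is the broadband $(\mathrm{Red}-\mathrm{Blue})/\mathrm{NIR}$
  variant rather than the narrow-band form common elsewhere.

`EVI` uses the canonical coefficients $G = 2.5$, $L = 1$, $C_1 = 6$,
$C_2 = 7.5$.

## Texture features

Fifteen second-order texture layers come from gray-level co-occurrence
matrices computed in a moving window over each of the three highest
principal-component score images of the cube (`texture_stack()`). Per
window, the four standard directions (0°, 45°, 90°, 135°) at the
configured offset are pooled into one symmetrized matrix $P$, and five
statistics are evaluated: contrast, angular second moment, entropy,
variance and correlation. Defaults — 32 gray levels between the 1st and
99th percentile of the score image (clipped), 7×7 window, offset 1 —
follow common practice for these features; all are configurable and
echoed to the run log. Borders are handled by symmetric reflection.
Layer names follow the `FEATURE(PCAk)` convention, e.g. `ASM(PCA2)`.

## Segmentation and image objects

Objects are produced by deterministic greedy region merging
(`segment_scene()`): every pixel starts as a region, and adjacent
regions merge in order of increasing Ward cost
$\sqrt{2 n_1 n_2 / (n_1+n_2)}\,\lVert m_1 - m_2 \rVert$ on standardized
feature means, until the cheapest merge exceeds $2.8 \times
\mathrm{scale}$. The Ward size factor was a deliberate choice over the
plain mean distance: thin, mixed strips along field borders are cheap
to absorb into large homogeneous fields, while two large dissimilar
fields stay expensive to join, which prevents the chaining across
borders that plain nearest-mean merging exhibits. Two properties are
guaranteed and tested: the labels always form a dense partition into
4-connected regions (8-connectivity by flag), and — because the greedy
merge sequence is identical for any two thresholds up to the smaller
one — the segment count is monotone non-increasing in scale.

The numeric meaning of `scale` is a calibration of this implementation,
not a quantity carried over from any external segmentation tool: on the
bundled scenes, scale ≈ 1 leaves pixels unmerged, scale ≈ 5 recovers
field-level objects, scale ≈ 20 produces few large segments. One
segmentation geometry, computed on the full feature stack, is shared by
all feature sets so that per-object predictions of different sets are
paired — which is what makes the McNemar comparison between sets valid.

Per-object feature means (`object_means()`) exclude non-finite pixels
(e.g. correlation over a constant window) and report the count used;
ground truth is attached per object as the modal pixel label
(`majority_label()`), ties toward the smaller class id, 0 meaning
unlabeled.

## Classification and assessment

Five feature sets are compared (`feature_set_specs()`): the six
comparison indices plus the fifteen textures (set 1, 21 variables), and
set 1 plus exactly one of MDIN, MDRLR, MDRRL, MDI (sets 2–5, 22
variables each). Labeled objects are split 30%/70% per class
(stratified, seeded, `round(0.3 n_c)` clamped so both sides stay
non-empty); the same split serves every set. Each set trains a random
forest (bagged CART ensemble; 500 trees, $\lfloor\sqrt{F}\rfloor$
candidate features per split, unlimited depth by default) and variable
importance is the permutation form: the drop in out-of-bag accuracy
when a variable is permuted, normalized by its standard deviation
(Gini importance by flag). All randomness is derived from the config
seed; `run_experiment()` is bit-stable under a fixed seed and config,
which the acceptance suite asserts.

Assessment uses the confusion matrix (rows = reference): overall
accuracy, per-class producer's accuracy (omission), user's accuracy
(commission), and the kappa coefficient
$(p_o - p_e)/(1 - p_e)$. Because whether per-object or per-pixel
weighting is intended can be ambiguous, both are reported
(`accuracy` and `accuracy_pixel`, the latter weighting each object by
its pixel count). Paired classifier comparisons use McNemar's
$Z = (f_{12} - f_{21})/\sqrt{f_{12} + f_{21}}$ over the shared test
objects, with $|Z| > 1.96$ flagged significant at the 5% level; the ten
pairwise set comparisons are reported raw, without multiplicity
correction (a flag-level choice left to the analyst).

## The synthetic study scene

`make_scene()` generates the study conditions used by the tests: a
64×64 scene, 100 bands over 400–1700 nm (the SWIR end is included so
NDII's 1649 nm band resolves), four classes in rectangular fields with
irregular (warped) borders, per-band Gaussian noise sd 0.01. Class
curves are piecewise-linear endmember templates — vegetation with green
peak, red trough, red edge, NIR plateau and SWIR water absorption; a
soil line; and a sparse-canopy mixture — qualitative stand-ins chosen
for shape control, not radiative-transfer realism.

Two realism terms make the scene's covariance structure resemble real
imagery: a per-pixel multiplicative brightness factor (sd 0.02,
illumination and canopy-density variability) and a zero-mean per-pixel
water-absorption term at 1450 nm (sd 0.03 at the trough). Without
them the scene spans only three spectral directions and the engineered
class contrast described next would surface in the top principal
components and leak into the texture features through quantization
clipping; with them, the top three components are claimed by the strong
material and moisture contrasts, as in real scenes.

### The shape-confusable pair

`make_confusable_pair()` constructs the scene's central challenge: two
classes with *identical broadband behavior* but different fine
structure. Class B equals class A plus a raised-cosine absorption dip,
plus a compensating constant offset over the broadband range hosting
the dip, sized so the two classes have exactly equal means over all
four broadband ranges on the scene's band grid. All six comparison
indices are then equal between the pair by construction (the dip's
default position, centre 470 nm with support 440–500 nm, also avoids
the four narrow bands), while the moment-distance metrics still differ.

The dip sits in the blue range by design: a mean-compensated dip is
nearly invisible to the moment distances when the weight
$\rho_i/\mathrm{hyp}_i$ is locally linear, and that weight curves most
strongly next to a pivot. Placing the dip near the left pivot makes the
MDRRL contrast between the pair about an order of magnitude larger than
the same dip placed mid-spectrum — the quantitative reason the shape
index succeeds where band averages cannot, and the property the
depth-ladder test checks monotonically.

The default field layout ("separated") interleaves pair-class fields
with the other classes so pair fields never share a border. This is a
deliberate study-design choice: the pair's mutual border carries
essentially no feature contrast, so any field-forming segmentation
would merge adjacent A and B fields into one object and the question
"can a classifier separate them?" would become unanswerable before any
classifier runs. A fully random layout remains available
(`layout = "random"`).

### What the tests do and do not show

The acceptance suite runs the whole pipeline on ten seeded scenes and
asserts the qualitative finding: the feature set containing MDRRL
attains strictly higher object-level test accuracy than the no-MD set
in at least 9 of 10 seeds, and MDRRL ranks first in that set's
permutation importance in at least 8 of 10. On this synthetic scene the
margin is large (set 4 ≈ 95% vs set 1 ≈ 78% at seed 1). That
demonstrates the mechanism — shape information surviving where band
averages carry none — under controlled conditions; it does not
calibrate accuracy on real airborne scenes, where mixed pixels,
atmospheric residuals, within-class spectral variability and
segmentation quality all intervene.

Problem sizes were chosen so the full suite and the acceptance script
run comfortably on a single CPU: 64×64×100 scenes, ten seeds for the
replication block, 500-tree forests on ~140 objects.

## Numerical choices, in one place

* Pivots must coincide with abscissa sample positions (tolerance
  1e-8); the window includes both pivots.
* Ratio guards: zero moment distances give `NaN` ratios plus a
  warning.
* Quantization for textures: equal-width bins between the 1st and 99th
  percentile, values clipped; a constant image maps to level 0, and
  correlation over a constant window is `NaN`.
* Segmentation ties break on the smaller (then larger) region id;
  dense relabeling follows first occurrence in column-major order;
  non-finite pixels are excluded from merging and afterwards take the
  nearest valid label (smallest on ties).
* The stratified split clamps per-class training counts to
  `[1, n_c - 1]`.
* PCA eigenvector signs are fixed by making the largest-magnitude
  loading positive, so score images are reproducible.

## Running against real airborne scenes

The pipeline accepts external cubes; the workflow for a public
hyperspectral scene with a labeled reference map is:

```sh
mdshape md --metric mdrrl cube.img mdrrl.img
mdshape classify --config run.yaml cube.img truth.img out/
```

with `run.yaml` setting the segmentation scale (5 is a reasonable
starting point for ~20 m agricultural scenes, 20 for finer urban
scenes), the texture configuration, and the seed. Cubes are ENVI
header + binary (BSQ/BIL/BIP; wavelengths from the header or a
`band,wavelength_nm` sidecar; integer products need `--scale-factor`).
Expect such comparisons to be calibration-dependent: this package's
segmentation is its own approximation, the band masks applied by any
particular study are usually unstated, and accuracy figures are
sensitive to both. Treat agreement at the level of ranking (which
feature set wins, which variable ranks first) as the reproducible
content, not the absolute percentages.
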