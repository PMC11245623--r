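---
title: "Charred grape-pip triage: models, calibration and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Charred grape-pip triage: models, calibration and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(carposort)
```

carposort models the deformation of grape pips (seeds) under charring and
the downstream decisions that deformation forces: which pips can still be
classified to variety by 3D shape matching, and how to estimate the
charring temperature of a pip with unknown history. This vignette is the
package's account of the science inside: the generative model, the
calibration sources, the registration and classification machinery, the
numerical choices, and the limits of what the synthetic experiments can
show.

## The generative pip model

A pip is modeled as a tapered ovoid sampled uniformly on a sphere and
mapped to semi-axes (L/2, W/2, H/2): length along x, breadth along y,
dorsoventral thickness along z, ventral face toward +z. Three features are
added on top of the ellipsoid:

* **Beak taper.** For the stalk half (x < −0.1·L/2) the cross-section is
  narrowed quadratically, reaching a factor `1 − beak_fraction` at the tip.
  The taper breaks fore–aft symmetry, which pose canonicalization exploits.
* **Fore–aft asymmetry.** A small cubic modulation shifts the widest
  cross-section away from mid-length, as in real pips.
* **Ventral infold grooves.** Two Gaussian-profile dents in the +z face at
  y = ±`infold_separation`/2, with σ = max(0.08, 0.12·separation) mm and
  depth `infold_depth`. The distance between the groove minima is the DVI
  (distance between ventral infolds) that the morphometry module measures.
  The groove dent sits on the sloping ellipsoid dome, which pushes the
  analytic minima slightly outward of ±separation/2 (≈ +0.015 mm per side
  at Cabernet-like geometry); this is inherent to carving grooves into a
  curved surface and is kept, since the same effect operates on real pips.

Isotropic surface jitter (default SD 0.01 mm) emulates scanner roughness.
All generation is deterministic given `rng_seed`.

### Charring deformation

Charring is modeled as anisotropic affine shrinkage plus stochastic crack
dropout:

* **Shrink factors.** For each calibrated variety, temperature and
  duration, the length factor is the tabulated mean charred length divided
  by the mean fresh length, and likewise for width (applied to y and z).
  Length shrinks faster than width above 250 °C, so L/W falls — the
  package's central deformation signal. Between tabulated temperatures the
  factors interpolate linearly at fixed duration; conditions outside the
  calibrated grid (e.g. 150 °C, or durations other than 2 h and 8 h) are
  refused rather than extrapolated.
* **Per-seed variability.** The tabulated SDs are converted to CVs and
  drawn as multiplicative noise. Fresh variability is decomposed into a
  shared size factor plus independent length and width parts such that the
  simulated L, W *and* L/W spreads all match the tabulated SDs — purely
  independent L and W noise would over-disperse the ratio. Where the
  tabulated ratio SD exceeds what independence allows, the shared
  component is capped at zero. Charred batches add the residual
  condition-specific CV beyond the fresh spread.
* **Cracks.** Intensity follows 0.3·(T − 250)/100, truncated to zero below
  300 °C (no cracks at mild charring; noticeable at 300 °C, widespread at
  350 °C; 8 h runs 20% stronger). Cracks remove points with that
  probability inside 2–4 random transverse bands of 0.1 mm width and
  jitter the surviving neighbourhood by 0.02 mm.

The DVI column of the calibration table behaves non-monotonically across
charring conditions and the mechanism is not understood; the generator
carries the fresh groove separation through the width shrink factor and
makes no attempt to reproduce those trends.

### The variety panel

Two varieties (Cabernet Sauvignon, Tzuriman S) take their fresh dimensions
and all shrinkage from the calibration table. The dorsoventral thickness,
which the table does not report, is set so the two cultivars differ in
relative plumpness (H/W ≈ 0.71 vs 0.83). The other three panel members
(`V9043`, `V98`, `V138`) are synthetic stand-ins — the real cultivars'
scans are not available — designed the way a real reference panel behaves:
distinct along several normalized axes at once (width per unit length
0.54–0.87, plumpness, groove separation and depth, beak taper). Because the
generator scales height with the per-seed width factor, H/W is noise-free
within a variety, making plumpness a reliable discriminant, as overall
silhouette is for real pips. A panel clustered more tightly than the
per-seed shape noise would make variety classification impossible by
construction, contradicting the observed high accuracy of mild-charred
classification that the package is built to reproduce qualitatively.

## Scanning and preprocessing

`simulate_scan()` projects a canonical cloud onto a pixel grid, keeping the
maximum height per pixel (heights are shifted so the lowest point maps to
0.001 mm; background is exactly 0). `scan_to_cloud()` inverts it: one point
per foreground pixel, scaled by the scanner intrinsics, with 0-based pixel
indices and pixel centers at integer coordinates. Coordinates are mm
throughout, right-handed, ventral toward +z.

`canonicalize_pose()` centers the cloud and aligns the principal axes of
the scatter to (x, y, z) in decreasing variance. Sign conventions: the
outer x-quartile with the smaller cross-sectional spread (the beak) points
to −x, ties keeping +x; the z side whose points sit closer to the midplane
(the grooved ventral face) points to +z; y completes a right-handed frame.
Fewer than 3 points or a rank-deficient scatter is an error.

`normalize_length()` multiplies all coordinates by `target_length/length`
(default target 1 mm — the choice is arbitrary since every downstream
feature is scale-free; it is configurable). This is the equal-length
presentation used before registration so that similarity reflects shape
rather than size; it leaves L/W and W/DVI unchanged and is idempotent.

## Morphometry

Length is the x extent. Breadth is the widest cross-section: the maximum y
extent over thin x slabs (slab = 2% of length). DVI is measured on a wide
transect (25% of length, centered at the widest slab — the grooves run
along the body, so the wide slab stabilizes the profile without moving the
minima): ventral-half points are binned in y (48 bins), the *mean* height
per bin forms the profile — a symmetric box filter; a max-per-bin envelope
is a morphological dilation that displaces dips outward on the sloping
dome and was rejected for that reason — smoothed with a 3-bin moving
average. The grooves are the interior local minima nearest the midline
ridge on each side, restricted to the central 70% of the breadth, refined
by a local parabola. A ridge prominence below 0.35% of the length (≈ 0.02
mm on a fresh pip) means no detectable grooves: DVI is reported missing
(`NA`), distinct from an error, as on a grooveless ellipsoid. Reliable DVI
wants roughly 1000+ points per cloud; L and W are stable from a few
hundred. All internal scales are proportional to cloud length, so
measurements commute exactly with uniform rescaling and ratios are scale
invariants.

Batch summaries report both the mean of per-seed L/W ratios and the ratio
of mean L to mean W; these differ in general, and the per-seed mean is the
statistic used for curve calibration.

## Registration and classification

`icp()` is classic point-to-point ICP: brute-force nearest-neighbour
correspondences (ties to the lowest index), Kabsch/SVD rigid update with
reflection correction, iterated until the relative MSE change falls below
1e-6 (with an absolute 1e-12 mm² floor so exact alignment terminates) or
50 iterations. The reported MSE — mean squared nearest-neighbour distance
under the final transform — is non-increasing across iterations, the
classic guarantee, asserted in tests. ICP is local: from an identity start
the convergence basin on surface-sampled pips is a few degrees, which is
precisely why the pipeline canonicalizes pose first. MSE is directional
(source into target); the similarity matrix entry [i, j] registers pip i
into pip j and is not symmetrized. No correspondence trimming is applied
by default. The inner loop is compiled (RcppArmadillo) because the
classifier needs all ordered pairs.

Similarity features are the rows of the pairwise MSE matrix. Each training
column is z-scored; the same training parameters normalize the test rows;
zero-variance columns map to zero. The classifier is scatter-matrix LDA
with ridge regularization S_w + γ·mean(diag(S_w))·I, γ = 1e-3 by default —
necessary because the feature dimension equals the number of training pips,
so S_w is singular; regularization was preferred to a pseudo-inverse for
stability. The projection is the top C−1 generalized eigendirections
(computed by Cholesky whitening to keep the problem symmetric), prediction
is nearest class centroid, ties to the first training label.

The tournament draws, per session, a stratified 80% subsample of the
training pool, builds the train and test blocks from a cached all-pairs
MSE table (cached and recomputed sessions are asserted identical), fits,
classifies the full test pool, and accumulates accuracy and a confusion
table over sessions. Everything is reproducible from one seed; per-session
seeds are derived by a fixed integer recurrence, so enlarging the session
count does not disturb earlier sessions.

The training library condition defaults to 200 °C / 2 h. One source
describes the training charring as 220 °C; the package treats the
condition as configuration, with 200 °C / 2 h as the default consistent
with the calibration grid.

## The charring curve and triage

The mean L/W ratio of charred seeds is fitted as r = a·x² + b by ordinary
least squares, with x = (T − 200)/150 mapping the calibrated range to
[0, 1]. This x mapping was chosen because refitting the packaged 16
condition means under it reproduces the published coefficients (−0.28,
1.44) within rounding; fresh seeds are excluded from the fit, consistent
with the same check. Durations enter only through which condition means
are supplied.

Inversion: for r ≤ b, x̂ = sqrt((b − r)/−a) and T̂ = 200 + 150·x̂;
extrapolation beyond 350 °C is permitted (ratios near 1 land well beyond
the calibrated range and signal drastic charring). Ratios above the
intercept clamp to x = 0 and are *accepted* with an explicit reason code:
they indicate milder-than-calibration charring, not damage. Sorting
accepts a pip when T̂ ≤ 275 °C — the upper edge of the range where
classification stays accurate — with the boundary counting as accepted
(comparison tolerance 1e-12 relative, absorbing inversion round-off).
Estimation is exactly monotone: lower ratio, higher temperature, so
acceptance is monotone in the ratio.

The sorter estimates a single temperature per pip; temperature and
duration are not jointly identifiable from one ratio, and no W/DVI-based
sorting is attempted.

## Group statistics

`two_way_anova()` wraps the balanced fixed-effects Type I decomposition
(via `stats::aov`, exact on balanced data); unbalanced designs are refused
with a clear error rather than silently switching SS types, and a single
replicate per cell drops the interaction term. All-constant responses
report F = 0, p = 1 instead of 0/0. `tukey_kramer()` computes the
studentized-range statistic with the Kramer unequal-n correction, with
tail areas from `stats::ptukey` rather than printed tables.
`compact_letters()` uses insert-and-absorb, and its defining invariant —
two groups share a letter exactly when their comparison is non-significant
— is property-tested over random significance patterns.

## Problem sizes and reproducibility

The packaged experiments and tests run at deliberately modest scales,
chosen as the smallest sizes at which each qualitative claim is stable:
clouds of 300–800 points (2000 for DVI-accuracy checks), 5 varieties × 10
pips for tournament experiments, 20-pip test batches (the study-scale test
size), 25 sessions, 100-pip sorting pools, and 2000 replicates for the
ANOVA type-I calibration. Every stochastic step takes an explicit integer
seed, and the pipeline fans a single experiment seed out to stages by a
fixed derivation, so reports are identical across runs of the same
configuration.

## What the synthetic experiments do and do not show

The generator reproduces the calibrated, population-level regularities:
mean dimensions and their spreads per charring condition, the fall of L/W
with temperature, crack onset, and a variety panel separable at mild
charring and progressively confusable as deformation accumulates. Within
it, the pipeline's properties — measurement invariances, registration
guarantees, classifier degradation with test charring temperature, curve
inversion and triage behaviour — are demonstrated end to end.

It does not reproduce individual-level shape richness: real pips carry
fine surface structure, within-variety covariances and post-depositional
alterations that a seven-parameter shape family cannot express. The
published per-condition classification percentages depend on scans of real
reference varieties and are not recoverable from synthetic data; what the
package asserts about classification is the qualitative regime — high
accuracy at ≤ 250 °C, monotone degradation toward 300 °C — not the exact
figures. Likewise the 54/100 acceptance split of the real archaeological
assemblage is emulated only as a generating mix; the sorter recovers it
approximately because the mild and harsh ratio distributions genuinely
overlap near the threshold, in the simulation as in reality.
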