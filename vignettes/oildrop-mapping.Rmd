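---
title: "Mapping essential-oil droplets across root cross-sections"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping essential-oil droplets across root cross-sections}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(oildrops)
```

## The measurement problem

Valerian (*Valeriana officinalis*) roots store their essential oil in
discrete droplets. Where those droplets sit in a root cross-section —
hugging the outer cell layers or spread through the inner parenchyma —
decides how much oil survives mechanized harvesting and washing, and
therefore matters to breeders selecting coarse-rooted, high-oil genotypes.
Stained thin slices photographed under a fluorescence microscope show the
droplets as bright round bodies on a dark background; the quantitative
question is how droplet counts and densities vary with radial position,
genotype, root diameter and harvest depth.

Two properties of real slices shape the method. First, slices are not
circles: they are oval, lobed, sometimes coved. An absolute radial
coordinate would make a droplet 0.8 mm from the center "deep inside" a
thick slice and "outside" a thin one. Second, slice area grows
quadratically towards the rim, so raw counts per radial band overstate the
rim unless normalised by band area.

## The radial model

Every droplet is reduced to its centroid $(x_i, y_i)$. With the manually
marked slice center $(x_C, y_C)$ as origin,

$$x_{mod} = x_i - x_C, \qquad y_{mod} = y_i - y_C,$$
$$r = \sqrt{x_{mod}^2 + y_{mod}^2}, \qquad
  \varphi = \arccos\!\left(\frac{x_{mod}}{r}\right),$$

where the arccos form covers the upper half-turn and is extended to
$[0, 2\pi)$ by the sign of $y_{mod}$ (pixel frame, $y$ downward; the same
convention applies to droplets and edge points, so any consistent choice
gives the same result). The ray from the center through the droplet is
intersected with the slice's edge contour; with $r_{CD}$ the
center-to-droplet and $r_{CE}$ the center-to-edge distance along the same
angle, the *relative distance* is

$$pp = \frac{100\, r_{CD}}{r_{CE}} \in [0, 100].$$

$pp$ is dimensionless and invariant under translation, rotation and
uniform scaling of the whole slice, which is what makes slices of
different sizes and shapes comparable. The $[0,100]$ range is divided into
nine equal classes of width $100/9 \approx 11.11$: class
$k = \min(\lfloor 9\,pp/100 \rfloor, 8) + 1$, half-open intervals with
class 9 closed at 100. Exact multiples of $100/9$ belong to the upper
class. Class 1–2 cover the central cylinder, 3–8 the parenchyma, 9 the
outer cell layers.

Per class the pipeline reports the droplet count and the droplet *density*
(count / class area in droplets/mm²). Class areas are measured pixel-wise:
every pixel center inside the edge polygon gets its own $pp$, and the nine
classes partition the interior exactly. This matches how areas behave for
concave contours, where an idealised shrunken-polygon model would not.

### Coved contours

A ray from the center can cross a coved contour more than twice. We take
the **farthest** intersection as $r_{CE}$. This keeps $pp$ monotone in
$r_{CD}$ along a ray and bounded by 100; a droplet sitting in a cove is
reported as deep tissue rather than "on the edge". Rays with more than two
crossings are flagged in the radial table (`ray_crossings`). Droplets
marginally outside the contour — a segmentation halo effect — are clamped:
$pp \in (100, 105]$ becomes 100 with a warning, $pp > 105$ is treated as a
center/edge pairing error and fails the slice.

## Segmentation

The droplet mask is produced by: conversion to 8-bit grayscale (green
channel by default, since the droplets fluoresce green; luminance
weighting is available), a median filter (radius 1 px), a grayscale
dilation (3×3), and the Huang fuzzy-entropy threshold. For a candidate
level $t$, pixels on each side get membership
$u = 1/(1 + |g - \mu_{side}|/C)$ with $\mu_{side}$ the side's mean gray
value and $C$ the histogram's gray range; the chosen $t$ minimises the
total Shannon entropy $\sum h(g) S(u(g))$. Ties take the lowest level. The
implementation is verified against an exhaustive scan of all candidate
levels in the test suite. Two practical notes:

* The fuzzy-entropy minimum tends to sit at the edge of the dominant dark
  mode rather than midway between modes; that is a property of the
  criterion, not a defect, and the oracle equivalence test pins it down.
* On a composed whole-slice image the black area *outside* the slice forms
  a second dark mode that dominates the objective and pulls the threshold
  between "outside" and "tissue". The batch pipeline therefore computes
  the threshold from the histogram of slice-interior pixels only
  (`binarize_droplets(region = )`). The interior itself comes from Otsu
  thresholding of the median-smoothed image (tissue autofluorescence vs.
  black background), hole filling, and keeping the largest component.

Connected components are labelled with 8-connectivity (the complementary
4-connectivity applies to background, the standard pairing that avoids
topological paradoxes). Components are filtered by area
(default $\geq 5$ px², unbounded above) and circularity
$4\pi A / P^2$ (default band $[0.3, 1]$), with the perimeter estimated
from the boundary chain code with the standard 0.95 smoothness correction
and circularity clipped at 1. The size/circularity defaults are exposed in
`segmentation_params()`; the source protocol states that such filters were
used but not their values, so these are deliberate, documented defaults —
not calibrated constants.

## Statistics

Factor levels (genotype CE1–CE4, root classification thin/thick, diameter
fraction RF1–RF4, horizon HZ1–HZ3) are compared on two things:

* **Class distributions.** The nine classes act as blocks and the factor
  levels as treatments on the level-mean per-class values: the Friedman
  test (mid-ranks, standard tie correction, chi-square p) for three or
  more levels; the paired Wilcoxon signed-rank test over the nine class
  pairs for two levels (zero differences dropped, exact distribution for
  the small n involved). Both are rank-based, hence invariant under
  monotone transforms of the counts.
* **Total densities.** Per-slice total density (droplets/mm² over the
  whole cross-section) feeds a fixed-effects one-way ANOVA; two-level
  factors are equivalently a pooled t test ($F = t^2$), with a Welch
  option. Post-hoc separation uses the Student–Newman–Keuls stepwise
  studentized-range procedure at $\alpha = 0.05$ with the SNK protection
  rule (non-significant ranges are not subdivided) and harmonic-mean group
  size for unbalanced designs, reported as compact letters.

All p-values are reported raw; no cross-factor multiplicity correction is
applied, mirroring the analysis this package operationalises. Which margin
of the data enters the Friedman test is a genuine design choice — we block
on classes and treat levels as treatments because it makes two-level
factors reduce naturally to the paired Wilcoxon — and is documented
rather than asserted as the only reading.

## The synthetic generator

No micrograph corpus is distributed with the package, so every claim the
tests make rests on `synthetic_slice_spec()` and friends, which emulate:

* an irregular closed edge: $r(\theta) = R(1 + \sum_{j=2}^{6} a_j
  \cos(j\theta + \varphi_j))$ with $\sum |a_j| < 0.35$, keeping the
  contour star-shaped about the true center (real coves exist but the
  generator stays in the regime where truth is analytic);
* a known radial droplet layout: per class $k$ a Poisson($\lambda_k$)
  count, positions drawn uniformly in angle and uniformly in $pp$ within
  the class band, with a minimum separation of two droplet diameters;
* photometry: Gaussian-profile droplets ($\sigma$ = radius/2) at peak 220
  on tissue background 30, Gaussian read noise (SD 8) and rare hot pixels,
  clipped to 8 bits.

Defaults are fixed once at study-like conditions: 640 px frames, mean
radius 260 px, scale 3.3 µm/px, droplet radii 2–4 px (≈ 1:100
droplet-to-root scale as under a 100× objective), and
$\lambda = (0, 0.5, 4, 6, 8, 10, 13, 15, 43)$ — a nearly droplet-free
central cylinder, a graded parenchyma, and about 43% of droplets in class
9, the distribution reported for real valerian material.

What the generator does **not** emulate: cell-wall texture, tile seams
from manual mosaicking, vignetting, non-star-shaped coves, droplet size
gradients, or intensity variation across tissue depth. Passing the
synthetic benchmarks therefore demonstrates the correctness of the
geometry, binning, counting and statistics, and the behaviour of the
segmentation under controlled noise — not segmentation robustness on
arbitrary real micrographs.

## Numerical choices

* Coordinates are 0-based pixels, origin top-left, x rightward, y
  downward; images are width × height matrices.
* Ray–segment intersection uses a half-open parameter band
  $s \in [-10^{-9}, 1 - 10^{-9})$ so a ray through a shared polygon vertex
  registers on exactly one adjacent segment.
* The per-pixel $pp$ map evaluates $r_{CE}$ on a 2048-ray lookup table
  with circular linear interpolation; for smooth contours the induced
  error is far below the 1% class-area tolerance (measured ≈ 0.03% on a
  rasterized disk).
* Display means are rounded half away from zero; all computation is in
  full precision. SDs are sample (n−1) SDs; single-slice levels report
  SD 0 and are flagged.
* Degenerate inputs error early with typed conditions: single-bin
  histograms, empty masks, centers outside the polygon, droplets > 105%
  of the edge radius.
* All randomness flows through explicit integer seeds; batch slices use
  `base seed + 10·i`, and generator functions restore the caller's RNG
  state.

## Problem sizes used in validation

The bundled tests validate on 256 px slices (fast paths) and on 30
full-size 640 px slices end-to-end; the statistical calibration uses a
2000-replicate ANOVA null, a 10 000-permutation Friedman null, and exact
enumeration of the $2^9$ Wilcoxon sign patterns. The geometry oracle
compares 100 star polygons × 360 angles against a dense contour
resampling. These sizes were chosen so the whole suite runs in minutes on
one core while keeping every Monte-Carlo band at three standard errors.

## Known limitations

* The center is an input, not an estimate; a misplaced center biases $pp$
  towards the displacement direction. The robustness tests budget ≤ 3 px.
* Densities are comparable across slices only when the metadata scale
  (µm/px) is correct per slice; no calibration is inferred from images.
* For heavily coved slices the farthest-intersection rule assigns
  cove-adjacent droplets conservative (low) $pp$; an alternative
  nearest-intersection reading would instead place them on the edge.
  The multiplicity flag lets users audit affected droplets.
* Huang thresholding assumes bright droplets on a darker, roughly
  unimodal tissue background within the analysed region.
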