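---
title: "Quantifying reversible perfusion defects on polar maps: methods"
author: "polarQuant"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying reversible perfusion defects on polar maps: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(polarQuant)
```

## The problem

Myocardial perfusion SPECT compares tracer uptake in the left ventricle at
stress and at rest. Territory that is hypoperfused at stress but recovers at
rest is *reversibly ischemic*, and current revascularization guidelines hinge
on how large that territory is: patients with more than about 10% of the left
ventricle ischemic are recommended for revascularization. The number that
matters clinically is therefore the *extent* of the reversible defect as a
percentage of the left ventricle, together with segmental summed scores.
Different readers and different software packages disagree substantially on
this number, which is why the quantification itself, and the statistics used
to measure agreement between readers, both belong in one toolkit.

polarQuant implements that toolkit on *polar maps* (bullseye plots): 2-D
circular projections of the left ventricle with the apex at the centre and
the base at the rim.

## Polar geometry and the 17-segment model

A `PolarGrid` has `nTheta` equal angular bins and `nRadial` equal-width
radial bins. The default is 64 x 32: much finer than the 17 segments, coarse
enough that an active contour runs in milliseconds. The angular origin is the
3-o'clock position, counterclockwise; matrices are stored rows = radial bins
(apex first), columns = angular bins, and this convention is the interchange
contract of the CSV format.

Cell area weights follow the polar Jacobian: with equal radial spacing the
ring areas are $r_j^2 - r_{j-1}^2$, split evenly over the angular bins and
normalised to sum to 1. Extent is "% of left ventricle", and counting cells
equally would over-represent the apex by an order of magnitude, so every
extent in the package is area-weighted. Commercial packages differ on this
point, which is one of several reasons their extents differ.

The 17-segment model uses four radial bands at radius fractions
0/0.25/0.5/0.75/1 (apex, apical, mid, basal) with a 1/4/6/6 angular split;
basal and mid segments are 60 degrees wide anchored so the anterior segment
spans 60-120 degrees, apical segments are 90 degrees anchored at 45 degrees.
No published layout accompanies the quantification this package models, so
the anchor table in `segmentModel17()` is the package's own fixed,
documented convention; any fixed layout supports the summed-score
arithmetic.

## The synthetic-study generator

There is no public corpus of stress/rest polar-map pairs with ground-truth
delineations, so the generator is a first-class module: it defines the
conditions under which every recovery claim in the test suite is made.

A `DefectSpec` is a separable angular x radial profile with a raised-cosine
edge: the profile is 1 in the core, exactly 0.5 at the stated half-widths,
and 0 at half-width + `edgeSoftness`. The two axes are combined with `min`,
so the set where the profile exceeds 0.5 is exactly the product of the two
half-width intervals - which makes ground truth unambiguous
(full-width-half-maximum convention) and lets axis-aligned cases be checked
against closed-form sector-annulus areas. Stress uptake over a uniform
baseline of 100 is reduced by `severity * profile`; rest uptake by
`severity * (1 - reversibility) * profile`; overlapping defects combine
multiplicatively. Noise is multiplicative Gaussian with SD proportional to
the signal, a desk-scale stand-in for Poisson count noise after filtered
back-projection; the default noise level in the recovery studies is drawn
from 0-5%, a realistic range for reconstructed, normalized polar maps.

What the generator does *not* emulate: coronary-territory defect shapes,
attenuation and reconstruction artefacts, apical thinning, and
normal-database variability between patients. Passing recovery tests
therefore show that the pipeline is correct and well-conditioned on
plateau-like defects with known truth - not that it matches clinical
readings on real studies.

Rater panels are drawn from the additive two-way model $y_{ij} = \mu + p_i +
o_j + e_{ij}$ with independent normal patient, observer and residual
effects, so the implied single-rater ICC
$\sigma_p^2/(\sigma_p^2+\sigma_o^2+\sigma_e^2)$ is known exactly. Values are
clipped to [0, 100] because extents are percentages; clipping truncates the
patient effect distribution and biases the ICC slightly downward, so the
count of clipped cells is carried on the panel object rather than hidden.
The default simulation (patient SD 15, observer SD 5, residual SD 5, grand
mean 20) clips roughly 10% of cells and recovers the implied ICC of 0.818
to within about 0.02 on average.

## Two-stage delineation

Stage 1 finds *stress defects*. Seeds are strict local minima (8-neighbour,
angular wrap-around, one-sided at the radial edges) of the normalized stress
map below a depth threshold of 70% of maximum; plateau minima collapse to
their centroid cell. From each seed an active contour of circular topology
is fit by greedy descent on the energy

$$E = \alpha \sum_k |v_{k+1}-v_k|^2 + \beta \sum_k |v_{k+1}-2v_k+v_{k-1}|^2
- \gamma_e \sum_k |\nabla I(v_k)| + \gamma_i \int_{\mathrm{int}} (I - L)\,dA$$

with $I$ the normalized uptake and $L$ a reference level equal to the depth
threshold. The first three terms are the classical membrane, thin-plate and
gradient-magnitude edge terms. The intensity term is deliberately a *region*
integral rather than a sum of $I$ over the vertices: low uptake attracts the
contour interior, uptake above $L$ repels it. A vertex-sampled intensity
term supplies no expansion force across the flat core of a plateau-shaped
defect (a greedy snake initialised as a small circle simply stays put in a
zero-gradient region), and a constant balloon pressure does not self-limit
in flat normal territory; the region term does both, halting expansion where
uptake crosses $L$, with the edge term then locking the contour onto the
gradient ridge.

The fit is star-shaped: vertex $k$ moves along a fixed ray from the seed, so
the polygon is closed, never self-intersects, and always contains its seed.
Greedy coordinate descent (one radius at a time, candidate moves of one step
in or out) makes the energy trace non-increasing by construction. Steps are
annealed 1, 1/2, 1/4 cells so vertices settle on the gradient ridge at
sub-cell precision; iteration ends when the energy change falls below `tol`
(1e-4) or at `maxIter` (500), in which case the contour is flagged
unconverged rather than raising an error.

Each region mask is the rasterized contour (cell centre inside the polygon,
even-odd rule, angular coordinate unwrapped once around the seed) *united
with* the seed's connected component of cells below the depth threshold. The
union matters in one specific situation: a discrete polygon minimising a
membrane energy slightly undercuts the corners of a plateau-shaped defect
(corner-cutting is intrinsic to snakes), and the sub-threshold component
restores exactly those cells while adding nothing on smooth defects, where
the contour is the better boundary estimate. Overlapping region masks are
merged (union, contours retained as provenance) and regions under
`minAreaCells` (4) are dropped as noise.

Stage 2 extracts the strictly reversible *difference defects*. The
rest-stress difference image (both maps normalized to percent of maximum) is
Gaussian-smoothed with `sigma` = 2 cells (circular in theta, reflected in
r); within each stress-defect mask separately, cells with smoothed
difference above `revThreshold` = 10 percentage points are selected and
split into connected components. Selecting within each parent mask
guarantees the containment invariant - every difference defect is a subset
of its parent stress defect - by construction. The threshold is absolute,
not adaptive per defect severity: an absolute threshold is reproducible and
makes the stage-2 output equal, on noise-free sharp-edged defects with
smoothing disabled, to plain thresholding of the difference image - an
equivalence the test suite checks cell for cell. An adaptive variant can be
had by passing a different `revThreshold`.

All delineation constants (`depthThreshold` 70%, 32 vertices, $\alpha$ 0.1,
$\beta$ 0.05, $\gamma_e$ 1, $\gamma_i$ 1, step 1 cell, `tol` 1e-4,
`maxIter` 500, `sigma` 2 cells, `revThreshold` 10 pp, `minAreaCells` 4) are
package configuration with no published provenance, exposed through
`delineationParams()`.

## Quantification

Extent is the area-weighted percent of the union of difference-defect masks
- the union prevents double counting, an empty delineation gives 0, and the
full disc gives 100. Segment scores bin each segment's area-weighted mean
uptake into 0-4 using uptake bins (>= 70 scores 0; 55-69: 1; 40-54: 2;
25-39: 3; < 25: 4). Commercial tools score against normal databases, which
are not publicly available; these transparent bins are the package's
documented stand-in and are configurable. SDS sums the per-segment positive
part max(stress - rest, 0), and SD% = 100 SDS / 68, the summed difference
score against the total possible score from 17 segments. Extent and SD% are
computed by independent routes - delineated area versus binned segment means
- so a study can legitimately show nonzero SD% with zero extent, as happens
in practice.

## Agreement statistics

The ICC is the single-rater, absolute-agreement intraclass correlation from
a two-way random-effects model (patients and observers random): variance
components come from the ANOVA mean squares by method of moments, negative
estimates are truncated to zero before forming
$ICC = \sigma_p^2/(\sigma_p^2+\sigma_o^2+\sigma_e^2)$, and the 95% CI is the
F-based interval with Satterthwaite denominator degrees of freedom. The
F-based interval was chosen over likelihood profiling because it is the
standard closed form for this design; a REML fit of the same model (via
lme4) is available behind `method = "reml"` for the point estimate, and the
two agree to about 0.02 on simulated panels. A constant panel has no
variance to apportion; it returns ICC 1 with a degenerate [1, 1] interval
and an explicit flag. "SD between observers" is reported as
$\sqrt{\sigma_o^2}$, the component-based reading; the SD of observer means
is attached as an attribute because the phrase is ambiguous and the two
estimators differ in finite samples.

Bland-Altman analysis reports test - reference differences, mean bias,
limits of agreement at bias +/- 1.96 sample SD, and the per-point bounds of
the attainable difference (extents live in [0, 100], so no difference below
-reference is possible - the diagonal line in the plots).

The Wilcoxon signed-rank test drops zero differences and midranks ties; the
exact two-sided p-value is computed by convolution over the doubled midranks
(equivalent to enumerating all sign assignments, and valid under ties) for
up to 20 nonzero pairs, with a continuity-corrected normal approximation
(variance $\sum r_i^2/4$) beyond. The exact distribution is the default
because the panels this package targets have ~25 patients, where n after
dropping zeros is often within exact range.

Method contrasts are restricted to complete balanced designs, where the
fixed-effect contrast of the corresponding linear mixed model (method fixed,
patient random) reduces algebraically to the paired mean difference across
patients with a paired t-test; unbalanced input is refused with an explicit
error rather than silently approximated, because the closed form no longer
holds there.

## Problem sizes and numerical choices

The recovery studies used throughout the tests and the acceptance script
are: 50-seed Monte-Carlo panels of 200 patients x 11 observers for ICC and
observer-SD recovery; 50 replicates of 25 x 11 panels for the
second-read-shrinkage property; and 50 synthetic studies (true extent 5-40%
of LV, severity 0.5-0.8, noise 0-5%) for extent recovery, where the
observed median absolute error is under 2 percentage points against a
tolerance of 3. These sizes give stable Monte-Carlo means while keeping a
full run in the order of a minute.

Degenerate inputs are handled explicitly rather than by convention-free
arithmetic: all-zero maps refuse to normalize; a constant panel flags its
degenerate ICC; a single observation reports a zero-variance flag instead of
an undefined SD; identical paired vectors return a no-test Wilcoxon result
with p = 1. Ties in the greedy descent keep the current vertex position, so
reruns are bit-identical; all simulation randomness is seeded through
`withr::with_seed`, leaving the caller's RNG state untouched.

## Known limitations

Synthetic defects are separable angular x radial blobs, not
coronary-territory shapes; the scoring bins are uptake thresholds, not
normal-database z-scores; the delineation constants were chosen on the
synthetic conditions above and will need re-tuning for maps from a
different reconstruction chain; and the agreement layer requires complete
panels - missing readings must be handled upstream.
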