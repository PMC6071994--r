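---
title: "Quantifying neural stem cell migration in brain histology"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying neural stem cell migration in brain histology}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nscmigration)
```

## The problem

Intracranially injected neural stem cells (NSCs) do not spread
isotropically: they preferentially migrate along myelinated white-matter
(WM) tracts such as the corpus callosum and accumulate near WM/grey
matter (GM) interfaces.  Quantifying this on 2-D histology requires four
ingredients, which this package implements as one pipeline:

1. a per-pixel map of local **tissue orientation and anisotropy** from a
   myelin-stain channel (structure-tensor analysis);
2. **cluster geometry**: detected NSC clusters, coalesced into regions
   whose fitted curves yield a per-cluster tangent orientation
   $\theta_{NSC}$;
3. **distance statistics**: cluster-size-weighted cumulative probability
   distributions (CPDs) of distance from the injection site and from the
   nearest WM/GM interface, and the weighted percentage of NSC signal in
   WM;
4. a **stochastic migration simulator** that follows the WM orientation
   axis inside tracts and reorients randomly in GM.

Because the original stained sections are not publicly deposited, the
package ships a synthetic-phantom module with exact ground truth; every
claim a test makes is validated against that stated world, not against
the in-vivo numbers.

## Structure tensor: model and conventions

For an intensity image $I(x,y)$ the structure tensor is the
Gaussian-windowed outer product of gradients,
$J = G_\sigma * (\nabla I\, \nabla I^\top)$, a symmetric 2x2 matrix per
pixel with eigenvalues $\lambda_{max} \ge \lambda_{min} \ge 0$.  Its
**coherence**

$$C = \frac{\lambda_{max} - \lambda_{min}}{\lambda_{max} + \lambda_{min}}$$

is 0 for locally isotropic texture and 1 for a single dominant
orientation.  Gradients default to natural cubic-spline derivatives
(`central_difference` is kept as a cross-check; both agree within 5% on
smooth input).  Two window widths matter in practice: $\sigma = 1$ px
for orientation/coherence maps and $\sigma = 5$ px for the smoother
field the simulator follows; both are exposed.

One convention deserves emphasis. The eigenvector of $\lambda_{max}$
points *across* the local texture (along the gradient); the tissue —
fibres, ridges, tracts — runs along the perpendicular axis.
`eigen_orientation()` exposes both (`axis = "dominant"` /
`"structure"`), and the user-facing `orientation_field()` reports the
structure axis, so a stripe pattern drawn at 30 degrees is recovered as
30 degrees:

```{r stripe}
img <- make_stripe_image(c(96, 96), period_px = 8, angle_deg = 30)
f <- orientation_field(img, window_sigma_px = 1)
c(theta = field_modal_orientation(f),
  coherence = mean(f$coherence[f$valid]))
```

Angles are axial (degrees on [0, 180), from the positive x axis, y
pointing down the image rows); axial data are averaged by angle
doubling (`mean_axial_orientation()`), so 179 and 1 average to 0, not
90.  Degenerate pixels (equal eigenvalues, flat patches) get
$\theta = 0$, $C = 0$ and are flagged in a validity mask, as are pixels
within $3\sigma$ of the border where the smoothing window is truncated.

## Synthetic phantoms: what they emulate, and what not

`make_tract_phantom()` builds a two-channel section: a DiI-like channel
with a band of ridge texture around a polynomial centreline $y = f(x)$
(texture phase = vertical offset from the centreline, so its level sets
run parallel to the local tangent and the analytic tangent
$\arctan f'(x)$ is per-pixel ground truth), embedded in low-amplitude
isotropic noise (GM).  `plant_clusters()` adds sharp-edged elongated
blobs whose ground-truth axial angle is the local tract tangent plus
uniform angular noise scaled by $1 - \mathrm{alignment}$: alignment 1
reproduces the tangent exactly; alignment 0 is uniform on [0, 180).

Two generator design points:

* **Chains.** $\theta_{NSC}$ is defined through coalesced-*region*
  fits, and a single cluster centre coalesces to a near-circular disk
  that the circularity filter rightly excludes.  Orientation recovery
  therefore needs multi-cluster regions: `chain_size > 1` lays clusters
  out spatially along the truth direction.  The default
  (`chain_size = 1`) keeps planted angles independent for
  distributional checks.
* **Validation power.** For the regression validation we use 20 chains
  of 4 on a 256x2000 phantom with tangents spanning about +/-18
  degrees.  With $k$ independent chains the null $r^2$ of the
  $\theta_{NSC}$-on-$\theta_{WM}$ regression has expectation
  $\approx 1/(k-1)$, so $k = 20$ puts the expected null mean (~0.05)
  well below the 0.1 acceptance bound.  This is a statistical-power
  choice, fixed before measuring, not a tuned constant.

The phantoms do **not** emulate staining artifacts, tissue tears,
section registration, 3-D structure, or realistic section dimensions
(unknown from the source); a green test establishes that the *methods*
recover a known truth under clean conditions, not that the in-vivo
numbers are reproduced.

## Cluster geometry

Clusters are connected components above an intensity threshold (Otsu by
default — the original colour/intensity cuts are unstated), centred at
the intensity-weighted centroid, weighted by pixel area.  Centres are
dilated by 200 px and eroded by 100 px (defaults; Euclidean disks
realised exactly through a Felzenszwalb distance transform) to form
coalesced regions.  Regions with circularity $4\pi A/P^2 > 0.7$ are
excluded from orientation analysis.  The perimeter uses the
Vossepoel–Smeulders corrected chain length
($0.980\,n_{axial} + 1.406\,n_{diag} - 0.091\,n_{corner}$): a raw
$\sqrt2$-weighted chain overestimates a circle's perimeter by ~5%,
which would push a perfect disk's circularity down to ~0.91 and make
the 0.7 threshold unreproducible.

Each retained region is rotated into its principal frame (long axis as
abscissa $u$ — a function-graph fit $v = au^2 + bu + c$ needs a
well-defined independent axis; the frame is defined up to sign, which
tangent angles are insensitive to).  The nearest point on the curve to
each member cluster is found by 1-px sampling plus golden-section
refinement, and the tangent slope $2au^* + b$, rotated back to the
image frame, gives $\theta_{NSC}$.

## Distance statistics

Distances are 2-D Euclidean, converted at 1.444 um/px by default — the
scale implied by the published 1000 px = 1444 um conversion of the
injection-site exclusion radius.  Clusters at or inside the exclusion
radius are dropped (the boundary case is excluded; the source is silent
and we follow the stricter reading).  The weighted CPD's median is the
smallest value whose cumulative weight reaches 0.5.  Interface distances
are the exact Euclidean distance transform of the WM/GM interface pixel
set (WM pixels with a GM 8-neighbour and vice versa), sampled at
pixel-rounded cluster centres.  Tissue class is the mask value at the
centre pixel; WM% + GM% + unclassified% = 100 exactly.
`wm_mask_from_dii()` smooths before thresholding (default 4 px, about
half the fibre texture period) so the stain *envelope* is segmented
rather than individual fibres — without this, every point sits within a
pixel of a spurious "interface".

## Orientation regression

Each cluster's local $\theta_{WM}$ is the coherence-weighted axial mean
over valid pixels within 25 px with coherence >= 0.2 (the neighbourhood
is not stated in the source; both knobs are exposed).  Pairs are
weighted by the total number of clusters in the pair's coalesced
region.

Wraparound is the delicate part.  Aligning each pair individually
(shifting $\theta_{NSC}$ by $\pm180$ to within 90 degrees of its
$\theta_{WM}$) seems natural but *biases the null*: for unrelated
angles the folded difference is uniform and centred on zero, so
$E[\theta_{NSC}\mid\theta_{WM}] = \theta_{WM}$ and the fitted slope
tends to 1 even for random data.  `correlate_by_tissue()` therefore
folds both angles of all pairs into the single 180-degree window
centred on the weighted axial mean of $\theta_{WM}$: aligned data still
regress with slope 1, independent data stay flat.  The pairwise rule is
kept behind `wrap = "pairwise"`, and both break down if the true angle
spread approaches the full 180 degrees.

## Migration simulator

500 paths (default) start uniformly in a disk around the injection
site.  Each step has fixed length (1 px default):

* **WM with a valid orientation**: the step follows the local
  $\theta_{WM}$ *axis*; since an axis has no sign, the sign keeping a
  non-negative dot product with the previous direction is chosen
  (preventing oscillation); the first step takes a random sign.
* **GM (or degenerate WM pixels)**: the heading turns by a random angle
  whose magnitude is uniform on [0, 180] degrees with equal-probability
  sign — an isotropic reorientation, our reading of "uniform 0–180
  degrees relative to the previous direction".  The literal one-sided
  reading is available as `gm_rule = "signed"`.

Paths stop when they re-enter one of their own 1-px occupancy cells
(self-intersection; paths do not block each other), leave the
brain/image, or exhaust the step budget (5000 default; the source does
not state one).  Everything is reproducible from `rng_seed`.  In the
analytic limits the walk behaves as required: ballistic in uniform WM
(displacement = steps x step length exactly), diffusive in GM
(displacement ~ sqrt(steps), exponent 0.5 +/- 0.1).

## Numerical choices and degenerate inputs

* Gaussian smoothing uses mirror boundaries, kernels truncated at
  4 sigma.
* Erosion treats out-of-image pixels as foreground (regions are not
  eroded from the image edge); dilation treats them as background.
* Flat tensors: coherence defined as 0 when
  $\lambda_{max}+\lambda_{min}$ is numerically zero.
* A rank-deficient quadratic region fit falls back to a flagged
  degree-1 fit; regions under 6 px are not fitted.
* An axial mean with zero resultant (e.g. equal weights at 0 and 90)
  warns and returns 0.
* `weighted_cpd()` forces the final cumulative probability to exactly 1
  against float roundoff.

## Limitations

The analysis is inherently 2-D; leptomeningeal/CSF and intravascular
routes are not modelled; chemoattraction is absent; simulator steps use
orientation only (coherence enters only through validity masking).  The
published in-vivo medians, WM percentages and the slope-0.65 regression
cannot be recomputed without the original sections; this package
reproduces the *methods* and validates them on phantoms.
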