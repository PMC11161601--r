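---
title: "Quantifying organoid-matrix mechanics: methods and design notes"
author: "mechanoquant"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying organoid-matrix mechanics: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mechanoquant)
```

Tumor organoids embedded in fibrillar collagen I pull on, align and tense
the surrounding matrix, and matrix mechanics in turn selects protrusive
leader cells with nuclear Yap. `mechanoquant` implements the image
quantifications this loop is studied with: per-cell Yap
nuclear/cytoplasmic ratios on segmented mid-plane confocal images, the
nematic order parameter of collagen fiber orientations near the organoid
rim, the protrusive index of tumor borders, and drift-corrected bead
displacement toward the organoid body. A synthetic-image generator with
exact ground truth makes every stage testable without microscope data.

## The nematic order parameter

Fiber orientations are *axial*: an axis at $\theta$ and at
$\theta + 180^\circ$ is the same fiber. A sample of orientations
$\{\theta_i\}$ (optionally weighted) is summarized by the second-order
tensor

$$S_2 = \begin{pmatrix} \langle\cos 2\theta\rangle & \langle\sin 2\theta\rangle \\
\langle\sin 2\theta\rangle & -\langle\cos 2\theta\rangle \end{pmatrix},$$

whose eigenvalues are $\lambda_{1,2} = \pm S$ with

$$S = \sqrt{\langle\cos 2\theta\rangle^2 + \langle\sin 2\theta\rangle^2} \in [0, 1].$$

$S = 0$ for uniformly distributed axes, $S = 1$ when all measurements
share one axis, and $S$ is invariant under rotation of the whole sample —
it measures concentration, not direction. Both identities are asserted in
the test suite: the closed form and a numerical diagonalization of $S_2$
agree to $10^{-10}$ on random samples, 180 evenly spaced angles give
$S \le 10^{-12}$, and identical angles give exactly 1.

```{r order-parameter}
order_parameter(seq(-90, 89, by = 1))$S   # uniform axial sample
order_parameter(rep(37, 100))$S           # delta sample
```

When doubled angles follow a von Mises distribution with concentration
$\kappa$, the expected order parameter is the Bessel ratio
$I_1(\kappa)/I_0(\kappa)$ (`vm_order_parameter()`), which
`kappa_from_order_parameter()` inverts to give a model-based
concentration estimate. This relation doubles as the analytic oracle for
the fiber-field generator.

## Orientation fields by the structure tensor

`structure_tensor_orientation()` computes per-pixel orientation and
coherency from the eigenstructure of the smoothed gradient outer
product. Two scales matter:

* `sigma_grad` (default 1 px) regularizes the gradient. Gradients are
  taken with separable derivative-of-Gaussian kernels; plain central
  differences were measured to bias orientations by up to 1.3°
  toward 45°, while the kernel gradients recover synthetic grating
  orientations to better than 0.01°.
* `sigma_window` (default 4 px) averages the tensor. It should sit
  between the fiber width (else no flank gradients are pooled) and the
  inter-fiber spacing (else crossing fibers mix). The default suits
  confocal collagen at common magnifications; the test fixtures, whose
  stamped fibers are ~1.5 px wide, use 1.5 px.

The reported angle is the axis of *least* intensity variation — the
fiber direction — in degrees counterclockwise from the image x-axis
(y up), wrapped to $[-90, 90)$. Coherency
$(\lambda_{max}-\lambda_{min})/(\lambda_{max}+\lambda_{min})$ grades
anisotropy and serves as the default pooling weight. Pixels with
gradient energy below $10^{-6}$ of the image maximum are invalid
(constant images yield no valid pixels rather than noise angles).

Pooling caveat: that floor is permissive, so in sparse fields most
off-fiber pixels remain "valid" through smoothing tails and dilute pooled
statistics. Image-level summaries therefore intersect the validity mask
with an intensity foreground (`fiber_foreground()`, Otsu on the smoothed
channel); `rim_order_profile()` accepts the same mask via its
`foreground` argument.

## Rim ROIs and the alignment profile

`extract_rim_rois()` anchors rectangles along the organoid boundary
contour: 30 µm tangential × 50 µm along the outward normal by default,
zero distance at the cell-matrix interface. `rim_order_profile()`
evaluates $S$ per ROI over valid pixels within `max_distance_um`,
weighted by coherency, and pools all ROIs per organoid. Because $S$ is
rotation invariant it cannot distinguish radial from tangential
alignment; the angle between each ROI's director and the local rim
normal is reported separately (`angle_vs_normal_deg`, ~0° for fibers
perpendicular to the rim).

A statistical note that shaped the tests: all pixels along one fiber
share one orientation, so the effective sample size of an ROI is its
*fiber* count, not its pixel count. Uniform-field fixtures are therefore
judged on the pooled estimate (measured $S \approx 0.007$ across a rim)
rather than per-ROI, and ROI geometry tests use organoids large enough
that the rim normal is nearly constant within one ROI width.

## Segmentation chain

1. **Organoid mask** — Otsu threshold of the Gaussian-smoothed K8+K14
   sum, holes filled, components above 500 px² kept. Smoothing is 1 px:
   larger values visibly bias the threshold contour outward and dilute
   the cytoplasmic means of rim cells (worst-case per-cell ratio error
   5.3% at σ=2 px vs 2.1% at σ=1 px on identical synthetic data).
   Thresholds are computed from the image, so segmentation is invariant
   to a positive intensity gain.
2. **Nuclei** — two-class k-means on DAPI intensities inside the mask
   (an adaptive nucleus/background split), then touching nuclei are
   separated by a watershed on the smoothed DAPI signal with a tolerance
   of 0.2 of the intensity range; specks under 20 px² are dropped.
3. **Cells** — every mask pixel is assigned to the nucleus with minimal
   elevation-weighted geodesic distance (Dijkstra on the 8-connected
   pixel graph). The elevation is a multi-scale Hessian membrane
   enhancement of K8+K14 (scale-normalized negative minor eigenvalue,
   maximum over scales {1, 2} px). Ridges between cells act as soft
   barriers; with no membrane signal the partition degrades to geodesic
   Voronoi. An earlier implementation using `EBImage::propagate`
   ignored the ridges in practice and clipped elongated protruding
   cells to roundish blobs, which is why the explicit graph formulation
   is used. The result is always a partition of the mask with exactly
   one nucleus per cell.
4. **Layers** — a cell is *outer* iff its region shares a pixel with the
   1 px boundary band of the mask ("in contact with the collagen");
   purely geometric.

## Yap quantification and cell classes

For each cell, `measure_cells()` reports the background-subtracted
nuclear over cytoplasmic mean of the Yap channel,
$(\bar I_{nuc} - b)/(\bar I_{cyto} - b)$, with $b$ the median intensity
outside a 10 px dilation of all organoid masks. Cells whose cytoplasmic
mean does not exceed $b$ are flagged invalid rather than given a
meaningless ratio. The ratio is exactly invariant to a gain applied to
channel and background together, and to an offset when the background is
re-estimated — both asserted to $10^{-9}$.

K14 classes follow the mean-gray-value rule: a cell is K14-high iff its
mean K14 exceeds the mean of the per-cell K14 means over the outer cells
of the same image; ties are Low; fewer than two outer cells skips
classification with a warning.

Roles operationalize the morphological leader-cell criteria ("elongated,
protrusive, extending outward"), which in practice are applied by eye:
inner cells are `none`; outer cells are `rim` unless elongation
(major/minor axis from the pixel covariance) ≥ `e_min` = 2 **and** the
cell's farthest point lies ≥ `p_min_um` = 5 µm beyond the convex outline
of the organoid body formed by the remaining cells. Both thresholds are
configurable; they are surrogates, not a reproduction, of manual
selection. Cell length is the geodesic diameter of the region (longest
internal shortest path, diagonal steps √2), which equals the medial path
length for elongated cells and the diameter for disks.

## Border morphometrics

`protrusive_index()` follows the macro pipeline — Gaussian blur (2 px),
threshold (Otsu for grayscale, half level for binary), binary erosion
(2 iterations), largest component — then measures the boundary on a
subpixel marching-squares contour of the lightly smoothed mask. Contours
of raw binary masks overestimate perimeters by up to ~6% in a
direction-dependent way; the smoothed contour brings a disk to within
0.5%. The index is boundary perimeter divided by convex-hull perimeter:
a ratio of two perimeters, dimensionless, exactly 1 for convex borders,
and ≥ 1 up to a 2% discretization allowance (asserted on random masks).
Strand metrics measure *given* annotations (polylines or label masks);
strand identification is deliberately not inferred, mirroring how such
counts are made by hand.

## Bead displacement

`estimate_drift()` registers consecutive frames by phase correlation
(Hann windowed, subpixel parabolic peak) and accumulates offsets against
frame 1; synthetic drifts are recovered to ≤ 0.03 px/frame. Spots are
smoothed local maxima above an Otsu floor with 5×5 weighted-centroid
refinement (components larger than `max_spot_area` — the organoid body —
are excluded). Linking works in drift-corrected coordinates by global
minimum-cost assignment (Hungarian) on constant-velocity predicted
positions with a `max_step_px` gate. Independent mutual-nearest linking
was tried first and systematically broke chains of beads advected along
a common ray toward the organoid — a trailing bead's detection lands
nearer than a bead's own next position — which the global assignment
resolves; tracks missing any frame stay flagged incomplete.

Selection mirrors the study rules: a bead is included iff it is
trackable through the whole time-lapse, its initial distance to the
organoid border (measured to the contour, not the centroid) is at most
the organoid's diameter or radius depending on `mode`, and it is not
within the selection distance of two organoids at once. Displacement is
the first-to-last change in border distance in µm (positive toward the
organoid); a path-integrated variant is available since first-to-last
versus path-integrated is not uniquely determined by the verbal rule.
On synthetic time-lapses, 2 µm/frame over 11 frames is recovered as
20 ± 0.1 µm with or without a (3, −2) px/frame drift.

## The synthetic generator: what it emulates, and what not

`gen_organoid_image()` builds a disk of Voronoi-packed cells with a
single rim layer, optional elongated leader cells protruding radially
(truth elongation 3, nucleus in the tip), flat-intensity cytoplasm and
nuclei, exact per-role nuclear/cytoplasmic Yap ratios before noise, a
bimodal K14 pattern with an exact high fraction among outer cells, and
per-cell K8 gain variation (±20%) so that cell borders carry an
intensity step as in real keratin stains — without that step, no image
evidence of cell boundaries would exist at all. `gen_fiber_field()`
stamps straight fibers with axes from the doubled-angle von Mises
sampler (Best-Fisher); `gen_bead_timelapse()` advects Gaussian spots
radially with superimposed global drift (beads are placed so they stay
outside the body and resolvable, ≥ 8 px apart initially);
`gen_border_mask()` rasterizes a cosine-lobed star polygon whose exact
perimeter and hull perimeter come from an independent segment-length
oracle. Noise is additive Gaussian clipped at zero. Everything is
deterministic given the spec's seed, and every generated object carries
its ground truth keyed by id.

What passing these tests shows — and does not. Recovery on this
generator validates the estimators' correctness, calibration and
invariances under known conditions. It does not certify performance on
real confocal data: the generator has no optical blur or depth
attenuation, no autofluorescence, flat (not textured) cytoplasm, fibers
that are straight rather than crimped, and no out-of-plane structure.
Mid-plane choice is the caller's; there is no automatic z selection.

## Problem sizes and numerical choices

Test fixtures are sized so the full suite runs in about a minute:
organoids of radius 32–40 µm at 0.5 µm/px (≈ 18 cells), fiber fields of
4000–9000 fibers on 512–1024 px frames, and three 5000-fiber fields on
2048 px frames for the von Mises recovery sweep (≈ 1% area fill, chosen
so individual fibers are resolvable; measured concentration errors are
1–5% against the 15% bound the suite asserts). Rim packings keep the spacing
above one cell diameter — tighter rims are unphysical and a crowded cell
can lose its boundary arc. Ties in the K14 rule go to Low; ambiguous
frame links beyond the gate start new (incomplete) tracks; ROIs with no
valid pixels report `S = NA`, never 0; degenerate inputs (blank images,
empty masks, organoids filling the frame, protrusion depth exceeding the
base radius) raise typed errors or return empty results as documented.

## Known limitations

Manual leader selection and manual strand identification cannot be
reproduced, only operationalized. Absolute ratios depend mildly on the
background-region convention (outside a 10 px dilation), which the
original workflow leaves unstated. The order parameter near a strongly
curved rim conflates curvature with disorder when ROIs are wide relative
to the organoid. All analysis is 2D; the study's headline experimental
values require the original images and movies and are out of scope.
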