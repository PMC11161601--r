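# mechanoquant

Quantification toolkit for collective invasion assays of tumor organoids
embedded in fibrillar collagen I. Breast-cancer organoids in collagen pull
on the matrix, align its fibers, and convert that tension into nuclear
localization of the mechanotransducer Yap in protrusive leader cells at
the organoid rim. `mechanoquant` implements the image analyses this loop
is measured with, for anyone quantifying organoid-matrix mechanics from
multichannel confocal TIFFs:

* **Yap localization** — organoid masking (Otsu on K8+K14), nucleus
  detection (two-class k-means on DAPI plus watershed splitting), seeded
  watershed cell segmentation over a multi-scale Hessian membrane
  enhancement, outer/inner layer calls, and the per-cell
  background-subtracted ratio
  `(nuc_mean − background) / (cyto_mean − background)`, with K14 Hi/Lo
  (threshold: mean gray value over outer cells) and rim/leader role
  classification.
* **Collagen alignment** — per-pixel orientation θ ∈ [−90°, 90°) and
  coherency ∈ [0, 1] by the structure tensor, and the nematic scalar
  order parameter obtained from the second-order tensor of the
  orientation sample,

  S₂ = [⟨cos 2θ⟩ ⟨sin 2θ⟩; ⟨sin 2θ⟩ −⟨cos 2θ⟩],  λ₁,₂ = ±S,
  S = √(⟨cos 2θ⟩² + ⟨sin 2θ⟩²),

  evaluated in 30 × 50 µm rectangles anchored perpendicular to the
  cell-ECM border (S = 0: uniform axial angles; S = 1: perfectly
  aligned). The von Mises relation S = I₁(κ)/I₀(κ) links S to a fiber
  concentration estimate.
* **Border morphometrics** — the protrusive index of a tumor border
  (Gaussian blur → threshold → erosion → subpixel contour; boundary
  perimeter divided by convex-hull perimeter; 1 for convex borders),
  organoid area growth, and strand count/length metrics.
* **Bead displacement** — phase-correlation drift correction, spot
  detection and min-cost track linking, the diameter/radius selection
  rule with the two-organoid and not-trackable exclusions, and net
  displacement toward the organoid border in µm.
* **Synthetic data** — generators for organoid planes, von Mises fiber
  fields, bead time-lapses and star-shaped border masks with exact
  ground truth, so every stage is testable without experimental images.

## Worked example

```r
library(mechanoquant)

g <- gen_organoid_image(synthetic_organoid_spec(n_leader_cells = 1,
                                                noise_sd = 2, seed = 42))
org    <- segment_organoid(g$image)[[1]]
nuclei <- detect_nuclei(get_channel(g$image, "DAPI"), org)
cells  <- segment_cells(nuclei, g$image, org)
tab    <- measure_cells(g$image, cells, org)
head(tab[, c("cell", "layer", "role", "k14_class", "ratio", "length_um")], 8)
#>   cell layer   role k14_class    ratio length_um
#> 1    1 outer    rim        Hi 2.039902  25.27817
#> 2    2 inner   none        Lo 1.201780  23.84924
#> 3    3 outer    rim        Hi 2.012422  24.21320
#> 4    4 outer    rim        Hi 2.040988  25.52082
#> 5    5 inner   none        Lo 1.199460  18.43503
#> 6    6 outer    rim        Lo 2.001781  21.65685
#> 7    7 outer leader        Lo 3.013730  25.82843
#> 8    8 outer    rim        Hi 2.046045  21.98528

tapply(tab$ratio[tab$ratio_valid], tab$role[tab$ratio_valid], median)
#>   leader     none      rim
#> 3.013730 1.200296 2.012422
```

The generator rendered rim cells at a true nuclear/cytoplasmic Yap ratio
of 2, inner cells at 1.2 and the leader at 3; the measured medians above
recover those values from the noisy rendered image through the full
segmentation chain. The leader call combines elongation (major/minor
axis ≥ 2) with protrusion (≥ 5 µm beyond the organoid body outline).

Fiber alignment on a sample of known concentration:

```r
op <- order_parameter(rfiber_angles(5000, mu_deg = 0, kappa = 2))
op
#> nematic order parameter S = 0.7058 (n = 5000, director 0.1 deg)
vm_order_parameter(2)   # analytic expectation I1(2)/I0(2)
#> [1] 0.6977747
```

For image-based analysis, `structure_tensor_orientation()` turns a
collagen channel into an orientation field, `extract_rim_rois()` anchors
measurement rectangles along a segmented organoid's border, and
`rim_order_profile()` reports per-ROI and pooled S together with the
angle between each ROI's director and the rim normal. `run_pipeline()`
drives the stages from a YAML config and writes annotated CSVs, label
TIFFs and a JSON run manifest; outputs are bit-identical under a fixed
seed.

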