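---
title: "Rough-set edge detection for orchard fruit images: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Rough-set edge detection for orchard fruit images: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(roughedge)
```

## The problem

Detecting the contours of individual apples in orchard photographs is hard
for three recurring reasons: specular highlights carve bright holes into
the fruit surface, branches and leaves clutter the background and cut
across fruit bodies, and in dense canopies the fruits occlude one another.
Classical gradient operators (Canny, Laplacian, Prewitt) respond to every
luminance edge in the frame and leave the fruit contour buried in noise.

`roughedge` implements a region-first alternative. A fruit detector (any
external detector writing the package's box sidecar format, or the bundled
naive colour-blob detector for synthetic fixtures) reduces the multi-fruit
problem to one crop per fruit. Each crop is segmented into a binary fruit
mask, the mask is cleaned morphologically, and the edge is extracted as
the *boundary region of a rough set*: everything the mask might be, minus
everything it certainly is.

## Pipeline

For each fruit bounding box the pipeline runs:

1. **Crop** with a relative margin (default 5% per side, at least 3 px)
   so the fruit contour never touches the crop border.
2. **Colour conversion** RGB → XYZ → CIELAB. The XYZ step is the fixed
   3×3 matrix applied directly to the stored channel values; the LAB step
   uses the standard CIE companding function
   f(t) = t^(1/3) for t > (6/29)^3, else t/(3(6/29)^2) + 4/29,
   with white point (Xn, Yn, Zn) = (0.950456, 1.0, 1.088754), which maps
   exactly to (L, a, b) = (100, 0, 0).
3. **K-means segmentation** on per-pixel (L, a, b) features; Lloyd
   iteration with k-means++ seeding, deterministic given the seed.
4. **Cluster selection**: the cluster holding the majority of the central
   50%×50% window (the ROI is fruit-centred by construction), or
   alternatively the cluster with the reddest centroid (`max_a`).
5. **Void sealing** (one closing iteration with hole filling in between).
6. **Refinement**: fill enclosed holes, then erode and dilate `n` times
   (an opening; default n = 3).
7. **Rough-set boundary**: upper approximation U(X) = dilation, lower
   approximation L(X) = erosion by the structural operator (default 3×3
   square); boundary Bn(X) = U(X) ∧ ¬L(X); optional thinning to a
   one-pixel contour (default on in the pipeline).
8. **Merge**: per-fruit edge maps pasted back at their box offsets with
   logical OR; the result is order-independent.

## The rough-set formulation

A rough set describes an uncertain region X of the pixel universe by two
definable sets induced by a structural operator Y (a small sliding
window): the lower approximation L(X) contains the pixels whose whole
window lies inside X (the minimum value under the window — erosion), and
the upper approximation U(X) contains the pixels whose window touches X
at all (the maximum value — dilation). Four regions partition the frame:

* L(X): certainly fruit;
* Bn(X) = U(X) − L(X): the uncertain band — exactly the pixels where the
  operator cannot decide, i.e. the edge;
* Neg(X) = ¬U(X): certainly background.

With a symmetric operator the boundary band is the morphological gradient
of the mask: a closed band, roughly as wide as the operator, straddling
the true contour. The identities L ⊆ X ⊆ U, U = L ∪ Bn (disjointly), and
Neg = ¬U hold by construction and are re-checked in the test suite
against brute-force double-loop oracles.

### Why the default edge is thinned, and on which side

The raw Bn band under a 3×3 operator is about two pixels wide. Evaluation
(and most edge ground truth) uses one-pixel contours drawn on object
pixels. Measured on ideal disks with *perfect* masks, scoring the raw
band against a one-pixel contour caps the windowed (3×3) Dice near 0.80,
and thinning the band to its mid-line caps it near 0.88 — the mid-line
sits half an operator outside the object-pixel contour. The pipeline
therefore keeps the object-side margin of the band (Bn ∧ X) and thins it
(Zhang–Suen), which raises the perfect-mask ceiling to about 0.95. The
raw band remains available (`boundary_region(..., thin = FALSE)`, the
module default, and `red_config(thin = FALSE)`).

## Tunable parameters

| Parameter | Default | Meaning |
|---|---|---|
| `k` | 3 | K-means clusters per crop: fruit, background, and one noise class (highlight, branch or foliage tone). `k = 2` suits clean two-tone crops. |
| `iterations` | 3 | Erosion/dilation passes of the opening. Too few keep speckle; too many erode genuine fruit area. |
| `operator_size` | 3 | Side of the square structural operator; sets the width of the raw boundary band. |
| `window` | 3 | Side of the evaluation window: an edge pixel counts as found if a true edge pixel lies within the window. |
| `margin` | 0.05 | Relative ROI expansion per side (≥ 3 px). |
| `close_gaps` | 1 | Void-sealing closing iterations before refinement (see below). |
| `thin` | TRUE | One-pixel object-side contour instead of the raw band. |
| `border_trim` | 2 | Width of the crop-border strip in which edges are discarded. |
| `seed` | 1 | Base RNG seed; ROI *i* uses `seed + i − 1`. |

Two details deserve explanation:

* **Void sealing (`close_gaps`).** Hole filling recovers voids (e.g. a
  specular highlight that K-means assigns to its own cluster) only when
  they are fully enclosed by the mask. When a branch crosses the fruit
  next to the highlight, the void can leak into the background through a
  one- or two-pixel pinch and filling does nothing. One dilation seals
  pinches up to two pixels, holes are filled while sealed, and one
  erosion restores the geometry — occluder corridors of three or more
  pixels stay open and nearly-touching fruits are not welded together.
* **Border trimming.** Crop borders cut through neighbouring fruits; the
  background-padding policy then manufactures a spurious boundary along
  the border. Since the ROI margin guarantees the target fruit's own
  contour is at least three pixels from the border, discarding edges in
  the outermost two-pixel strip removes only artifacts.

## Numerical and convention choices

* **Coordinates**: boxes are 0-based, half-open, `[x_min, x_max) ×
  [y_min, y_max)`; rasters are indexed (row, col) from the top left.
* **Border policy**: structuring-element cells outside the raster count
  as background for both erosion and dilation. Consequence: the duality
  erode(A, B) = ¬dilate(¬A, reflect(B)) and the gradient symmetry
  Bn(X) = Bn(¬X) hold exactly only where the element footprint stays
  inside the raster; the tests check them there.
* **Colour matrix**: the default (1,2) coefficient is 0.35780, so the
  first row sums to 0.950676 rather than Xn = 0.950456 — a ~2·10⁻⁴
  mismatch for pure white. `strict_cie = TRUE` substitutes 0.357580. No
  gamma linearisation is applied by default; `gamma_linearize = TRUE`
  enables the sRGB transfer for real photographs.
* **K-means**: k-means++ seeding, 4 restarts from one seeded stream, the
  lowest-inertia fit wins (restarts guard against local optima that split
  one colour class in two); convergence when the largest centroid
  movement drops below `tol = 1e-4` LAB units or after 100 iterations;
  `k` is reduced with a warning if the crop has fewer distinct colours.
* **Cluster-selection ties** go to the larger cluster.
* **Degenerate inputs**: empty box files give an empty result with a
  warning, not an error; a mask that vanishes under erosion returns empty
  with an over-erosion warning; zero metric denominators yield `NA` with
  a warning.
* **mask AP**: greedy score-descending matching at IoU ≥ 0.5 with
  all-point interpolation; a COCO-style 0.50:0.95 average is available
  via `coco = TRUE`.
* **Aggregation**: multi-fruit scenes are scored micro-style from one
  pooled confusion matrix per frame.

## The synthetic orchard generator

Real orchard imagery with pixel-exact edge ground truth is scarce, so the
package ships a deterministic generator (`scene_spec()`,
`generate_scene()`, `make_fixture_suite()`). Fruits are shaded ellipses
(radial lightness falloff, per-fruit hue jitter) over a green background
with darker foliage dapples and smooth luminance texture; optional
specular highlight near the fruit top; branches as thick dark segments
and leaves as rotated green ellipses drawn *over* the fruits; additive
Gaussian noise last. Ground truth is exact: per-fruit amodal and visible
masks, tight boxes of the visible masks, and a one-pixel edge map defined
as the 4-neighbour contour of the union of visible masks. All randomness
flows from one seed; identical specs give byte-identical scenes.

The three standard study conditions (`fixture_specs()`):

* *illumination*: two large fruits, highlight strength 0.85;
* *complex background*: three fruits, two branches, five leaves;
* *dense occlusion*: seven fruits with pairwise overlap allowed up to
  0.30 of the smaller fruit, one branch, three leaves.

Scene sizes (240×320) and fruit counts were chosen once as representative
of close-range orchard crops; the end-to-end checks run in seconds at
these sizes.

What the generator does **not** emulate: anti-aliased or motion-blurred
contours, gradual shading across fruit/background boundaries, JPEG
artifacts, true 3-D occlusion geometry, and the colour statistics of real
cultivars. Passing the bundled tests therefore demonstrates the internal
correctness and robustness of the pipeline under controlled noise,
highlights and occlusion — not field performance on photographs.

A deliberate consequence of the ground-truth convention: the visible-mask
contour runs *along* occluders, while the pipeline by design fills voids
and recovers slightly amodal contours. Scenes in which a branch bisects a
fruit therefore score structurally lower (high eighties windowed Dice)
than clean scenes (mid nineties); this is the evaluation convention
disagreeing with the recovery goal, not a detection failure.

## Known limitations

* The fruit-cluster selection takes exactly one cluster; a fruit whose
  colour genuinely splits across clusters (strong highlight plus deep
  shadow) relies on void filling/sealing to be recovered.
* Edges of fruits touching the frame border are partially suppressed by
  border trimming.
* Adjacent fruits of identical colour within one crop merge into a single
  mask; their shared interface produces no edge (the merged full-frame
  map still contains each fruit's own outer contour from its own ROI).
* The blob detector is a fixture aid, not a fruit detector; real use
  expects boxes from a trained detector via the sidecar format.
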