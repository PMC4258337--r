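---
title: "Extracting the tongue body from color images in HSI space"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Extracting the tongue body from color images in HSI space}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tongueseg)
```

## The problem

Tongue inspection is one of the classical diagnostic procedures of
traditional Chinese medicine: the color of the tongue body, and the
presence and color of any coating on its surface, carry diagnostic
meaning. Quantitative, camera-based tongue analysis needs the tongue
region extracted from the photograph first — separated from the face,
teeth and, hardest of all, the lips, which sit directly adjacent to the
tongue and share its red hue. Coated tongues add a second difficulty:
a thick white or yellow coating covers much of the tongue surface with
pixels whose color says "not tongue tissue" even though they lie squarely
inside the tongue region. `tongueseg` implements three extraction
pipelines that share one color model but differ in how much spatial
information they use, together with pixel-level accuracy metrics and a
synthetic scene generator that makes the whole chain testable without
clinical photographs.

## The HSI color model

All three pipelines describe color in hue/saturation/intensity terms,
which separates *what* color a pixel has (hue, an angle in degrees) from
how colorful (saturation) and how bright (intensity) it is. For channels
$R,G,B \in [0,1]$:

$$\theta = \arccos\frac{\tfrac12[(R-G)+(R-B)]}
  {\left[(R-G)^2+(R-B)(G-B)\right]^{1/2}}, \qquad
H = \begin{cases}\theta & B \le G\\ 360^\circ - \theta & B > G\end{cases}$$

$$S = 1 - \frac{3\min(R,G,B)}{R+G+B}, \qquad I = \frac{R+G+B}{3}.$$

The arccosine alone only covers $[0^\circ,180^\circ]$; the $B>G$
complement rule extends hue to the full circle. Two guards make the
formulas total: when the denominator of $\theta$ vanishes the pixel is
achromatic and its hue is *undefined* (stored as `NA`, and excluded from
every histogram and hue window), and when $R+G+B=0$ we define $S=0$.

Red hue — the tongue's hue — sits at *both* ends of the hue axis, near
$0^\circ$ and near $360^\circ$, so a raw hue histogram shows the tongue
split into two edge peaks. The package therefore works on **shifted
hue**, $H' = (H + 180^\circ) \bmod 360^\circ$, which moves the two red
ends to a single peak near $180^\circ$. The shift is a bijection and its
own inverse. Valley thresholds between the merged red peak and the
background peak are found by maximizing the Otsu between-class variance
over the 360 one-degree bins; ties are broken toward the smallest bin
index. One-degree bins match the degree-level granularity at which hue
windows are specified; nothing in the pipelines needs finer resolution.

## Three pipelines

**Morphology + HSI** (`segment_morph_hsi`): binarize on the hue window
alone, keep the largest connected component, then clean up with
morphological opening and closing (disk structuring element). Fast, and
accurate for uncoated tongues — but the coating falls outside the red hue
window, so a thickly coated tongue loses its coating region entirely, and
with it most of its area.

**Sequential labeling + HSI** (`segment_sequential_hsi`): threshold on
hue *and* intensity, label the connected regions with a two-pass raster
scan (union-find equivalence resolution; the partition is identical to
flood fill), select the largest region, and close small holes. The
intensity floor exploits the one reliable photometric feature of the
tongue/lip boundary: it is *dark* relative to both regions, so tongue and
lip separate into different components. The pipeline inherits the
morphology method's blindness to coating, and fails when the boundary is
bridged by bright pixels — then the selected component contains the lip.

**Greedy color/space fusion** (`segment_greedy_fusion`): the package's
centerpiece. Growth starts from a seed pixel that must be bright,
saturated tongue tissue ("substance") and proceeds one pixel at a time:
the frontier pixel whose shifted hue is closest to the running circular
mean of accepted substance hues is examined first, and is accepted if it
is substance, **or** if it is coating-colored *and already surrounded by
accepted tongue pixels* (at least `enclosure_min_neighbors` of its
8-neighbors, default 2). Rejected pixels leave the frontier for good.
After growth, background holes fully enclosed by the region are filled:
an interior pixel that is not substance can only be coating. The output
is by construction a single connected region containing the seed, and
every pixel in it carries a justification flag — substance, coating, or
enclosed-hole fill.

## Design choices in the greedy method

Several points of the growth procedure admit more than one reading; the
package resolves them as follows.

* **"Most similar to the region"** is made concrete as circular hue
  distance to the running circular mean of the accepted *substance*
  hues (coating pixels do not pull the mean toward white or yellow).
  A pixel with undefined hue ranks after every defined hue but can still
  be accepted under the white-coating rule. Ties go to the pixel that
  entered the frontier earliest, which makes the whole procedure
  deterministic.
* **Frontier discipline.** A pixel enters the frontier at most once
  (when its first neighbor is accepted) and leaves it exactly once,
  accepted or rejected. This bounds the work at $H\times W$ acceptances
  plus $H\times W$ rejections. A coating pixel examined too early — before
  enough of its neighbors were accepted — is rejected permanently; the
  final enclosed-hole fill recovers such pixels wherever the region has
  closed around them, which is exactly the situation in which they are
  legitimately "surrounded by substance".
* **"High intensity" is a stricter bar than the threshold floor.** The
  growth rules demand high intensity of every accepted pixel; the
  sequential pipeline's floor merely has to sit above the dark
  tongue/lip boundary. The package's defaults encode that asymmetry:
  `intensity_min = 0.15` for the thresholding pipelines, `0.30` for the
  fusion pipeline. This is what stops greedy growth at a moderately
  bright bridge across the tongue/lip boundary that the sequential
  threshold happily admits — the mechanism behind the two methods'
  different lip behavior.
* **A saturation floor in the substance predicate** (`saturation_min`,
  default 0.15). Hue is numerically meaningless near zero saturation;
  without the floor, noise on near-achromatic (white-coating) pixels
  scatters their hues uniformly and a sixth of them would masquerade as
  substance. With it, "white coating is not substance" holds
  deterministically.
* **Seed search window** (`seed_search_fraction`, default 0.3 of each
  image side, centered). The lip shares the tongue's hue *and*
  intensity, so the automatic seed must be found in a window that cannot
  touch the lip; 0.3 keeps a comfortable margin for a roughly centered
  tongue while remaining large enough to find bright substance on every
  preset.
* **Pre-resize** to a longest side of 400 px (nearest-neighbor, masks
  upsampled back the same way). Segmentation quality is governed by the
  hue structure, not by resolution; shrinking keeps the growth loop's
  cost proportional to a fixed working area.

## Parameters that matter

| Parameter | Default | Units | Why |
|---|---|---|---|
| `hue_center`, `hue_half_width` | 180, 30 | degrees (shifted hue) | the red band after the hue shift; wide enough to cover light-red through purple bodies |
| `intensity_min` (sequential) | 0.15 | channel mean | above the dark tongue/lip boundary, below any tongue body |
| `intensity_min` (fusion) | 0.30 | channel mean | the "high intensity" acceptance bar; above bridge-level brightness |
| `saturation_min` | 0.15 | saturation | hue reliability floor; separates white coating from pale tongue bodies |
| `white_s_max`, `white_i_min` | 0.25, 0.4 | saturation, intensity | white coating: desaturated and bright |
| `yellow_band` | [210, 280] | degrees (shifted hue) | yellow coating: raw hue 30–100 |
| `enclosure_min_neighbors` | 2 | neighbors of 8 | "surrounded by substance", evaluated incrementally during growth |
| `se_radius` | 5 per 400 px width | pixels | structuring element small relative to the tongue |
| `connectivity` | 4 (labeling), 8 (growth) | — | conservative for component counting; growth should not be blocked by diagonal steps |

All hue windows are on the shifted scale. None of these values is learned
from data; each is an exposed configuration choice with the rationale
above.

## The synthetic scene generator

`preset_scene()` renders the seven classical tongue classes — light red,
light white, red, deep red, purple, thick white coating, thick yellow
coating — as an ellipse against a skin-toned face, with an adjacent lip
crescent painted in the *same color as the tongue body* (the worst case
for any hue-only method), separated by a dark desaturated boundary band
(intensity 0.075), and, for the coated classes, a concentric coating
patch covering 40% of the tongue area. Channel noise is clipped additive
Gaussian with $\sigma = 0.02$, mild camera noise that perturbs hues by a
few degrees without flipping any class across its window boundaries
(distribution tails excepted). The optional `lip_bridge` variant brightens
a narrow gap of the boundary band to intensity 0.20 — above the sequential
floor, below the fusion bar — to reproduce the bright-boundary failure
mode. Ground truth is exact by construction: the tongue mask is the
ellipse (coating included, lip excluded).

What the generator deliberately does **not** model: papillae texture,
specular highlights, illumination gradients, teeth, color calibration
errors, and realistic lip geometry. Passing tests on these scenes
therefore demonstrates that each pipeline behaves as designed under its
stated assumptions — red connected tongue, hue-distinct surroundings,
dark lip boundary — not that it reaches any particular accuracy on
clinical photographs, where those assumptions hold only approximately.

## Numerical and degenerate-input conventions

* Hue arithmetic is circular everywhere: distances via
  $\min(|a-b|, 360-|a-b|)$, means via the arctangent of summed sines and
  cosines.
* Otsu valley search: classes are "bins $< t$" vs "bins $\ge t$"; ties
  broken toward the smallest $t$; histograms with fewer than two
  nonempty bins signal a no-valley error rather than returning a
  meaningless split.
* Labeling renumbers components consecutively in raster order of first
  appearance; equal-size region ties resolve to the smallest label.
* Morphological operations use replicate-style borders (out-of-image
  counts as foreground for erosion, background for dilation), the
  convention of the underlying morphology backend.
* Degenerate inputs fail loudly with classed conditions: no foreground
  after thresholding (`tongueseg_no_foreground`), no qualifying seed
  (`tongueseg_seed_failure`), channel values outside $[0,1]$, shape
  mismatches. Accuracy metrics with empty prediction or reference are
  `NA`, never silently 0 or 1.
* Everything is deterministic: fixed input and parameters give
  bit-identical masks, and a fixed `rng_seed` gives bit-identical
  synthetic scenes (the generator restores the caller's RNG state).

## Problem sizes

The test suite and the reproduction script work at a canvas of
$200 \times 200$ pixels with three noise realizations per preset — small
enough to run the full 7-preset × 3-method comparison in seconds, large
enough that the tongue (about 7,200 pixels), lip (about 2,000) and
coating (about 2,900) regions are well resolved and the morphological
scales (structuring element radius 2–3 at this width) behave as at
camera resolution.

## Known limitations

* The comparative accuracy claims are about the *ordering* of methods on
  scenes with the stated structure, not about absolute rates on real
  photographs.
* The greedy method assumes a single connected tongue roughly centered
  in the frame; multiple red regions compete only through the seed
  window.
* Coating patches touching the tongue *boundary* (rather than strictly
  interior) can leak the enclosed-hole fill toward the background side;
  the generator keeps coating strictly interior, as thick central
  coating presents clinically.
* BMP input is not supported (PNG, JPEG, TIFF are).
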