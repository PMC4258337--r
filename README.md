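# tongueseg

Extraction of the tongue body region from color photographs, for
quantitative tongue diagnosis. The package is aimed at researchers
building computerized tongue-analysis pipelines: before tongue color,
moisture or coating can be measured, the tongue has to be separated from
the face and — hardest of all — from the lips, which share its red hue.
Coated tongues add a second difficulty: a thick white or yellow coating
lies spatially *inside* the tongue region while its pixel colors say
"not tongue tissue".

`tongueseg` implements three extraction pipelines that share one color
model, plus evaluation metrics and a synthetic scene generator with
exact ground truth:

* **Morphology + HSI** — hue binarization, largest connected component,
  morphological opening/closing. Fast; loses the coating.
* **Sequential labeling + HSI** — hue *and* intensity thresholding,
  two-pass connected-region labeling, region selection, hole closing.
  Separates tongue from lip across their dark boundary; loses the
  coating, and leaks into the lip when the boundary is bridged.
* **Greedy color/space fusion** — seeded region growing whose rules fuse
  color and spatial information: a pixel is accepted if it is tongue
  *substance* (red-hued, saturated, bright), or if it is
  coating-colored **and already surrounded by accepted tongue pixels**.
  This is the pipeline that extracts thickly coated tongues whole.

## The model

Colors are described in hue/saturation/intensity (HSI) space. For
channels $R,G,B \in [0,1]$:

$$\theta = \arccos\frac{\tfrac12[(R-G)+(R-B)]}{[(R-G)^2+(R-B)(G-B)]^{1/2}},
\quad H = \begin{cases}\theta & B \le G\\ 360^\circ-\theta & B>G,\end{cases}
\quad S = 1-\frac{3\min(R,G,B)}{R+G+B}, \quad I=\frac{R+G+B}{3}.$$

Red hues sit at both ends of the hue circle, so all windows operate on
the *shifted* hue $H' = (H+180^\circ) \bmod 360^\circ$, which merges the
two red histogram peaks into one near $180^\circ$.

Segmentations are scored against a reference mask by the recognition
rate and error rate

$$\eta = \frac{TP}{TP+FN}, \qquad \varepsilon = \frac{FP}{FP+TP},$$

where $TP$ counts tongue pixels recovered, $FN$ tongue pixels missed,
and $FP$ background pixels wrongly claimed.

## Worked example

```r
library(tongueseg)

# a 200x200 scene: red tongue, thick white coating, decoy lip in the
# tongue's own color behind a dark boundary band
sc <- preset_scene("thick_white_coating", rng_seed = 7)
sc
#> <tongue_scene> 200 x 200, tongue 7180 px, coating 2871 px

mask <- segment_greedy_fusion(sc$image)
seg_metrics(confusion(mask, sc$truth))
#> <tongue_metrics> recognition = 100.00%, error = 0.00%

table(attr(mask, "flags"))
#>     0     1     2     3
#> 32820  4309   311  2560
```

Every extracted pixel carries its justification: 4,309 pixels were
accepted as tongue substance (flag 1), 311 as enclosed coating during
growth (flag 2), and 2,560 by the final enclosed-hole fill (flag 3) —
together recovering the whole coated tongue, while the equally red lip
stays excluded. The full picture across methods:

```r
scenes <- lapply(c("red", "thick_white_coating"), function(nm) {
  s <- preset_scene(nm, rng_seed = 7)
  list(image = s$image, truth = s$truth, id = nm, preset = nm, seed = 7)
})
compare_methods(scenes)
#>             scene_id              preset seed     method eta_pct eps_pct
#>                  red                 red    7      morph   99.96    0.03
#>                  red                 red    7 sequential  100.00    0.00
#>                  red                 red    7     greedy  100.00    0.00
#>  thick_white_coating thick_white_coating    7      morph   60.03    0.05
#>  thick_white_coating thick_white_coating    7 sequential   60.53    0.00
#>  thick_white_coating thick_white_coating    7     greedy  100.00    0.00
```

On the uncoated tongue all three methods agree; on the coated tongue the
two thresholding pipelines keep only the substance ring (about 60% of
the tongue) while greedy fusion recovers it completely.

A command-line interface wraps the same functions:

```sh
CLI=$(Rscript -e 'cat(system.file("cli", "tongueseg", package = "tongueseg"))')
Rscript $CLI synth   --preset thick_white_coating --seed 7 --out scenes/
Rscript $CLI segment --method greedy --in scenes/thick_white_coating_7.png --out mask.png
Rscript $CLI evaluate --pred mask.png --ref scenes/thick_white_coating_7_truth.png
Rscript $CLI benchmark --seed 2 --out table.csv
```

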