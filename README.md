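# wishtools

Computational decomposition of whole-mount in situ hybridisation (WISH)
photographs of *Xenopus* embryos, for curators and computational biologists
who need to process large, heterogeneous image collections: find the embryo
against arbitrary backgrounds, separate the in situ stain from natural
pigment and background bleed-through, sort collections into cleared and
un-cleared preparations, group quasi-spherical-stage photographs by
anatomical viewpoint, and select representative images from redundant sets.

## The methods in brief

**Segmentation.** Each image is analysed in CIELAB at two adjacent Gaussian
pyramid scales (finer layer under 200 px); per low-resolution pixel, the
colour channels and their Scharr derivatives at both scales give an
18-vector, whitened and modelled as a full-covariance Gaussian mixture
(≤ 2 components for un-cleared images, ≤ 3 for cleared; count by BIC).
Components are classified as background/embryo by Bayesian model selection:
background pixels uniform over the frame (density 1/wh), embryo pixels
Gaussian around the centre with an inverse-Wishart prior
(ν = 1, Ψ = diag((w/2)², (h/2)²)) integrated in closed form, with an
edge-frequency fallback when no model wins by a Bayes factor of 3. The best
foreground island (argmax √|S| · ‖M_S − M_bg‖) is closed, hole-filled,
smoothed by an 8-iteration geodesic active contour, upsampled and
contracted by one fine-layer pixel width.

**Stain unmixing.** Embryo pixels in CMY follow a linear paint model
x = A s with unit-length paint colours. Independent colour axes come from
FastICA; the component count (1–3) is chosen from per-source
Kullback–Leibler divergences; expected colours (blue-purple stain hint,
red-brown pigment hint, measured background) are resolved, rotated (≤ ±15°)
toward the pixel principal plane, and matched to data-driven paint
proposals by a weighted specificity criterion (weights 0.5/0.05/1). Amounts
solve X = ÂS; a sigmoid rim mask suppresses bleed-through; a two-Gaussian
adaptive threshold t ∈ [0.25, 0.67] keeps significant staining, scored by
its 85th percentile.

**Classification and clustering.** Collections are split cleared/un-cleared
by a 2-component Gaussian mixture over per-image colour signatures (LAB
mean + Cholesky factor of the pixel covariance). Same-gene/stage
spherical-stage images are compared by affine alignment of their stain maps
(BFGS from 8 canonical starts, scale-penalised; the minimum of 16 residuals
is the distance) and clustered by affinity propagation (≤ 4 clusters).
Validation statistics use Beta(1,1)-posterior error rates and Wallace
partition-agreement coefficients.

## Worked example

```r
library(wishtools)

# render a synthetic un-cleared embryo with known stain and pigment
f <- makeEmbryoImage(embryoSpec(), seed = 2)

seg <- segmentEmbryo(f$record, seed = 1)
seg
#> SegmentationResult: 6232 embryo pixels, bbox (28,21,133,100), incomplete=FALSE, downscale=1x

st <- extractPattern(f$record, seg, seed = 1)
st
#> StainResult: 3 paint component(s), threshold=0.250, stain score=0.399, confident=TRUE

# agreement with the generator's ground truth
sum(embryoMask(seg) & f$masks$embryo) / sum(embryoMask(seg) | f$masks$embryo)
#> [1] 0.9231386                      # mask IoU
ts <- thresholdedStain(st)
2 * sum(ts > 0 & f$masks$stain > 0) / (sum(ts > 0) + sum(f$masks$stain > 0))
#> [1] 0.8429119                      # stain Dice
```

The segmentation found a single embryo component whose outline overlaps the
true mask at IoU 0.92; three colour components were retained (stain,
pigment, background bleed), the stain colour was confidently identified,
and the thresholded stain map matches the true stained region at Dice 0.84.

Command line, over a directory of images named like `gene_st15_lateral.png`:

```sh
inst/exec/wishtools analyse-image --input embryo.png --out results/embryo --cleared no
inst/exec/wishtools select-images --collection images/ --out selected/ --seed 1
inst/exec/wishtools evaluate --mode beta --trials 1000 --errors 3
```

Configuration (colour hints as hex RGB, unmixing constants, stage cutoff)
can be given as a YAML file via `--config`; CLI flags override the file,
which overrides the built-in defaults.

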