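# veinfuse

Enhancement and segmentation of near-infrared (NIR) dorsal hand-vein
images. Under ~850 nm illumination, subcutaneous veins absorb more light
than the surrounding tissue and appear as dark curvilinear structures on a
brighter background — but captured images are low contrast, unevenly lit
and noisy, which hurts downstream uses such as biometric identification
and intravenous access guidance. `veinfuse` is for researchers and
engineers who need a reproducible, fully scripted version of this
pipeline, complete with synthetic phantoms that carry exact ground truth.

## Method

The enhancement runs two branches on the standardized 192×192 image and
fuses them:

1. **CLAHE** (local): per-tile histogram equalization with a clip limit.
   Each tile's histogram is clipped at a fraction of the tile pixel count,
   the excess redistributed uniformly, and the mapping
   `g = (g_max − g_min)·Pf + g_min` (with `Pf` the cumulative
   distribution) applied through bilinear blending of neighboring tile
   mappings.
2. **FAG** (global, fuzzy adaptive gamma): gray levels are fuzzified to
   memberships `m = (I − I_min)/(I_max − I_min)`, transformed with an
   adaptive exponent `γ = −log₂(σ)` — bright images (`μ ≥ 0.5`) by the
   power law `m^γ`, dark images by
   `m^γ / (m^γ + (1 − m^γ)·μ^γ)` — and defuzzified hyperbolically:
   `I' = (L−1)(e⁻¹−1)⁻¹(e^{−m}−1)`.
3. **Improved weighted-average fusion**:
   `f = (1−ω₀)·g₀ + ω₀·g₁ + α − β(g₀ − g₁)` with `ω₀ = 0.5`, `β = 0.01`,
   and `α = 7` (bright profile) or `α = 1` (dark profile).

Veins are then segmented with a matched filter paired with the first-order
derivative of Gaussian (MF-FODG): an orientation bank of inverted-Gaussian
vessel templates, an adaptive threshold `T = (1 + D_m)·c·mean(H)` that
uses the local mean of the derivative response to suppress step edges, and
8-connected small-object removal. FHH (fuzzy histogram hyperbolization)
and plain AGC baselines, quality metrics (MSE, PSNR, global SSIM),
segmentation metrics (sensitivity, accuracy, Dice), isodata thresholding
and a seeded phantom generator round out the package.

## Worked example

```r
library(veinfuse)

ph <- generate_phantom(phantom_spec(seed = 7))   # bright low-contrast phantom
ph$image
#> <gray_image 192x192, L=256, range [84, 196], mean 162.92>
classify_brightness(ph$image)$label
#> [1] "bright"

enh <- enhance_image(ph$image, technique = "improved_fusion")
enh$settings$fusion$alpha                        # bright profile selected
#> [1] 7
unlist(quality_metrics(ph$image, enh$image))
#>         mse        psnr        ssim
#> 554.0017090  20.6956926   0.6483484

mask <- segment_veins(ph$image)
unlist(seg_scores(confusion(mask, ph$mask)))
#>        se       acc      dice
#> 0.5708725 0.9641113 0.7268222
```

The quality row says the fused image differs from the original by an MSE
of 554 gray levels² (PSNR 20.7 dB) while keeping a global structural
similarity of 0.65 — a substantial, structure-preserving contrast change.
The segmentation row scores the predicted mask against the generator's
exact ground truth: 57% of vein pixels recovered, 96% of all pixels
correct, Dice overlap 0.73 on this noisy, low-contrast phantom. Clean
matched-width veins are recovered with Dice ≈ 0.9 (see the tests).

## Command line

```sh
inst/cli/veinfuse simulate --out data --n 20 --seed 1 --profile bright
inst/cli/veinfuse enhance  --input data --out enhanced --technique improved_fusion
inst/cli/veinfuse segment  --input data --out masks --technique improved_fusion
inst/cli/veinfuse evaluate --pred masks --truth data --orig data --out report.csv
```

Every enhancement writes a JSON sidecar with the effective parameters, so
a run is reproducible from its outputs alone.

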