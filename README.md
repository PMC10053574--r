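# xgifuse

Tri-contrast image fusion for X-ray grating (Talbot–Lau) interferometry.

A single interferometry acquisition retrieves three co-registered images:
attenuation contrast (AC, the conventional radiograph), differential phase
contrast (DPC, a refraction signal sensitive to soft-tissue boundaries and
fine structure), and dark-field contrast (DFC, a small-angle scattering
signal from sub-resolution microstructure such as bone cortex). Each channel
sees things the others miss; reading all three at once is cumbersome.
`xgifuse` merges them into one image that keeps the familiar attenuation
appearance while importing the channel-exclusive detail. It is intended for
researchers working with phase-contrast / dark-field radiography data and
for anyone who needs a reproducible, testable reference implementation of
this fusion family.

## The method

Three steps, all parameters exposed in a single configuration object:

1. **Adaptive Wiener denoising** per channel:
   `Î = m + max(σ² − v², 0)/σ² · (I − m)` with local moments over a 5×5
   window and the noise variance v² estimated as the mean local variance.
2. **NSCT-SCM fusion.** Each channel is decomposed by an undecimated
   multiscale + multidirectional transform (non-subsampled pyramid +
   directional filter bank; every sub-band keeps the image size, redundancy
   `R = Σⱼ 2^{l_j}`, default levels (4,4,4,4) → 64 directional bands).
   A spiking cortical model

   `U ← f·U + S·(1 + β·W∗Y)`, `Y ← [U > Θ]`, `Θ ← g·Θ + h·Y`

   (f = 0.8, g = 0.7, h = 20, k = 200 iterations) turns every sub-band into
   an *ignition matrix* of per-pixel spike counts measuring local salience.
   Lowpass coefficients are selected by comparing `a·T_AC` against
   `(1−a)·T_DPC` and `(1−a)·T_DFC` (a = 0.55 keeps the fused image close to
   AC); highpass coefficients follow a seven-case rule on ignition
   differences with threshold T_th = 1 and blend weights
   (b, c, d) = (0.41, 0.29, 0.30). The fused coefficients are inverted
   exactly.
3. **Enhancement**: CLAHE (5×5 tiles, clip 0.00125, 500 bins), entropy-
   adaptive unsharp masking (gain = argmax-entropy C divided by α = 3), and
   a sigmoid tone curve `1/(1 + exp(λ₁(λ₂ − v)))` with λ₁ = 4.8, λ₂ = 0.49.

A nine-measure evaluation suite (edge strength, spatial frequency, SD,
entropy, feature mutual information, FSIM, fusion factor, SSIM, radially
averaged PSD) with region-of-interest support, two comparison baselines, and
a seeded synthetic tri-contrast phantom generator make the whole pipeline
testable without access to interferometry data. See the methods vignette
(`vignettes/nsct-scm-fusion.Rmd`) for the model details and design choices.

## Worked example

```r
library(xgifuse)

ph  <- generate_phantom(phantom_spec(seed = 1))   # 256 x 256 tri-contrast set
res <- run_pipeline(ph$tri, fusion_config())      # denoise + fuse + enhance
res
#> <fusion_result> nsct-scm, 256 x 256; stages (s): denoise 0.04, fuse 16.2, enhance 0.4

fusion_report(ph$tri, res$fused, roi = c(65, 65, 193, 193))
#> Fusion quality report (ROI 65,65,193,193)
#>   ES       0.3204
#>   SF       0.1687
#>   SD       0.2095
#>   ENTROPY  7.6771
#>   FMI      2.6682
#>   FSIM     0.7286
#>   FF       4.3038
#>   SSIM     0.2879
#>   PSD      92 radial bins (Nyquist ring 91)
```

The report's entropy (7.68 bits) and SD (0.21) say how much information and
contrast the fused image carries; for the same phantom the per-pixel mean
baseline reaches only 6.37 bits and SD 0.087, while FF/FMI/SSIM/FSIM
measure how much of each source channel survived into the result. The
channel-exclusive phantom features (trabecular DPC texture, cortical DFC
rim) appear in the fused image with 6–8× the detail energy they have in the
attenuation channel.

A command-line front end is installed with the package:

```sh
CLI=$(Rscript -e 'cat(system.file("cli", "xgifuse", package = "xgifuse"))')
$CLI phantom --out ph --shape 256,256 --seed 1
$CLI fuse --ac ph/ac.tif --dpc ph/dpc.tif --dfc ph/dfc.tif --out fused.tif
$CLI metrics --ac ph/ac.tif --dpc ph/dpc.tif --dfc ph/dfc.tif \
     --fused fused.tif --roi 65,65,193,193 --out report.json
```

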