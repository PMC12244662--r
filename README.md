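# compassFusion

Pixel-level fusion of co-registered multimodal medical image pairs (CT +
MR and similar), for image-analysis practitioners who need a reproducible,
fully scripted fusion pipeline with quality metrics built in.

## Method

Given two registered grayscale sources `I1`, `I2` in `[0, 1]`:

1. **Gradient-compass edges.** The 3x3 Sobel kernel rotated in 45° steps
   gives eight masks `E0..E315`; since `E(θ+180) = −E(θ)`, the per-pixel
   edge strength is `EI(x,y) = max(|E0|, |E45|, |E90|, |E135|)`.
2. **Detail images.** `DI1 = I2 − EI1`, `DI2 = I1 − EI2` isolate the
   content each modality contributes beyond the other's edge structure.
3. **Covariance weights.** At each pixel, the `W×W` window `M` of the
   detail image yields `C_h = M_c' M_c/(W−1)` (and `C_v` on the transposed
   window); the fusion weight is the sum of both eigenvalue sums
   (= traces): `weight(x,y) = Σλ(C_h) + Σλ(C_v)`.
4. **Optimized merge.** A variable-order fractional multi-objective
   Darwinian PSO (VF-MODPSO) tunes window sides, gains and exponents of
   the two weight maps against the bi-objective
   `Fitness1 = 1 − (ENT/8 + FMI + Qabf)` (quality, minimized) and an
   operation-count cost, maintaining a crowding-pruned Pareto archive.
   Its velocity memory is the truncated Grünwald–Letnikov series
   `Σ c_k(α) v_{t−k+1}`, `c_1 = α`, `c_{k+1} = c_k (k−α)/(k+1)`, with the
   order α scheduled from 1.0 down to 0.6.
5. **Fusion.** `F = (I1·wt1 + I2·wt2)/(wt1 + wt2 + ε)` — every fused
   pixel is a convex combination of the sources.

Quality metrics: entropy, mutual information, feature mutual information,
Qabf edge preservation, SSIM; search indicators: IGD and exact 2-D
hypervolume. A seeded synthetic CT/MR phantom generator makes the whole
pipeline testable without any external data. See
`vignettes/compassFusion-methods.Rmd` for the full model description and
design rationale.

## Worked example

```r
library(compassFusion)

p  <- generatePhantomPair(256, seed = 7)   # registered CT-like / MR-like pair
res <- fuseImages(ctImage(p), mrImage(p), popSize = 12, maxIter = 8, seed = 11)
res
#> FusionResult: 256 x 256 fused image
#>   decision: W1=3 W2=5 g=(4.32, 5.28) gamma=(2.9, 0.327)
#>   Fitness1 = -0.7132, cost = 2.228e+06
#>   metrics: ent=5.5149, mi1=1.2683, mi2=4.5538, fmi=0.3416, qabf=0.6821,
#>            ssim1=0.6202, ssim2=0.7970
#>   archive: 4 solutions; 8 iterations run

writeImageGray(fusedImage(res), "fused.png")
```

The knee-point solution chose a 3/5 window pair; its quality objective
(−0.71) improves markedly on the unoptimized `W = 3`, unit-gain baseline
(−0.21 on this pair): the fused image keeps about 5.5 bits of entropy,
carries 4.6 bits of mutual information with the MR source, and preserves
68% of the sources' edge information (Qabf).

A thin CLI wraps the same functions:

```sh
compassfusion phantom --out pairs/ --n 2 --seed 7
compassfusion fuse --i1 pairs/pair01_ct.png --i2 pairs/pair01_mr.png \
                   --out fused.png --report metrics.csv --seed 11
```

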