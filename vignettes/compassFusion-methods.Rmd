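---
title: "Methods: gradient-compass fusion driven by variable-order fractional multi-objective DPSO"
author: "compassFusion"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: gradient-compass fusion driven by VF-MODPSO}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(compassFusion)
```

## The problem

Multimodal medical image fusion merges two co-registered grayscale scans of
the same anatomy — typically a CT image, which renders bone and other dense
structure, and an MR image, which renders soft-tissue variation — into a
single image that preserves the clinically relevant content of both.
`compassFusion` implements a pixel-level, spatial-domain fusion pipeline in
four stages: directional edge extraction, detail-image formation, windowed
covariance weighting, and a guarded weighted pixel merge, with the weighting
stage tuned by a multi-objective swarm optimizer.

## Edge extraction and detail images

Edges are detected with a gradient compass: the 3x3 Sobel kernel rotated in
45-degree steps into eight masks `E0 ... E315`. The rotation permutes the
kernel's outer ring `(-1, 0, 1, 2, 1, 0, -1, -2)`, so each mask sums to zero
and `E(theta+180) = -E(theta)`. Because of that reversal symmetry only the
four masks `E0, E45, E90, E135` are applied; the per-pixel **edge strength**
is the maximum of their absolute responses, which equals the maximum over
all eight signed responses. Correlation (not flipped convolution) is used;
for these antisymmetric kernels the distinction only flips the sign, which
the absolute value removes. Borders are handled by replicate padding so all
rasters keep the input shape.

The **detail images** cross-subtract: `DI1 = I2 - EI1` and `DI2 = I1 - EI2`.
Each detail image isolates the content of one modality that the other
modality's edge structure does not account for. Detail images are signed
and are deliberately not clamped — the covariance statistics downstream are
shift-invariant, so the signed residue carries no cost.

Source intensities are normalized to `[0, 1]` on ingest (RGB inputs are
converted by Rec. 601 luminance); quantization back to 8 bits happens only
when an image is written.

## Covariance weight maps

At every pixel of a detail image a `W x W` window (replicate-padded,
`W` odd in `{3, 5, 7, 9}`) is collected into a matrix `M` whose columns are
treated as variables and rows as observations. The horizontal covariance is
`C_h = M_c' M_c / (W - 1)` with column means removed; the vertical
covariance `C_v` applies the same construction to the transposed window
(the source material names both but defines only the horizontal one — the
transpose construction is this package's documented reading of the
"vertical" direction, symmetric by design). The directional edge strengths
are the eigenvalue sums of `C_h` and `C_v`, and the pixel weight is their
sum.

Since a covariance matrix's eigenvalue sum equals its trace, the production
path computes traces through vectorized moving-window variances — exactly
equivalent, and validated against an explicit eigendecomposition oracle in
the test suite at `1e-10` relative tolerance. Weights are nonnegative,
shift-invariant, and quadratic in the intensity scale.

## The fusion rule and its search space

Pixels merge by the non-adaptive weighted mean
`F = (I1 wt1 + I2 wt2) / (wt1 + wt2 + eps)` with guard `eps = 1e-12`;
where both weights vanish the arithmetic mean is used. Every fused pixel is
therefore a convex combination of the two source pixels — the per-pixel
bound `min(I1, I2) <= F <= max(I1, I2)` is asserted in the tests.

Optimizing every one of the `2 H W` weights directly would be intractable
and would discard the constructive covariance definition, so the optimizer
tunes a six-parameter reshaping of the covariance maps instead:

* window sides `W1, W2` (each from `{3, 5, 7, 9}`, encoded as an index in
  `[0, 3]` and rounded),
* gains `g1, g2` in `[0.1, 10]`,
* exponents `gamma1, gamma2` in `[0.25, 4]`,

with `wt_i = g_i * pixelWeightMap(DI_i, W_i)^gamma_i`. This keeps the
constructive weighting while letting the search trade detail emphasis
between modalities. It is the package's principal design decision and the
largest gap filled relative to the method narrative it implements.

Two objectives are minimized:

* **Quality**: `Fitness1 = 1 - (ENT/8 + FMI + Qabf)`. The entropy is
  divided by its 8-bit cap so all three terms share the `[0, 1]` scale;
  otherwise raw entropy (typically 6–8 bits) would dominate the sum. Raw
  entropy is still reported.
* **Cost**: by default the deterministic operation-count proxy
  `(W1^2 + W2^2) * H * W`, which makes runs hardware-independent and
  reproducible; a wall-clock mode exists for parity with timing-based
  evaluation.

The returned solution is the **knee point** of the final archive — the
member closest to the ideal point after normalizing both objectives to
`[0, 1]` over the archive. One particle is warm-started at the baseline
configuration (`W = 3`, unit gains and exponents). Because the baseline has
the minimum possible proxy cost, every archive member either is that
min-cost solution (whose quality is at least as good as the baseline's) or
has strictly better quality — so the selected solution can never lose to
the baseline on `Fitness1`, whichever archive member the knee rule picks.

## The optimizer

The search engine is a multi-objective Darwinian PSO. Velocities update as

```
v <- memory(history, alpha) + rho1 r1 (gbest - x)
     + rho2 r2 (pbest - x) + rho3 r3 (nbest - x)
```

with fresh uniform `r` draws per component, `rho = 0.8` for all three
attractors (no values are prescribed by the source material; 0.8 is a
conventional mild-acceleration setting), velocity clamped to 20% of the box
width, and clip-with-velocity-reflection at the bounds.

* **Global leader** `gbest`: drawn from the bounded global Pareto archive
  by binary tournament on NSGA-II crowding distance (prefers sparse
  regions of the front).
* **Personal leader**: a uniform draw from the particle's bounded personal
  archive (capacity 5, same dominance/crowding rules).
* **Neighbourhood leader**: within a ring neighbourhood of radius 1, the
  member minimizing the scaled objective sum — a deterministic choice that
  is always nondominated within the trio.
* **Archive**: candidates enter iff nondominated, remove what they
  dominate, and overflow drops the most crowded entry (smallest crowding
  distance). Capacity defaults to the population size (50).
* **Darwinian rules**: a particle whose personal archive has not improved
  for 5 consecutive iterations is deleted (respecting a population floor
  of 10); each deletion increments `Nkill`; a new uniform particle spawns
  with probability `SCc(Nkill) = 0.9 (1 - 1/(Nkill + 1))` up to a
  population cap of 60.

### Variable-order fractional memory

The inertia term is replaced by a truncated Grünwald–Letnikov series over
the last `r = 4` velocities with weights `c_1 = alpha`,
`c_{k+1} = c_k (k - alpha)/(k + 1)`. At `alpha = 1` all but the first
weight vanish and the classical unit-inertia update is recovered exactly —
with depth 1 and Darwinian rules disabled, `runVFMODPSO()` is bit-identical
to `runMODPSO()` under the same seed, which the tests assert. The order
follows a linear schedule from `alphaHi = 1.0` down to `alphaLo = 0.6`
(high order early for fast convergence, longer memory late for
exploration). The order range is read as `[0.6, 1.0]`: orders above 1 break
the decaying-memory interpretation, and the fractional-PSO literature
operates in `(0, 1]`. The GL step `h` is absorbed into the unit iteration
step.

A frequency-domain route to the same memory ships alongside: the Oustaloup
recursive pole/zero ladder approximates `s^alpha` over `[0.01, 100]` rad/s
with a degree-`2N+1` rational function (`N = 2`), its gain normalized so
the magnitude at the geometric center frequency is exact; each coefficient
is fitted as a degree-5 polynomial in `alpha` over `M - 1 = 19` sampled
orders (`M = 20`). The printed form of the velocity rule that motivates
this machinery applies a rational transfer function to *powers of the
velocity vector*, which is dimensionally ill-defined for vector velocities;
the package therefore uses the GL series as the default memory and exposes
the frequency-domain construction through a documented adapter
(`oustaloupMemoryWeights()`) that discretizes the rational filter by the
bilinear transform and takes its leading impulse-response samples as
effective memory weights. The adapter is tested for stability and scaling,
not asserted equivalent to the GL path.

### Termination

A run stops at the first of: the iteration cap; hypervolume improvement
over a 50-iteration window below 0.01; mean pairwise distance of the
archive objectives (each normalized by its archive range) below 0.2; or
the wall-clock limit (3600 s). The diversity statistic is this package's
concrete choice for the named "population diversity" criterion, which is
otherwise unspecified. All stochastic draws go through R's seeded RNG;
identical configuration and seed reproduce the run log bit-for-bit.

## Quality metrics and indicators

* **ENT**: Shannon entropy on 256 uniform bins over `[0, 1]`.
* **MI**: `H(a) + H(b) - H(a,b)` on the 256x256 joint histogram. (The
  printed difference-of-entropies form that motivates it is internally
  inconsistent with its own conditional-entropy gloss; the standard joint-
  histogram definition is used.) Note the plug-in estimator carries an
  upward bias of roughly `(K-1)^2 / (2 N ln 2)` bits for `K` occupied
  levels and `N` pixels, which matters when checking independence on
  continuous noise.
* **FMI**: normalized mutual information `2 MI / (H1 + H2)` between Sobel
  gradient-magnitude images of the fused image and each source, averaged
  over the sources; 1 for self-fusion, 0 for featureless inputs.
* **Qabf**: Xydeas–Petrovic-style edge preservation. Per-pixel gradient
  strength/orientation agreement maps through sigmoid models with the
  conventional constants (`0.9994, -15, 0.5` for strength;
  `0.9879, -22, 0.8` for orientation). The sigmoid product is normalized
  by its value at perfect preservation so an exactly preserved edge scores
  1 (the raw sigmoid product saturates near 0.975, which would understate
  perfect self-fusion); the per-source maps are averaged with source
  gradient strengths as weights.
* **SSIM**: mean local structural similarity over an 11x11 Gaussian window
  (`sigma = 1.5`), `C1 = 0.01^2`, `C2 = 0.03^2` at unit dynamic range.
* **IGD**: mean distance from dense reference-front samples to the nearest
  archive member. **HV**: exact 2-D sweep of the dominated region bounded
  by a reference point (inclusion–exclusion up to 4 objectives), checked
  against a Monte-Carlo oracle in the tests.

## Synthetic phantoms

`generatePhantomPair()` draws a seeded, registered CT-like/MR-like pair:
one shared elliptical head geometry; a skull ring bright (> 0.9) in CT and
dark (< 0.1) in MR; flat CT soft tissue with high-intensity bone inserts;
smoothly textured MR interior with bright lesions; additive Gaussian noise
(default sigma 0.01, a mild acquisition-noise level) clipped to `[0, 1]`.
The generator emulates exactly the property the pipeline exploits —
complementary, spatially registered structure — and the masks it returns
make edge-recall assertions possible (at zero noise, at least 95% of
ring-boundary pixels exceed the 90th percentile of the CT edge-strength
map).

What the phantoms do **not** emulate: anatomical realism, partial-volume
effects, bias fields, modality-specific noise statistics, or registration
error. Passing tests therefore demonstrate algorithmic correctness and the
claimed invariants, not clinical image quality.

## Problem sizes and numerical choices

The test suite and the acceptance script choose sizes that exercise every
code path at full fidelity: toy-problem convergence uses population 50 for
200 iterations over 10 seeds (the convergence studies disable the
stagnation-based early stops so the stated iteration budget actually runs);
end-to-end fusion uses 256x256 phantoms with a 12-particle, 8-iteration
search (96 full-image quality evaluations), and smaller 64x64 phantoms
where only invariants are asserted. Degenerate inputs are defined, not
errors: constant images have zero entropy and zero weights; both-zero
weights fall back to the pixel mean; featureless inputs score 0 on FMI and
Qabf. `maxIter = 0` returns the nondominated subset of the initial
population. Ties in the neighbourhood leader resolve to the first member;
archive duplicates (equal objective vectors) are not re-inserted.

## Known limitations

* The six-parameter search space is a deliberate, documented reduction of
  "optimize all per-pixel weights"; richer parameterizations (e.g.
  region-wise gains) would slot into the same decision-vector interface.
* Grayscale 2-D only; color and volumetric fusion are out of scope.
* The dominance filter and archive updates are quadratic in archive size —
  appropriate at the default capacity of 50, not for archives of many
  thousands.
* The Oustaloup adapter is a faithful bridge, not a calibrated equivalent
  of the GL memory; the default optimizer path never depends on it.
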