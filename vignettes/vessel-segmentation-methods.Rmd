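---
title: "Methods: Retinex correction, local-phase enhancement and graph-cut segmentation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: Retinex correction, local-phase enhancement and graph-cut segmentation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vesselseg)
```

vesselseg segments blood vessels in 2D retinal images by an unsupervised
three-stage pipeline: intensity-inhomogeneity correction (Retinex with a
bilateral filter), tubular-structure enhancement (a multi-scale,
multi-orientation quadrature filter bank producing a local-phase
"vesselness" map), and two-phase region segmentation of that map (the
Chan–Vese energy, minimized exactly at each step by a min-cut). This
vignette documents the model behind each stage, the parameters that
matter, the numerical choices we made where the design was genuinely
open, and the limits of what the synthetic test phantoms can show.

## Stage 1 — Retinex inhomogeneity correction

The Retinex model writes the observed image as a pixelwise product
`I = R · L` of a reflectance `R` (the tissue signal we want) and a
slowly varying illumination `L`. We estimate `L` with a bilateral
filter: at each pixel the illumination is the weighted average of the
window values, with weights

* a spatial Gaussian of the Euclidean pixel distance (spread `sigma_d`),
* an intensity Gaussian of the intensity difference (spread `sigma_r`,
  on the [0, 1] intensity scale),

normalized so the weights sum to one (`bilateral_illumination()`). The
corrected image is the min–max-normalized log-reflectance
`R = log(255·I + 1) − log(255·L + 1)` (`reflectance()`).

Numerical choices:

* **Spatial scale of `sigma_d`.** The two spreads default to 0.3 each.
  For `sigma_r` the natural scale is the unit intensity range. We place
  `sigma_d` on the unit-normalized *spatial* domain as well (distances
  divided by the image diagonal). Measured in raw pixels, `sigma_d = 0.3`
  would give every neighbor a weight of `exp(-5.6)` — the filter would be
  the identity and the correction a no-op; on the normalized domain the
  spatial kernel is effectively flat inside a small window and the range
  kernel provides all the selectivity, which is the behavior an
  edge-preserving illumination estimate needs.
* **Log scale.** The "+1" is applied on the native 8-bit scale
  (0–255), where it only guards `log(0)` and the difference of logs is a
  genuine log *ratio*, so multiplicative shading cancels. On [0, 1]
  intensities `log(1 + I)` is nearly linear and the operator would keep
  shading (min–max normalization absorbs affine maps, not the log
  curvature).
* **Borders** are handled by clipping the window; the normalization
  constant renormalizes automatically.
* **Degenerate normalization.** If the raw reflectance is constant (a
  constant image), min–max normalization is undefined; we return the
  information-free midpoint image 0.5.

Intrinsic limitation worth stating plainly: with a 3×3 window the
correction is a one-pixel-scale high-pass. It flattens the interior of
any structure wider than the window (only vessels up to ~2–3 px keep an
interior residual) and it passes almost all pixel noise while responding
to only part of the structural contrast. It therefore helps only on
imagery with thin vessels and low sensor noise — which is the regime of
screening fundus photography — and it degrades high-noise synthetic
phantoms. The tests and the acceptance script measure both regimes
honestly; see "What the phantoms do and do not show" below.

## Stage 2 — Local-phase vessel enhancement

A quadrature filter pairs an even-symmetric kernel `E` and an
odd-symmetric kernel `O` with a 90° phase offset. Convolving an image
with `E + iO` gives a complex response `q = e + i·o` whose magnitude is
the local energy and whose argument is the local phase: on a line the
even part dominates (`|e|` maximal, `o ≈ 0`), on an edge the odd part
dominates and the real part crosses zero. This lets a filter bank
separate lines (vessels) from edges by phase rather than by amplitude
alone.

The bank is built in the frequency domain (`make_lognorm_quadrature()`)
as a log-normal radial profile
`exp(−4 ln²(ρ/ρ_n) / (B² ln 2))` with center frequency
`ρ_n = ρ_0 / 2^(n−1)` and bandwidth `B` octaves, times an angular
`cos²(φ − θ)` restricted to the half-plane `cos(φ − θ) > 0`. Defaults:
`ρ_0 = 5π/7` radians/pixel (wavelength ≈ 2.8 px, matched to thin
vessels), `B = 2`, kernel size 15×15, four orientations
`{0, π/4, π/2, 3π/4}`, two scales.

Responses are combined in three steps:

1. per scale, orientations are summed after rectifying the odd part,
   `q_n = Σ_j (e_n^j + i |o_n^j|)` — the odd sign flips with structure
   polarity across direction, so only its magnitude is informative;
2. scales are blended with magnitude weights,
   `P = Σ_n q_n |q_n|^β / Σ_n |q_n|^β` (default `β = 1`; pixels where
   all scales vanish get 0);
3. the vesselness map is the soft-normalized real part,
   `LP = Re(P)·|P| / (|P|² + a²)`.

The map is positive inside bright line structures, negative in the
background (the even kernels' flanking lobes; the DC-free kernels make
the map integrate to ≈ 0), and zero at structure edges.

Numerical choices:

* **Design grid 65×65, then crop.** The kernels are sampled on an odd
  frequency grid so every `+k` has a matching `−k` and the grid has an
  exact center; this makes the even/odd symmetries, the θ → θ+90°
  transpose identity and 90°-rotation equivariance of the whole bank
  exact to machine precision. (An even grid's unpaired Nyquist row breaks
  all three at the ~1e-3 level.)
* **Apodization and DC projection.** A plain 15×15 crop of the ideal
  kernel rings: its measured DC leakage is ~5e-3 of the peak and its
  response peak sits ~19% above the design frequency. We taper the crop
  with a separable raised-cosine window and subtract the even kernel's
  mean (the minimal-norm correction that zeroes DC exactly; the odd
  kernel is DC-free by antisymmetry). The realized peak then lands
  within ~5% of `5π/7`.
* **The regularization constant `a`** defaults to `max|P|` of the image
  at hand. The normalization `t·|t|/(|t|²+a²)` attains its extremum 1/2
  exactly at `|P| = a`, so this choice maps the strongest response to
  1/2 and bounds the map to `[−1/2, 1/2]`; smaller `a` saturates the map
  toward ±1 and amplifies weak noise responses. `a` is exposed for users
  who prefer a fixed constant.
* **Convolution** is FFT-based with mirrored (symmetric) border padding;
  a complex kernel computes both responses in one pass. The direct
  spatial convolution is kept in the test suite as the oracle.

## Stage 3 — Chan–Vese segmentation by graph cuts

The two-phase Chan–Vese energy scores a binary labeling `x` of the map
`I` by

`E(x) = μ Σ_{(i,j)} w_ij [x_i ≠ x_j] + λ1 Σ_{x_i=1} (I_i − c1)² + λ2 Σ_{x_i=0} (I_i − c2)²`

with `c1`, `c2` the foreground/background means. The boundary term uses
the Cauchy–Crofton (geo-cuts) weights
`w_ij = δ² Δφ / (2 |e_ij|)` — `π/4` per edge at 4-connectivity;
`π/8` axial and `π/(8√2)` diagonal at 8-connectivity — so the cut cost
approximates the Euclidean boundary length.

For fixed means the energy is a submodular binary labeling problem and a
single min-cut/max-flow finds its *global* minimizer; `min_cut()` builds
the two-terminal grid graph (after subtracting each pixel's smaller
unary, which shrinks the flow without changing the minimizer) and solves
it with a compiled Dinic max-flow (`src/maxflow.cpp`). The labeling
returned is the canonical cut whose source side is the set reachable in
the residual network — deterministic, and resolving indifferent pixels
(equal unaries at `μ = 0`) to background. `segment_cv_graphcut()`
alternates exact mean updates with exact cuts; both half-steps are
descent steps, so the recorded energy trace is non-increasing — an
invariant the test suite checks on every run it makes.

Numerical choices:

* **`λ1 = 1, λ2 = 4` defaults** follow the published calibration for
  graph-cut segmentation of vesselness maps. With `λ2 > λ1` the
  background class is the tight one, which raises sensitivity when the
  background mode of the map is narrow.
* **`μ = 0.02` default.** Boundary edges cost `μ·w` with `w ≈ 0.2–0.4`,
  while per-pixel data differences on a map bounded by ±1/2 are
  typically 0.01–0.05. A length weight of order 1 would dominate every
  attainable data gain and make a constant labeling globally optimal;
  0.02 puts the prior at the same order as the data term.
* **Initialization.** The foreground seed is `map > mean + 2·sd`
  (clearly positive vesselness). Seeding with *all* positive pixels is
  unreliable: under noise about half the background is barely positive,
  the initial `c1` is dragged toward zero, and the first global cut can
  absorb the entire background. With the conservative seed the
  noise-free thin-vessel phantom is recovered essentially exactly
  (Dice ≈ 0.999 in the test suite).
* **Empty regions** fall back to the global mean so the iteration stays
  defined; convergence is declared when the fraction of pixels changing
  label falls below `tol = 0.001`, or after 30 cuts.
* **Field of view**: when a FOV mask is supplied, outside pixels are
  forced to background after convergence, matching dataset practice.

## Evaluation

Pixel-wise confusion counts (label 1 = vessel) give sensitivity
`tp/(tp+fn)`, specificity `tn/(tn+fp)`, accuracy, and the two-point AUC
surrogate `(Se+Sp)/2` — not a threshold sweep. When a FOV mask is
present only in-mask pixels are counted (the DRIVE convention); both
modes are available. Dataset tables average per-image metrics
unweighted. Dice overlap is provided for phantom work.

## Synthetic phantoms: what they emulate, and what passing tests show

`vessel_phantom()` renders straight constant-intensity tubes (a pixel is
vessel iff its center is within `width/2` of the axis; round caps), then
multiplies an optional smooth shading field in [0.5, 1], then adds
Gaussian noise and clips to [0, 1]. Ground truth is fixed before shading
and noise. All generators are pure functions of their spec, seed
included. Two presets:

* `fig_phantom_spec()` — a high-contrast symbol of tubes with widths
  2–10 px and orientations 0–135°, with heavy noise (σ = 0.2): the
  classic stress test for tubular *enhancement*. Test problem size is
  160×160.
* `retinal_phantom_spec()` — thin (2–3 px), moderate-contrast (0.25)
  vessels over a mid-gray background with realistic sensor noise
  (σ = 0.01), optionally shaded and with a soft-edged bright disc
  mimicking the optic nerve head: the regime the *full pipeline* is
  designed for.

The phantoms deliberately omit branching trees, caliber variation along
a vessel, texture, and the central light reflex; passing phantom tests
therefore demonstrates the numerical correctness and the qualitative
behavior of each stage, not dataset-level accuracy. Two negative results
on phantoms are themselves informative and are reported (not hidden) by
the acceptance material:

* On the σ = 0.2 high-contrast phantom the *full* pipeline fails: the
  3×3 Retinex stage cannot pass structures wider than its window at any
  contrast that also beats that noise level, and on the noisy map the
  `λ2 > λ1` data weighting slowly absorbs the background (the
  enhancement-plus-segmentation core without Retinex, or realistic noise
  levels, recover the phantom well).
* On smoothly shaded phantoms disabling Retinex does **not** lower the
  AUC: the band-pass filter bank is nearly invariant to a [0.5, 1]
  multiplicative field, and the map's edge-zero-crossing property
  already nulls soft disc rims, so there is nothing left for Retinex to
  fix — while its noise amplification has a cost. The published benefit
  of the correction on real fundus data comes from textured optic-disc
  regions that these smooth phantoms do not contain.

## Known limitations

* AUC here is the two-point surrogate, comparable across methods that
  report it the same way but not equal to a swept ROC area.
* The graph cut solves each inner problem globally but the alternating
  scheme is only a block-coordinate descent; on heavy-noise maps with
  `λ2 > λ1` it can drift to a trivial labeling (see above).
* The Retinex stage presumes thin vessels and low noise; for wide-field
  angiograms with thick bright vessels, run with `retinex = FALSE`
  and/or `invert = TRUE`.
* Supported raster formats are PNG, TIFF and JPEG.
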