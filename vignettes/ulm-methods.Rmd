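---
title: "Methods: super-resolution ULM analysis of tumor microvasculature"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: super-resolution ULM analysis of tumor microvasculature}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vasculm)
```

## Scope and model

`vasculm` analyzes contrast-enhanced ultrasound IQ ensembles of tumor
microvasculature: it suppresses tissue clutter, localizes and tracks
individual microbubbles, reconstructs super-resolved density and velocity
maps, and reduces them to per-tumor scalar read-outs suitable for
treatment-arm comparisons. The acquisition itself (beamforming, angle
compounding, probe control) is outside the package: the input contract is a
complex stack `S(z, x, t)` with known pixel pitch, effective frame rate and
center frequency, as produced by any plane-wave imaging chain. Because no
public acquisitions accompany this kind of experiment, the package carries
a first-class synthetic-scene module whose output exercises every
downstream stage against known ground truth.

Coordinates follow one convention everywhere: axial `z` = depth, increasing
downward; lateral `x` = width; physical positions in mm (µm for
super-resolved quantities), pixel indices 0-based with positions at pixel
centers. This is what makes sub-pixel accuracy checks meaningful across
module boundaries.

## Clutter filtering

The stack is reshaped to a Casorati matrix (space × slow time; axial index
fastest) and SVD-filtered: the `k` leading singular values are zeroed and
the stack reconstructed. The filter is exactly the orthogonal projection
off the top-`k` left-singular subspace; energy is conserved between the
removed and retained parts (Frobenius identity), which the tests assert to
1e-6 relative.

The cutoff `k` is chosen adaptively as the point of maximum curvature
(largest discrete second difference) of the log singular-value curve,
bounded to a configurable window (default [2, 40]); a flat spectrum falls
back to the window minimum with a warning, and a fixed-cutoff override
exists. The published adaptive selectors in this area are not specified to
the formula level; maximum log-spectrum curvature was chosen because it is
deterministic, parameter-light, and lands in the 10–20 range typically
reported for tumor acquisitions when run on matched synthetic scenes
(clutter rank 15 — the midpoint of that range — is the generator default).

Only the low-order side is removed. High-order (noise) truncation is
deliberately not applied; instead a noise-reference ensemble, filtered
identically, yields a per-depth-row gain `g(z) = 1/sqrt(mean noise power)`
(lateral averaging, 9-row moving-average smoothing) that flattens the
depth-dependent noise floor. The depth law in the generator is
`variance ∝ exp(z/τ)` (default τ = 1.5 mm), so the estimated gain can be
checked against the closed form `exp(−z/2τ)`.

## Localization

Filtered frames are interpolated to the 5 µm reconstruction grid by a
tensor-product cubic interpolating spline. Interpolation is linear in the
data, so the package precomputes one interpolation matrix per axis (spline
through each unit impulse) and applies two matrix products per frame;
original nodes are preserved exactly and the dense-oracle error on
band-limited fixtures stays below 1% of peak.

Overlapping bubble populations are split by a three-cone partition of the
3-D spectrum: each voxel is classified by apparent axial speed
`|f_t| / |k|` (spatial-frequency magnitude; the `k = 0` plane goes to the
slow cone) against two thresholds (default 1 and 5 mm/s). The cones
partition the spectrum — no overlap, no gap — so the three subsets sum to
the input exactly; losslessness is favored over replicating any particular
published cone geometry, which is not restated at parameter level.

Centroids are regional maxima (8-connected, plateaus collapsed to their
centroid) of the normalized cross-correlation between the frame envelope
(magnitude — the phase of upsampled IQ carries speckle structure the
Gaussian model does not represent) and a separable Gaussian PSF truncated
at ±3σ. Scores below `min_corr` (default 0.6, validated on the synthetic
false-positive Monte-Carlo) are discarded, and centroids closer than
FWHM/2 keep only the higher score, preventing sidelobe double-counting.
PSF widths default to the generator's rendering values (σ = 25 µm axial,
40 µm lateral at 20 MHz) and can be fitted from the brightest isolated
blob (`fit_psf_sigma`) or set explicitly.

Two resolution regimes matter. A *simultaneous* pair of equal Gaussians
merges below ≈ 2σ separation (and the matched filter broadens peaks by
√2), so 50 µm twin bubbles are only a well-posed single-frame oracle for
σ ≤ ~17 µm. ULM's practical super-resolution instead comes from temporal
sparsity: bubbles transit at different times, so the accumulated map
resolves 50 µm vessel pairs even with the realistic 40 µm PSF. The test
suite demonstrates both regimes separately.

## Tracking and maps

Linking is optimal per frame pair: squared displacements gated at
`max_disp` enter an augmented linear assignment (Hungarian algorithm in
C++) whose objective is the total linked squared displacement plus
`max_disp²` per unlinked detection. Gap closing, merging and splitting are
deliberately absent: gaps would contradict the consecutive-frame
persistence semantics, and the simple linker is verifiable against
exhaustive enumeration (asserted exactly for ≤ 6 detections/frame). Tracks
shorter than 10 frames are removed. The default gate is 1.5× the largest
expected per-frame advection plus two super-pixels of localization-jitter
allowance.

Speeds are step length × frame rate after a centered moving average
(window 3, symmetric shrink at the edges so linear motion is preserved
exactly); differencing amplifies localization jitter and the light
smoothing keeps recovered speeds within 10% of assigned values on
synthetic vessels. Density maps count track points (post-persistence, per
the pipeline order; raw-centroid counting remains available by passing
unlinked centroids), and the velocity raster is the count-weighted mean
speed per super-pixel. Σ density = Σ track points exactly.

## Vascular metrics

ROIs are closed Hobby interpolating splines through manual control points
(unit tension; the cyclic mock-curvature system solved exactly),
discretized to ≥ 200 boundary points and rasterized by even-odd
pixel-center parity. Long-axis diameter is the convex-hull diameter
(equals exhaustive pairwise search). Intervessel distance binarizes the
density map at count ≥ 1 (any localized bubble marks vasculature;
threshold configurable) and takes the exact Euclidean distance transform
of avascular pixels to the nearest vascular pixel; both mean and median
are reported, the mean being the headline. Chamfer approximations were
rejected because the brute-force oracle equivalence is asserted exactly.

DM and SOAM operate on centerline paths obtained by Zhang–Suen thinning of
the binarized map, cut at junctions (diagonal adjacencies shortcut by an
orthogonal 2-path are dropped so staircase pixels are not mistaken for
branch points), with paths under 50 µm discarded. In 2-D the SOAM is the
in-plane restriction of the 3-D formulation — no torsion term exists.
Closed skeleton loops have no chord and are excluded from DM. Skeleton
paths, not tracks, feed the tortuosity metrics: tracks are noisy and
fragmented, while the skeleton is deterministic given the map.

The box-counting dimension uses dyadic boxes anchored at the raster
origin, `s = 1 … 2^k`, `k = floor(log2(min side)) − 1`, and a least-squares
line on `log N(s)` vs `log s`. The default fit window excludes the three
smallest scales (s = 1, 2, 4) and the largest: for structures rendered one
pixel wide (skeletal vasculature, DLA branches) box sizes comparable to
the pixel sit below the set's inner cutoff and pull the slope toward 1 —
on 20,000-particle DLA clusters local slopes rise from ~1.1 at s = 2 to
~1.7 at s = 32–64, while the mass–radius exponent of the same clusters is
1.65–1.70. Exactly self-similar fixtures (line, plane, dyadic Sierpinski
gasket) measure identically under any window, so the window choice only
matters, and is documented, for pixel-thin mass fractals. R² of the fit is
reported as a quality flag. A gasket rendered by 3 copies at scale 1/3
(a "729 px / 6 iteration" construction) has dimension log3/log3 = 1 and is
not a valid 1.585 fixture; the tests use 9 dyadic iterations at 512 px.

The DLA generator is the standard lattice model: single seed, walkers
launched from a circle at cluster radius + 5, 4-neighbor steps, stick on
arrival at a 4-adjacent site, killed at 3× the birth radius; walkers far
outside the cluster take exact circular long jumps. These are the textbook
choices that reproduce the literature dimension ≈ 1.71 asymptotically;
at n = 20,000 the box-counting estimate is 1.63–1.66 across seeds.

## Histology

DAB is extracted by optical-density conversion (`OD = −log10(I/255)`,
intensities clipped at 1) and unmixing with the standard published
hematoxylin/DAB stain vectors (residual = normalized cross product;
matrix configurable). H-scores are pixel-based:
`H = 100·(p₁ + 2p₂ + 3p₃)` with OD bin thresholds (0.2, 0.4, 0.6) —
defaults chosen mid-range because no thresholds are standardized for
pixel scoring. This is a documented divergence from pathologist per-cell
scoring, which would require nuclear segmentation; it is deterministic and
round-trip testable against the synthetic section generator, whose forward
model is the exact inverse of the unmixing matrix (8-bit quantization is
the only loss, ±10 H-score points bounds the round trip comfortably).

## Statistics

Endpoint-only quantities use `stats::aov` + `stats::TukeyHSD`;
longitudinal quantities use the ANCOVA `post ~ pre + arm` with the
nested-model F test, refusing missing baselines. When the arms explain
nothing beyond the covariate — including the degenerate exact
`post = f(pre)` case where the F ratio is 0/0 — the group p-value is
reported as 1. No correction is applied across different metrics, only
across pairwise contrasts within a metric (Tukey). Tumors missing an
endpoint are dropped from longitudinal tests. The statistics functions
operate on whatever stratum they are handed, so cohort analyses are run
per cell line by subsetting the cohort table (pooling is the caller's
choice), mirroring how arm contrasts are reported per xenograft line.

Calibration is tested, not assumed: type-I error of the ANOVA path is
asserted within [0.03, 0.07] at α = 0.05 over 1000 null replicates, and
ANCOVA power ≥ 0.8 for a +2σ arm shift at n = 8/arm over 500 replicates
(generator: `post = 0.5·pre + N(0,1) + shift`).

## Problem sizes and generator realism

Tests and the acceptance script run scaled-down scenes — 1.5 × 2 mm
fields, 40–240 frames, 6–50 bubbles — chosen so each stage still operates
in its intended regime (clutter ≥ 20 dB above bubbles, rank 15; 20 dB
localization SNR; recirculating constant bubble count). Full-scale
defaults (2.93 × 8.82 mm, 1600 frames × 20 acquisitions, 1000 Hz) remain
the `scene_config` defaults.

What the generator does *not* emulate bounds what green tests show about
real data: clutter is exactly low-rank with smooth orthonormalized modes
(real tissue is approximately low-rank at best; the chicken-embryo
clutter statistics are not characterized anywhere, so the low-rank model
is an assumption, not a fit); bubbles are linear Gaussian echoes with
log-normal amplitude constant along a track (no nonlinear oscillation,
shadowing, or destruction); noise is Gaussian with a clean exponential
depth law; vessel trees are 2-D with circular cross-sections and plug
flow. Passing tests therefore validate the algorithms' correctness and
calibration under stated assumptions, not robustness to every in-vivo
artifact.

## Known limitations

No gap closing in tracking (fragmented tracks at missed detections are
counted separately); localization reports grid positions (no sub-grid
quadratic refinement — the 5 µm pitch already dominates the error
budget); DM/SOAM inherit skeletonization noise at map pitch; pixel-based
H-scores are not cell-based; all analysis is 2-D in-plane.
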