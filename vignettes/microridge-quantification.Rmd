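---
title: "Quantifying microridge patterns: models, parameters and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying microridge patterns}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ridgemetrics)
```

## The measurement problem

Microridges are laterally elongated, actin-filled protrusions that tile the
apical surface of periderm cells in labyrinthine patterns. Live confocal
imaging of the developing epidermis produces 4D stacks in which the
patterned periderm layer sits above a speckled basal layer, cells drift and
deform, and the ridges themselves continuously merge, split, elongate and
fragment. `ridgemetrics` implements the full chain from such stacks to
biophysical summary statistics. This vignette records the models behind
each stage, the tunable parameters with their defaults and units, the
design choices that were genuinely open, and the known limitations.

## Slice filtering and projection

Periderm slices carry sparse, smooth structure and therefore have low
Shannon entropy; basal slices are speckle-rich and entropy-dense. We
compute global entropy in bits over a 256-bin histogram after min–max
scaling of each slice to 0–255 (`shannon_entropy()`); the 256-level
quantization is fixed here rather than inherited from an image toolbox
default. Slices at or below a per-movie `global_threshold` are kept;
within kept slices, pixels whose 3×3-window entropy
(`local_entropy_map()`, replicate-padded borders) exceeds a
`local_threshold` are set to zero before the per-time-point mean
projection. Both thresholds are configuration inputs held constant across
the time points of one movie, mirroring how they are set by inspection in
practice; masked pixels are zeroed rather than excluded from the mean —
the alternative (renormalizing the mean over surviving slices per pixel)
is equally defensible, and we chose the simpler, bias-transparent rule.

## Cell segmentation and extraction

Frames are smoothed with a unit-DC-gain Gaussian (σ = 0.7 px), high-passed
with a Butterworth transfer function `H = 1/(1 + (D0/D)^(2n))` (order
n = 1, cutoff D0 = 3 frequency-pixels; `H(D0) = 1/2`), binarized by Otsu's
global threshold, and closed with a disk structuring element
(`close_radius`, default 2 px) to seal membrane gaps. The distance term is
centred symmetrically on the spectrum centre for both axes. Enclosed
regions are labelled on the complemented mask; regions touching the image
border are dropped explicitly, as are regions failing `min_area` or
`min_solidity` cutoffs. Each surviving cell is reported with its bounding
box, convex mask, centroid, area and solidity, and its *patterned image* —
the bounding-box crop of the grayscale frame multiplied elementwise by the
convex mask — which is the unit of all downstream per-cell analysis.
Binarization method and structuring-element size are contrast-dependent in
real data and are exposed as configuration rather than fixed.

## Tracking

Cells (2.5 µm cutoff) and ridges (2.3 µm cutoff) are linked frame to frame
by minimum-total-cost bipartite assignment on centroid distances, with
pairings beyond the cutoff forbidden (they terminate one track and start
another). Plain nearest-neighbour linking is ambiguous when detections
converge; optimal assignment coincides with it in the unambiguous case and
resolves conflicts globally otherwise. No linear-assignment solver is
available among the installed packages, so the package carries a Hungarian
algorithm with potentials, which the tests check against brute-force
permutation enumeration on all small cost matrices.

## Ridge labeling

The classical labeling used to create training data is: Gaussian smoothing
(σ = 0.7 px) → derivative-of-Gaussian gradient (σ_g = 0.7 px) → second
derivative of the gradient image (derivative-of-Gaussian applied twice, not
finite differences — stable on noisy data) → Laplacian as the Hessian trace
→ rectification keeping only non-positive values (bright crests have
negative Laplacian) → logistic squashing `S = 1/(1 + exp(-sqrt(|L|)))`,
which maps background to 0.5 and crests toward 1 → Otsu binarization of
`S`. Discrete derivative kernels are renormalized so a unit ramp yields a
unit gradient, making the operators calibration-exact on affine images.

## U-net segmentation

The trainable segmenter is an encoder–decoder with `depth` levels of 3×3
convolution + ReLU + 2× max-pooling, a bottleneck convolution, nearest-
neighbour upsampling with skip connections, and a 1×1 two-class head,
trained with median-frequency-weighted pixel-wise cross-entropy by SGD with
momentum 0.9. Channel widths double per level from `base_channels`.
Normalization divides each image by its median non-zero intensity, and the
per-class weights `w_c = median(freq)/freq_c` balance the sparse foreground
against the background. Augmentation applies identical reflections,
right-angle rotations and integer translations to image and label
(nearest-neighbour, so labels stay binary).

The engine is written in plain R (im2col convolution as matrix
multiplication) and its backward pass is verified against numerical
differentiation in the test suite. The full-scale configuration
(256² inputs, depth 6, base 64, learning rate 1e-4, hundreds of epochs) is
expressible but is a multi-hour computation; the tested regime is the
reduced one — 64² synthetic striped/labyrinthine scenes, depth 2,
`base_channels = 4`, 200 pairs, 30 epochs — where a learning rate of 0.2
is appropriate for the much smaller, shallower network (at 1e-4 such a net
barely moves in 30 epochs). On this regime the held-out mean IoU exceeds
0.85, and the qualitative hyperparameter trend — smaller mini-batches with
more epochs beat large batches with few epochs at a fixed data budget — is
reproduced. Passing these tests demonstrates the training loop, loss
weighting and metrics are correct; it says nothing about accuracy on real
microscopy, which depends on data the synthetic scenes do not emulate
(occlusions, contrast gradients, out-of-focus light).

After prediction, physical pixel sizes of the resized grid are restored as
`dx = x_o · psz / input_size` (and likewise for y), where `(x_o, y_o)` is
the original extracted-cell size and `psz` the acquisition pixel size
(default 0.1977 µm); the physical extent `input_size · dx = x_o · psz` is
preserved exactly.

## Persistence length

Branches of the skeletonized mask (Zhang–Suen thinning; junction pixels
removed; 8-connected components; ≥ 10 points) are walked endpoint to
endpoint. Each trace is smoothed by a Gaussian-weighted moving window
(5 points, σ = 1 point — the window length is standard, the weight scale is
our choice) in each of 21 rotated frames spanning \[-π, π\], keeping the
rotation whose smoothed curve lies closest to the raw trace in mean
standardized Euclidean distance (standardized by the raw trace's coordinate
standard deviations); this makes the smoothing orientation-independent.
A natural parametric cubic spline (chord-length parameter) then densifies
the contour.

From ordered coordinates we compute spacings `ds_k`, four-quadrant tangent
angles, turn angles `phi_k` wrapped to (-π, π], curvature
`kappa = 2 phi / (ds_prev + ds_next)` and rescaled curvature
`kappa_s = 2 phi / sqrt(ds_prev + ds_next)`. Pooled over all branches of
all cells, `kappa_s` is fitted by the zero-mean Gaussian
`P(kappa_s) = sqrt(Lp/4π) exp(-Lp kappa_s²/4)`; both the moment estimator
`Lp = 2/var` and a least-squares histogram fit are reported (the fit is the
headline value; the moment estimator is the fallback). Then
`EI = Lp · kB · T` with T defaulting to 300 K; at `Lp = 6.1` µm this gives
`EI ≈ 2.5e-26 N m²`, and the buckling load of a 1 µm segment,
`f_c = π² kB T Lp / L²`, is ≈ 0.25 pN (≈ 0.69 pN at the pure-actin
`Lp = 17` µm).

Two properties matter for interpretation. First, the rescaling makes the
Gaussian width independent of segment length *at the sampling scale of the
chain*: the parameter-recovery tests therefore pool `kappa_s` computed
directly on worm-like-chain coordinates, and recover `Lp` within a few
percent at 1e5 segments across 1–20 µm. Second, spline densification
changes the effective `ds` and with it the `kappa_s` variance, so the
image-pipeline estimate (`estimate_lp_from_mask()`) is the literal
procedure, not a scale-free estimator; comparisons should hold the spline
factor and pixel size fixed.

## Pattern wavelength and branch lengths

The characteristic wave number integrates `|k|²` against the *amplitude*-
normalized Fourier transform, `wn² = ∫∫ |k|² |I_f| / sqrt(∫∫ |I_f|) dk`,
with the 1/(2π) transform prefactor, physical frequency axes spanning
`[-K, K)`, `K = π/Δs`, Riemann-sum integrals, and the DC bin excluded from
both integrals (a constant offset carries no wavelength). We implement the
definition literally — integrating `|I_f|`, not `|I_f|²` — and verify it
against an independently written transcription using explicit DFT matrices
to 1e-6 relative on random fixtures. A consequence of the amplitude (rather
than power) moment is worth stating plainly: for binary patterns the edge
harmonics dominate the `|k|²` moment, so `wn` scales with the frequency
bound and `lambda` is proportional to the pixel pitch — on identical
physical stripes sampled at Δs = 0.2/0.1/0.05 µm the statistic returns
λ = 0.377/0.184/0.098 µm. The statistic is therefore comparable only
between images sharing one pixel size (as in a single-instrument study);
the tests pin this scaling down, and cross-resolution comparisons should
use the spectral peak instead. Mean branch length is the pixel count per
junction-free skeleton branch times Δs, with no √2 diagonal weighting —
the literal pixel-count reading.

## Flow and strain

Optic flow solves the brightness-constancy constraint
`ΔI/Δt = -v · ∇I` per pixel by least squares over a 5×5 window, with
spatial gradients from derivative-of-Gaussian kernels (σ = 1.5 px). The
temporal difference is smoothed with the *same* Gaussian as the spatial
gradients; otherwise the mismatch of transfer functions biases the ratio
upward by tens of percent on textured scenes, while with matched smoothing
the estimates track analytic fields to a few percent. Rank-deficient local
systems (texture-free pixels) get zero velocity and are flagged. Velocities
are converted to µm/min using the pixel size and frame interval.

Velocity components are smoothed with the 3×3 mean kernel before
differentiation. Box averaging preserves affine fields exactly, so repeated
passes (`smooth_field(..., passes = n)`) suppress estimator noise in the
derivatives without biasing linear flow; divergence-level analysis uses
several passes (the tests use 8), at the cost of blurring genuinely
nonlinear flow structure below the ~n-pixel scale. Divergence and the
velocity gradient use central differences with physical spacing (one-sided
at borders, exact on affine fields). The strain-rate tensor keeps the
symmetric part only; its eigenvalues are the tensile/compressive rates, and
the area–deviatoric split `S = tr(S)/2 · I + S_dev` satisfies
`tr(S_dev) = 0` and `tr(S) = div` to machine precision by construction.
The overall pattern-strain summary is `sqrt(2) ||S||_F` averaged over
ridge pixels with non-zero divergence, then over frames; the Frobenius norm
makes `sqrt(2)||S||` equal the principal strain magnitude for pure shear.
Growth/shrinkage event velocities average the velocity *magnitude* over
pixels with `div < -0.12` or `div > +0.12 /min` respectively.

## Cluster dynamics

Ridge components are tracked by the same assignment machinery (2.3 µm
cutoff). The ridge axis is the dominant unit eigenvector of the
intensity-weighted coordinate covariance, sign-fixed (`e1 ≥ 0`, ties by
`e2 > 0`); near-isotropic components are flagged but still return a
deterministic axis. Intensity profiles project pixel coordinates onto the
axis (`delta_l = (x_p, y_p)·(e1, e2)`), binned at the source pixel pitch;
binning conserves total intensity exactly. Gaussian curvature treats
intensity as height over the physical grid: first/second derivatives by
derivative-of-Gaussian at σ = 1.2 µm, fundamental forms
`E = 1 + zx²`, `F = zx zy`, `G = 1 + zy²`,
`L = zxx/q`, `M = zxy/q`, `N = zyy/q` with `q = sqrt(1 + zx² + zy²)`
(Monge normalization), and `K = (LN - M²)/(EG - F²)`. For the pipeline,
images are rescaled to \[0, 1\] before differentiation so the `|K| > 5`
threshold has consistent units; calibrated height surfaces can disable
this (`normalize = FALSE`), which is how the tests verify the plane/sphere/
saddle closed forms. No extra pre-smoothing is applied beyond the σ = 1.2 µm
derivative scale. Coincidence analysis counts the four overlaps between
`{+K, -K}` pixel sets at frame t and `{+div, -div}` sets for t → t+1.

## The synthetic generators

The generators define the conditions under which everything is tested;
they are first-class, seeded (each draws under its own restored RNG state,
so adding one call never perturbs another) and bit-reproducible.

- `make_wormlike_chains()`: per-step turn angles i.i.d.
  `Normal(0, step/Lp)` — the standard 2D discretization under which the
  rescaled-curvature variance is exactly `2/Lp`. Defaults used in tests:
  step 0.1 µm, ~1e5 segments per `Lp`.
- `make_labyrinth()`: exact-period binary stripes, or thresholded band-pass
  noise whose radial spectrum peaks at `2π/period`; grayscale rendering is
  the mask blurred by a 1-px Gaussian ridge profile plus additive noise
  (noise sd 0.2 against unit ridge amplitude ≈ SNR 5 in the segmentation
  tests, periods 0.5–0.9 µm — the scale of real patterns).
- `make_cell_scene()`: a membrane lattice enclosing interior cells (plus
  border-clipped ones) with striped interiors at 0.25× membrane brightness,
  and ground-truth centroids; an optional membrane gap exercises
  morphological closing.
- `make_flow_scene()`: translation/source/shear/rotation analytic fields;
  frame t+1 is frame t backward-warped by `v·dt` (bilinear), so brightness
  constancy holds by construction; displacements are clamped (with a
  warning) below 3 px, the small-displacement regime of the estimator.
- `make_zstack()`: skeleton-thin labyrinths on dark background (low
  entropy, ~5 bits) versus uniform speckle (~8 bits), with ground-truth
  slice labels.

What the synthetic scenes do **not** emulate: microscope PSF anisotropy,
depth-dependent attenuation, photobleaching, occlusions between cells, 3D
ridge height, and the intensity statistics of real actin reporters.
Passing tests therefore validate the mathematics and the code paths, not
instrument-specific performance.

## Numerical choices and degenerate inputs

- Convolutions use replicate borders; derivative kernels are renormalized
  to unit first moment; Gaussian kernels to unit sum.
- The spectrum shift convention places DC at `floor(n/2) + 1` on each axis
  (forward and inverse shifts differ for odd sizes; this is covered by the
  odd-dimension oracle tests).
- Otsu thresholds operate on \[0, 1\]-rescaled inputs; the sigmoid response
  is affinely mapped from \[0.5, 1) to \[0, 1) first.
- Degenerate inputs: all-background labeling warns and returns zeros;
  empty skeletons return empty statistics; all-zero images are an error for
  the wavelength; zero kept slices is an error naming the time point;
  rank-deficient flow pixels are zeroed and flagged; collinear traces pass
  through smoothing unchanged; duplicate spline knots are deduplicated.
- Ties: the rotation scan keeps the first minimizer; eigenvector signs are
  fixed as above; equal-cost assignments resolve to the lower index through
  the solver's deterministic sweep.

## Problem sizes used in the tests

The suite runs entirely on synthetic data: 1e5-segment chains for
parameter recovery at `Lp` ∈ {1, 6, 20} µm; 64–128 px scenes for
segmentation and spectra; 64² flow scenes; and the reduced U-net regime
(200 pairs, 64², depth 2, 30 epochs, ~4–5 min) plus a smaller 32²
hyperparameter-trend comparison. These sizes were chosen so the full suite
completes in a few minutes while leaving each statistical check well
powered.

## Known limitations

- The per-movie entropy thresholds are inputs, not auto-tuned.
- The wavelength statistic is pixel-pitch-bound (see above).
- `estimate_lp_from_mask()` inherits the spline-densification scale
  dependence of `kappa_s`; treat it as the defined procedure, not a
  calibrated estimator.
- Tracking has no gap closing across skipped frames and no division
  handling; loops (closed skeleton paths) are skipped in branch tracing.
- Rotational (vorticity) flow components are discarded by design.
- The U-net trainer is CPU-bound plain R: suitable for the reduced regime
  and for correctness, not for full-scale training.
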