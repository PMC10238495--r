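# ridgemetrics

Quantitative analysis of **microridges** — the actin-filled, maze-like
protrusions tiling the apical surface of squamous epithelial (periderm)
cells — from live fluorescence imaging. The package turns 4D confocal
stacks (XYZT) into biophysical numbers: it filters periderm z-slices by
Shannon entropy, segments and tracks single cells, labels the microridge
pattern inside each cell (both by a classical rectified-Laplacian algorithm
and by a trainable U-net), and measures the pattern's mechanics and
dynamics:

- **Persistence length and flexural rigidity.** Each skeletonized ridge
  branch is traced endpoint-to-endpoint, smoothed, spline-interpolated,
  and reduced to a rescaled curvature `kappa_s = 2 phi / sqrt(ds_prev + ds_next)`
  (turn angle over the root of the adjacent segment spacings). For a 2D
  worm-like chain in equilibrium `kappa_s` is zero-mean Gaussian with density
  `P(kappa_s) = sqrt(Lp / 4 pi) exp(-Lp kappa_s^2 / 4)`, so its variance is
  `2 / Lp`. The fitted width gives the effective persistence length `Lp`,
  the flexural rigidity `EI = Lp kB T`, and the Euler buckling load
  `f_c = pi^2 kB T Lp / L^2` of a ridge segment of length `L`.
- **Pattern wavelength and branch lengths.** The characteristic wave number
  of a segmented pattern is the `|k|^2` moment of the normalized 2D Fourier
  amplitude, `wn = sqrt( integral |k|^2 |I_fN| dk )`, `lambda = 2 pi / wn`;
  branch lengths are skeleton pixel counts times the pixel pitch after
  junction removal.
- **Flow and strain.** Lucas–Kanade optic flow with derivative-of-Gaussian
  gradients yields per-pixel velocities; the divergence
  `D = dvx/dx + dvy/dy` classifies growth (`D < -0.12 /min`, inflow:
  elongation/merging) versus shrinkage (`D > 0.12 /min`, outflow:
  fragmentation/splitting) events, and the strain-rate tensor
  `S = (V + V^T)/2` is decomposed into an area-changing part
  `S_area = tr(S)/2 I` and a traceless, shape-changing part `S_dev`.
- **Actin-cluster dynamics.** Ridge components are tracked across frames by
  optimal linear assignment (2.3 µm cutoff), 1D intensity profiles are taken
  along each ridge's dominant eigenvector, and the Gaussian curvature of the
  intensity-as-height surface (`K = (LN - M^2)/(EG - F^2)`, Monge patch) is
  compared against divergence hot spots.

Every algorithm ships with a synthetic generator of known ground truth
(worm-like chains, striped/labyrinthine patterns, analytically advected
image sequences, entropy-separable z-stacks), so the whole pipeline is
testable without any imaging data.

## Worked example

```r
library(ridgemetrics)

# a noisy labyrinthine scene with known ground truth
scene <- make_labyrinth(period = 0.66, shape = c(128, 128),
                        pixel_size = 0.0989, seed = 42, noise_sd = 0.15)
pair <- label_cell(scene$image)              # classical ridge labeling
mean_iou(pair$label, scene$ridge_mask)
#> <seg_metrics> mean IoU 0.867 (bg 0.875, fg 0.859), accuracy 0.932

# persistence length from worm-like chains of known Lp = 6.1 um
chains <- make_wormlike_chains(lp_true = 6.1, step = 0.1,
                               n_points = 1001, n_chains = 101, seed = 1)
pool <- unlist(lapply(chains$chains,
                      function(ch) curvature_series(ch)$kappa_s))
fit_lp(pool)
#> <lp_estimate> Lp = 6.1 um (moment 6.1, fit 6.1), EI = 2.53e-26 N m^2, n = 100899
critical_force(6.1, length = 1)              # buckling load of a 1-um ridge
#> [1] 0.2494403   # pN

# flow analysis on an analytically advected scene (divergence 0.1 /min)
fs  <- make_flow_scene("source", magnitude = 0.05, shape = c(64, 64),
                       dt = 0.5, pixel_size = 0.2, seed = 7)
vel <- smooth_field(optic_flow(fs$frames[[1]], fs$frames[[2]], dt = fs$dt),
                    passes = 8)
median(divergence(vel)[12:53, 12:53])
#> [1] 0.1015   # /min
```

The mean IoU says how well the labeling recovered the known ridge mask
(1 = perfect, per-class intersection over union averaged over background
and foreground). The `Lp` estimate recovers the generator's persistence
length from ~1e5 curvature samples; 0.25 pN is the corresponding buckling
force for a 1 µm segment at 300 K. The flow example shows the estimated
divergence matching the analytic source strength `2c = 0.1 /min`.

A full stack-to-metrics run (`run_pipeline()`) and a command-line interface
(`inst/cli/ridgemetrics.R`, subcommands `synth`, `preprocess`,
`segment-cells`, `track-cells`, `label-ridges`, `pattern-metrics`,
`lp-estimate`, `flow`, `clusters`, `run`) are also provided. See the
vignette `vignettes/microridge-quantification.Rmd` for the methods.

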