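---
title: "Models and methods behind pabscope"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind pabscope}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

pabscope quantifies the mechanics of fibroblasts that concentrate F-actin in
a peripheral ring — the "peripheral actin band" (PAB) phenotype of rounded,
slow-migrating, strongly contractile cells. This vignette documents the
models, the tunable parameters and their defaults, the synthetic-data
generators used for validation, and the numerical and design choices where
the method left room for judgement.

## Morphometry and the PAB classifier

A cell in a phalloidin image is segmented by Gaussian smoothing
(σ = 1 px), Otsu thresholding, keeping the largest 8-connected component
(ties broken by total intensity), and hole filling. Three metrics follow:

* **Area** `A` — foreground pixel count × pixel area (µm²).
* **Perimeter** `P` — the mask is lightly smoothed and its 0.5-level contour
  traced by marching squares; the polygon length is the perimeter. A
  pixel-edge perimeter would overestimate a circle's boundary by a factor of
  4/π and bias its circularity to ≈ 0.79; the sub-pixel contour brings a
  100 px-radius digital disk to within 1.2% of 2πr.
* **Circularity** `C = 4πA/P²`, clamped at 1 (particle-analysis convention).
* **Border actin fraction** `f` — the share of background-subtracted
  intensity inside a border band. The band contains every mask pixel within
  Euclidean distance `d` of the background, with
  `d = band_fraction × r_eq` (px, rounded, at least 1) and
  `r_eq = sqrt(A/π)`. Background defaults to the median intensity outside
  the mask.

A cell is PAB iff `f > f_thresh` **and** `C > c_thresh`, both strict, with
defaults `f_thresh = 0.50` and `c_thresh = 0.60`. Rates are aggregated per
imaging field as a percentage.

**Open choices.** The band depth is not a published constant; the default
`band_fraction = 0.20` is wide enough to contain the visible cortical ring
in round phantoms while leaving most of a polarized cell's stress-fiber
signal outside, and it is exposed in `pab_thresholds()` so users can match
any archived convention. Whether circularity should be clamped is likewise
convention; the clamped version is used because unclamped values > 1 are
artefacts of perimeter underestimation on small masks.

## Track and calcium kinetics

Mean speed is total path length over elapsed time (the common track-plugin
definition) rather than the average of instantaneous speeds; the two agree
for uniform sampling, and the path/time form is stable under dropped
frames. The directionality index is net displacement over path length.
Wind-rose plots bin each track's net-displacement angle into half-open
sectors starting at the +x axis, counter-clockwise, one count per track;
zero-net-displacement tracks are reported as unbinnable rather than
assigned a sector arbitrarily. Calcium traces are reported as fold change
relative to the first frame, which removes multiplicative illumination and
dye-loading factors exactly. Group comparisons use the unpaired two-tailed
Student's t test (two groups) or one-way ANOVA (more), the tests used
throughout this kind of study; no multiple-testing correction is applied by
default because figure statistics are per-comparison.

## Traction force microscopy

The substrate is modelled as an isotropic elastic half-space. In Fourier
space the surface displacement responds to surface traction through the
Boussinesq Green tensor

$$\tilde G(\mathbf k) = \frac{2(1+\nu)}{E k^3}
\begin{pmatrix} (1-\nu)k^2 + \nu k_y^2 & -\nu k_x k_y \\
                -\nu k_x k_y & (1-\nu)k^2 + \nu k_x^2 \end{pmatrix},$$

so the forward model is `u(k) = G(k) T(k)` and the inverse (FTTC) solves,
per wavevector, the Tikhonov-regularized normal equations
`T(k) = (G*G + λI)^{-1} G* u(k)`. The DC mode is set to zero (G diverges at
k = 0 and a cell exerts no net force); the mean of the displacement field is
removed as a drift proxy before inversion.

**Parameters.**

* Substrate: shear modulus 16 kPa with ν = 0.5 (near-incompressible
  polyacrylamide), i.e. E = 48 kPa; both configurable via
  `substrate_model()`.
* Window size for displacement estimation: 16 px.
* λ default 9.34×10⁻⁹. A Tikhonov constant is only meaningful together with
  its units convention, which for the historical value is unrecoverable;
  here λ multiplies the identity with u in µm, T in Pa, and k in rad/µm,
  and every traction field records the convention string alongside the λ
  used. Under this convention the default λ is a few percent of `G²` at the
  signal band of a 48 kPa substrate sampled at ~1 µm and dominates at high
  frequency, i.e. it acts as a gentle low-pass filter — the regime a
  practitioner tunes for. It should be re-tuned for substrates or grids far
  from these conditions.
* Residual-energy margin: the cell mask is dilated by 10 px before asking
  what fraction of the (positive-part) energy density lies outside; cells
  at ≥ 20% are excluded. "Residual energy" has no standard definition; this
  footprint-based form is the stated assumption and both margin and
  threshold are configurable.

**Numerical choices.** Zero-padding to a power of two with a cosine edge
taper is implemented (`fttc(pad = TRUE)`) but off by default: the synthetic
validation fields are periodic by construction, and padding would solve a
slightly different discrete problem than the periodic forward model,
degrading the round-trip oracle; for cropped experimental images padding
suppresses wrap-around artefacts and should be enabled. Displacement
estimation uses normalized cross-correlation over an integer search
neighbourhood followed by iterative Lucas–Kanade sub-pixel refinement on
the bilinearly warped window; the refinement is capped at 1.5 px from the
correlation match (divergence guard) and windows whose best correlation
falls below 0.5 (typically bead-free windows) are filled from valid
neighbours. Registration of the reference bead image uses the FFT
cross-correlation peak with a 3-point Gaussian sub-pixel estimator and
fails loudly when the peak does not exceed the strongest sidelobe by 1.3×.

Strain energy is `U = ½ Σ (u·T) dA` over in-mask nodes, converted to
joules, and normalized by the cell area in µm². With the noiseless forward
model this range sits at ~10⁻¹⁵ J for a 300 Pa dipole on 48 kPa — small
because a stiff substrate stores little energy; softer gels or stronger
spots scale it up linearly in `T²/E`.

## AFM Hertz fitting

An approach force curve is deflection `d` versus piezo travel `z`. With
cantilever stiffness `k` and tip radius `R`, force is `F = k d` and
indentation `δ = (z − z₀) − d` (the exact subtraction, not the stiff-lever
approximation). The spherical-indenter Hertz relation

$$F = \frac{4 E \sqrt{R}}{3(1-\mu^2)}\,\delta^{3/2}$$

is linear in `E` given `δ^{3/2}`, so the least-squares modulus is closed
form. Defaults are the study cantilever (k = 0.00664 N/m, R = 1.75 µm) and
an incompressible cell (µ = 0.5).

The contact point is found in three stages: a grid search over sample
positions scoring a piecewise model (linear pre-contact baseline + Hertz
rise), with samples whose indentation would be non-positive penalized as
zero-force predictions (otherwise late candidates win by discarding data);
a continuous refinement between samples; and a joint Nelder–Mead polish of
(z₀, log E) against the *exact self-consistent deflection model* — solving
`k d = C(ζ − d)^{3/2}` by vectorized Newton iteration — because the
measurement noise lives on the deflection axis, and regressing F on a noisy
`δ^{3/2}` is an errors-in-variables problem that biases stiff-cell fits.
The admissible baseline tilt is capped (default 0.3 deflection per travel):
real optical-interference baselines are gentle, and without the cap a steep
"baseline" can swallow the near-linear contact rise of a cell much stiffer
than the cantilever. Only the approach segment is fitted; a flat curve
(rise below 5× the baseline residual spread) raises a no-contact error.

## Synthetic generators and what they do (not) cover

Every assay has a generator returning the latent quantity the pipeline
estimates, so recovery is testable exactly:

* **Cell phantoms** — disks (PAB) or ellipses with longitudinal ridges
  (polarized), a cosine-tapered peripheral ring holding an exact target
  share of the total intensity, constant background, and Gaussian noise.
  Ground truth: ring intensity share and the analytic (Ramanujan) ellipse
  circularity.
* **Traction scenes** — Gaussian traction spots with enforced zero net
  force; displacements from the forward Boussinesq model; optional iid
  Gaussian displacement noise. The standard validation scene is a
  contractile dipole: two opposing 300 Pa spots (σ = 4 µm) on the 16 kPa
  (shear) substrate, 128×128 nodes at 1 µm spacing.
* **Bead images** — Gaussian PSF spots (σ = 1.5 px, matching
  sub-diffraction beads) at uniform positions, displaced by the bilinearly
  interpolated field. Bead density matters: windowed matching wants ~5
  beads per 16 px window, the PIV seeding rule used in the tests.
* **Tracks** — persistent random walks: wrapped-normal turning angles with
  spread `tan(π/2 · (1 − persistence))` (0 = isotropic, 1 = collinear) and
  Rayleigh step lengths whose mean matches the requested speed, at 10-min
  frames — the sampling used in overnight live imaging at typical MEF
  speeds (0.2–0.6 µm/min).
* **Force curves** — the exact self-consistent deflection model above plus
  Gaussian force noise; **calcium traces** — flat baseline, instantaneous
  rise to `peak_fold`, exponential decay.

All generators are deterministic given a single integer seed; sub-draws use
a stable seed-derivation rule so partial regeneration does not reshuffle
unrelated draws.

**What passing tests do and do not show.** The phantoms omit shot noise,
uneven illumination, touching cells, filopodia, and out-of-focus light; the
bead model has no 3D PSF or photobleaching; the substrate is a linear,
infinite-thickness half-space. Recovery on these phantoms validates the
*estimators* (segmentation, band logic, inversion, fitting) under their
stated assumptions — it does not certify performance on real micrographs,
where thresholds (especially the band fraction and λ) may need study-
specific calibration.

## Problem sizes and determinism

The validation suite uses 128×128 traction grids, 256 px bead images,
~192 px phantom fields, cohorts of 40–100 phantoms, 1000 simulated tracks,
and 100 noisy force curves — sizes chosen so the full suite and the
acceptance script each complete in well under a minute on a single core
while keeping Monte-Carlo standard errors far below the test tolerances.
Batch runners write deterministic CSV/YAML outputs and report an MD5 hash
so reruns can be verified bytewise.

## Known limitations

* No finite-thickness or nonlinear substrate corrections; no FEM/BEM
  traction reconstruction; no 3D TFM.
* No viscoelastic (Ting-type) AFM models and no bottom-effect correction
  for thin cells; retract segments are ignored.
* No cell tracking/linking — tracks are inputs.
* Touching-cell splitting and filopodia quantification are out of scope.
* The default λ is not transferable across unit conventions or very
  different substrate/grid scales; log output records the convention to
  keep this explicit.
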