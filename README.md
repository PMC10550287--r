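# pabscope

Quantification toolkit for the cell-mechanics phenotype of fibroblasts that
form a **peripheral actin band (PAB)** — a ring of cortical F-actin seen in
rounded, poorly spreading cells (e.g. mitofusin-2-deficient mouse embryonic
fibroblasts). The package implements the four quantitative assays such a
study rests on, plus synthetic phantom generators with known ground truth so
every stage can be validated end to end:

1. **Morphometry & PAB classification.** Cells are segmented from
   phalloidin images; area `A`, perimeter `P`, circularity `C = 4πA/P²`
   (clamped at 1) and the **border actin fraction** `f` — the share of
   background-subtracted actin intensity inside a peripheral band (default
   depth: 20% of the equivalent radius) — are measured. A cell is called PAB
   iff `f > 0.5` **and** `C > 0.6` (strict inequalities); rates are reported
   per imaging field. Focal adhesions are counted by threshold + particle
   analysis.
2. **Migration & calcium kinetics.** Per-track mean speed (path length over
   elapsed time), directionality index (net displacement / path length),
   wind-rose sector counts, Fluo-4 fold-change traces normalized to the
   first frame, and the usual group statistics (Student's t / one-way
   ANOVA).
3. **Traction force microscopy (FTTC).** Bead-image registration (FFT
   cross-correlation), windowed optical-flow displacement estimation
   (default window 16 px), regularized Fourier-transform traction cytometry
   on an elastic half-space (Boussinesq Green tensor, zeroth-order Tikhonov,
   default λ = 9.34×10⁻⁹ under this package's µm/Pa convention), strain
   energy `U = ½ Σ u·T dA` under the cell, normalized by cell area, and the
   QC rule that excludes cells with ≥20% of their energy outside the cell
   footprint. Default substrate: 16 kPa shear modulus, ν = 0.5.
4. **AFM stiffness (Hertz model).** Approach force curves are converted via
   `F = k·d`, `δ = (z − z₀) − d` and fitted with the spherical-indenter
   Hertz relation `F = 4E√R δ^{3/2} / (3(1 − µ²))` (defaults: cantilever
   k = 0.00664 N/m, tip radius 1.75 µm, µ = 0.5), with automatic
   contact-point detection.

All user-facing functions take and return tibbles where the data are
tabular; gridded objects (images, displacement/traction fields) are light
S3 wrappers with `as_tibble()` and `autoplot()` methods, and fitted objects
have `tidy()`/`glance()` methods.

## Worked example

Simulate a traction scene with known ground truth, invert it, and read out
the strain energy:

```r
library(pabscope)

scene <- make_traction_scene(traction_scene_spec(seed = 1))
t_hat <- fttc(scene$displacement, scene$substrate, lambda = 0)

mask <- matrix(FALSE, 128, 128); mask[24:104, 24:104] <- TRUE
tfm_result(scene$displacement, t_hat, mask)
#> # A tibble: 1 × 6
#>   strain_energy_j cell_area_um2 normalized_energy_j_per_um2
#>             <dbl>         <dbl>                       <dbl>
#> 1        1.24e-15          6561                    1.88e-19
#>   residual_energy_fraction passed_qc lambda_used
#>                      <dbl> <lgl>           <dbl>
#> 1                 3.52e-13 TRUE                0
```

The recovered strain energy (1.24×10⁻¹⁵ J over a 6561 µm² footprint) equals
the generator's ground truth to machine precision in this noiseless case,
and the cell passes QC with essentially zero residual energy outside its
footprint.

Classify a synthetic PAB cell:

```r
ph <- make_cell_phantom(phantom_cell_spec("pab", ring_intensity_share = 0.8,
                                          seed = 7))
measure_cell(ph$image)
#> # A tibble: 1 × 7
#>   cell_id field_id area_um2 perimeter_um circularity border_fraction is_pab
#>   <chr>   <chr>       <dbl>        <dbl>       <dbl>           <dbl> <lgl>
#> 1 cell    field       1157.         121.       0.992           0.811 TRUE
```

The measured border fraction (0.81) matches the generator's 0.80 target,
circularity is ~1 for the round phantom, and the cell is called PAB.

Fit a synthetic AFM force curve:

```r
fit <- fit_force_curve(make_force_curve(E_pa = 10000, z0_um = 1,
                                        z_range_um = c(0, 3)))
glance(fit)
#> # A tibble: 1 × 4
#>   modulus_pa contact_point_um rms_residual_n n_points_used
#>        <dbl>            <dbl>          <dbl>         <int>
#> 1     10000.             1.00       1.52e-16           133
```

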