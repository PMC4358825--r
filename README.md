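# fluorcell

Quantitative fluorine-19 MRI cell tracking in R.

## The problem

Therapeutic cells (e.g. mesenchymal stromal cells) can be labeled with a
perfluorocarbon nanoemulsion and followed after transplantation with
¹⁹F MRI. Biological tissue contains no MR-detectable fluorine, so every
voxel's ¹⁹F magnitude signal is proportional to the number of labeled
spins it holds — which makes *absolute* cell counting possible, something
iron-oxide signal-void tracking cannot do. `fluorcell` is for imaging
scientists who want to validate and exercise that quantification chain:
it simulates ¹⁹F phantoms with exact ground truth, calibrates the
per-cell spin loading from NMR spectra, converts ROI signal to cell
counts, and analyzes longitudinal cell-count decay.

## The method

Two calibrated ratios take an image to a cell count:

1. **Reference normalization.** With a tube of known spin concentration
   C_ref (spins/µL) in the field of view, the background-corrected ROI
   signal is converted to total spins

       X = (Σ_ROI S_v / mean_ref S_v) · C_ref · V_voxel

   (V_voxel in µL). Receiver gain cancels in the ratio, so X is absolute.
   The background constant x is the dataset-wide minimum voxel value,
   subtracted from every voxel first.
2. **Comparative NMR calibration.** Spectroscopy of a known number of the
   same labeled cells next to a source of known spin count N_ref gives
   the per-cell loading

       Y = (A_cell / A_ref) · N_ref / n_cells

   and the apparent cell number is **N̂ = X / Y**.

The repeated-measures one-way ANOVA used for time courses applies the
Greenhouse–Geisser sphericity correction, ε̂ = (Σλ)² / ((k−1)Σλ²) over
the eigenvalues of the double-centered timepoint covariance, giving the
fractional degrees of freedom (df₂/df₁ = n−1) seen in reports like
F(1.703, 6.812); Tukey post-hoc tests use the studentized-range
distribution on the within-subject error term.

## Worked example

Calibrate a loading from a (simulated) spectrum, image a pellet of
8×10⁵ labeled cells next to the reference tube, and quantify it:

```r
library(fluorcell)

s <- simulate_spectrum(true_y = 1.5e11, n_cells = 1e6, ref_spins = 1e17,
                       noise_sd = 2, seed = 8)
cal <- calibrate_loading(s, ref_spins = 1e17, n_cells = 1e6)
cal
#> 19F loading: 1.52e+11 spins/cell (1e+06 cells vs 1e+17 reference spins)

ph <- generate_fluorine_image(
  phantom_spec(voxel_grid(c(32, 32, 16)),
               pellet_spec(c(10, 16, 16), 2, n_cells = 8e5,
                           spins_per_cell = cal$spins_per_cell),
               reference = reference_tube_spec(c(24, 16, 16), 1.5, 24)),
  acquisition_params(seed = 5))
q <- quantify_cells(ph$image, ph$masks$pellet_1, ph$masks$reference,
                    spins_per_cell = cal$spins_per_cell)
q
#> 19F quantification: N = 8.039e+05 cells (X = 1.22e+17 spins; SNR 40.57, detectable)
```

The estimate (803 900) is within 0.5% of the true 800 000: the NMR
round-trip recovered Y to ~1% and the imaging chain added sub-percent
noise at this SNR. The `detectable` flag applies the Rose criterion
(ROI SNR ≥ 5 against the Rayleigh background noise estimate).

The full in-vitro linearity study — six pellets from 2×10⁵ to 2×10⁶
cells, imaged on three occasions, quantified and regressed against the
true counts:

```r
rep <- run_pellet_study(study_config(seed = 1))
rep
#> Pellet linearity study: 6 pellets x 3 replicates (Y = 1.24e+11 spins/cell)
#>   slope = 0.9988, intercept = 2751
#>   R^2 = 1.0000, Pearson r = 1.0000
rep$per_pellet
#>   true_count mean_estimate sd_estimate
#> 1      2e+05      203603.1   4050.2929
#> 2      4e+05      403337.4    698.7304
#> 3      6e+05      599569.8   7182.1645
#> 4      8e+05      798756.4   5375.2965
#> 5      1e+06     1004825.2   9053.3057
#> 6      2e+06     2000230.0   1403.6533
```

Slope ≈ 1 and R² ≈ 1: quantified counts track true counts one-to-one,
with per-pellet SD reflecting scan-to-scan noise. A synthetic two-cohort
clearance study (`run_longitudinal_study()`) exercises the longitudinal
statistics the same way; see the vignette
(`vignettes/fluorine-quantification.Rmd`) for the models, defaults and
their rationale.

A thin command-line front end with `simulate`, `calibrate`, `quantify`,
`longitudinal`, `validate-linearity` and `demo-cohort` subcommands is
installed at `inst/cli/fluorcell.R`.

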