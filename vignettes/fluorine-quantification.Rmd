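---
title: "Absolute cell quantification with fluorine-19 MRI: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Absolute cell quantification with fluorine-19 MRI: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fluorcell)
```

## The quantification problem

Cells labeled with a perfluorocarbon (PFC) emulsion carry fluorine-19
nuclei into tissue that otherwise contains no MR-detectable fluorine. The
magnitude of the ¹⁹F image signal in a voxel is therefore proportional to
the number of ¹⁹F spins in that voxel, and an absolute cell count can be
recovered in two calibrated steps:

1. **Image to spins.** An external reference tube of known spin
   concentration $C_{ref}$ (spins/µL) is imaged next to the subject. After
   subtracting the dataset-wide minimum voxel value $x$ (a constant
   left-shift that anchors the intensity distribution at zero), the signal
   inside a region of interest is summed and expressed in reference-voxel
   equivalents:
   $$X = \frac{\sum_{v \in ROI} S_v}{\bar S_{ref}} \; C_{ref} \, V_{voxel},$$
   where $V_{voxel}$ is the voxel volume in µL (1 mm³ = 1 µL). $X$ is the
   total number of ¹⁹F spins at the ROI. Because both numerator and
   denominator scale with the receiver gain, $X$ is gain-invariant — the
   property that makes the method absolute rather than relative.
2. **Spins to cells.** A comparative NMR measurement of a known number of
   the same labeled cells next to a second ¹⁹F source of known spin count
   yields the per-cell loading
   $$Y = \frac{A_{cell}}{A_{ref}} \cdot \frac{N_{ref}}{n_{cells}},$$
   and the apparent cell number is $\hat N = X / Y$.

The package implements this chain (`background_correct()`,
`roi_total_signal()`, `reference_mean()`, `estimate_total_spins()`,
`estimate_cell_number()`, bundled in `quantify_cells()`), a synthetic
phantom generator with exact ground truth to validate it against, and the
longitudinal statistics used to follow a transplant over time.

## The phantom generator

`generate_fluorine_image()` produces 3D magnitude images from a scene of
spherical cell pellets, a cylindrical reference tube and optionally an
off-resonance compartment, on a default grid of 32 × 32 × 16 voxels of
1 × 1 × 2 mm (the fluorine acquisition resolution it emulates).

**Signal model.** Voxel signal is strictly proportional to the ¹⁹F spins
it contains: `gain` (signal per spin per voxel, default 1e-12) is
identical for every compartment. This deliberately ignores the relaxation
and flip-angle dependence of the bSSFP sequence; equality of gain between
sample and reference is precisely the assumption that validates reference
normalization, so the simulator adopts it as its contract rather than
modelling sequence physics. Pellet spins (`n_cells × spins_per_cell`) are
spread uniformly over the pellet's voxels; each reference voxel carries
$C_{ref} V_{voxel}$ spins.

**Voxelization.** Compartments are voxelized by centre-inclusion (a voxel
belongs to a compartment iff its centre lies inside the continuous shape).
There is no sub-voxel partial volume: every simulated spin lands in
exactly one voxel of its ground-truth mask, which keeps the noise-free
round trip exact to machine precision — the key correctness oracle. The
cost is a staircase boundary; real hand-drawn ROIs on real data include
partial-volume voxels that this model does not exercise.

**Noise model.** Magnitude reconstruction of complex Gaussian noise gives
Rician-distributed voxels: the simulator computes
$|S + n_1 + i n_2|$ with $n_1, n_2 \sim N(0, \sigma)$ per voxel.
Signal-free regions are then Rayleigh with mode σ (property-tested with a
Kolmogorov–Smirnov test). The default σ = 125 was fixed by a forward
calculation: with the default gain, geometry (24-voxel pellet mask) and a
mid-range loading of 1.5 × 10¹¹ spins/cell, it puts the smallest pellet of
the dilution series (2 × 10⁵ cells) at an ROI SNR of about 10 — a
realistic low-but-clearly-detectable operating point for the smallest
sample. Rician bias (≈ σ²/2A per voxel) is *not* corrected; at SNR ≥ 10
it contributes well under 1% and is part of what the linearity study
absorbs.

**Excitation-bandwidth model.** bSSFP is sensitive to off-resonance
species; inhaled isoflurane accumulating in fat contributes ¹⁹F signal at
a chemical-shift offset and can corrupt quantification if excited. The
pulse model uses a fixed time-bandwidth relation $B \cdot T = 2$
(kHz · ms), the unique constant consistent with both pulse/bandwidth
pairs it emulates: a 1.32 ms plain sinc ↔ ≈1.5 kHz, and a 0.66 ms
Gaussian-filtered sinc ↔ ≈3.0 kHz. The normalized excitation response at
offset $f$ is

* plain sinc: $r(f) = 1/(1 + (2f/B)^{12})$, a flat-top passband that is
  exactly 1 at resonance, exactly 0.5 at $B/2$, ≥ 0.9 inside $B/4$ and
  < 0.1 at 1.2 kHz for the narrow pulse;
* filtered sinc: a Gaussian with FWHM $B$,
  $r(f) = \exp(-4\ln 2 \, f^2/B^2)$ (0.65 at 1.2 kHz for the broad
  pulse).

The flat-top form was chosen over an erf-smoothed rectangle because no
erf-smoothed rectangle can satisfy $r(0) = 1$ exactly and
$r(B/2) \le 0.5$ simultaneously. The off-resonance compartment defaults
to a 1.2 kHz offset — inside the broad pulse's passband, far outside the
narrow one's — and a spin density of 10¹⁵ spins/µL, which makes its total
spin content a substantial fraction (~0.4) of the largest pellet so that
the broad-pulse bias is conspicuous while the narrow-pulse change stays
below 1%.

## NMR calibration

`simulate_spectrum()` builds a two-Gaussian fixture (cell peak and
reference peak at ±3 kHz, SD 0.3 kHz) with areas proportional to
`n_cells × Y` and `ref_spins`, plus white noise. `integrate_peak()` uses
a trapezoidal rule after subtracting a linear baseline through the
window's edge points — the method detail is genuinely open in practice
(integration limits and baseline handling vary between spectrometers), and
the linear-edge baseline is robust for well-separated peaks while leaving
the area ratio exactly scale-invariant. Windows are explicit inputs, not
auto-detected: peak picking is out of scope, and in both simulation and
routine calibration the resonance positions are known. Round-trip
recovery is < 0.5% at zero noise (pure discretization, ±6 SD windows) and
unbiased to < 3% at a peak SNR of 50 over 100 seeds.

## Longitudinal statistics

`rm_anova()` performs the within-subject one-way ANOVA of counts over
timepoints: $F = MS_{time}/MS_{time \times subject}$ with nominal df
$(k-1, (k-1)(n-1))$. Repeated measures rarely satisfy sphericity, so the
reported df are scaled by the Greenhouse–Geisser
$$\hat\varepsilon = \frac{(\sum_i \lambda_i)^2}{(k-1)\sum_i \lambda_i^2},$$
with $\lambda_i$ the eigenvalues of the double-centered covariance matrix
of the timepoint columns. This produces the fractional df familiar from
reports such as $F(1.703, 6.812)$ — note $6.812/1.703 = 4$, the invariant
$df_2/df_1 = n-1$ that identifies a 5-complete-subject, 4-timepoint
design. Greenhouse–Geisser was chosen (over Huynh–Feldt or lower-bound
corrections) because it is the default in the statistics packages whose
output the fractional-df style matches, and it reproduces that df
structure exactly. $\hat\varepsilon$ is clamped to its theoretical range
$[1/(k-1), 1]$ against numerical noise; a constant table returns
$F = 0, p = 1$ rather than an error.

`tukey_posthoc()` compares all timepoint pairs with the studentized-range
distribution using the within-subject $MS_{error}$ and, by default, its
*uncorrected* df $(k-1)(n-1)$ — standard practice; a `df = "gg"` option
applies the corrected df for a more conservative test. Missing data are
handled by complete-case analysis with a logged warning: the analysis set
is made explicit (`n` is carried in every result) rather than guessed.
Zero counts are valid observations — an undetectable transplant is data,
not a missing value.

## The validation studies

`run_pellet_study()` reproduces the in-vitro linearity experiment on
synthetic data: the six-pellet dilution series (2, 4, 6, 8, 10, 20 × 10⁵
cells) is generated and quantified with ground-truth ROI masks on three
"occasions" that share geometry and differ only in their noise seed —
replicate variation is pure measurement noise, as when one physical
phantom is rescanned. Unless fixed, the per-study loading is drawn
uniformly from the observed 8.2 × 10¹⁰–2.4 × 10¹¹ spins/cell range; the
same value is used for generation and quantification, mirroring the
practice of calibrating each transplant against its own NMR measurement.
The regression is estimates-on-true (true counts are exact in
simulation); with the default configuration the study yields R² > 0.999
and Pearson r > 0.999, comfortably above the 0.98/0.99 achieved on real
phantom data — as it should be, since the simulation contains no
partial-volume error, coil shading or manual-ROI variability.

`run_longitudinal_study()` is a synthetic stand-in for the in-vivo cohort
comparison. Each subject's transplant clears exponentially,
$N(t) = N_0 e^{-k_s t}$, with $k_s$ log-normal across subjects
(sdlog 0.3); a fast cohort (median 0.25/day, i.e. ~2% of baseline by day
16) is compared with a slow one (median 0.05/day, ~45% by day 16) at days
0, 3, 9 and 16 with 7 subjects each. The exponential-clearance model is a
fixture for exercising the statistics — detectability tallies
(`detectability_tally()`, the "x/n subjects" form), percent remaining and
the ANOVA — not a biological claim: real clearance involves cell death,
label dilution, migration and label transfer to bystander macrophages,
none of which are modelled. Real in-vivo F statistics and day-wise counts
are consequently *not* reproduction targets; the study's assertable
property is ordinal (the fast cohort never retains detectability longer
than the slow one).

## Detectability

`classify_detectable()` applies the Rose criterion: an ROI is detectable
when its mean corrected signal exceeds 5 × the noise SD, estimated from a
signal-free background mask via the Rayleigh maximum-likelihood estimator
$\hat\sigma = \sqrt{\overline{v^2}/2}$. The threshold of 5 is a
convention (no detection limit is standard in the field), inclusive at
the boundary, and configurable. At zero estimated noise the SNR is
reported as `Inf` and any positive ROI is detectable.

## Numerical and design notes

* All randomness is scoped: generators take explicit seeds and restore
  the caller's RNG state, so identical (spec, acq, seed) give
  bit-identical images and full studies are byte-reproducible.
* Problem sizes: the default grid (16 384 voxels), 2048-point spectra and
  the 100-table/100-seed property checks keep every study in the seconds
  range; grid and cohort sizes are constructor arguments when larger
  scenes are wanted.
* The dataset-minimum background constant $x$ is taken over the entire
  volume including the reference tube; on noisy magnitude data the
  minimum is near zero, and the correction is idempotent.
* Two printed reference concentrations circulate for the same class of
  reference tube (7.3 × 10¹⁶ vs 2.6 × 10¹⁶ spins/µL); the package takes
  $C_{ref}$ as a parameter (default 2.6 × 10¹⁶, the value used at the
  quantification step) and makes no attempt to reconcile them.
* Apparent cell number is reported as a continuous value, never rounded:
  it is an estimate of signal-equivalent cells, not a census.

## Limitations

The simulator validates the *quantification arithmetic*, not the physics:
no k-space sampling, banding, coil sensitivity profile or relaxation
weighting is modelled, and passing its oracles says nothing about
sequence-dependent bias on a real scanner. Partial volume is absent by
construction. The clearance model is a fixture. Hand-drawn ROI
variability — a real source of error the original workflow absorbs by
expert judgement — enters only through the optional threshold-based
`auto_roi()`.

```{r example}
rep <- run_pellet_study(study_config(seed = 1))
rep
rep$per_pellet
```
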