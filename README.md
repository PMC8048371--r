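# raddwi — simulation and repeatability analysis of radial and EPI diffusion-weighted MRI

Quantitative diffusion-weighted MRI (DWI) of the mouse abdomen is dominated
by respiratory motion: mice breathe at 80–100 breaths/min, and a
diffusion-sensitized sequence turns millimeter-scale breathing displacement
into artifacts and biased apparent diffusion coefficients (ADC). Two
acquisition strategies handle this differently — radially sampled spin-echo
DWI (motion errors disperse as streaks; prospective gating works well) and
multi-shot interleaved EPI (fast and high-SNR, but shot-to-shot phase errors
produce coherent ghosts at FOV/n<sub>shots</sub> offsets, and off-resonance
species like 1-butanol are corrupted along the echo train).

`raddwi` is an analysis workflow for studying exactly this trade-off in
silico, for MR physicists and preclinical imaging scientists. It provides,
as a tested R package:

- a digital mouse-abdomen phantom (tumor, spinal muscle, water and 1-butanol
  tubes; 32 × 32 mm FOV at 4.7 T) with known diffusivities;
- a k-space simulator for both protocols — radial: 64 readout × 101 views;
  EPI: 128 × 128 in 4 interleaves, 16 averages; five b-values (0.64, 535,
  1071, 1478, 2141 s/mm², Δ = 14.4 ms, δ = 9 ms), both diffusion-gradient
  polarities, a respiratory motion model with prospective gating, and
  complex Gaussian noise (Rician magnitudes);
- reconstruction: zero/first-order phase correction + filtered
  back-projection (Ram-Lak) for radial data, interleave reassembly + 2-D FFT
  for EPI;
- ADC mapping by the geometric-mean polarity combination and the pixel-wise
  bounded least-squares fit of the three-parameter model

  S(b) = S₀ · exp(−b·D) + A,  with S₀, D, A ≥ 0,

  where D is the ADC and A absorbs the Rician noise floor;
- QIBA-style test–retest repeatability statistics over paired measurements
  with differences ΔDᵢ and pair means mᵢ:

  SD<sub>ws</sub> = √(Σ ΔDᵢ² / 2n),  CV<sub>ws</sub> = √(Σ (ΔDᵢ/mᵢ)² / 2n),
  RC = 1.96·√2 · SD<sub>ws</sub> ≈ 2.77 · SD<sub>ws</sub>,

  plus Bland–Altman summaries (limits at bias ± RC) and kernel density
  estimates of pixel-wise tumor ADC.

The numbered scripts under `analysis/` run the study end to end and write
tables under `results/`: `01_gating_comparison.R` (gated vs non-gated radial
ADC), `02_artifact_comparison.R` (SNR, interleave ghosting, off-resonance
corruption), `03_test_retest.R` (a 10-subject virtual test–retest cohort and
its repeatability table), `04_adc_distributions.R` (test vs retest pixel-ADC
densities).

## Worked example

Simulate a gated radial acquisition of the default phantom at low noise,
reconstruct, fit, and summarize the ADC per compartment:

```r
library(raddwi)

phantom <- default_phantom()
maps <- rasterize(phantom, matrix = 64)

model <- respiration_model(seed = 3)
params <- acq_params("RAD")
params$noise_sigma <- calibrate_noise_sigma(maps, params, model, snr_target = 100)

kspace <- simulate_radial_kspace(maps, params, model, seed = 1)
stack <- fbp_reconstruct(kspace)   # phase-correct + filtered back-projection
adc <- fit_stack(stack)            # geometric-mean combine + 3-parameter fit
roi_table(adc, roi_masks(maps, erode = 2))
#>       roi slice_range  mean     sd n_pixels
#> 1   tumor         1-1 1.319 0.0377      217
#> 2  muscle         1-1 1.824 0.0521       77
#> 3   water         1-1 3.292 0.1264       21
#> 4 butanol         1-1 0.465 0.0385       21
```

The `mean` column is the ROI-mean ADC in 10⁻³ mm²/s: the pipeline recovers
the phantom's true diffusivities (tumor 1.3, muscle 1.8, water 3.2, butanol
0.44) to within a few percent; the small upward remainder is the estimator's
genuine noise-floor/offset bias, discussed in the methods vignette.

Repeatability statistics work on paired test–retest ROI means:

```r
pairs <- paired_measurements(
  test   = c(1.25, 1.41, 1.30, 1.19, 1.35),
  retest = c(1.28, 1.38, 1.33, 1.22, 1.31))
summ <- repeatability_summary(pairs)
sprintf("SD_ws = %.3f, CV_ws = %.3f, RC = %.3f", summ$sd_ws, summ$cv_ws, summ$rc)
#> "SD_ws = 0.023, CV_ws = 0.018, RC = 0.063"
```

Here `RC` means: with 95% confidence, two repeated ADC measurements of the
same subject differ by less than 0.063 × 10⁻³ mm²/s.

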