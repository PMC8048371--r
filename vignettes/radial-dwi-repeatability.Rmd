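---
title: "Simulating radial and EPI diffusion-weighted MRI of the mouse abdomen: models, parameters and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating radial and EPI diffusion-weighted MRI of the mouse abdomen}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(raddwi)
```

## What this package models

Quantitative diffusion-weighted MRI (DWI) of the mouse abdomen is hard
because mice breathe fast (80–100 breaths/min under anesthesia) and DWI pulse
sequences, being sensitized to micrometer-scale water motion, respond
violently to millimeter-scale respiratory motion. Two acquisition strategies
deal with this differently: radially sampled spin-echo DWI (every view passes
through the k-space center, so view-to-view inconsistencies disperse as
diffuse streaks) and multi-shot interleaved EPI (fast, higher SNR, but
shot-to-shot phase errors produce coherent ghosts at FOV/n_shots offsets, and
off-resonance species are corrupted by phase accrual along the echo train).

The package builds a complete in-silico version of such an experiment:

1. **Digital abdominal phantom** (`default_phantom()`): a tumor ellipse, a
   spinal-muscle band and two 5-mm tubes (water, 1-butanol) in a 32 × 32 mm
   field of view at 4.7 T. Compartment diffusivities default to the
   radial-protocol tissue estimates for this system:
   tumor 1.3 × 10⁻³, muscle 1.8 × 10⁻³, water at 37 °C 3.2 × 10⁻³ and
   1-butanol 0.44 × 10⁻³ mm²/s.
2. **Acquisition simulation** (`simulate_radial_kspace()`,
   `simulate_epi_kspace()`): complex k-space under a respiratory motion
   model, with prospective gating, both diffusion-gradient polarities,
   complex Gaussian noise (hence Rician magnitudes) and seeded
   reproducibility.
3. **Reconstruction** (`fbp_reconstruct()`, `epi_reconstruct()`): zero- and
   first-order phase correction plus filtered back-projection for the radial
   data; interleave reassembly plus Fourier inversion for EPI.
4. **ADC mapping** (`combine_polarities()`, `fit_stack()`): geometric-mean
   polarity combination, then the pixel-wise bounded least-squares fit of
   $S(b) = S_0 e^{-bD} + A$.
5. **Repeatability statistics** (`sd_ws()`, `cv_ws()`, `rc()`,
   `bland_altman()`, `pdf_estimate()`): QIBA-style test–retest metrics.

The `analysis/` scripts drive these stages as a narrative workflow
(gating comparison, artifact comparison, virtual test–retest cohort,
pixel-ADC distributions) and write their tables under `results/`.

## The acquisition protocols

Both protocols share the five b-values 0.64, 535, 1071, 1478 and
2141 s/mm², diffusion time Δ = 14.4 ms, gradient duration δ = 9 ms, and
acquire every image with positive and negative diffusion-gradient polarity —
ten diffusion-weighted images per slice. The radial protocol acquires 64
readout points × 101 views (one view per effective TR of 2 respiratory
periods), reconstructed at 64 × 64; the EPI protocol acquires 128 × 128 in 4
interleaved shots with 16 complex-summed averages. `b_value()` provides the
Stejskal–Tanner relation $b = \gamma^2 g^2 \delta^2 (\Delta - \delta/3)$ as
supporting plumbing.

## The respiratory motion model and how motion corrupts the data

`respiration_model()` describes periodic rigid in-plane displacement: each
period (drawn from 0.6–0.75 s) begins with a quiescent end-expiration window
(default 60% of the period, displacement exactly zero) followed by a
raised-sine breath excursion of default amplitude 1 mm. Prospective gating
schedules one view/shot per `tr_resp_periods` periods inside the quiescent
window; the non-gated variant uses a uniform TR of the same mean duration,
deliberately incommensurate with the breathing period so that events sample
all respiratory phases.

Motion enters the signal three ways:

- **Displacement → linear k-space phase.** A rigid translation at a view's
  acquisition time multiplies the sampled k-line by
  $e^{-2\pi i\,\mathbf{k}\cdot\mathbf{d}(t)}$. Note that for a radial view
  only the along-view component of the displacement affects the samples, so
  this term alone is *fully removable* by first-order phase correction.
- **Bulk phase error.** Motion during the diffusion-encoding interval adds a
  per-view/per-shot constant phase, modeled as
  `bulk_phase_scale × v(t) × sqrt(b/b_max)` with `v` the instantaneous
  velocity. This too is removed by zero-order phase correction in the radial
  chain, but drives the interleave ghosting in EPI (shot-to-shot
  inconsistency).
- **Intravoxel dephasing attenuation.** Tissue does not move as a perfect
  rigid body; the velocity *spread* across a voxel during the diffusion time
  dephases spins and attenuates the signal by
  $\exp\{-\tfrac12(\texttt{dephasing\_scale}\cdot v \cdot \sqrt{b/b_{max}})^2\}$.
  This term is essential: with phase errors alone, a zero/first-order
  phase-corrected radial reconstruction of rigid motion would be *identical*
  to the gated one, and gating would appear useless — contradicting what is
  observed on real systems, where non-gated scans show faster apparent decay
  (inflated ADC) and streaking. The default `dephasing_scale = 0.35` rad per
  mm/s was calibrated once so that the simulated non-gated/gated water-ADC
  contrast approximates the reported magnitude of that effect (roughly 3.2
  vs 4 × 10⁻³ mm²/s); the direction of the effect holds for any positive
  value and is what the tests assert.

EPI shots additionally draw a constant and a readout-linear phase error per
shot per average, with SD `shot_phase_floor + bulk_phase_scale·|v|·√(b/b_max)`.
The floor (default 0.4 rad) represents residual motion within the gating
window: ghosting is observed in gated multi-shot EPI of breathing animals
even though the scheduled instantaneous velocity is near zero. Off-resonance
compartments (butanol, single effective shift −3.1 ppm, the aliphatic
centroid relative to water, chosen instead of the four separate butanol
resonances because one effective offset suffices to reproduce the corruption
mechanism) accrue phase $2\pi\,\Delta f\,t_{line}$ along the echo train,
which displaces and smears them in the phase-encode direction — EPI only;
the radial readout is short enough that the effect is ignored there.

Averages are simulated as independent noise (and shot-phase) realizations
summed complex-valued before reconstruction; this is why averaging visibly
suppresses the EPI ghosts (independent per-average phase errors cancel) while
leaving systematic effects untouched.

## Reconstruction choices

**k-space synthesis** is by direct evaluation of the discrete Fourier
transform of the rasterized phantom along each view (exact, desk-scale, one
code path for arbitrary compartments); the tests check it against a naive
double-loop DFT oracle. The rasterizer uses pixel-center point sampling
(optional ×4 oversampling flag for partial-volume averaging); its area
convergence is tested against the analytic disk area.

**Radial phase correction.** The classic recipe — zero the phase at the echo
peak, remove the linear phase across the readout — is implemented per view in
`phase_correct_radial()`. Inside `fbp_reconstruct()` a *view-consistent*
variant is used: the projections of a static object have centers of mass that
follow the rigid sinogram law $c(\theta) = c_0 + x_0\cos\theta +
y_0\sin\theta$; the correction fits that sinusoid across views and removes
only per-view residuals (as first-order k-space phase), plus the full
zero-order phase (a real, non-negative object contributes none). Removing
each view's full linear phase instead would silently re-center the object —
differently at every b-value, as compartments fade — and blur the
reconstruction. Whether the first-order correction is per-view or global is
a genuinely open design point; per-view with the rigid-consistency constraint
is the package's choice.

**Filtered back-projection.** Per view: inverse DFT to a projection,
convolution with the band-limited Ram-Lak kernel
($h_0 = 1/(4\Delta s^2)$, $h_n = -1/(\pi n \Delta s)^2$ for odd lags, 0
otherwise; optional Hann apodization, default off), sinc interpolation of the
filtered projection onto a 4× finer grid (zero-padded FFT), then
linear-interpolation back-projection with angular weight $\pi/n_{views}$.
The 4× band-limited upsampling before the linear interpolation is what keeps
the reconstruction within a few percent NRMSE of the Fourier-inversion
oracle; with plain linear interpolation at the native grid the interpolation
error dominates. Normalization includes the pixel-area factor $\Delta s^2$
relating DFT samples to the continuous Fourier transform, so reconstructed
values match the phantom's pixel values and image energy is conserved within
2% on static noiseless data. Magnitude (not real-part) images are passed
downstream, consistent with Rician statistics and the offset term of the
fitting model.

**EPI reconstruction** reassembles interleaves into the Cartesian raster and
applies a 2-D inverse FFT. Even/odd readout reversal is assumed ideally
corrected (it is not simulated); only shot-to-shot errors reach the image.

## The diffusion fit and its biases

Each pixel's geometric-mean-combined magnitudes over the five b-values are
fit to $S(b) = S_0 e^{-bD} + A$ with $S_0, D, A \ge 0$ by bounded
Levenberg–Marquardt with analytic Jacobian (cost tolerance 1e-10, D bounded
above by 0.02 mm²/s — hitting a bound invalidates the pixel). Initialization:
$A_0 = \min S$, $D_0$ from the log-linear slope of $S - A_0$ over the first
three b-values clipped to $[10^{-5}, 10^{-2}]$, $S_{0,0} = S(b_{min}) - A_0$.
Pixels whose max-over-b signal is below 3× a background-SD estimate (taken
from the four image corners, which are air in the default geometry) are
excluded from the validity mask. The geometric-mean combination
$\sqrt{S_+ S_-}$ cancels the polarity-odd cross term between diffusion and
background/imaging gradients exactly (tested), leaving the unbiased decay
constant.

Two finite-noise biases of this estimator are worth understanding, and the
test suite pins both down by Monte Carlo:

- With the offset free, the Rician noise floor couples into $A$ and the
  mid-b Rician signal inflation is then attributed to a *steeper* decay:
  $D$ is biased **up**, substantially so when $b \cdot D \gtrsim 1.5$ at the
  second b-value (the water compartment). With $A$ fixed at zero the
  un-decayed floor instead pulls $D$ mildly **down**. Both biases shrink
  monotonically as the noise level decreases.
- With all points far above the floor, the $A \ge 0$ bound truncates the
  offset's sampling distribution at its true value (zero), which still
  biases $D$ slightly up.

Consequently the diffusivity-recovery analyses (acceptance script, recovery
tests) run in a low-noise regime — thermal reference SNR 100, i.e. complex
noise calibrated so the reconstructed water amplitude is 100× the Rayleigh-
corrected background SD — and use conservative interior ROIs (2-pixel
erosion) to avoid partial-volume edge pixels of the small tubes. A
background-*derived* SNR of 15–20, as printed for real radial scans of this
kind, conflates thermal noise with motion artifacts dispersed into the
background and would be an overestimate of the per-pixel noise appropriate to
the simulation; at a true thermal SNR of 20 the floor-coupling bias alone
inflates the water estimate by roughly a fifth, which no faithful
implementation of this estimator avoids. Property tests that specifically
exercise the noisy regime (gating direction, offset-model bias directions)
run at reference SNR 20.

ADC is stored in mm²/s internally and reported as 10⁻³ mm²/s at the
reporting layer (`roi_table(scale = 1e3)`), the field's printing convention.

## Repeatability statistics

For $n$ paired test–retest measurements with differences $\Delta D_i$
(test minus retest) and pair means $m_i$:

$$SD_{ws} = \sqrt{\frac{\sum_i \Delta D_i^2}{2n}}, \qquad
  CV_{ws} = \sqrt{\frac{\sum_i (\Delta D_i/m_i)^2}{2n}}, \qquad
  RC = 1.96\sqrt{2}\,SD_{ws} \approx 2.77\,SD_{ws}.$$

The unrounded $1.96\sqrt{2}$ is used internally; "2.77" is a display
rounding. Bland–Altman summaries place the agreement limits at
bias ± RC (not the conventional 1.96·SD of the differences) — a deliberate
divergence from the Bland–Altman norm so that the limits display the
repeatability coefficient itself. Published summary rows of this form can be
checked for internal consistency by reconstructing
$\sum \Delta D^2 = (n-1)\,SD_{\Delta}^2 + n\,\bar{\Delta}^2$ from a printed
"mean ± SD" of the differences; the tests do exactly that, treating the
printed SD as the sample (n−1) standard deviation, the only reading that
reproduces all published $SD_{ws}$ values, and allowing RC one unit in the
last printed digit since the inputs are themselves rounded. Pixel-ADC
distributions are compared with a Gaussian KDE on a caller-supplied grid
(Silverman's rule-of-thumb bandwidth).

## The virtual cohort

`run_experiment()` scans `n_subjects` virtual animals twice with each
protocol. Biological inter-subject variation is modeled as Gaussian jitter on
the compartment diffusivities (relative SD 0.15, giving a tumor
inter-subject SD of about 0.2 × 10⁻³ mm²/s, in the range seen across real
cohorts); a subject keeps its diffusivities across sessions, so test–retest
differences arise from noise, gating realization and motion only. Everything
derives from the config seed: the same configuration reproduces byte-
identical CSVs. What the generator does *not* emulate: anatomical deformation
and through-plane motion, relaxation weighting (absorbed into $S_0$),
perfusion/IVIM at low b, eddy currents, coil sensitivities, and
session-to-session physiological drift — so a zero within-subject SD in the
noiseless limit is a pipeline invariant here, not a biological claim, and
passing tests say nothing about those unmodeled real-data effects.

## Problem sizes and determinism

The test suite and acceptance script keep simulations at the scale a desk
machine handles in seconds: full-protocol radial runs (64 × 101 views, 10
images) for the recovery analyses (five seeds; water reported over three),
and reduced 32 × 32 / 51-view variants for property sweeps (10 seeds per
gating arm) and the noiseless two-subject cohort. All random stages are
seeded; simulation is bit-reproducible for a fixed seed.

## Known limitations

- The motion model is rigid and in-plane; the dephasing attenuation is a
  one-parameter stand-in for intravoxel velocity-spread physics.
- The EPI chain models neither readout-reversal (even/odd) artifacts nor
  geometric distortion from field inhomogeneity; off-resonance enters only
  through compartment chemical shift.
- The fit is least squares on magnitudes; a Rician likelihood would change
  the noise-floor behavior and is deliberately out of scope.
- Radial gridding alternatives (NUFFT, iterative recon) are not provided;
  filtered back-projection is the reference chain.
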