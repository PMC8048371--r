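Package: raddwi
Title: Simulation and Repeatability Analysis of Radial and EPI Diffusion-Weighted MRI
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantitative diffusion-weighted MRI (DWI) of the freely
    breathing mouse abdomen, built around a digital abdominal phantom. Simulates
    complex k-space for radially sampled (projection) and multi-shot interleaved
    EPI diffusion-weighted spin-echo acquisitions under a respiratory motion
    model with prospective gating, reconstructs magnitude images by zero- and
    first-order phase correction plus filtered back-projection (radial) or
    interleave reassembly plus Fourier inversion (EPI), combines opposite
    diffusion-gradient polarities by their geometric mean, fits the
    three-parameter signal model S(b) = S0*exp(-b*D) + A pixel-wise to produce
    apparent diffusion coefficient (ADC) maps, and computes QIBA-style
    test-retest repeatability statistics (within-subject SD and CV,
    repeatability coefficient, Bland-Altman summaries, pixel-ADC densities).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    minpack.lm,
    RNifti,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
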