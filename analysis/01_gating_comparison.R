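#!/usr/bin/env Rscript

# Does prospective respiratory gating matter for radially sampled DWI?
#
# Simulates the radial diffusion-weighted spin-echo protocol on the default
# abdominal phantom with and without gating (same respiratory motion model,
# same thermal noise calibrated to a reference SNR of 20), reconstructs,
# fits the three-parameter decay model and compares ROI-mean ADCs across
# seeds. Expected direction: motion during the diffusion time attenuates
# high-b views in the non-gated scans, steepening the apparent decay, so
# non-gated ADCs sit above the gated ones (most visibly for fast-diffusing
# water).

suppressMessages(library(raddwi))
dir.create("results", showWarnings = FALSE)

n_seeds <- 6
spec <- default_phantom()
maps <- rasterize(spec, 64)
model <- respiration_model(seed = 3)
params <- acq_params("RAD")
params$noise_sigma <- calibrate_noise_sigma(maps, params, model, snr_target = 20)
masks <- roi_masks(maps, erode = 1L)

run_arm <- function(gated) {
  p <- params; p$gated <- gated
  sapply(seq_len(n_seeds), function(s) {
    message(sprintf("  %s seed %d", if (gated) "gated" else "non-gated", s))
    pm <- fit_stack(fbp_reconstruct(simulate_radial_kspace(maps, p, model,
                                                           seed = s)))
    tab <- roi_table(pm, masks)
    stats::setNames(tab$mean, tab$roi)
  })
}

message("gated arm ...")
g <- run_arm(TRUE)
message("non-gated arm ...")
ng <- run_arm(FALSE)

out <- data.frame(
  tissue = rownames(g),
  gated_mean = rowMeans(g), gated_sd = apply(g, 1, sd),
  nongated_mean = rowMeans(ng), nongated_sd = apply(ng, 1, sd))
out$inflation_pct <- 100 * (out$nongated_mean / out$gated_mean - 1)
write.csv(out, "results/gating_comparison.csv", row.names = FALSE)

message("\nROI-mean ADC (1e-3 mm^2/s), ", n_seeds, " seeds per arm:")
print(out, row.names = FALSE, digits = 4)
message(sprintf(
  "\nwater: gated %.2f vs non-gated %.2f -> non-gated inflated by %.0f%%",
  out$gated_mean[out$tissue == "water"],
  out$nongated_mean[out$tissue == "water"],
  out$inflation_pct[out$tissue == "water"]))
message("written: results/gating_comparison.csv")
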