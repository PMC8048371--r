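#!/usr/bin/env Rscript

# Image-quality phenomenology of the two protocols under identical breathing.
#
# Simulates one gated acquisition of the default phantom with each protocol,
# measures (a) SNR of water and tumor in the lowest-b image, (b) coherent
# ghost-band energy relative to background (EPI interleave ghosts appear at
# multiples of matrix/n_shots lines; radial errors disperse as streaks), and
# (c) the butanol tube's ROI signal, which off-resonance corrupts in EPI but
# not in the radial images. Writes the reconstructed stacks as NIfTI plus a
# metrics CSV.

suppressMessages(library(raddwi))
dir.create("results", showWarnings = FALSE)

spec <- default_phantom()
model <- respiration_model(seed = 3)

message("radial protocol ...")
maps_r <- rasterize(spec, 64)
pr <- acq_params("RAD")
pr$noise_sigma <- calibrate_noise_sigma(maps_r, pr, model, snr_target = 20)
st_r <- fbp_reconstruct(simulate_radial_kspace(maps_r, pr, model, seed = 1))
write_dwi_stack(st_r, "results/stack_rad.nii.gz")

message("4-shot EPI protocol ...")
maps_e <- rasterize(spec, 128)
pe <- acq_params("EPI")
pe$noise_sigma <- calibrate_noise_sigma(maps_e, pe, model, snr_target = 20)
st_e <- epi_reconstruct(simulate_epi_kspace(maps_e, pe, model, seed = 1))
write_dwi_stack(st_e, "results/stack_epi.nii.gz")

corner_mask <- function(n, cb) {
  m <- matrix(FALSE, n, n)
  m[1:cb, 1:cb] <- TRUE; m[1:cb, (n - cb + 1):n] <- TRUE
  m[(n - cb + 1):n, 1:cb] <- TRUE; m[(n - cb + 1):n, (n - cb + 1):n] <- TRUE
  m
}

ghost_ratio <- function(img, obj, offset) {
  n <- nrow(img)
  gb <- matrix(FALSE, n, n)
  for (k in seq_len(n %/% offset - 1)) {
    sh <- ((row(obj) - 1 + offset * k) %% n) + 1
    gb[cbind(as.vector(sh), as.vector(col(obj)))] <-
      gb[cbind(as.vector(sh), as.vector(col(obj)))] | as.vector(obj)
  }
  gb <- gb & !obj
  mean(img[gb]^2) / mean(img[!obj & !gb]^2)
}

# ghost mechanism, isolated: single average, no thermal noise -- complex
# averaging over shots with independent phase errors partially cancels the
# coherent ghosts in the full protocol, and thermal noise hides the residue,
# so the single-average acquisition is where the interleave ghosts are visible
message("single-average noiseless acquisitions (ghost mechanism) ...")
# chemical shift off here: the displaced butanol signal would otherwise land
# in the background region and mask the ghost-band contrast being measured
spec_ns <- default_phantom(butanol_shift_ppm = 0)
maps_rg <- rasterize(spec_ns, 64)
maps_eg <- rasterize(spec_ns, 128)
pr1 <- acq_params("RAD")
st_r1 <- fbp_reconstruct(simulate_radial_kspace(maps_rg, pr1, model, seed = 2))
pe1 <- acq_params("EPI", n_averages = 1L)
st_e1 <- epi_reconstruct(simulate_epi_kspace(maps_eg, pe1, model, seed = 2))

metrics <- do.call(rbind, lapply(list(
  list(name = "RAD", st = st_r, st1 = st_r1, maps = maps_r),
  list(name = "EPI", st = st_e, st1 = st_e1, maps = maps_e)), function(x) {
  n <- dim(x$st$images)[4]
  masks <- roi_masks(x$maps, erode = 1L)
  img1 <- x$st$images[1, 1, 1, , ]
  bg <- corner_mask(n, n %/% 8)
  data.frame(
    protocol = x$name,
    snr_water_b1 = snr(img1, masks$water, bg),
    snr_tumor_b1 = snr(img1, masks$tumor, bg),
    ghost_ratio_b5_1avg = ghost_ratio(x$st1$images[1, 5, 1, , ],
                                      x$maps$s0_map > 0,
                                      n %/% acq_params("EPI")$n_shots),
    butanol_b1_mean = mean(img1[masks$butanol]),
    butanol_b1_expected = 0.8)
}))
write.csv(metrics, "results/artifact_metrics.csv", row.names = FALSE)
message("\nartifact metrics:")
print(metrics, row.names = FALSE, digits = 3)
message("\nSingle-average EPI shows coherent interleave ghosts")
message("(ghost_ratio_b5_1avg >> 1) which averaging then suppresses; the same")
message("shot errors disperse as streaks in the radial images (ratio near 1).")
message("Off-resonance displaces the butanol signal out of its ROI in EPI")
message("only. written: results/artifact_metrics.csv")
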