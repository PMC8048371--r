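# Small fixtures shared across tests; everything is generated in code.

paper_b_values <- c(0.64, 535, 1071, 1478, 2141)

# two-compartment phantom in a 16-mm FOV, cheap to simulate exactly
tiny_phantom <- function() {
  phantom_spec(list(
    compartment("fast", "disk", c(-3, 2), 2.5, s0 = 1.0, d_true = 3.2e-3, priority = 2L),
    compartment("slow", "ellipse", c(3, -2), c(3, 2), s0 = 0.9, d_true = 1.3e-3, priority = 2L)
  ), fov = 16)
}

# reduced radial protocol for property tests (32 x 32, 51 views)
small_rad_params <- function(...) {
  acq_params("RAD", matrix_read = 32L, n_views = 51L, ...)
}

small_epi_params <- function(...) {
  acq_params("EPI", matrix_read = 32L, matrix_phase = 32L, n_shots = 4L,
             n_averages = 1L, ...)
}

still_model <- function(...) {
  respiration_model(seed = 1, displacement_amp = 0, shot_phase_floor = 0, ...)
}

# build a dwi_stack directly from the forward signal model (no k-space /
# recon), with optional complex Gaussian noise of SD sigma before the
# magnitude operation -- the generator-side ground truth for fit tests
synthetic_stack <- function(maps, b_values = paper_b_values, sigma = 0,
                            seed = 1L, b_background = 0) {
  set.seed(seed)
  n <- nrow(maps$s0_map)
  images <- array(0, c(1, length(b_values), 2, n, n))
  for (bi in seq_along(b_values)) for (pi_ in 1:2) {
    pol <- c(1, -1)[pi_]
    beff <- b_values[bi] + b_background + pol * 2 * sqrt(b_values[bi] * b_background)
    tr <- maps$s0_map * exp(-beff * maps$d_map)
    img <- if (sigma > 0) {
      Mod(tr + matrix(complex(real = rnorm(n * n, sd = sigma),
                              imaginary = rnorm(n * n, sd = sigma)), n, n))
    } else tr
    images[1, bi, pi_, , ] <- img
  }
  params <- acq_params("RAD", matrix_read = as.integer(n), b_values = b_values)
  raddwi:::new_dwi_stack(images, maps$pixel_mm, "SYNTH", params)
}

# naive O(N^2) direct DFT along a radial line -- independent oracle
naive_radial_dft <- function(img, pixel_mm, theta, kvec) {
  n <- nrow(img)
  xs <- (seq_len(n) - 1 - n / 2) * pixel_mm
  out <- complex(length.out = length(kvec))
  for (m in seq_along(kvec)) {
    acc <- 0+0i
    for (iy in seq_len(n)) for (ix in seq_len(n)) {
      u <- cos(theta) * xs[ix] + sin(theta) * xs[iy]
      acc <- acc + img[iy, ix] * exp(-2i * pi * kvec[m] * u)
    }
    out[m] <- acc
  }
  out
}

# printed repeatability rows (ADC units of 1e-3 mm^2/s): DeltaD mean/SD and
# the published SD_ws and RC per tissue x protocol, n = 10 pairs each
published_repeatability_rows <- function() {
  data.frame(
    tissue   = c("water", "water", "muscle", "muscle", "tumor", "tumor"),
    protocol = c("RAD", "EPI", "RAD", "EPI", "RAD", "EPI"),
    delta_mean = c(-0.048, 0.069, 0.045, 0.060, -0.017, -0.082),
    delta_sd   = c(0.28, 0.15, 0.20, 0.26, 0.18, 0.34),
    sd_ws      = c(0.19, 0.11, 0.14, 0.18, 0.12, 0.24),
    rc         = c(0.53, 0.31, 0.38, 0.50, 0.34, 0.66),
    n = 10L)
}

# construct n pairs with an exact DeltaD sample mean/SD and a common pair mean
pairs_from_moments <- function(delta_mean, delta_sd, center = 1.3, n = 10L) {
  z <- as.numeric(scale(seq_len(n)))   # mean 0, sample SD 1
  dd <- delta_mean + delta_sd * z
  paired_measurements(test = center + dd / 2, retest = center - dd / 2)
}
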