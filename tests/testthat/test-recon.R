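test_that("phase correction inverts a known zero/first-order corruption", {
  n <- 64
  m <- seq_len(n) - 1 - n / 2
  echo <- complex(real = exp(-m^2 / 50))   # centered, real, non-negative
  # identity on an already clean echo
  out0 <- phase_correct_radial(echo)
  expect_equal(unclass(out0), echo, tolerance = 1e-12, ignore_attr = TRUE)
  # invert a known constant + linear phase
  corrupted <- echo * exp(complex(imaginary = 0.4 + 0.05 * m))
  out <- phase_correct_radial(corrupted)
  expect_lt(max(Mod(out - echo)) / max(Mod(echo)), 1e-6)
  expect_equal(attr(out, "phi1"), 0.05, tolerance = 1e-8)
  expect_equal(attr(out, "phi0"), 0.4, tolerance = 1e-6)
  # magnitude profile is preserved exactly
  expect_equal(Mod(out), Mod(corrupted), tolerance = 1e-12, ignore_attr = TRUE)
  # all-zero view: unchanged, flagged
  z <- complex(length.out = 16)
  outz <- phase_correct_radial(z)
  expect_true(attr(outz, "warn"))
  expect_equal(unclass(outz), z, ignore_attr = TRUE)
  expect_error(phase_correct_radial(z[1:4]), "at least 8")
})

test_that("FBP agrees with a Fourier-inversion oracle on a noiseless disk", {
  # centered disk, 64 x 64, 101 views
  sp <- phantom_spec(list(
    compartment("disk", "disk", c(0, 0), 8, s0 = 1, d_true = 1e-3)), fov = 32)
  maps <- rasterize(sp, 64)
  params <- acq_params("RAD", b_values = c(0.5, 900))
  ks <- simulate_radial_kspace(maps, params, still_model(), seed = 1)
  st <- fbp_reconstruct(ks)
  # oracle: circularly band-limited image via the 2-D FFT path
  tru <- maps$s0_map * exp(-0.5 * maps$d_map)
  K <- raddwi:::cdft2(tru + 0i)
  kg <- raddwi:::centered_grid(64, 1 / 32)
  KR <- sqrt(outer(kg^2, kg^2, `+`))
  ref <- Mod(raddwi:::cidft2(K * (KR <= max(abs(kg)))) / 64^2)
  nrmse <- sqrt(mean((st$images[1, 1, 1, , ] - ref)^2)) / sqrt(mean(ref^2))
  expect_lt(nrmse, 0.05)
})

test_that("FBP maps all-zero k-space to an all-zero image and rejects few views", {
  maps <- rasterize(tiny_phantom(), 16)
  params <- acq_params("RAD", matrix_read = 16L, n_views = 12L,
                       b_values = c(0.5, 900))
  ks <- simulate_radial_kspace(maps, params, still_model(), seed = 1)
  ks$samples[] <- 0+0i
  st <- fbp_reconstruct(ks)
  expect_true(all(st$images == 0))
  ks$samples <- ks$samples[, , 1:6, , drop = FALSE]
  expect_error(fbp_reconstruct(ks), "8 views")
})

test_that("the FBP point-spread function is mirror-symmetric", {
  sp <- phantom_spec(list(
    compartment("pt", "disk", c(0, 0), 0.2, s0 = 1, d_true = 0)), fov = 32)
  maps <- rasterize(sp, 64)
  expect_identical(sum(maps$s0_map > 0), 1L)  # single pixel at the center
  params <- acq_params("RAD", b_values = c(0.5, 900))
  ks <- simulate_radial_kspace(maps, params, still_model(), seed = 1)
  psf <- fbp_reconstruct(ks, phase_correct = FALSE)$images[1, 1, 1, , ]
  ctr <- 33
  for (k in 1:10) {
    expect_equal(psf[ctr + k, ctr], psf[ctr - k, ctr], tolerance = 1e-6)
    expect_equal(psf[ctr, ctr + k], psf[ctr, ctr - k], tolerance = 1e-6)
  }
})

test_that("EPI reconstruction inverts an artifact-free acquisition", {
  maps <- rasterize(tiny_phantom(), 32)
  maps$shift_map[] <- 0
  params <- small_epi_params()
  ks <- simulate_epi_kspace(maps, params, still_model(), seed = 1)
  st <- epi_reconstruct(ks)
  for (bi in seq_along(params$b_values)) {
    tru <- maps$s0_map * exp(-params$b_values[bi] * maps$d_map)
    nrmse <- sqrt(mean((st$images[1, bi, 1, , ] - tru)^2)) / sqrt(mean(tru^2))
    expect_lt(nrmse, 0.01)
  }
  # all-zero input -> all-zero output
  ks$samples[] <- 0+0i
  expect_true(all(epi_reconstruct(ks)$images == 0))
  # missing interleave -> error
  ks2 <- simulate_epi_kspace(maps, params, still_model(), seed = 1)
  ks2$samples[, , 2, , ] <- NA
  expect_error(epi_reconstruct(ks2), "missing interleave")
})

test_that("per-shot phase errors create ghost energy at the interleave offsets", {
  maps <- rasterize(tiny_phantom(), 32)
  maps$shift_map[] <- 0
  params <- small_epi_params()
  clean <- epi_reconstruct(simulate_epi_kspace(maps, params, still_model(), seed = 2))
  noisy <- epi_reconstruct(simulate_epi_kspace(
    maps, params, respiration_model(seed = 1, displacement_amp = 0,
                                    shot_phase_floor = 0.5), seed = 2))
  obj <- maps$s0_map > 0
  # ghost band: object mask displaced by matrix_phase/n_shots = 8 lines
  gb <- matrix(FALSE, 32, 32)
  for (k in 1:3) {
    sh <- ((row(obj) - 1 + 8 * k) %% 32) + 1
    gb[cbind(as.vector(sh), as.vector(col(obj)))] <-
      gb[cbind(as.vector(sh), as.vector(col(obj)))] | as.vector(obj)
  }
  gb <- gb & !obj
  e_clean <- sum(clean$images[1, 5, 1, , ][gb]^2)
  e_noisy <- sum(noisy$images[1, 5, 1, , ][gb]^2)
  expect_gt(e_noisy, 10 * max(e_clean, 1e-20))
})

test_that("snr implements the Rayleigh-corrected estimator", {
  set.seed(11)
  n <- 48
  s0 <- 2
  sigma <- 0.1
  sig_mask <- matrix(FALSE, n, n); sig_mask[9:24, 9:24] <- TRUE
  bg_mask <- matrix(FALSE, n, n); bg_mask[33:48, 33:48] <- TRUE
  est <- replicate(20, {
    img <- Mod(matrix(complex(real = rnorm(n * n, sd = sigma),
                              imaginary = rnorm(n * n, sd = sigma)), n, n) +
               s0 * sig_mask)
    snr(img, sig_mask, bg_mask)
  })
  expect_lt(abs(mean(est) - s0 / sigma) / (s0 / sigma), 0.10)
  # doubling the signal doubles the SNR for the same noise realization
  set.seed(12)
  noise <- matrix(complex(real = rnorm(n * n, sd = sigma),
                          imaginary = rnorm(n * n, sd = sigma)), n, n)
  r1 <- snr(Mod(noise + s0 * sig_mask), sig_mask, bg_mask)
  r2 <- snr(Mod(noise + 2 * s0 * sig_mask), sig_mask, bg_mask)
  expect_equal(r2 / r1, 2, tolerance = 1e-3)
  # degenerate zero background
  img0 <- matrix(0, n, n); img0[sig_mask] <- 1
  expect_true(is.infinite(snr(img0, sig_mask, bg_mask)))
  expect_error(snr(img0, sig_mask, matrix(FALSE, n, n)), "empty mask")
  expect_error(snr(img0, sig_mask, sig_mask), "disjoint")
})

test_that("reconstruction conserves image energy for static noiseless phantoms", {
  maps <- rasterize(default_phantom(), 64)
  params <- acq_params("RAD", b_values = c(0.64, 1071))
  ks <- simulate_radial_kspace(maps, params, still_model(), seed = 1)
  st <- fbp_reconstruct(ks)
  for (bi in 1:2) {
    tru <- true_signal(maps, params$b_values[bi])
    ratio <- sum(st$images[1, bi, 1, , ]^2) / sum(tru^2)
    expect_lt(abs(ratio - 1), 0.02)
  }
  maps128 <- rasterize(default_phantom(), 128)
  maps128$shift_map[] <- 0
  pe <- acq_params("EPI", n_averages = 1L, b_values = c(0.64, 1071))
  ste <- epi_reconstruct(simulate_epi_kspace(maps128, pe, still_model(), seed = 1))
  for (bi in 1:2) {
    tru <- maps128$s0_map * exp(-pe$b_values[bi] * maps128$d_map)
    ratio <- sum(ste$images[1, bi, 1, , ]^2) / sum(tru^2)
    expect_lt(abs(ratio - 1), 0.02)
  }
})
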