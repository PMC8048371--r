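test_that("respiratory trace is periodic, quiescent-gated and amplitude-scaled", {
  model <- respiration_model(period = 0.7, displacement_amp = 1.5,
                             quiescent_fraction = 0.6, seed = 1)
  t <- seq(0, 2.8, by = 1e-3)
  tr <- respiratory_trace(t, model)
  # zero amplitude -> identically zero
  m0 <- respiration_model(period = 0.7, displacement_amp = 0, seed = 1)
  expect_true(all(respiratory_trace(t, m0) == 0))
  # periodicity to machine precision
  expect_equal(respiratory_trace(t, model),
               respiratory_trace(t + model$period, model), tolerance = 1e-12)
  # quiescent census on a fine grid: at least quiescent_fraction of the
  # period is below 1% of the amplitude
  tt <- seq(0, model$period, length.out = 20001)
  mag <- sqrt(rowSums(respiratory_trace(tt, model)^2))
  expect_gte(mean(mag < 0.01 * model$displacement_amp), model$quiescent_fraction)
  # continuity at the quiescent/active boundary
  expect_lt(max(abs(diff(mag))), 0.01 * model$displacement_amp)
  expect_error(respiratory_trace(-1, model), "t must")
})

test_that("respiratory velocity matches a numerical derivative", {
  model <- respiration_model(period = 0.66, displacement_amp = 2, seed = 1)
  t <- seq(0.01, 1.3, by = 0.013)
  h <- 1e-6
  num <- (respiratory_trace(t + h, model) - respiratory_trace(t - h, model)) / (2 * h)
  v <- respiratory_velocity(t, model) # signed speed along displacement_dir
  expect_equal(as.vector(num %*% model$displacement_dir), v, tolerance = 1e-5)
})

test_that("acquisition scheduling honors gating and event counts", {
  model <- respiration_model(seed = 2)
  params <- acq_params("RAD")
  sg <- schedule_acquisition(params, model)
  # 101 views x 5 b x 2 polarities = 1010 events per slice
  expect_identical(nrow(sg), 1010L)
  # gated: every event sees (numerically) zero displacement
  disp <- respiratory_trace(sg$time, model)
  expect_lt(max(sqrt(rowSums(disp^2))), 0.01 * model$displacement_amp)
  # non-gated has the same number of events
  png_ <- params; png_$gated <- FALSE
  sn <- schedule_acquisition(png_, model)
  expect_identical(nrow(sn), nrow(sg))
  # non-gated events sample non-quiescent phases too
  dispn <- respiratory_trace(sn$time, model)
  expect_gt(max(sqrt(rowSums(dispn^2))), 0.5 * model$displacement_amp)
  # quiescent window shorter than readout -> error
  slow <- acq_params("RAD", bandwidth_hz = 100)  # 0.64 s readout
  expect_error(schedule_acquisition(slow, model), "quiescent window")
})

test_that("Stejskal-Tanner b-value follows the closed form", {
  expect_identical(b_value(2.675e8, 0, 9e-3, 14.4e-3), 0)
  b1 <- b_value(2.675e8, 2.5e-4, 9e-3, 14.4e-3)
  # independent arithmetic: gamma^2 g^2 delta^2 (Delta - delta/3)
  expect_equal(b1, 4129.69, tolerance = 1e-5)
  # doubling the gradient amplitude quadruples b
  expect_equal(b_value(2.675e8, 5e-4, 9e-3, 14.4e-3) / b1, 4, tolerance = 1e-12)
  expect_error(b_value(2.675e8, 1e-4, 15e-3, 14.4e-3), "delta")
})

test_that("radial k-space equals the direct DFT oracle for a static phantom", {
  maps <- rasterize(tiny_phantom(), 16)
  params <- acq_params("RAD", matrix_read = 16L, n_views = 9L,
                       b_values = c(0.5, 800))
  ks <- simulate_radial_kspace(maps, params, still_model(), seed = 1)
  for (v in c(1L, 4L, 9L)) {
    for (bi in 1:2) {
      img <- maps$s0_map * exp(-params$b_values[bi] * maps$d_map)
      oracle <- naive_radial_dft(img, maps$pixel_mm, ks$theta[v], ks$kvec)
      expect_equal(ks$samples[bi, 1, v, ], oracle, tolerance = 1e-10)
    }
  }
  # central (k = 0) sample identical across all views of one b/polarity
  ctr <- 16 / 2 + 1
  k0 <- ks$samples[1, 1, , ctr]
  expect_lt(max(Mod(k0 - k0[1])), 1e-9 * Mod(k0[1]))
})

test_that("simulations are bit-reproducible for a fixed seed", {
  maps <- rasterize(tiny_phantom(), 16)
  model <- respiration_model(seed = 5)
  pr <- acq_params("RAD", matrix_read = 16L, n_views = 11L,
                   b_values = c(0.5, 900), noise_sigma = 0.3)
  expect_identical(simulate_radial_kspace(maps, pr, model, seed = 7)$samples,
                   simulate_radial_kspace(maps, pr, model, seed = 7)$samples)
  pe <- small_epi_params(noise_sigma = 0.3)
  maps32 <- rasterize(tiny_phantom(), 32)
  expect_identical(simulate_epi_kspace(maps32, pe, model, seed = 7)$samples,
                   simulate_epi_kspace(maps32, pe, model, seed = 7)$samples)
  # different seeds differ
  expect_false(identical(simulate_radial_kspace(maps, pr, model, seed = 7)$samples,
                         simulate_radial_kspace(maps, pr, model, seed = 8)$samples))
})

test_that("a common constant phase on all EPI shots leaves the magnitude image unchanged", {
  maps <- rasterize(tiny_phantom(), 32)
  maps$shift_map[] <- 0
  ks <- simulate_epi_kspace(maps, small_epi_params(), still_model(), seed = 1)
  st0 <- epi_reconstruct(ks)
  ks$samples <- ks$samples * exp(0.8i)
  st1 <- epi_reconstruct(ks)
  expect_equal(st1$images, st0$images, tolerance = 1e-12)
})

test_that("polarity cross terms from a background gradient cancel under the geometric mean", {
  maps <- rasterize(tiny_phantom(), 16)
  b <- 1071; b_bg <- 25
  splus  <- maps$s0_map * exp(-(b + b_bg + 2 * sqrt(b * b_bg)) * maps$d_map)
  sminus <- maps$s0_map * exp(-(b + b_bg - 2 * sqrt(b * b_bg)) * maps$d_map)
  gm <- combine_polarities(splus, sminus)
  expect_equal(gm, maps$s0_map * exp(-(b + b_bg) * maps$d_map), tolerance = 1e-12)
})
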