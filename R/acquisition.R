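#' Acquisition parameters for the radial or EPI DWI protocol
#'
#' Defaults follow the two in-vivo protocols: a radially sampled
#' diffusion-weighted spin echo (64 readout points x 101 views, one view per
#' effective TR of 2-3 respiratory periods) and a 4-shot interleaved EPI
#' (128 x 128, 16 averages). Both use the five b-values 0.64, 535, 1071,
#' 1478, 2141 s/mm^2, diffusion time Delta = 14.4 ms and gradient duration
#' delta = 9 ms, with positive and negative diffusion-gradient polarity.
#'
#' @param protocol `"RAD"` or `"EPI"`.
#' @param te Echo time (ms, metadata).
#' @param tr_resp_periods Repetition time in respiratory periods.
#' @param matrix_read,matrix_phase Readout / phase matrix sizes (even).
#' @param n_views Number of radial views (RAD).
#' @param n_shots Number of EPI interleaves; must divide `matrix_phase`.
#' @param fov Field of view (mm).
#' @param b_values Diffusion weightings (s/mm^2), strictly increasing, first
#'   value < 10.
#' @param delta_big Diffusion time Delta (ms).
#' @param delta_small Diffusion-gradient duration delta (ms); must be < Delta.
#' @param polarities Diffusion-gradient polarities, subset of `c(1, -1)`.
#' @param n_averages Number of complex-summed averages.
#' @param gated Prospective respiratory gating on/off.
#' @param noise_sigma Per-sample complex Gaussian noise SD (signal units).
#' @param gamma Gyromagnetic ratio (rad s^-1 T^-1; default 1H).
#' @param bandwidth_hz Readout bandwidth (Hz), sets the readout duration.
#' @param echo_spacing_ms EPI echo spacing (ms per phase-encode line).
#' @param b_background Background/imaging-gradient b-value (s/mm^2). When
#'   nonzero, polarity p acquires an effective weighting
#'   `b + b_background + p*2*sqrt(b*b_background)` (the cross term that the
#'   geometric-mean polarity combination cancels).
#' @return An object of class `acq_params`.
#' @export
acq_params <- function(protocol = c("RAD", "EPI"),
                       te = NULL,
                       tr_resp_periods = NULL,
                       matrix_read = NULL, matrix_phase = NULL,
                       n_views = 101L, n_shots = 4L,
                       fov = 32,
                       b_values = c(0.64, 535, 1071, 1478, 2141),
                       delta_big = 14.4, delta_small = 9,
                       polarities = c(1, -1),
                       n_averages = NULL,
                       gated = TRUE,
                       noise_sigma = 0,
                       gamma = 2.6752e8,
                       bandwidth_hz = NULL,
                       echo_spacing_ms = 0.5,
                       b_background = 0) {
  protocol <- match.arg(protocol)
  if (protocol == "RAD") {
    if (is.null(te)) te <- 30
    if (is.null(tr_resp_periods)) tr_resp_periods <- 2
    if (is.null(matrix_read)) matrix_read <- 64L
    if (is.null(matrix_phase)) matrix_phase <- matrix_read
    if (is.null(n_averages)) n_averages <- 1L
    if (is.null(bandwidth_hz)) bandwidth_hz <- 50e3
  } else {
    if (is.null(te)) te <- 26
    if (is.null(tr_resp_periods)) tr_resp_periods <- 4
    if (is.null(matrix_read)) matrix_read <- 128L
    if (is.null(matrix_phase)) matrix_phase <- 128L
    if (is.null(n_averages)) n_averages <- 16L
    if (is.null(bandwidth_hz)) bandwidth_hz <- 250e3
  }
  p <- structure(list(protocol = protocol, te = te,
                      tr_resp_periods = tr_resp_periods,
                      matrix_read = as.integer(matrix_read),
                      matrix_phase = as.integer(matrix_phase),
                      n_views = as.integer(n_views), n_shots = as.integer(n_shots),
                      fov = fov, b_values = b_values,
                      delta_big = delta_big, delta_small = delta_small,
                      polarities = polarities, n_averages = as.integer(n_averages),
                      gated = gated, noise_sigma = noise_sigma, gamma = gamma,
                      bandwidth_hz = bandwidth_hz,
                      echo_spacing_ms = echo_spacing_ms,
                      b_background = b_background),
                 class = "acq_params")
  check_acq_params(p)
  p
}

check_acq_params <- function(p) {
  if (p$delta_small >= p$delta_big)
    stop("diffusion gradient duration delta (", p$delta_small,
         " ms) must be shorter than diffusion time Delta (", p$delta_big, " ms)")
  if (any(diff(p$b_values) <= 0)) stop("b_values must be strictly increasing")
  if (p$b_values[1] >= 10) stop("first b-value must be < 10 s/mm^2")
  if (p$protocol == "EPI" && p$matrix_phase %% p$n_shots != 0)
    stop("n_shots (", p$n_shots, ") must divide matrix_phase (", p$matrix_phase, ")")
  if (p$matrix_read %% 2 != 0) stop("matrix_read must be even")
  invisible(p)
}

#' Respiratory motion model
#'
#' Periodic rigid in-plane displacement of the abdomen: each respiratory
#' period starts with a quiescent (end-expiration) window of zero displacement
#' followed by a raised-sine breath excursion. Prospective gating schedules
#' acquisition inside the quiescent window. Motion corrupts the diffusion
#' acquisition through (i) a linear k-space phase from the instantaneous
#' displacement, (ii) a per-view/per-shot bulk phase error from
#' velocity-induced phase during diffusion encoding, and (iii) an intravoxel
#' dephasing attenuation `exp(-(dephasing_scale * v * sqrt(b/b_max))^2 / 2)`
#' modeling the velocity spread across a voxel during the diffusion time.
#'
#' @param period Respiratory period in s; if `NULL`, drawn reproducibly from
#'   0.6-0.75 s (80-100 breaths/min) using `seed`.
#' @param displacement_amp Peak displacement (mm).
#' @param displacement_dir Unit 2-vector of the displacement direction.
#' @param quiescent_fraction Fraction of each period with zero displacement.
#' @param bulk_phase_scale Bulk phase error per unit velocity (rad per mm/s),
#'   scaled by sqrt(b/b_max).
#' @param dephasing_scale Intravoxel phase-dispersion SD per unit velocity
#'   (rad per mm/s), scaled by sqrt(b/b_max).
#' @param shot_phase_floor Baseline SD (rad) of EPI shot-to-shot phase errors
#'   present even at zero instantaneous velocity (residual motion within the
#'   gating window).
#' @param seed Integer used only for drawing the period when `period = NULL`.
#' @return An object of class `respiration_model`.
#' @export
respiration_model <- function(period = NULL, displacement_amp = 1,
                              displacement_dir = c(0, 1),
                              quiescent_fraction = 0.6,
                              bulk_phase_scale = 0.5,
                              dephasing_scale = 0.35,
                              shot_phase_floor = 0.4,
                              seed = 1L) {
  if (quiescent_fraction <= 0 || quiescent_fraction >= 1)
    stop("quiescent_fraction must be in (0, 1)")
  if (displacement_amp < 0) stop("displacement_amp must be >= 0")
  if (is.null(period)) {
    # deterministic hash of the seed onto 0.6-0.75 s, independent of the RNG state
    u <- ((as.numeric(seed) * 9301 + 49297) %% 233280) / 233280
    period <- 0.6 + 0.15 * u
  }
  dirn <- displacement_dir / sqrt(sum(displacement_dir^2))
  structure(list(period = period, displacement_amp = displacement_amp,
                 displacement_dir = dirn,
                 quiescent_fraction = quiescent_fraction,
                 bulk_phase_scale = bulk_phase_scale,
                 dephasing_scale = dephasing_scale,
                 shot_phase_floor = shot_phase_floor,
                 seed = as.integer(seed)),
            class = "respiration_model")
}

#' Respiratory displacement at given times
#'
#' @param t Time(s) in seconds (>= 0).
#' @param model A `respiration_model`.
#' @return An n x 2 matrix of displacement vectors (mm).
#' @export
respiratory_trace <- function(t, model) {
  stopifnot(inherits(model, "respiration_model"))
  if (any(t < 0)) stop("t must be >= 0")
  w <- resp_waveform(t, model)
  outer(model$displacement_amp * w, model$displacement_dir)
}

resp_waveform <- function(t, model) {
  q <- model$quiescent_fraction
  ph <- (t / model$period) %% 1
  w <- numeric(length(t))
  act <- ph >= q
  u <- pi * (ph[act] - q) / (1 - q)
  w[act] <- sin(u)^2
  w
}

#' Respiratory speed (signed, along the displacement direction) at given times
#'
#' Analytic time derivative of the displacement magnitude (mm/s).
#'
#' @inheritParams respiratory_trace
#' @return Numeric vector of signed speeds.
#' @export
respiratory_velocity <- function(t, model) {
  stopifnot(inherits(model, "respiration_model"))
  q <- model$quiescent_fraction
  ph <- (t / model$period) %% 1
  v <- numeric(length(t))
  act <- ph >= q
  u <- pi * (ph[act] - q) / (1 - q)
  v[act] <- model$displacement_amp * pi * sin(2 * u) / ((1 - q) * model$period)
  v
}

#' Schedule acquisition events
#'
#' Gated: one view/shot per `tr_resp_periods` respiratory periods, placed at a
#' fixed phase inside the quiescent window (so every event sees zero
#' displacement). Non-gated: a uniform TR of the same mean duration,
#' deliberately incommensurate with the respiratory period (a real scanner TR
#' is not synchronized to breathing), so events sample all respiratory phases.
#'
#' @param params An `acq_params`.
#' @param model A `respiration_model`.
#' @return A data frame with one row per event: `pol_index`, `b_index`,
#'   `average`, `unit` (view or shot index) and `time` (s).
#' @export
schedule_acquisition <- function(params, model) {
  check_acq_params(params)
  n_units <- if (params$protocol == "RAD") params$n_views else params$n_shots
  readout_s <- if (params$protocol == "RAD") {
    params$matrix_read / params$bandwidth_hz
  } else {
    (params$matrix_phase / params$n_shots) * params$echo_spacing_ms * 1e-3
  }
  q_window <- model$quiescent_fraction * model$period
  t_off <- 0.25 * q_window
  if (params$gated && t_off + readout_s >= q_window)
    stop("quiescent window (", signif(q_window, 3),
         " s) is shorter than the readout duration (", signif(readout_s, 3), " s)")
  ev <- expand.grid(unit = seq_len(n_units),
                    average = seq_len(params$n_averages),
                    b_index = seq_along(params$b_values),
                    pol_index = seq_along(params$polarities))
  n_ev <- nrow(ev)
  if (params$gated) {
    ev$time <- (seq_len(n_ev) - 1) * params$tr_resp_periods * model$period + t_off
  } else {
    tr_u <- params$tr_resp_periods * model$period * 1.0137
    ev$time <- (seq_len(n_ev) - 1) * tr_u
  }
  ev[, c("pol_index", "b_index", "average", "unit", "time")]
}

#' Stejskal-Tanner b-value
#'
#' `b = gamma^2 * g^2 * delta^2 * (Delta - delta/3)` for rectangular diffusion
#' gradient lobes.
#'
#' @param gamma Gyromagnetic ratio (rad s^-1 T^-1).
#' @param g_amp Diffusion gradient amplitude (T/mm); may be 0.
#' @param delta_small Gradient duration delta (s).
#' @param delta_big Diffusion time Delta (s); must exceed `delta_small`.
#' @return b in s/mm^2.
#' @export
b_value <- function(gamma, g_amp, delta_small, delta_big) {
  if (g_amp < 0 || gamma <= 0 || delta_small <= 0 || delta_big <= 0)
    stop("arguments must be positive (g_amp may be zero)")
  if (delta_small >= delta_big) stop("delta must be < Delta")
  gamma^2 * g_amp^2 * delta_small^2 * (delta_big - delta_small / 3)
}

# effective b for polarity p with a background-gradient cross term
b_effective <- function(b, pol, b_bg) {
  b + b_bg + pol * 2 * sqrt(b * b_bg)
}

# per-event bulk phase and intravoxel dephasing attenuation
motion_phase_atten <- function(v, b, b_max, model) {
  s <- sqrt(b / b_max)
  list(phase = model$bulk_phase_scale * v * s,
       atten = exp(-0.5 * (model$dephasing_scale * v * s)^2))
}

#' Simulate radial diffusion-weighted k-space
#'
#' For each scheduled view at angle theta and time t, evaluates the discrete
#' Fourier transform of the phantom's diffusion-weighted image along the
#' sampled k-line, displaced by the instantaneous respiratory displacement
#' (a linear phase in k), applies the velocity-scaled bulk phase error and
#' intravoxel dephasing attenuation, and adds complex Gaussian noise of SD
#' `noise_sigma` per sample. View angles uniformly cover 180 degrees in
#' sequential order.
#'
#' @param maps A `parameter_images` (any grid; its pixel size sets the DFT).
#' @param params An `acq_params` with `protocol = "RAD"`.
#' @param model A `respiration_model`.
#' @param seed Integer RNG seed (noise).
#' @return An object of class `kspace_set` with `samples` indexed
#'   (b, polarity, view, readout), `trajectory` (view, readout, kx/ky in
#'   cycles/mm), `times` (b, polarity, view) and metadata.
#' @export
simulate_radial_kspace <- function(maps, params, model, seed = 1L) {
  stopifnot(inherits(maps, "parameter_images"))
  check_acq_params(params)
  if (params$protocol != "RAD") stop("params$protocol must be 'RAD'")
  n_read <- params$matrix_read
  n_views <- params$n_views
  n_b <- length(params$b_values)
  n_pol <- length(params$polarities)
  n_img <- n_b * n_pol
  b_max <- max(params$b_values)

  dk <- 1 / params$fov
  kvec <- centered_grid(n_read, dk)
  theta <- (seq_len(n_views) - 1) * pi / n_views

  npix <- length(maps$s0_map)
  nm <- nrow(maps$s0_map)
  xs <- centered_grid(nm, maps$pixel_mm)
  X <- matrix(xs, nm, nm, byrow = TRUE)   # column coordinate
  Y <- matrix(xs, nm, nm)                 # row coordinate

  # image matrix: one column per (b, pol), b outer loop
  P <- matrix(0, npix, n_img)
  col <- 0
  for (bi in seq_len(n_b)) for (pi_ in seq_len(n_pol)) {
    col <- col + 1
    beff <- b_effective(params$b_values[bi], params$polarities[pi_], params$b_background)
    P[, col] <- as.vector(maps$s0_map * exp(-beff * maps$d_map))
  }

  sched <- schedule_acquisition(params, model)
  # average dimension collapses below; radial default is 1 average
  time_arr <- array(NA_real_, c(n_b, n_pol, params$n_averages, n_views))
  idx <- cbind(sched$b_index, sched$pol_index, sched$average, sched$unit)
  time_arr[idx] <- sched$time

  set.seed(as.integer(seed))
  samples <- array(0+0i, c(n_b, n_pol, n_views, n_read))
  traj <- array(0, c(n_views, n_read, 2))

  for (v in seq_len(n_views)) {
    nv <- c(cos(theta[v]), sin(theta[v]))
    traj[v, , 1] <- kvec * nv[1]
    traj[v, , 2] <- kvec * nv[2]
    u <- as.vector(nv[1] * X + nv[2] * Y)
    ph <- -2 * pi * outer(kvec, u)
    E <- matrix(complex(real = cos(ph), imaginary = sin(ph)), n_read, npix)
    S_static <- E %*% P   # n_read x n_img
    col <- 0
    for (bi in seq_len(n_b)) for (pi_ in seq_len(n_pol)) {
      col <- col + 1
      acc <- complex(length.out = n_read)
      for (av in seq_len(params$n_averages)) {
        t_ev <- time_arr[bi, pi_, av, v]
        disp <- drop(respiratory_trace(t_ev, model))
        proj <- sum(disp * nv)
        vel <- respiratory_velocity(t_ev, model)
        ma <- motion_phase_atten(vel, params$b_values[bi], b_max, model)
        sig <- S_static[, col] *
          exp(complex(imaginary = -2 * pi * kvec * proj + ma$phase)) * ma$atten
        acc <- acc + sig
      }
      samples[bi, pi_, v, ] <- acc
    }
  }
  if (params$noise_sigma > 0) {
    samples <- samples + array(
      complex_rnorm(length(samples), sd = params$noise_sigma * sqrt(params$n_averages)),
      dim(samples))
  }

  structure(list(samples = samples, trajectory = traj,
                 times = time_arr[, , 1, , drop = TRUE],
                 params = params, model = model, protocol = "RAD",
                 theta = theta, kvec = kvec, fov = params$fov,
                 seed = as.integer(seed), schedule = sched),
            class = "kspace_set")
}

#' Simulate interleaved multi-shot EPI diffusion-weighted k-space
#'
#' The phase-encode raster is partitioned into `n_shots` interleaves (shot s
#' acquires lines s, s + n_shots, ...). Each shot of each average carries one
#' random constant and one random linear (along readout) phase error, with SD
#' `shot_phase_floor + bulk_phase_scale * |v| * sqrt(b/b_max)` rad, plus the
#' intravoxel dephasing attenuation; compartments with a nonzero chemical
#' shift accrue off-resonance phase along the echo train
#' (`2*pi * df * t_line`, `df = shift_ppm * 1e-6 * gamma/(2*pi) * B0`).
#' Complex Gaussian noise is added per sample and averages are summed
#' complex-valued.
#'
#' @param maps A `parameter_images` rasterized at the EPI matrix size.
#' @param params An `acq_params` with `protocol = "EPI"`.
#' @param model A `respiration_model`.
#' @param seed Integer RNG seed (noise and shot phase errors).
#' @return A `kspace_set` with `samples` indexed
#'   (b, polarity, shot, line-in-shot, readout).
#' @export
simulate_epi_kspace <- function(maps, params, model, seed = 1L) {
  stopifnot(inherits(maps, "parameter_images"))
  check_acq_params(params)
  if (params$protocol != "EPI") stop("params$protocol must be 'EPI'")
  n_read <- params$matrix_read
  n_ph <- params$matrix_phase
  if (!all(dim(maps$s0_map) == c(n_ph, n_read)))
    stop("maps must be rasterized at the EPI matrix size (", n_ph, " x ", n_read, ")")
  S <- params$n_shots
  L <- n_ph / S
  n_b <- length(params$b_values)
  n_pol <- length(params$polarities)
  b_max <- max(params$b_values)

  # off-resonance groups: one k-space per distinct chemical shift
  shifts <- sort(unique(as.vector(maps$shift_map[maps$s0_map > 0])))
  if (length(shifts) == 0) shifts <- 0
  esp_s <- params$echo_spacing_ms * 1e-3
  gamma_bar <- params$gamma / (2 * pi)
  b0 <- maps$field_strength

  # echo-train timing: line j of a shot is read at (j - (L+1)/2) * esp relative
  # to the echo center
  t_line <- (seq_len(L) - (L + 1) / 2) * esp_s
  # ky row index of shot s, line j
  row_of <- function(s, j) (j - 1L) * S + s

  sched <- schedule_acquisition(params, model)
  time_arr <- array(NA_real_, c(n_b, n_pol, params$n_averages, S))
  time_arr[cbind(sched$b_index, sched$pol_index, sched$average, sched$unit)] <- sched$time

  set.seed(as.integer(seed))
  samples <- array(0+0i, c(n_b, n_pol, S, L, n_read))
  kx_ramp <- centered_grid(n_read, 1) / n_read  # unit ramp across readout

  for (bi in seq_len(n_b)) for (pi_ in seq_len(n_pol)) {
    beff <- b_effective(params$b_values[bi], params$polarities[pi_], params$b_background)
    img <- maps$s0_map * exp(-beff * maps$d_map)
    Kg <- lapply(shifts, function(sh) cdft2(img * (maps$shift_map == sh)))
    dfs <- shifts * 1e-6 * gamma_bar * b0   # Hz
    for (av in seq_len(params$n_averages)) {
      for (s in seq_len(S)) {
        t_ev <- time_arr[bi, pi_, av, s]
        vel <- respiratory_velocity(t_ev, model)
        disp <- drop(respiratory_trace(t_ev, model))
        ma <- motion_phase_atten(vel, params$b_values[bi], b_max, model)
        sdp <- model$shot_phase_floor +
          model$bulk_phase_scale * abs(vel) * sqrt(params$b_values[bi] / b_max)
        phi_c <- stats::rnorm(1, sd = sdp)
        phi_l <- stats::rnorm(1, sd = sdp)
        rows <- row_of(s, seq_len(L))
        ky <- centered_grid(n_ph, 1 / params$fov)[rows]
        kx <- centered_grid(n_read, 1 / params$fov)
        # shot lines: sum off-resonance groups with per-line phase accrual
        block <- matrix(0+0i, L, n_read)
        for (g in seq_along(shifts)) {
          lp <- exp(complex(imaginary = 2 * pi * dfs[g] * t_line))
          block <- block + Kg[[g]][rows, , drop = FALSE] * lp
        }
        # rigid displacement -> linear phase in (kx, ky)
        dphase <- exp(complex(imaginary = -2 * pi * (outer(ky * disp[2], rep(1, n_read)) +
                                                     outer(rep(1, L), kx * disp[1]))))
        shot_phase <- exp(complex(imaginary = phi_c + phi_l * kx_ramp))
        block <- block * dphase * ma$atten * exp(complex(imaginary = ma$phase))
        block <- sweep(block, 2, shot_phase, `*`)
        if (params$noise_sigma > 0)
          block <- block + matrix(complex_rnorm(L * n_read, sd = params$noise_sigma), L, n_read)
        samples[bi, pi_, s, , ] <- samples[bi, pi_, s, , ] + block
      }
    }
  }

  structure(list(samples = samples, trajectory = list(
                   ky_rows = outer(seq_len(S), (seq_len(L) - 1L) * S, `+`),
                   kx = centered_grid(n_read, 1 / params$fov),
                   ky = centered_grid(n_ph, 1 / params$fov)),
                 times = time_arr[, , 1, , drop = TRUE],
                 params = params, model = model, protocol = "EPI",
                 fov = params$fov, seed = as.integer(seed), schedule = sched),
            class = "kspace_set")
}
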