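#' Zero- and first-order phase correction of one radial view
#'
#' Estimates the linear phase across the readout by the Ahn-Cho
#' autocorrelation estimator and the residual constant phase by the
#' magnitude-weighted mean phase, then removes both; finally the echo peak
#' (maximum magnitude) is rolled to the central readout index. The correction
#' is a pure phase operation plus a circular index shift: the magnitude
#' profile is preserved. For a rigidly displaced object the first-order term
#' is exactly the displacement-induced linear phase, so this step
#' re-registers each view.
#'
#' @param view Complex vector of one view's samples (length >= 8).
#' @return Corrected complex vector with attributes `phi0`, `phi1` (removed
#'   phases, rad) and `warn` (TRUE for an all-zero input, returned unchanged).
#' @export
phase_correct_radial <- function(view) {
  n <- length(view)
  if (n < 8) stop("a view must have at least 8 samples")
  if (all(Mod(view) == 0)) {
    attr(view, "warn") <- TRUE
    return(view)
  }
  m <- seq_len(n) - 1 - n / 2
  # first order: phase increment per sample
  z <- sum(view[-1] * Conj(view[-n]))
  phi1 <- Arg(z)
  out <- view * exp(complex(imaginary = -phi1 * m))
  # zero order: magnitude-weighted mean phase
  phi0 <- Arg(sum(out * Mod(out)))
  out <- out * exp(complex(imaginary = -phi0))
  # echo centering: roll the magnitude peak to index n/2 + 1
  pk <- which.max(Mod(out))
  shift <- (n %/% 2 + 1) - pk
  if (shift != 0) out <- out[((seq_len(n) - 1 - shift) %% n) + 1]
  attr(out, "phi0") <- phi0
  attr(out, "phi1") <- phi1
  attr(out, "warn") <- FALSE
  out
}

# band-limited Ram-Lak kernel values at integer lags (spacing ds)
ramlak_kernel <- function(lags, ds) {
  h <- numeric(length(lags))
  h[lags == 0] <- 1 / (4 * ds^2)
  odd <- lags %% 2 != 0
  h[odd] <- -1 / (pi^2 * lags[odd]^2 * ds^2)
  h
}

# filter one projection (length n) with the ramp kernel via zero-padded FFT
ramp_filter <- function(p, ds, hann = FALSE) {
  n <- length(p)
  hfull <- ramlak_kernel(c(0:(n - 1), -n:-1), ds)
  H <- stats::fft(hfull)
  if (hann) {
    f <- c(0:(n - 1), -n:-1) / n   # normalized frequency of the length-2n FFT
    H <- H * 0.5 * (1 + cos(pi * pmin(abs(f), 1)))
  }
  q <- stats::fft(stats::fft(c(p, rep(0+0i, n))) * H, inverse = TRUE) / (2 * n)
  ds * q[seq_len(n)]
}

# View-consistent zero/first-order phase correction for a whole image's views.
#
# A rigid in-plane displacement at view v's acquisition time adds a linear
# phase along the sampled k-line, i.e. it shifts that view's projection by
# the along-view displacement component. The projections of a *static* object
# have centers of mass that follow the rigid sinogram law
# c(theta) = c0 + x0*cos(theta) + y0*sin(theta); motion shows up as per-view
# residuals from that law. The residual shift of each view is estimated from
# the magnitude projection's center of mass, the sinusoid is fitted across
# views by least squares, and only the residual is removed (as a first-order
# k-space phase). Removing each view's full linear phase instead would
# silently re-center the object, differently at every b-value as compartments
# fade. The zero-order (constant) phase of each projection is removed
# entirely: a real non-negative object contributes none, so whatever is there
# is the motion-induced bulk phase error.
phase_correct_views <- function(V, theta, kvec, sgrid) {
  n_views <- nrow(V); n_read <- ncol(V)
  com <- numeric(n_views)
  P <- matrix(0+0i, n_views, n_read)
  for (v in seq_len(n_views)) {
    P[v, ] <- cidft1(V[v, ])
    w <- Mod(P[v, ])
    com[v] <- if (sum(w) > 0) sum(w * sgrid) / sum(w) else 0
  }
  des <- cbind(1, cos(theta), sin(theta))
  fit <- des %*% qr.solve(des, com)
  resid <- com - fit
  for (v in seq_len(n_views)) {
    # undo the residual projection shift: multiply k samples by e^{+2pi i k d}
    sv <- V[v, ] * exp(complex(imaginary = 2 * pi * kvec * resid[v]))
    pv <- cidft1(sv)
    phi0 <- if (all(Mod(pv) == 0)) 0 else Arg(sum(pv * Mod(pv)))
    V[v, ] <- sv * exp(complex(imaginary = -phi0))
  }
  V
}

new_dwi_stack <- function(images, pixel_mm, protocol, params, provenance = list()) {
  structure(list(images = images, pixel_mm = pixel_mm, protocol = protocol,
                 params = params, provenance = provenance),
            class = "dwi_stack")
}

#' Filtered back-projection reconstruction of radial k-space
#'
#' Per view: optional zero/first-order phase correction (view-consistent: the
#' rigid across-view sinusoidal component of the linear phase is preserved and
#' only per-view motion residuals are removed), 1-D inverse Fourier transform
#' to a projection, band-limited ramp (Ram-Lak) filtering (optional Hann
#' apodization), then linear-interpolation back-projection over the uniformly
#' spaced view angles onto the target matrix. The output stack holds magnitude
#' images.
#'
#' @param kspace A radial `kspace_set`.
#' @param matrix_out Output matrix size (default: the readout matrix,
#'   i.e. regridding to matrix_read x matrix_read).
#' @param phase_correct Apply [phase_correct_radial()] per view (default TRUE).
#' @param hann Apply Hann apodization to the ramp filter (default FALSE).
#' @return A `dwi_stack` with images indexed (slice, b, polarity, y, x).
#' @export
fbp_reconstruct <- function(kspace, matrix_out = NULL, phase_correct = TRUE,
                            hann = FALSE) {
  stopifnot(inherits(kspace, "kspace_set"))
  if (kspace$protocol != "RAD") stop("fbp_reconstruct expects radial k-space")
  dims <- dim(kspace$samples)
  n_b <- dims[1]; n_pol <- dims[2]; n_views <- dims[3]; n_read <- dims[4]
  if (n_views < 8) stop("at least 8 views are required")
  nout <- if (is.null(matrix_out)) n_read else as.integer(matrix_out)
  fov <- kspace$fov
  ds <- fov / n_read
  dk <- 1 / fov
  sgrid <- centered_grid(n_read, ds)
  xs <- centered_grid(nout, fov / nout)
  X <- matrix(xs, nout, nout, byrow = TRUE)
  Y <- matrix(xs, nout, nout)
  dtheta <- pi / n_views
  theta <- kspace$theta

  # band-limited (zero-pad) interpolation factor for the filtered projections
  up <- 4L
  sfine <- centered_grid(up * n_read, ds / up)
  images <- array(0, c(1, n_b, n_pol, nout, nout))
  for (bi in seq_len(n_b)) for (pi_ in seq_len(n_pol)) {
    V <- matrix(kspace$samples[bi, pi_, , ], n_views, n_read)
    if (phase_correct) V <- phase_correct_views(V, theta, kvec = kspace$kvec,
                                                sgrid = sgrid)
    acc_re <- matrix(0, nout, nout)
    acc_im <- matrix(0, nout, nout)
    for (v in seq_len(n_views)) {
      sv <- V[v, ]
      # dk: quadrature weight of the k integral; ds^2: pixel-area factor
      # relating the DFT samples to the continuous Fourier transform at the
      # readout resolution (the calibration that makes recon values match the
      # phantom's pixel values)
      p <- dk * ds^2 * cidft1(sv)
      q <- ramp_filter(p, ds, hann = hann)
      # sinc-interpolate the filtered projection onto a 4x finer grid before
      # linear back-projection interpolation
      Q <- cdft1(q)
      Qp <- c(rep(0+0i, (up - 1L) * n_read / 2), Q, rep(0+0i, (up - 1L) * n_read / 2))
      qf <- cidft1(Qp) / n_read
      spix <- cos(theta[v]) * X + sin(theta[v]) * Y
      acc_re <- acc_re + matrix(stats::approx(sfine, Re(qf), xout = as.vector(spix),
                                              yleft = 0, yright = 0)$y, nout, nout)
      acc_im <- acc_im + matrix(stats::approx(sfine, Im(qf), xout = as.vector(spix),
                                              yleft = 0, yright = 0)$y, nout, nout)
    }
    images[1, bi, pi_, , ] <- sqrt((dtheta * acc_re)^2 + (dtheta * acc_im)^2) /
      kspace$params$n_averages
  }
  new_dwi_stack(images, fov / nout, "RAD", kspace$params,
                provenance = list(phase_correct = phase_correct, hann = hann,
                                  filter = "ram-lak", seed = kspace$seed))
}

#' Fourier reconstruction of interleaved EPI k-space
#'
#' Reassembles the shot interleaves into the full Cartesian raster
#' (shot s contributes phase-encode lines s, s + n_shots, ...) and applies a
#' 2-D inverse Fourier transform; outputs magnitude images. Even/odd readout
#' reversal is assumed ideally corrected upstream; only shot-to-shot errors
#' present in the data reach the image (as coherent ghosts at multiples of
#' matrix_phase/n_shots lines).
#'
#' @param kspace An EPI `kspace_set`.
#' @return A `dwi_stack` with images indexed (slice, b, polarity, y, x).
#' @export
epi_reconstruct <- function(kspace) {
  stopifnot(inherits(kspace, "kspace_set"))
  if (kspace$protocol != "EPI") stop("epi_reconstruct expects EPI k-space")
  if (anyNA(kspace$samples)) stop("missing interleave: k-space contains NA samples")
  dims <- dim(kspace$samples)
  n_b <- dims[1]; n_pol <- dims[2]; S <- dims[3]; L <- dims[4]; n_read <- dims[5]
  n_ph <- S * L
  images <- array(0, c(1, n_b, n_pol, n_ph, n_read))
  for (bi in seq_len(n_b)) for (pi_ in seq_len(n_pol)) {
    full <- matrix(0+0i, n_ph, n_read)
    for (s in seq_len(S)) {
      rows <- (seq_len(L) - 1L) * S + s
      full[rows, ] <- kspace$samples[bi, pi_, s, , ]
    }
    img <- cidft2(full) / (n_ph * n_read)
    images[1, bi, pi_, , ] <- Mod(img) / kspace$params$n_averages
  }
  new_dwi_stack(images, kspace$fov / n_ph, "EPI", kspace$params,
                provenance = list(seed = kspace$seed))
}

#' Signal-to-noise ratio of a magnitude image
#'
#' `mean(signal pixels) / (SD(background pixels) / 0.655)`: the background of
#' a magnitude image with complex Gaussian noise of SD sigma is Rayleigh
#' distributed with SD `sqrt((4 - pi)/2) * sigma = 0.655 * sigma`, so dividing
#' the background SD by 0.655 recovers sigma.
#'
#' @param image Numeric matrix (magnitude image).
#' @param signal_mask,background_mask Disjoint logical masks; the background
#'   mask must cover an air region.
#' @return The SNR (possibly `Inf`, flagged with attribute `degenerate`).
#' @export
snr <- function(image, signal_mask, background_mask) {
  if (!any(signal_mask) || !any(background_mask)) stop("empty mask")
  if (any(signal_mask & background_mask)) stop("masks must be disjoint")
  bg_sd <- stats::sd(image[background_mask])
  val <- mean(image[signal_mask]) / (bg_sd / sqrt((4 - pi) / 2))
  if (!is.finite(val)) attr(val, "degenerate") <- TRUE
  val
}

#' Calibrate the k-space noise SD for a target image-domain SNR
#'
#' Reconstruction is linear in the k-space samples, so the background noise in
#' the magnitude image scales linearly with `noise_sigma`. This routine
#' measures (a) the image-domain noise per unit k-space sigma by
#' reconstructing a pure-noise acquisition, and (b) the reconstructed
#' reference-compartment amplitude from a noiseless acquisition, and returns
#' the k-space sigma giving `amplitude / sigma_image = snr_target` in the
#' lowest-b image.
#'
#' @param maps A `parameter_images`.
#' @param params An `acq_params`.
#' @param model A `respiration_model`.
#' @param snr_target Desired SNR of the reference compartment.
#' @param ref_compartment Compartment name used as the signal reference.
#' @param calib_seed Internal seed for the pure-noise realization.
#' @return The calibrated `noise_sigma` (scalar).
#' @export
calibrate_noise_sigma <- function(maps, params, model, snr_target,
                                  ref_compartment = "water", calib_seed = 9901L) {
  stopifnot(snr_target > 0)
  simfun <- if (params$protocol == "RAD") simulate_radial_kspace else simulate_epi_kspace
  reconfun <- function(ks, pc) {
    if (params$protocol == "RAD") fbp_reconstruct(ks, phase_correct = pc) else epi_reconstruct(ks)
  }
  # (a) unit-noise, zero-signal acquisition
  maps0 <- maps
  maps0$s0_map[] <- 0
  p1 <- params; p1$noise_sigma <- 1
  ks0 <- simfun(maps0, p1, model, seed = calib_seed)
  st0 <- reconfun(ks0, pc = FALSE)
  sigma_img_unit <- stats::sd(as.vector(st0$images[1, 1, 1, , ])) / sqrt((4 - pi) / 2)
  # (b) noiseless reference amplitude
  p0 <- params; p0$noise_sigma <- 0
  ks1 <- simfun(maps, p0, model, seed = calib_seed)
  st1 <- reconfun(ks1, pc = TRUE)
  nout <- dim(st1$images)[4]
  maps_out <- if (nrow(maps$s0_map) == nout) maps else
    stop("calibration requires maps at the reconstruction matrix size")
  masks <- roi_masks(maps_out, erode = 1L)
  if (!ref_compartment %in% names(masks)) stop("unknown reference compartment")
  amp <- mean(st1$images[1, 1, 1, , ][masks[[ref_compartment]]])
  amp / (snr_target * sigma_img_unit)
}
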