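#' Geometric-mean combination of opposite diffusion-gradient polarities
#'
#' Pixel-wise `sqrt(img_plus * img_minus)`. Cross terms between the diffusion
#' gradient and background/imaging gradients enter the two polarities with
#' opposite sign (`exp(-+2*sqrt(b*b_bg)*D)`), so the geometric mean cancels
#' them exactly, leaving `S0 * exp(-(b + b_bg) * D)` whose decay constant is
#' the unbiased D.
#'
#' @param img_plus,img_minus Non-negative arrays of identical shape.
#' @return The combined array.
#' @export
combine_polarities <- function(img_plus, img_minus) {
  if (!identical(dim(img_plus), dim(img_minus)) ||
      length(img_plus) != length(img_minus))
    stop("polarity images must have the same shape")
  if (any(img_plus < 0) || any(img_minus < 0))
    stop("polarity images must be non-negative")
  sqrt(img_plus * img_minus)
}

#' Three-parameter diffusion fit of one pixel
#'
#' Bounded nonlinear least squares of `S(b) = S0*exp(-b*D) + A` with
#' `S0, D, A >= 0` (Levenberg-Marquardt with analytic Jacobian). The offset A
#' absorbs the Rician noise floor of magnitude images. Initialization:
#' `A0 = min(S)`, `D0` from the log-linear slope of `S - A0` over the first
#' three b-values clipped to `[1e-5, 1e-2]`, `S0_0 = S(b_min) - A0`.
#'
#' @param signal Numeric vector of magnitudes over b (length >= 4).
#' @param b_values Strictly increasing b-values (s/mm^2), same length.
#' @param d_upper Upper bound on D (mm^2/s); hitting it invalidates the fit.
#' @param fix_a Fit with A fixed at zero (two-parameter model).
#' @return A list: `s0`, `d` (ADC, mm^2/s), `a`, `rss`, `ok`.
#' @export
fit_pixel <- function(signal, b_values, d_upper = 2e-2, fix_a = FALSE) {
  if (length(signal) != length(b_values) || length(signal) < 4)
    stop("need >= 4 (b, S) points of equal length")
  if (any(diff(b_values) <= 0)) stop("b_values must be strictly increasing")
  if (all(signal == 0))
    return(list(s0 = 0, d = 0, a = 0, rss = 0, ok = FALSE))
  if (max(signal) - min(signal) < 1e-12 * max(abs(signal)))
    return(list(s0 = 0, d = 0, a = signal[1], rss = 0, ok = FALSE))

  a0 <- if (fix_a) 0 else min(signal)
  eps <- 1e-9 * max(signal)
  y3 <- pmax(signal[1:3] - a0, eps)
  sl <- stats::coef(stats::lm(log(y3) ~ b_values[1:3]))[2]
  d0 <- min(max(-sl, 1e-5), 1e-2)
  s00 <- max(signal[1] - a0, eps)

  resid_fn <- function(p) p[1] * exp(-b_values * p[2]) + p[3] - signal
  jac_fn <- function(p) {
    e <- exp(-b_values * p[2])
    cbind(e, -p[1] * b_values * e, rep(1, length(b_values)))
  }
  upper <- c(Inf, d_upper, if (fix_a) 0 else Inf)
  # convergence status is captured in `ok`; the optimizer's own warnings
  # (e.g. maxiter on degenerate background pixels) carry no extra information
  fit <- try(suppressWarnings(minpack.lm::nls.lm(
    par = c(s00, d0, a0), lower = c(0, 0, 0), upper = upper,
    fn = resid_fn, jac = jac_fn,
    control = minpack.lm::nls.lm.control(ftol = 1e-10, ptol = 1e-10,
                                         maxiter = 200))), silent = TRUE)
  if (inherits(fit, "try-error"))
    return(list(s0 = 0, d = 0, a = 0, rss = Inf, ok = FALSE))
  p <- fit$par
  ok <- fit$info %in% 1:4 && p[2] > 1e-12 && p[2] < d_upper - 1e-12
  list(s0 = p[1], d = p[2], a = p[3], rss = fit$deviance, ok = ok)
}

#' Pixel-wise ADC mapping of a diffusion-weighted image stack
#'
#' Per b-value, combines the two gradient polarities by their geometric mean,
#' then fits [fit_pixel()] at every pixel whose max-over-b signal exceeds
#' 3x a background-SD estimate (taken from the four corner blocks of the
#' lowest-b image, which are air in the default phantom geometry). Pixels
#' below the threshold, or with failed fits, are excluded from `valid_mask`.
#'
#' @param stack A `dwi_stack` containing both polarities for every b.
#' @param bg_sd Optional externally supplied background SD (magnitude units);
#'   default estimates it from the image corners.
#' @param d_upper Passed to [fit_pixel()].
#' @return An object of class `parameter_maps`: arrays `s0_map`, `d_map`,
#'   `a_map`, `rss_map` indexed (slice, y, x), logical `valid_mask`, plus
#'   `pixel_mm` and `b_values`.
#' @export
fit_stack <- function(stack, bg_sd = NULL, d_upper = 2e-2) {
  stopifnot(inherits(stack, "dwi_stack"))
  dims <- dim(stack$images)
  n_slice <- dims[1]; n_b <- dims[2]; n_pol <- dims[3]; ny <- dims[4]; nx <- dims[5]
  if (n_pol != 2) stop("stack must contain both polarities for every b")
  b_values <- stack$params$b_values
  if (length(b_values) != n_b) stop("b_values metadata inconsistent with stack")

  s0m <- dm <- am <- rssm <- array(NA_real_, c(n_slice, ny, nx))
  vm <- array(FALSE, c(n_slice, ny, nx))
  for (sl in seq_len(n_slice)) {
    comb <- array(0, c(n_b, ny, nx))
    for (bi in seq_len(n_b)) {
      comb[bi, , ] <- combine_polarities(stack$images[sl, bi, 1, , ],
                                         stack$images[sl, bi, 2, , ])
    }
    if (is.null(bg_sd)) {
      cb <- max(4L, ny %/% 8)
      corners <- c(comb[1, 1:cb, 1:cb], comb[1, 1:cb, (nx - cb + 1):nx],
                   comb[1, (ny - cb + 1):ny, 1:cb],
                   comb[1, (ny - cb + 1):ny, (nx - cb + 1):nx])
      bg <- stats::sd(corners)
    } else bg <- bg_sd
    maxsig <- apply(comb, c(2, 3), max)
    candidate <- maxsig > 3 * bg
    for (iy in seq_len(ny)) for (ix in seq_len(nx)) {
      if (!candidate[iy, ix]) next
      f <- fit_pixel(comb[, iy, ix], b_values, d_upper = d_upper)
      s0m[sl, iy, ix] <- f$s0; dm[sl, iy, ix] <- f$d
      am[sl, iy, ix] <- f$a; rssm[sl, iy, ix] <- f$rss
      vm[sl, iy, ix] <- f$ok
    }
  }
  structure(list(s0_map = s0m, d_map = dm, a_map = am, rss_map = rssm,
                 valid_mask = vm, pixel_mm = stack$pixel_mm,
                 b_values = b_values),
            class = "parameter_maps")
}

#' ROI statistics of an ADC map
#'
#' Mean and SD of the ADC over the intersection of an ROI mask with the fit
#' validity mask, pooled across the listed slices.
#'
#' @param maps A `parameter_maps` from [fit_stack()].
#' @param roi_mask Logical matrix (y, x).
#' @param slices Slice indices to pool (default: all).
#' @return A list: `mean`, `sd`, `n_pixels` (ADC in mm^2/s).
#' @export
roi_stats <- function(maps, roi_mask, slices = NULL) {
  stopifnot(inherits(maps, "parameter_maps"))
  if (is.null(slices)) slices <- seq_len(dim(maps$d_map)[1])
  vals <- numeric(0)
  for (sl in slices) {
    sel <- roi_mask & maps$valid_mask[sl, , ]
    vals <- c(vals, maps$d_map[sl, , ][sel])
  }
  if (length(vals) == 0) stop("ROI does not intersect the valid fit mask")
  list(mean = mean(vals), sd = stats::sd(vals), n_pixels = length(vals))
}

#' ROI summary table over several ROIs
#'
#' @param maps A `parameter_maps`.
#' @param masks Named list of logical ROI masks.
#' @param slices Slice indices to pool (default: all).
#' @param scale Multiplier applied to the reported mean/SD (default `1e3`:
#'   ADC reported in 1e-3 mm^2/s, the field's reporting unit).
#' @return A data frame with columns `roi`, `slice_range`, `mean`, `sd`,
#'   `n_pixels`.
#' @export
roi_table <- function(maps, masks, slices = NULL, scale = 1e3) {
  if (is.null(slices)) slices <- seq_len(dim(maps$d_map)[1])
  rows <- lapply(names(masks), function(nm) {
    st <- roi_stats(maps, masks[[nm]], slices)
    data.frame(roi = nm, slice_range = paste(range(slices), collapse = "-"),
               mean = st$mean * scale, sd = st$sd * scale,
               n_pixels = st$n_pixels)
  })
  do.call(rbind, rows)
}
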