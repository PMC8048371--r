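#' Construct paired test-retest measurements
#'
#' @param test,retest Positive finite ADC values (same length), conventionally
#'   in 1e-3 mm^2/s.
#' @param subject Optional subject identifiers.
#' @param tissue Optional tissue label.
#' @return A data frame of class `paired_measurements` with columns `subject`,
#'   `tissue`, `test`, `retest`.
#' @export
paired_measurements <- function(test, retest, subject = seq_along(test),
                                tissue = NA_character_) {
  if (length(test) != length(retest)) stop("test and retest must have equal length")
  if (any(!is.finite(test)) || any(!is.finite(retest)) ||
      any(test <= 0) || any(retest <= 0))
    stop("all paired values must be positive and finite")
  structure(data.frame(subject = subject, tissue = tissue,
                       test = test, retest = retest),
            class = c("paired_measurements", "data.frame"))
}

delta_d <- function(pairs) pairs$test - pairs$retest
pair_mean <- function(pairs) (pairs$test + pairs$retest) / 2

#' Within-subject standard deviation
#'
#' `SD_ws = sqrt( sum(DeltaD_i^2) / (2n) )` where `DeltaD_i` is the
#' test-minus-retest difference of subject i and n the number of pairs.
#'
#' @param pairs A `paired_measurements` (or data frame with `test`/`retest`).
#' @return Scalar SD_ws in the units of the inputs.
#' @export
sd_ws <- function(pairs) {
  if (is.null(pairs) || nrow(pairs) < 1) stop("at least one pair is required")
  dd <- delta_d(pairs)
  sqrt(sum(dd^2) / (2 * length(dd)))
}

#' Within-subject coefficient of variation
#'
#' `CV_ws = sqrt( sum((DeltaD_i / m_i)^2) / (2n) )` with `m_i` the mean of
#' pair i; dimensionless.
#'
#' @inheritParams sd_ws
#' @return Scalar CV_ws.
#' @export
cv_ws <- function(pairs) {
  if (is.null(pairs) || nrow(pairs) < 1) stop("at least one pair is required")
  m <- pair_mean(pairs)
  if (any(m <= 0)) stop("every pair mean must be > 0")
  dd <- delta_d(pairs)
  sqrt(sum((dd / m)^2) / (2 * length(dd)))
}

#' Repeatability coefficient
#'
#' `RC = 1.96 * sqrt(2) * SD_ws` (approximately 2.77 x SD_ws): the 95% limit
#' for the absolute difference between two repeated measurements. The
#' unrounded constant `1.96*sqrt(2)` is used internally; "2.77" is a
#' reporting-layer rounding.
#'
#' @param sd_ws_value A within-subject SD (>= 0).
#' @return Scalar RC in the units of `sd_ws_value`.
#' @export
rc <- function(sd_ws_value) {
  if (any(sd_ws_value < 0)) stop("sd_ws must be >= 0")
  1.96 * sqrt(2) * sd_ws_value
}

#' Repeatability summary of a paired cohort
#'
#' @inheritParams sd_ws
#' @return A list of class `repeatability_result`: `n`, `delta_mean`,
#'   `delta_sd` (sample SD), `sd_ws`, `cv_ws`, `rc`.
#' @export
repeatability_summary <- function(pairs) {
  dd <- delta_d(pairs)
  structure(list(n = length(dd), delta_mean = mean(dd),
                 delta_sd = stats::sd(dd), sd_ws = sd_ws(pairs),
                 cv_ws = cv_ws(pairs), rc = rc(sd_ws(pairs))),
            class = "repeatability_result")
}

#' Bland-Altman summary of paired measurements
#'
#' Bias = mean(DeltaD) with agreement limits at bias +/- RC (the repeatability
#' coefficient, rather than the conventional 1.96*SD of the differences), and
#' the per-pair (mean, DeltaD) points. Sign convention: test minus retest.
#'
#' @inheritParams sd_ws
#' @return A list: `bias`, `upper`, `lower`, `points` (data frame with
#'   columns `mean` and `delta`).
#' @export
bland_altman <- function(pairs) {
  if (nrow(pairs) < 2) stop("at least two pairs are required")
  dd <- delta_d(pairs)
  bias <- mean(dd)
  r <- rc(sd_ws(pairs))
  list(bias = bias, upper = bias + r, lower = bias - r,
       points = data.frame(mean = pair_mean(pairs), delta = dd))
}

#' Kernel density estimate of pixel-wise ADC values
#'
#' Gaussian KDE evaluated on a caller-supplied grid, with Silverman's
#' rule-of-thumb bandwidth (`stats::bw.nrd0`). Used to compare the pixel-ADC
#' distributions of test vs retest scans.
#'
#' @param pixel_adc_values Numeric vector (>= 30 values).
#' @param grid Evaluation grid (should generously cover the sample support).
#' @return A data frame with columns `x` (grid) and `density`.
#' @export
pdf_estimate <- function(pixel_adc_values, grid) {
  x <- pixel_adc_values[is.finite(pixel_adc_values)]
  if (length(x) < 30) stop("at least 30 pixels are required")
  bw <- stats::bw.nrd0(x)
  dens <- vapply(grid, function(g) mean(stats::dnorm(g, mean = x, sd = bw)),
                 numeric(1))
  data.frame(x = grid, density = dens)
}

#' Ordinary least-squares correlation between the two protocols
#'
#' Regresses the radial-protocol ADC on the EPI-protocol ADC for matched
#' subjects and reports slope, intercept and R^2. Plain OLS plumbing (no
#' repeated-measures modeling).
#'
#' @param pairs_rad,pairs_epi `paired_measurements` for the two protocols with
#'   matching `subject` columns.
#' @param session `"test"` or `"retest"`: which session's values to correlate.
#' @return A list: `slope`, `intercept`, `r_squared`, `n`.
#' @export
correlate_protocols <- function(pairs_rad, pairs_epi, session = c("test", "retest")) {
  session <- match.arg(session)
  m <- merge(pairs_rad[, c("subject", session)],
             pairs_epi[, c("subject", session)], by = "subject",
             suffixes = c("_rad", "_epi"))
  if (nrow(m) < 3) stop("at least 3 matched subjects are required")
  y <- m[[paste0(session, "_rad")]]
  x <- m[[paste0(session, "_epi")]]
  fit <- stats::lm(y ~ x)
  list(slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       r_squared = summary(fit)$r.squared, n = nrow(m))
}

#' Repeatability table over tissues and protocols
#'
#' Produces one row per tissue x protocol in the shape of a test-retest
#' summary table: test/retest cohort mean +/- SD, DeltaD mean +/- SD, SD_ws,
#' CV_ws and RC.
#'
#' @param measurements Data frame with columns `subject`, `session`
#'   (`"test"`/`"retest"`), `protocol`, `tissue`, `adc`.
#' @return A data frame with one row per tissue x protocol.
#' @export
repeatability_table <- function(measurements) {
  need <- c("subject", "session", "protocol", "tissue", "adc")
  if (!all(need %in% names(measurements))) stop("missing columns")
  combos <- unique(measurements[, c("tissue", "protocol")])
  rows <- lapply(seq_len(nrow(combos)), function(i) {
    sub <- measurements[measurements$tissue == combos$tissue[i] &
                        measurements$protocol == combos$protocol[i], ]
    te <- sub[sub$session == "test", ]
    re <- sub[sub$session == "retest", ]
    m <- merge(te[, c("subject", "adc")], re[, c("subject", "adc")],
               by = "subject", suffixes = c("_test", "_retest"))
    pr <- paired_measurements(m$adc_test, m$adc_retest, subject = m$subject,
                              tissue = combos$tissue[i])
    s <- repeatability_summary(pr)
    data.frame(tissue = combos$tissue[i], protocol = combos$protocol[i],
               n = s$n,
               test_mean = mean(pr$test), test_sd = stats::sd(pr$test),
               retest_mean = mean(pr$retest), retest_sd = stats::sd(pr$retest),
               delta_mean = s$delta_mean, delta_sd = s$delta_sd,
               sd_ws = s$sd_ws, cv_ws = s$cv_ws, rc = s$rc)
  })
  do.call(rbind, rows)
}
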