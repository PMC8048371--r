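test_that("within-subject SD follows its closed form", {
  same <- paired_measurements(c(1.2, 1.4, 1.1), c(1.2, 1.4, 1.1))
  expect_equal(sd_ws(same), 0)
  one <- paired_measurements(3, 1)   # DeltaD = 2
  expect_equal(sd_ws(one), sqrt(2), tolerance = 1e-12)
  # ten pairs with DeltaD mean -0.017 and sample SD 0.18 (tumor, radial
  # protocol) reproduce the published 0.12 at two decimals
  pr <- pairs_from_moments(-0.017, 0.18)
  expect_equal(round(sd_ws(pr), 2), 0.12)
  expect_error(sd_ws(pr[0, ]), "at least one")
})

test_that("within-subject CV follows its closed form", {
  same <- paired_measurements(c(1, 2), c(1, 2))
  expect_equal(cv_ws(same), 0)
  one <- paired_measurements(1.1, 0.9)
  expect_equal(cv_ws(one), sqrt(0.04 / 2), tolerance = 1e-12)
  # tumor radial cohort: CV_ws of about 9%
  pr <- pairs_from_moments(-0.017, 0.18, center = 1.3)
  expect_lt(abs(cv_ws(pr) - 0.09), 0.005)
  bad <- data.frame(test = c(1, 0.1), retest = c(1, -0.2))
  expect_error(cv_ws(bad), "pair mean")
})

test_that("repeatability coefficient is 1.96*sqrt(2) times SD_ws", {
  expect_equal(rc(0), 0)
  expect_equal(round(rc(1), 2), 2.77)
  expect_equal(round(rc(0.19086), 2), 0.53)
  expect_error(rc(-0.1), ">= 0")
  # ratio constant for arbitrary cohorts
  set.seed(3)
  for (i in 1:5) {
    pr <- paired_measurements(runif(8, 1, 2), runif(8, 1, 2))
    expect_equal(rc(sd_ws(pr)) / sd_ws(pr), 1.96 * sqrt(2), tolerance = 1e-12)
  }
})

test_that("published repeatability rows are internally consistent", {
  rows <- published_repeatability_rows()
  for (i in seq_len(nrow(rows))) {
    n <- rows$n[i]
    sum_sq <- (n - 1) * rows$delta_sd[i]^2 + n * rows$delta_mean[i]^2
    sdws <- sqrt(sum_sq / (2 * n))
    # SD_ws matches at two decimals; RC to within one unit of the printed
    # last digit (the printed DeltaD SD is itself rounded to 2 figures)
    expect_lt(abs(sdws - rows$sd_ws[i]), 0.005 + 1e-12)
    expect_lt(abs(rc(sdws) - rows$rc[i]), 0.01 + 1e-12)
  }
})

test_that("Bland-Altman bias and limits follow the repeatability coefficient", {
  same <- paired_measurements(c(1.2, 1.4, 1.1), c(1.2, 1.4, 1.1))
  ba0 <- bland_altman(same)
  expect_equal(c(ba0$bias, ba0$upper, ba0$lower), c(0, 0, 0))
  # tumor radial cohort reconstructed from its moments: bias -0.017
  pr <- pairs_from_moments(-0.017, 0.18)
  ba <- bland_altman(pr)
  expect_equal(ba$bias, -0.017, tolerance = 1e-12)
  expect_equal(ba$upper - ba$bias, rc(sd_ws(pr)), tolerance = 1e-12)
  expect_equal(nrow(ba$points), 10L)
  # a known injected bias is recovered within its standard error
  set.seed(9)
  beta <- 0.08
  truth <- runif(40, 1, 2)
  noise_t <- rnorm(40, sd = 0.05); noise_r <- rnorm(40, sd = 0.05)
  pr2 <- paired_measurements(truth + beta / 2 + noise_t, truth - beta / 2 + noise_r)
  se <- sd(noise_t - noise_r) / sqrt(40)
  expect_lt(abs(bland_altman(pr2)$bias - beta), 3 * se)
  expect_error(bland_altman(same[1, ]), "two pairs")
})

test_that("the kernel density estimate integrates to one and tracks the normal", {
  set.seed(5)
  x <- rnorm(1e4)
  grid <- seq(-5, 5, by = 0.01)
  kd <- pdf_estimate(x, grid)
  trap <- sum((kd$density[-1] + kd$density[-length(grid)]) / 2 * diff(grid))
  expect_lt(abs(trap - 1), 1e-3)
  expect_lt(max(abs(kd$density - dnorm(grid))), 0.05)
  # a narrow uniform sample keeps its mass on its support (+/- bandwidth)
  u <- runif(500, 2, 2.2)
  bw <- stats::bw.nrd0(u)
  g2 <- seq(0, 4, by = 0.005)
  kd2 <- pdf_estimate(u, g2)
  inside <- g2 >= 2 - bw & g2 <= 2.2 + bw
  mass <- function(sel) sum(kd2$density[sel]) * 0.005
  expect_gte(mass(inside) / mass(rep(TRUE, length(g2))), 0.95)
  expect_error(pdf_estimate(rnorm(10), grid), "at least 30")
})

test_that("protocol correlation is plain least squares with R^2", {
  rad <- paired_measurements(c(1.0, 1.2, 1.4, 1.6), c(1, 1, 1, 1),
                             subject = 1:4)
  epi <- paired_measurements(2 * c(1.0, 1.2, 1.4, 1.6) + 0.3, c(1, 1, 1, 1),
                             subject = 1:4)
  r <- suppressWarnings(correlate_protocols(rad, epi))  # exact fit warns in summary.lm
  expect_equal(r$r_squared, 1, tolerance = 1e-12)
  expect_equal(r$slope, 0.5, tolerance = 1e-12)
  # uncorrelated inputs: R^2 near zero
  set.seed(8)
  a <- paired_measurements(abs(rnorm(1000)) + 0.5, rep(1, 1000), subject = 1:1000)
  b <- paired_measurements(abs(rnorm(1000)) + 0.5, rep(1, 1000), subject = 1:1000)
  expect_lt(correlate_protocols(a, b)$r_squared, 0.01)
  # slope invariant under a common scaling of both variables
  rad2 <- rad; epi2 <- epi
  rad2$test <- rad2$test * 3.7; epi2$test <- epi2$test * 3.7
  expect_equal(suppressWarnings(correlate_protocols(rad2, epi2))$slope,
               r$slope, tolerance = 1e-12)
  expect_error(correlate_protocols(rad[1:2, ], epi[1:2, ]), "3 matched")
})

test_that("cv_ws equals sd_ws over the grand mean when all pair means are equal", {
  pr <- pairs_from_moments(0.03, 0.1, center = 1.7)
  expect_equal(cv_ws(pr), sd_ws(pr) / 1.7, tolerance = 1e-12)
})

test_that("paired measurement validation rejects non-positive values", {
  expect_error(paired_measurements(c(1, -1), c(1, 1)), "positive")
  expect_error(paired_measurements(c(1, NA), c(1, 1)), "positive")
  expect_error(paired_measurements(1:3, 1:2), "equal length")
})
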