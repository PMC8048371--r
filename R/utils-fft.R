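# Centered discrete Fourier transform helpers.
#
# Conventions used throughout the package (even matrix sizes only):
#   pixel centers   x_j = (j - 1 - N/2) * dx,   j = 1..N
#   k-space samples k_m = (m - 1 - N/2) * dk,   m = 1..N,  dk = 1/(N*dx)
# so that S[m] = sum_j I[j] exp(-2*pi*i * k_m * x_j) is computed by
# fftshift(fft(ifftshift(I))) with no extra phase factors.

fftshift1 <- function(x) {
  n <- length(x)
  c(x[(n %/% 2 + 1):n], x[1:(n %/% 2)])
}

ifftshift1 <- function(x) {
  # inverse of fftshift1; identical for even n
  n <- length(x)
  k <- n - n %/% 2
  c(x[(k + 1):n], x[1:k])
}

fftshift2 <- function(x) {
  n1 <- nrow(x); n2 <- ncol(x)
  x[c((n1 %/% 2 + 1):n1, 1:(n1 %/% 2)), c((n2 %/% 2 + 1):n2, 1:(n2 %/% 2)), drop = FALSE]
}

ifftshift2 <- function(x) {
  n1 <- nrow(x); n2 <- ncol(x)
  k1 <- n1 - n1 %/% 2; k2 <- n2 - n2 %/% 2
  x[c((k1 + 1):n1, 1:k1), c((k2 + 1):n2, 1:k2), drop = FALSE]
}

# Forward centered DFT (unnormalized): S[m] = sum_j x[j] e^{-2pi i (m-1-N/2)(j-1-N/2)/N}
cdft1 <- function(x) fftshift1(stats::fft(ifftshift1(x)))

# Inverse centered DFT (unnormalized): x[j] = sum_m S[m] e^{+2pi i (...)/N}
cidft1 <- function(s) fftshift1(stats::fft(ifftshift1(s), inverse = TRUE))

cdft2 <- function(x) fftshift2(stats::fft(ifftshift2(x)))

cidft2 <- function(s) fftshift2(stats::fft(ifftshift2(s), inverse = TRUE))

# Centered coordinate vector: n points with spacing d
centered_grid <- function(n, d = 1) (seq_len(n) - 1 - n / 2) * d

complex_rnorm <- function(n, sd = 1) {
  complex(real = stats::rnorm(n, sd = sd), imaginary = stats::rnorm(n, sd = sd))
}
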