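#' @importFrom stats fft mad median quantile sd approx lm coef rnorm runif
#'   rpois rlnorm setNames convolve spline splinefun
#' @importFrom utils head tail
NULL

# Robust noise SD from median absolute deviation (Gaussian-consistent).
mad_sd <- function(x) stats::median(abs(x - stats::median(x))) / 0.6745

#' Analytic signal via the FFT half-spectrum method
#'
#' Returns the complex analytic signal of a real vector: the signal itself
#' plus i times its Hilbert transform. Used for instantaneous phase of the
#' periodicity activity traces.
#'
#' @param x numeric vector.
#' @return complex vector of the same length.
#' @keywords internal
analytic_signal <- function(x) {
  stopifnot(is.numeric(x), all(is.finite(x)))
  n <- length(x)
  if (n < 2L) return(complex(real = x, imaginary = rep(0, n)))
  X <- stats::fft(x)
  h <- numeric(n)
  if (n %% 2L == 0L) {
    h[1L] <- 1; h[n / 2L + 1L] <- 1
    h[2:(n / 2L)] <- 2
  } else {
    h[1L] <- 1
    h[2:((n + 1L) / 2L)] <- 2
  }
  stats::fft(X * h, inverse = TRUE) / n
}

# Wrap angles (degrees) into [0, 360).
wrap_deg <- function(theta) ((theta %% 360) + 360) %% 360

# Circular mean (degrees in [0,360)) and mean resultant length of angles.
circ_summary <- function(theta_deg, weights = NULL) {
  if (length(theta_deg) == 0L) {
    return(list(mean_deg = NA_real_, resultant = NA_real_))
  }
  if (is.null(weights)) weights <- rep(1, length(theta_deg))
  w <- weights / sum(weights)
  z <- sum(w * exp(1i * theta_deg * pi / 180))
  list(mean_deg = wrap_deg(Arg(z) * 180 / pi), resultant = Mod(z))
}

# Zero-phase Butterworth band-pass (forward-backward), order `order` per pass.
zero_phase_bandpass <- function(x, fs, low_hz, high_hz, order = 2L) {
  nyq <- fs / 2
  if (low_hz <= 0 || high_hz <= low_hz || high_hz >= nyq) {
    stop("band edges must satisfy 0 < low < high < Nyquist (", nyq, " Hz)")
  }
  bf <- signal::butter(order, c(low_hz, high_hz) / nyq, type = "pass")
  as.numeric(signal::filtfilt(bf, x))
}

# Gaussian smoothing by direct FFT-free convolution with a truncated kernel.
gaussian_smooth <- function(x, fs, sigma_s) {
  if (sigma_s <= 0) return(x)
  half <- max(1L, as.integer(ceiling(4 * sigma_s * fs)))
  k <- exp(-0.5 * ((-half:half) / (sigma_s * fs))^2)
  k <- k / sum(k)
  n <- length(x)
  # reflect-pad with index clamping so short windows still work
  left_idx <- pmax(1L, pmin(n, (half:1L) + 1L))
  right_idx <- pmax(1L, pmin(n, n - (1L:half)))
  xp <- c(x[left_idx], x, x[right_idx])
  out <- stats::filter(xp, k, sides = 2)
  as.numeric(out[(half + 1L):(half + n)])
}

# Deterministic child seed derived from a parent seed and a stream label.
# Keeps results reproducible when one seed fans out to several generators.
child_seed <- function(seed, label) {
  h <- rlang::hash(list(as.integer(seed), as.character(label)))
  # fold the first 7 hex digits into a positive 32-bit integer
  as.integer(strtoi(substr(h, 1, 7), base = 16L) %% .Machine$integer.max)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
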