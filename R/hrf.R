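#' Double-gamma haemodynamic response function
#'
#' Difference of two peak-normalised gamma densities: a positive lobe
#' peaking at `peak_s` and an undershoot peaking at `undershoot_s`
#' scaled by `1/ratio`. The default (peak 4 s, undershoot 10 s, ratio 6)
#' is an earlier-peaking response than the common human default,
#' appropriate for macaque BOLD; all simulation and fitting routines
#' take the HRF as an explicit parameter.
#'
#' @param peak_s Time-to-peak of the positive lobe (s).
#' @param undershoot_s Time-to-peak of the undershoot (s).
#' @param ratio Peak-to-undershoot amplitude ratio.
#' @param duration_s Kernel support (s).
#' @return An object of class `"hrf"`.
#' @export
hrf_double_gamma <- function(peak_s = 4, undershoot_s = 10, ratio = 6,
                             duration_s = 30) {
  stopifnot(peak_s > 0, undershoot_s > peak_s, ratio > 0, duration_s > 0)
  structure(list(peak_s = peak_s, undershoot_s = undershoot_s,
                 ratio = ratio, duration_s = duration_s),
            class = "hrf")
}

#' Sample an HRF on a regular time grid
#'
#' @param hrf An [hrf_double_gamma()] object.
#' @param dt Sampling interval (s), e.g. the TR.
#' @return Numeric kernel sampled at `seq(0, duration_s, by = dt)`,
#'   peak-normalised to 1.
#' @export
hrf_kernel <- function(hrf, dt) {
  stopifnot(inherits(hrf, "hrf"), dt > 0)
  t <- seq(0, hrf$duration_s, by = dt)
  # gamma with rate 1: mode = shape - 1, so shape = peak + 1
  lobe <- function(tt, peak) {
    g <- stats::dgamma(tt, shape = peak + 1, rate = 1)
    g / stats::dgamma(peak, shape = peak + 1, rate = 1)
  }
  k <- lobe(t, hrf$peak_s) - lobe(t, hrf$undershoot_s) / hrf$ratio
  k / max(k)
}

#' Causal discrete convolution, truncated to the input length
#'
#' @param x Input series.
#' @param kernel Impulse response (same sampling interval as `x`).
#' @return Numeric vector of `length(x)`.
#' @export
convolve_causal <- function(x, kernel) {
  n <- length(x)
  full <- stats::convolve(x, rev(kernel), type = "open")
  full[seq_len(n)]
}

## Lower-triangular Toeplitz matrix implementing convolve_causal.
.conv_matrix <- function(kernel, n) {
  m <- matrix(0, n, n)
  for (j in seq_len(n)) {
    idx <- j:min(n, j + length(kernel) - 1L)
    m[cbind(idx, j)] <- kernel[seq_along(idx)]
  }
  m
}
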