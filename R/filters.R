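#' Design a windowed-sinc FIR low-pass kernel
#'
#' Hamming-windowed sinc kernel of even order `order` (length `order + 1`),
#' normalized to unit DC gain. The kernel is symmetric (linear phase), so a
#' single centered pass is zero-phase.
#'
#' @param cutoff_hz Cutoff frequency in Hz.
#' @param order Filter order (even integer); the kernel has `order + 1` taps.
#' @param rate_hz Sampling rate in Hz.
#' @return Numeric vector of `order + 1` filter taps summing to 1.
#' @export
fir_lowpass_kernel <- function(cutoff_hz, order = 60L, rate_hz = 40) {
  stopifnot_scalar(cutoff_hz, "cutoff_hz", positive = TRUE)
  stopifnot_scalar(rate_hz, "rate_hz", positive = TRUE)
  if (order < 2 || order %% 2 != 0) {
    stop("`order` must be a positive even integer", call. = FALSE)
  }
  if (cutoff_hz >= rate_hz / 2) {
    stop("`cutoff_hz` must be below the Nyquist frequency", call. = FALSE)
  }
  m <- order / 2
  n <- seq(-m, m)
  fc <- cutoff_hz / rate_hz               # normalized cutoff (cycles/sample)
  h <- 2 * fc * sinc(2 * fc * n)
  w <- 0.54 + 0.46 * cos(pi * n / m)      # Hamming window
  h <- h * w
  h / sum(h)
}

sinc <- function(x) ifelse(x == 0, 1, sin(pi * x) / (pi * x))

#' Zero-phase FIR low-pass smoothing
#'
#' Applies a symmetric windowed-sinc low-pass kernel in a single centered pass
#' (zero phase by symmetry) with reflection padding at the edges. DC gain is
#' exactly 1: a constant trace is returned unchanged.
#'
#' @param x Numeric trace sampled uniformly at `rate_hz`.
#' @param cutoff_hz Cutoff frequency in Hz (default 1).
#' @param order Filter order (default 60).
#' @param rate_hz Sampling rate in Hz (default 40).
#' @return Smoothed trace, same length as `x`.
#' @export
smooth_lowpass <- function(x, cutoff_hz = 1, order = 60L, rate_hz = 40) {
  h <- fir_lowpass_kernel(cutoff_hz, order, rate_hz)
  m <- (length(h) - 1L) / 2L
  n <- length(x)
  if (n <= m) {
    stop("trace too short for edge padding (need > order/2 samples)",
         call. = FALSE)
  }
  # reflect interior samples about each end
  padded <- c(x[(m + 1L):2L], x, x[(n - 1L):(n - m)])
  y <- stats::filter(padded, h, method = "convolution", sides = 2L)
  as.numeric(y[(m + 1L):(m + n)])
}
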