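#' Analytic amplitude and frequency of an IMF
#'
#' Builds the discrete analytic signal of an oscillatory component by the FFT
#' construction of the Hilbert transform, and returns the per-sample
#' instantaneous amplitude (modulus) and instantaneous frequency (scaled
#' derivative of the unwrapped phase, in Hz). The phase derivative uses
#' central differences in the interior and one-sided differences at the ends.
#'
#' Near-zero-amplitude samples can carry meaningless (including negative)
#' frequency values; raw tracks keep them signed, downstream feature code
#' clips at zero where it consumes them.
#'
#' @param imf Numeric vector (an IMF), length >= 8, finite values.
#' @param rate Sampling rate in Hz.
#' @return List of class `imemd_analytic_track` with `amplitude` (>= 0) and
#'   `frequency` (Hz, signed), both the length of `imf`.
#' @export
analytic_track <- function(imf, rate) {
  v <- as.numeric(imf)
  n <- length(v)
  if (n < 8L) stop("IMF too short for an analytic track (length >= 8)")
  if (anyNA(v) || any(!is.finite(v))) stop("IMF must be finite")
  X <- stats::fft(v)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[1L] <- 1; h[n / 2 + 1L] <- 1; h[2:(n / 2)] <- 2
  } else {
    h[1L] <- 1; h[2:((n + 1) / 2)] <- 2
  }
  z <- stats::fft(X * h, inverse = TRUE) / n
  amp <- Mod(z)
  ph <- unwrap_phase(Arg(z))
  freq <- numeric(n)
  freq[2:(n - 1L)] <- (ph[3:n] - ph[1:(n - 2L)]) / 2
  freq[1L] <- ph[2L] - ph[1L]
  freq[n] <- ph[n] - ph[n - 1L]
  freq <- freq * rate / (2 * pi)
  structure(list(amplitude = amp, frequency = freq),
            class = "imemd_analytic_track")
}

unwrap_phase <- function(p) {
  d <- diff(p)
  d <- d - 2 * pi * round(d / (2 * pi))
  c(p[1L], p[1L] + cumsum(d))
}
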