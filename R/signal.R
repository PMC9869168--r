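#' Construct a uniformly sampled signal
#'
#' The universal input/output currency of the package: a real-valued,
#' uniformly sampled waveform together with its sampling rate.
#'
#' @param samples Numeric vector of finite sample values.
#' @param rate Sampling rate in Hz (samples per second), > 0.
#' @return An object of class `imemd_signal` with elements `samples` and
#'   `rate`.
#' @examples
#' s <- imemd_signal(sin(2 * pi * 5 * seq(0, 1, by = 1 / 100)), rate = 100)
#' s
#' @export
imemd_signal <- function(samples, rate) {
  samples <- as.numeric(samples)
  if (length(rate) != 1L || !is.finite(rate) || rate <= 0)
    stop("`rate` must be a single positive number (Hz)")
  if (anyNA(samples) || any(!is.finite(samples)))
    stop("`samples` must be finite real values")
  structure(list(samples = samples, rate = as.numeric(rate)),
            class = "imemd_signal")
}

#' @export
print.imemd_signal <- function(x, ...) {
  cat(sprintf("<imemd_signal> %d samples @ %g Hz (%.3f s)\n",
              length(x$samples), x$rate, length(x$samples) / x$rate))
  invisible(x)
}

#' @export
length.imemd_signal <- function(x) length(x$samples)

# Coerce numeric vectors on the fly; rate required then.
as_imemd_signal <- function(x, rate = NULL) {
  if (inherits(x, "imemd_signal")) return(x)
  if (is.null(rate)) stop("numeric input needs an explicit `rate`")
  imemd_signal(x, rate)
}

#' Time axis of a signal
#'
#' @param x An `imemd_signal`.
#' @return Numeric vector of sample times in seconds, starting at 0.
#' @export
signal_time <- function(x) {
  (seq_along(x$samples) - 1L) / x$rate
}
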