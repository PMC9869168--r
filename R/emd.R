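#' Sifting configuration
#'
#' Controls the inner sifting loop used by [emd()], [emd1()] and the masked
#' decompositions. The sift count is capped (default 10 iterations) with an
#' early exit once the candidate satisfies the intrinsic-mode-function (IMF)
#' criterion: extrema and zero-crossing counts differ by at most one and the
#' mean envelope is close to zero.
#'
#' @param max_sift_iters Maximum number of envelope subtractions per IMF
#'   (default 10).
#' @param boundary_extension How many extrema are mirrored past each signal
#'   end before spline fitting (default 2); suppresses end swings.
#' @param envelope_tol Relative RMS level of the mean envelope below which a
#'   candidate counts as having a near-zero local mean (default 0.05).
#' @return An object of class `sift_config`.
#' @export
sift_config <- function(max_sift_iters = 10L, boundary_extension = 2L,
                        envelope_tol = 0.05) {
  max_sift_iters <- as.integer(max_sift_iters)
  if (max_sift_iters < 1L) stop("`max_sift_iters` must be >= 1")
  structure(list(max_sift_iters = max_sift_iters,
                 boundary_extension = as.integer(boundary_extension),
                 envelope_tol = envelope_tol),
            class = "sift_config")
}

#' Locate local extrema
#'
#' Interior local maxima and minima of a sampled signal. Runs of equal values
#' (plateaus) contribute a single extremum at the plateau midpoint, so spline
#' knots are never duplicated. Monotonic (or constant) input yields empty
#' result vectors.
#'
#' @param x An `imemd_signal` or numeric vector.
#' @return List with integer `max_idx`, numeric `max_val`, integer `min_idx`,
#'   numeric `min_val` (1-based indices).
#' @export
find_extrema <- function(x) {
  v <- if (inherits(x, "imemd_signal")) x$samples else as.numeric(x)
  n <- length(v)
  empty <- list(max_idx = integer(0), max_val = numeric(0),
                min_idx = integer(0), min_val = numeric(0))
  if (n < 3L) return(empty)
  d <- diff(v)
  s <- sign(d)
  nz <- which(s != 0)
  if (length(nz) < 2L) return(empty)
  sn <- s[nz]
  # transitions between successive nonzero slopes
  tr <- which(sn[-length(sn)] != sn[-1L])
  if (!length(tr)) return(empty)
  i1 <- nz[tr]        # last index of the rising/falling run (diff index)
  i2 <- nz[tr + 1L]   # first diff index of the next run
  # plateau spans samples (i1+1)..i2; midpoint is the knot
  pos <- (i1 + 1L + i2) %/% 2L
  is_max <- sn[tr] > 0
  list(max_idx = pos[is_max], max_val = v[pos[is_max]],
       min_idx = pos[!is_max], min_val = v[pos[!is_max]])
}

# Mirror `depth` extrema of each kind beyond both ends so the spline is
# anchored outside [1, n]; standard EMD boundary treatment.
extend_extrema <- function(idx, val, n, depth) {
  k <- length(idx)
  take_l <- seq_len(min(depth, k))
  take_r <- seq.int(k, by = -1L, length.out = min(depth, k))
  left_idx <- 2L - idx[take_l]          # reflect about sample 1
  right_idx <- 2L * n - idx[take_r]     # reflect about sample n
  ord <- order(c(left_idx, idx, right_idx))
  all_idx <- c(left_idx, idx, right_idx)[ord]
  all_val <- c(val[take_l], val, val[take_r])[ord]
  keep <- !duplicated(all_idx)
  list(idx = all_idx[keep], val = all_val[keep])
}

#' Mean spline envelope
#'
#' Cubic-spline upper and lower envelopes through the local maxima and minima
#' (after mirror extension at the boundaries), averaged per sample.
#'
#' @param x An `imemd_signal` or numeric vector.
#' @param extrema Optional result of [find_extrema()]; computed if missing.
#' @param boundary_extension Number of extrema mirrored past each end.
#' @return Numeric vector `e(t) = (upper + lower) / 2`, same length as `x`.
#'   Errors with class `imemd_monotonic` when fewer than 2 maxima or 2 minima
#'   exist (the residual is a trend and sifting must stop).
#' @export
envelope_mean <- function(x, extrema = NULL, boundary_extension = 2L) {
  v <- if (inherits(x, "imemd_signal")) x$samples else as.numeric(x)
  n <- length(v)
  if (is.null(extrema)) extrema <- find_extrema(v)
  if (length(extrema$max_idx) < 2L || length(extrema$min_idx) < 2L)
    stop(structure(class = c("imemd_monotonic", "error", "condition"),
                   list(message = "monotonic/trend residual: too few extrema for envelopes",
                        call = sys.call(-1))))
  up <- extend_extrema(extrema$max_idx, extrema$max_val, n, boundary_extension)
  lo <- extend_extrema(extrema$min_idx, extrema$min_val, n, boundary_extension)
  fu <- stats::splinefun(up$idx, up$val, method = "natural")
  fl <- stats::splinefun(lo$idx, lo$val, method = "natural")
  (fu(seq_len(n)) + fl(seq_len(n))) / 2
}

count_zero_crossings <- function(v) {
  s <- sign(v)
  s <- s[s != 0]
  if (length(s) < 2L) return(0L)
  sum(s[-1L] != s[-length(s)])
}

is_imf_candidate <- function(v, e, tol) {
  ex <- find_extrema(v)
  n_ext <- length(ex$max_idx) + length(ex$min_idx)
  n_zc <- count_zero_crossings(v)
  rms_v <- sqrt(mean(v^2))
  if (rms_v == 0) return(TRUE)
  abs(n_ext - n_zc) <= 1L && sqrt(mean(e^2)) / rms_v < tol
}

#' Extract one IMF candidate by sifting
#'
#' Repeatedly subtracts the mean spline envelope from the residual, stopping
#' after `max_sift_iters` subtractions or as soon as the candidate satisfies
#' the IMF criterion (extrema/zero-crossing counts within one of each other
#' and near-zero mean envelope).
#'
#' @param x An `imemd_signal` or numeric vector (the current residual).
#' @param cfg A [sift_config()].
#' @param rate Sampling rate when `x` is a bare vector.
#' @return Numeric vector: the IMF candidate. Errors with class
#'   `imemd_monotonic` when the input has too few extrema to sift at all.
#' @export
sift <- function(x, cfg = sift_config(), rate = NULL) {
  v <- if (inherits(x, "imemd_signal")) x$samples else as.numeric(x)
  r <- v
  for (it in seq_len(cfg$max_sift_iters)) {
    ex <- find_extrema(r)
    if (length(ex$max_idx) < 2L || length(ex$min_idx) < 2L) {
      if (it == 1L)
        stop(structure(class = c("imemd_monotonic", "error", "condition"),
                       list(message = "no IMF extractable: input is monotonic or degenerate",
                            call = sys.call(-1))))
      break
    }
    e <- envelope_mean(r, ex, cfg$boundary_extension)
    r <- r - e
    # early exit: candidate already an IMF
    e2 <- tryCatch(envelope_mean(r, boundary_extension = cfg$boundary_extension),
                   imemd_monotonic = function(cnd) NULL)
    if (is.null(e2)) break
    if (is_imf_candidate(r, e2, cfg$envelope_tol)) break
  }
  r
}

#' First IMF of a signal
#'
#' The `EMD_1` operator: the first intrinsic mode function obtained by
#' sifting the raw signal. Identical to [sift()] applied once to the input.
#'
#' @inheritParams sift
#' @return Numeric vector: the first IMF.
#' @export
emd1 <- function(x, cfg = sift_config(), rate = NULL) {
  sift(x, cfg, rate)
}

#' Empirical mode decomposition
#'
#' Decomposes a signal into intrinsic mode functions plus a residue by
#' iterating [sift()] on successive residuals until the residual is monotonic
#' (fewer than two maxima or minima). The IMFs are ordered from first
#' extracted (highest frequency) to last; summing all IMFs and the residue
#' reconstructs the input to floating-point precision.
#'
#' @param x An `imemd_signal`.
#' @param cfg A [sift_config()].
#' @param max_imfs Safety cap on the number of extracted IMFs.
#' @return An `imemd_decomposition`: list with `imfs` (list of numeric
#'   vectors), `residue`, `rate`, `source_length`.
#' @export
emd <- function(x, cfg = sift_config(), max_imfs = 50L) {
  x <- as_imemd_signal(x)
  if (length(x$samples) < 4L) stop("signal too short to decompose (length >= 4 required)")
  r <- x$samples
  imfs <- list()
  for (k in seq_len(max_imfs)) {
    c_k <- tryCatch(sift(r, cfg), imemd_monotonic = function(cnd) NULL)
    if (is.null(c_k)) break
    imfs[[k]] <- c_k
    r <- r - c_k
  }
  new_decomposition(imfs, r, x$rate)
}

new_decomposition <- function(imfs, residue, rate) {
  structure(list(imfs = imfs, residue = residue, rate = rate,
                 source_length = length(residue)),
            class = "imemd_decomposition")
}

#' @export
print.imemd_decomposition <- function(x, ...) {
  cat(sprintf("<imemd_decomposition> %d IMF(s) + residue, %d samples @ %g Hz\n",
              length(x$imfs), x$source_length, x$rate))
  invisible(x)
}

#' Number of IMFs in a decomposition
#'
#' The residue is never counted as an IMF.
#'
#' @param d An `imemd_decomposition`.
#' @return Integer IMF count.
#' @export
n_imfs <- function(d) length(d$imfs)
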