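#' Frame grid for short-time analysis
#'
#' Fixed 25 ms frames with a 10 ms hop by default, the framing used for all
#' frame-wise features. Frame and hop lengths are rounded to whole samples.
#'
#' @param n_samples Signal length in samples.
#' @param rate Sampling rate in Hz.
#' @param frame_s Frame length in seconds (default 0.025).
#' @param hop_s Hop length in seconds (default 0.010).
#' @return List of class `imemd_frame_grid` with `frame_len`, `hop`,
#'   `n_frames` and integer `starts` (1-based first sample of each frame).
#' @export
frame_grid <- function(n_samples, rate, frame_s = 0.025, hop_s = 0.010) {
  frame_len <- round(frame_s * rate)
  hop <- round(hop_s * rate)
  if (frame_len < 2L || hop < 1L) stop("frame grid too fine for this rate")
  if (n_samples < frame_len) stop("signal shorter than one frame")
  n_frames <- (n_samples - frame_len) %/% hop + 1L
  structure(list(frame_len = as.integer(frame_len), hop = as.integer(hop),
                 n_frames = as.integer(n_frames),
                 starts = as.integer((seq_len(n_frames) - 1L) * hop + 1L),
                 rate = rate),
            class = "imemd_frame_grid")
}

#' Per-frame spectral summaries of a decomposition
#'
#' For each IMF, the instantaneous amplitude/frequency track over the full
#' signal is summarized per frame: `E_me` is the mean instantaneous
#' amplitude and `F_ce` the amplitude-weighted centroid of the instantaneous
#' frequency (negative frequency samples clipped to 0; an all-zero-amplitude
#' frame defines `F_ce = 0`).
#'
#' @param d An `imemd_decomposition` with at least one IMF.
#' @param grid An [frame_grid()].
#' @return List of class `imemd_frame_summary` with matrices `e_me` and
#'   `f_ce`, both `n_imfs x n_frames`.
#' @export
frame_summaries <- function(d, grid) {
  k <- n_imfs(d)
  if (k < 1L) stop("decomposition has no IMFs")
  e_me <- matrix(0, k, grid$n_frames)
  f_ce <- matrix(0, k, grid$n_frames)
  idx <- outer(0L:(grid$frame_len - 1L), grid$starts, `+`)  # frame_len x frames
  for (j in seq_len(k)) {
    tr <- analytic_track(d$imfs[[j]], d$rate)
    a <- tr$amplitude
    f <- pmax(tr$frequency, 0)
    am <- matrix(a[idx], nrow = grid$frame_len)
    fm <- matrix(f[idx], nrow = grid$frame_len)
    e_me[j, ] <- colMeans(am)
    wsum <- colSums(am)
    num <- colSums(am * fm)
    f_ce[j, ] <- ifelse(wsum > 0, num / wsum, 0)
  }
  structure(list(e_me = e_me, f_ce = f_ce, n_frames = grid$n_frames),
            class = "imemd_frame_summary")
}

#' Hilbert spectrum distribution features
#'
#' Per-frame energy-weighted moments of the IMF centroid frequencies: the
#' spectral centroid SC, the squared spread SP, and skewness SK / kurtosis
#' SU normalized by `sqrt(SP)^3` and `sqrt(SP)^4`. Degenerate frames
#' (single IMF, zero spread, or zero total energy) yield guarded zeros, so
#' no NaN ever escapes.
#'
#' @param s An `imemd_frame_summary`.
#' @return Matrix `4 x n_frames` with rows `SC`, `SP`, `SK`, `SU`.
#' @export
hilbert_spectrum_features <- function(s) {
  out <- matrix(0, 4L, s$n_frames,
                dimnames = list(c("SC", "SP", "SK", "SU"), NULL))
  for (ph in seq_len(s$n_frames)) {
    w <- s$e_me[, ph]
    f <- s$f_ce[, ph]
    sw <- sum(w)
    if (sw <= 0) next
    sc <- sum(w * f) / sw
    sp <- sum(w * (f - sc)^2) / sw
    out["SC", ph] <- sc
    out["SP", ph] <- sp
    if (sp > 0) {
      sd3 <- sp^1.5
      out["SK", ph] <- sum(w * (f - sc)^3) / (sd3 * sw)
      out["SU", ph] <- sum(w * (f - sc)^4) / (sp^2 * sw)
    }
  }
  out
}

#' Hilbert contour features
#'
#' Per-frame envelope peak SE (the maximum over IMFs of the mean
#' instantaneous amplitude) and its regression-style first and second
#' temporal derivatives, computed with the same three-branch operator as the
#' cepstral deltas (see [delta_features()]).
#'
#' @param s An `imemd_frame_summary`.
#' @param Q Regression half-width of the derivative (default 2).
#' @return Matrix `3 x n_frames` with rows `SE`, `dSE`, `d2SE`.
#' @export
hilbert_contour_features <- function(s, Q = 2L) {
  if (s$n_frames < 2L) stop("too short: need at least 2 frames")
  se <- apply(s$e_me, 2L, max)
  dse <- delta_features(matrix(se, 1L), Q)
  d2se <- delta_features(dse, Q)
  out <- rbind(se, dse, d2se)
  dimnames(out) <- list(c("SE", "dSE", "d2SE"), NULL)
  out
}

#' Regression-style delta of frame-wise coefficients
#'
#' The piecewise temporal-derivative operator applied to every coefficient
#' row: simple forward differences on the first `Q` frames, the normalized
#' regression sum `sum_q q (c(phi+q) - c(phi-q)) / (2 sum_q q^2)` in the
#' interior, and simple backward differences on the last `Q` frames. The
#' operator is linear in its input; a second derivative is the operator
#' applied to the first.
#'
#' @param coeffs Matrix `n_coef x n_frames` (a vector is treated as one row).
#' @param Q Regression half-width (default 2); requires
#'   `n_frames >= 2 Q + 1`.
#' @return Matrix of the same shape.
#' @export
delta_features <- function(coeffs, Q = 2L) {
  if (is.null(dim(coeffs))) coeffs <- matrix(coeffs, 1L)
  n <- ncol(coeffs)
  Q <- as.integer(Q)
  if (n < 2L * Q + 1L) stop("too short: need at least 2Q + 1 frames")
  out <- matrix(0, nrow(coeffs), n)
  head_idx <- seq_len(Q)
  out[, head_idx] <- coeffs[, head_idx + 1L, drop = FALSE] -
    coeffs[, head_idx, drop = FALSE]
  tail_idx <- (n - Q + 1L):n
  out[, tail_idx] <- coeffs[, tail_idx, drop = FALSE] -
    coeffs[, tail_idx - 1L, drop = FALSE]
  mid <- (Q + 1L):(n - Q)
  denom <- 2 * sum((1:Q)^2)
  acc <- matrix(0, nrow(coeffs), length(mid))
  for (q in seq_len(Q))
    acc <- acc + q * (coeffs[, mid + q, drop = FALSE] -
                        coeffs[, mid - q, drop = FALSE])
  out[, mid] <- acc / denom
  out
}

#' Zero-crossing-rate signal trend
#'
#' Assembles the slow trend of the signal from its decomposition: the
#' residue plus every IMF beyond the first whose zero-crossing count,
#' relative to the first IMF's, falls below the threshold. If the first IMF
#' has no zero crossings the trend is the residue alone.
#'
#' @param d An `imemd_decomposition` with at least one IMF.
#' @param zc_ratio_threshold Membership threshold on
#'   `ZeroCross(c_k) / ZeroCross(c_1)` (default 0.01).
#' @return Numeric trend vector of the source length.
#' @export
signal_trend <- function(d, zc_ratio_threshold = 0.01) {
  if (n_imfs(d) < 1L) stop("decomposition has no IMFs")
  trend <- d$residue
  zc1 <- count_zero_crossings(d$imfs[[1L]])
  if (zc1 > 0L && n_imfs(d) >= 2L) {
    for (k in 2L:n_imfs(d)) {
      if (count_zero_crossings(d$imfs[[k]]) / zc1 < zc_ratio_threshold)
        trend <- trend + d$imfs[[k]]
    }
  }
  trend
}

# --- MFCC machinery (conventional 12-order pipeline) ------------------------

hz_to_mel <- function(f) 2595 * log10(1 + f / 700)
mel_to_hz <- function(m) 700 * (10^(m / 2595) - 1)

mel_filterbank <- function(n_filters, nfft, rate) {
  f_pts <- mel_to_hz(seq(hz_to_mel(0), hz_to_mel(rate / 2),
                         length.out = n_filters + 2L))
  bins <- floor((nfft + 1) * f_pts / rate)
  fb <- matrix(0, n_filters, nfft %/% 2 + 1L)
  for (m in seq_len(n_filters)) {
    lo <- bins[m]; ce <- bins[m + 1L]; hi <- bins[m + 2L]
    for (k in lo:hi) {
      # rising branch up to the center bin, falling after; degenerate
      # triangles (collapsed bins at small FFT sizes) contribute nothing
      fb[m, k + 1L] <- if (k <= ce) {
        if (ce > lo) (k - lo) / (ce - lo) else 0
      } else {
        if (hi > ce) (hi - k) / (hi - ce) else 0
      }
    }
  }
  fb
}

mfcc_frames <- function(v, rate, grid, n_filters = 26L, n_coef = 12L,
                        log_floor = 1e-10) {
  nfft <- 2^ceiling(log2(grid$frame_len))
  win <- 0.54 - 0.46 * cos(2 * pi * (0:(grid$frame_len - 1L)) /
                             (grid$frame_len - 1L))
  fb <- mel_filterbank(n_filters, nfft, rate)
  idx <- outer(0L:(grid$frame_len - 1L), grid$starts, `+`)
  frames <- matrix(v[idx], nrow = grid$frame_len) * win
  frames <- rbind(frames, matrix(0, nfft - grid$frame_len, grid$n_frames))
  spec <- stats::mvfft(frames)
  pow <- (Mod(spec[seq_len(nfft %/% 2 + 1L), , drop = FALSE])^2) / nfft
  fe <- log(pmax(fb %*% pow, log_floor))
  # DCT-II over the filter axis, coefficients 1..n_coef (0th excluded)
  m <- seq_len(n_filters) - 0.5
  dct <- sapply(seq_len(n_coef), function(k) cos(pi * k * m / n_filters))
  t(dct) %*% fe * sqrt(2 / n_filters)
}

#' Trend-removed MFCCs (SMFCC)
#'
#' Mel-frequency cepstral coefficients of the signal after subtracting the
#' zero-crossing-rate trend assembled from the decomposition: the
#' reconstructed signal `x - x_tr` goes through a conventional MFCC pipeline
#' (Hamming window, 26-filter mel bank spanning 0 to Nyquist, floored log,
#' DCT-II, coefficients 1-12).
#'
#' @param x An `imemd_signal`.
#' @param d Its `imemd_decomposition`.
#' @param grid An [frame_grid()].
#' @param zc_ratio_threshold Trend membership threshold (see
#'   [signal_trend()]).
#' @return Matrix `12 x n_frames`.
#' @export
smfcc <- function(x, d, grid, zc_ratio_threshold = 0.01) {
  x <- as_imemd_signal(x)
  recon <- x$samples - signal_trend(d, zc_ratio_threshold)
  mfcc_frames(recon, x$rate, grid)
}

#' The 43-dimensional frame-wise feature matrix
#'
#' Runs the adaptive masked decomposition and assembles the full feature
#' stack in fixed row order: Hilbert spectrum distribution features (SC, SP,
#' SK, SU), Hilbert contour features (SE, dSE, d2SE), then 12 trend-removed
#' cepstral coefficients and their first and second regression derivatives.
#'
#' @param x An `imemd_signal` (typically a preprocessed 3 s segment).
#' @param cfg An [imemd_config()].
#' @param grid An [frame_grid()]; defaults to the 25 ms / 10 ms grid of the
#'   input.
#' @param Q Regression half-width for all delta features (default 2).
#' @param d Optional precomputed `imemd_decomposition` of `x` (skips the
#'   decomposition).
#' @return Matrix `43 x n_frames` with fixed row names; guaranteed free of
#'   NaN/Inf.
#' @export
extract_features <- function(x, cfg = imemd_config(), grid = NULL, Q = 2L,
                             d = NULL) {
  x <- as_imemd_signal(x)
  if (is.null(grid)) grid <- frame_grid(length(x$samples), x$rate)
  if (is.null(d)) d <- imemd(x, cfg)
  if (n_imfs(d) < 1L)
    stop("decomposition produced no IMFs; cannot extract features")
  s <- frame_summaries(d, grid)
  hs <- hilbert_spectrum_features(s)
  hc <- hilbert_contour_features(s, Q)
  sm <- smfcc(x, d, grid)
  dsm <- delta_features(sm, Q)
  d2sm <- delta_features(dsm, Q)
  rownames(sm) <- paste0("SMFCC", 1:12)
  rownames(dsm) <- paste0("dSMFCC", 1:12)
  rownames(d2sm) <- paste0("d2SMFCC", 1:12)
  out <- rbind(hs, hc, sm, dsm, d2sm)
  stopifnot(nrow(out) == 43L)
  if (any(!is.finite(out))) stop("internal error: non-finite feature values")
  out
}
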