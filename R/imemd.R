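#' IMEMD configuration
#'
#' Parameters of the improved masking-signal decomposition. The defaults are
#' the published operating point: `n_p = 64` uniformly distributed mask
#' phases, mask amplitude scale `xi0 = 1.5`, and a 30 dB stop threshold on
#' the ratio of input energy to residual energy.
#'
#' @param n_p Number of uniformly phase-shifted masking sinusoids (>= 2).
#' @param xi0 Mask amplitude scale multiplying the mean instantaneous
#'   amplitude of the probe IMF (>= 0). `xi0 = 0` reduces every extraction
#'   step to plain EMD.
#' @param eps1_db Stop threshold in dB: extraction continues while
#'   `10 * log10(E_x / E_r) < eps1_db`.
#' @param select_cleanest Per-step model selection: when `TRUE` (default)
#'   each extraction step computes both the plain `EMD_1` candidate (the
#'   probe) and the phase-averaged masked candidate, and keeps whichever has
#'   the smaller amplitude-weighted instantaneous-frequency dispersion.
#'   Masking exists to counter mode mixing; when the residual already holds
#'   a single clean mode a large mask only re-injects leakage, and the
#'   dispersion criterion detects this without a tuned threshold. `FALSE`
#'   always keeps the masked candidate.
#' @param sift A [sift_config()].
#' @return An object of class `imemd_config`.
#' @export
imemd_config <- function(n_p = 64L, xi0 = 1.5, eps1_db = 30,
                         select_cleanest = TRUE, sift = sift_config()) {
  n_p <- as.integer(n_p)
  if (n_p < 2L) stop("`n_p` must be >= 2")
  if (xi0 < 0) stop("`xi0` must be >= 0")
  if (eps1_db <= 0) stop("`eps1_db` must be > 0")
  structure(list(n_p = n_p, xi0 = xi0, eps1_db = eps1_db,
                 select_cleanest = isTRUE(select_cleanest), sift = sift),
            class = "imemd_config")
}

# Energy-weighted coefficient of variation of the instantaneous frequency
# (weights A^2, the Hilbert marginal-spectrum energy density): a dispersion
# score for how far a candidate is from a single clean mode (mode mixing =
# widely distributed scales = large dispersion).
if_dispersion <- function(v, rate) {
  if (sum(v^2) == 0) return(Inf)
  tr <- tryCatch(analytic_track(v, rate), error = function(e) NULL)
  if (is.null(tr)) return(Inf)
  a <- tr$amplitude^2
  f <- pmax(tr$frequency, 0)
  sa <- sum(a)
  if (sa == 0) return(Inf)
  fbar <- sum(a * f) / sa
  if (fbar <= 0) return(Inf)
  sqrt(sum(a * (f - fbar)^2) / sa) / fbar
}

#' Adaptive mask parameters for one extraction step
#'
#' Derives the masking-signal amplitude and frequency from the residual
#' itself: a probe IMF is extracted with `EMD_1`, its instantaneous
#' amplitude/frequency tracks give the mask amplitude
#' `xi_k = xi0 * mean(A_k)` and the amplitude-weighted mean frequency
#' `f_k = sum(A_k F_k) / sum(A_k)` (negative instantaneous frequencies are
#' edge artifacts and are clipped to 0 in the weighted mean). The mask
#' frequency is `2 f_k` for the first component and `f_{k-1} + f_k`
#' afterwards, clamped below Nyquist.
#'
#' @param residual An `imemd_signal` or numeric vector (current residual).
#' @param prev_freq Weighted probe frequency of the previous step (Hz), or
#'   `NULL` for the first component.
#' @param cfg An [imemd_config()].
#' @param rate Sampling rate when `residual` is a bare vector.
#' @return List of class `imemd_mask_spec`: `amplitude` (xi_k), `frequency`
#'   (mask frequency, Hz), `n_p`, `probe_freq` (f_k, to pass as `prev_freq`
#'   next step). Errors with class `imemd_monotonic` when no probe IMF can
#'   be extracted (terminal residual).
#' @export
estimate_mask <- function(residual, prev_freq = NULL, cfg = imemd_config(),
                          rate = NULL) {
  if (inherits(residual, "imemd_signal")) {
    rate <- residual$rate
    residual <- residual$samples
  }
  if (is.null(rate)) stop("`rate` required for numeric input")
  probe <- emd1(residual, cfg$sift)  # may signal imemd_monotonic
  tr <- analytic_track(probe, rate)
  a <- tr$amplitude
  f <- pmax(tr$frequency, 0)
  sa <- sum(a)
  f_k <- if (sa > 0) sum(a * f) / sa else 0
  xi_k <- cfg$xi0 * mean(a)
  if (!is.null(prev_freq) && f_k >= prev_freq)
    warning(sprintf(
      "probe frequency did not decrease (f_k = %.4g >= f_{k-1} = %.4g); proceeding",
      f_k, prev_freq))
  fbar <- if (is.null(prev_freq)) 2 * f_k else prev_freq + f_k
  nyq_cap <- 0.49 * rate
  if (fbar > nyq_cap) {
    warning(sprintf("mask frequency %.4g Hz clamped to %.4g Hz (below Nyquist)",
                    fbar, nyq_cap))
    fbar <- nyq_cap
  }
  structure(list(amplitude = xi_k, frequency = fbar, n_p = cfg$n_p,
                 probe_freq = f_k, probe = probe),
            class = "imemd_mask_spec")
}

#' One IMF by masking-signal EMD with an explicit mask
#'
#' The classic two-branch masking construction: a sinusoidal mask
#' `beta * sin(2 pi f_w t + theta)` is added to and subtracted from the
#' signal, `EMD_1` is applied to each branch, and the two first IMFs are
#' averaged so the mask cancels.
#'
#' @param x An `imemd_signal`.
#' @param beta Mask amplitude (signal units).
#' @param f_w Mask frequency (Hz).
#' @param theta Mask phase (radians).
#' @param cfg A [sift_config()].
#' @return Numeric vector: the extracted IMF.
#' @export
msemd_imf <- function(x, beta, f_w, theta = 0, cfg = sift_config()) {
  x <- as_imemd_signal(x)
  tt <- signal_time(x)
  mask <- beta * sin(2 * pi * f_w * tt + theta)
  cp <- emd1(x$samples + mask, cfg)
  cm <- emd1(x$samples - mask, cfg)
  (cp + cm) / 2
}

#' Improved masking-signal EMD
#'
#' Full adaptive decomposition: while the residual still holds a substantial
#' share of the input energy (the `eps1_db` rule) and is not monotonic, a
#' mask is derived from the residual with [estimate_mask()], `n_p` copies of
#' the residual plus phase-shifted masks are decomposed with `EMD_1`, and
#' the phase-averaged first IMFs become the next component. The uniform
#' phases cancel the mask in the average; the procedure is fully
#' deterministic.
#'
#' @param x An `imemd_signal`.
#' @param cfg An [imemd_config()].
#' @param max_imfs Safety cap on the number of extracted components.
#' @return An `imemd_decomposition` (residue never counted as an IMF).
#'   Degenerate input yields an empty IMF list with `residue = x`.
#' @export
imemd <- function(x, cfg = imemd_config(), max_imfs = 30L) {
  x <- as_imemd_signal(x)
  if (length(x$samples) < 4L) stop("signal too short to decompose (length >= 4 required)")
  v <- x$samples
  e_x <- sum(v^2)
  tt <- signal_time(x)
  r <- v
  imfs <- list()
  prev_freq <- NULL
  for (k in seq_len(max_imfs)) {
    e_r <- sum(r^2)
    if (e_x == 0 || e_r == 0) break
    if (10 * log10(e_x / e_r) >= cfg$eps1_db) break
    mask <- tryCatch(
      estimate_mask(r, prev_freq, cfg, rate = x$rate),
      imemd_monotonic = function(cnd) NULL)
    if (is.null(mask)) break
    acc <- numeric(length(r))
    ok <- TRUE
    for (i in seq_len(cfg$n_p)) {
      v_ki <- mask$amplitude *
        sin(2 * pi * mask$frequency * tt + 2 * pi * (i - 1) / cfg$n_p)
      branch <- tryCatch(emd1(r + v_ki, cfg$sift),
                         imemd_monotonic = function(cnd) NULL)
      if (is.null(branch)) { ok <- FALSE; break }
      acc <- acc + branch
    }
    if (!ok) break
    c_k <- acc / cfg$n_p
    if (cfg$select_cleanest &&
        if_dispersion(mask$probe, x$rate) < if_dispersion(c_k, x$rate))
      c_k <- mask$probe
    imfs[[k]] <- c_k
    r <- r - c_k
    prev_freq <- mask$probe_freq
  }
  new_decomposition(imfs, r, x$rate)
}

#' Reconstruct a signal from its decomposition
#'
#' Element-wise sum of all IMFs and the residue.
#'
#' @param d An `imemd_decomposition`.
#' @return An `imemd_signal`.
#' @export
reconstruct <- function(d) {
  out <- d$residue
  for (c_k in d$imfs) out <- out + c_k
  imemd_signal(out, d$rate)
}
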