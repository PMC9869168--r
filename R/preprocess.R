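#' Labeled utterance
#'
#' A signal with its emotion label and speaker metadata.
#'
#' @param signal An `imemd_signal`.
#' @param label Categorical emotion label (character scalar).
#' @param speaker_id Speaker identifier (character scalar).
#' @param source_id Free-text provenance tag.
#' @return An object of class `imemd_utterance`.
#' @export
utterance <- function(signal, label, speaker_id = "unknown", source_id = "") {
  stopifnot(inherits(signal, "imemd_signal"))
  structure(list(signal = signal, label = as.character(label),
                 speaker_id = as.character(speaker_id),
                 source_id = as.character(source_id)),
            class = "imemd_utterance")
}

#' Segment an utterance into fixed-length pieces
#'
#' Utterances shorter than the target duration are right-padded with zeros;
#' longer ones are split into consecutive segments (final partial segment
#' zero-padded). Every segment inherits the utterance's label and speaker.
#'
#' @param u An `imemd_utterance`.
#' @param duration_s Target segment duration in seconds (default 3).
#' @return List of `imemd_utterance` objects, each exactly
#'   `duration_s * rate` samples long.
#' @export
segment_and_pad <- function(u, duration_s = 3) {
  stopifnot(inherits(u, "imemd_utterance"))
  v <- u$signal$samples
  if (!length(v)) stop("empty signal")
  rate <- u$signal$rate
  seg_len <- round(duration_s * rate)
  n_seg <- max(1L, ceiling(length(v) / seg_len))
  lapply(seq_len(n_seg), function(i) {
    lo <- (i - 1L) * seg_len + 1L
    hi <- min(i * seg_len, length(v))
    seg <- v[lo:hi]
    if (length(seg) < seg_len) seg <- c(seg, numeric(seg_len - length(seg)))
    utterance(imemd_signal(seg, rate), u$label, u$speaker_id,
              sprintf("%s#%d", u$source_id, i))
  })
}

#' Peak-normalize an utterance
#'
#' Divides the waveform by its maximum absolute sample so the peak magnitude
#' is exactly 1; the sign pattern is preserved. All-zero input is rejected.
#'
#' @param u An `imemd_utterance`.
#' @return The normalized `imemd_utterance`.
#' @export
normalize_max <- function(u) {
  stopifnot(inherits(u, "imemd_utterance"))
  peak <- max(abs(u$signal$samples))
  if (peak == 0) stop("silent utterance: cannot normalize an all-zero signal")
  u$signal$samples <- u$signal$samples / peak
  u
}

#' Augmentation specification
#'
#' Ranges for the three augmentation families (pitch shift, time shift,
#' additive Gaussian noise at a drawn SNR) and how many augmented copies
#' each file yields. Defaults are the published ranges: pitch in [-2, 2]
#' semitones, time shift in [-0.4, 0.4] s, SNR in [-20, 40] dB, 60 copies
#' per file.
#'
#' @param pitch_semitones Length-2 range in semitones.
#' @param time_shift_s Length-2 range in seconds.
#' @param noise_snr_db Length-2 SNR range in dB (`c(Inf, Inf)` disables
#'   noise).
#' @param copies_per_file Augmented copies per input.
#' @param seed Integer seed for the parameter draws.
#' @param apply Character vector naming which families apply per copy
#'   (default all three jointly).
#' @return An object of class `imemd_augment_spec`.
#' @export
augment_spec <- function(pitch_semitones = c(-2, 2), time_shift_s = c(-0.4, 0.4),
                         noise_snr_db = c(-20, 40), copies_per_file = 60L,
                         seed = 1L, apply = c("pitch", "shift", "noise")) {
  stopifnot(length(pitch_semitones) == 2L, length(time_shift_s) == 2L,
            length(noise_snr_db) == 2L, copies_per_file >= 1L)
  structure(list(pitch_semitones = pitch_semitones, time_shift_s = time_shift_s,
                 noise_snr_db = noise_snr_db,
                 copies_per_file = as.integer(copies_per_file),
                 seed = as.integer(seed), apply = apply),
            class = "imemd_augment_spec")
}

#' Augment an utterance
#'
#' Produces `copies_per_file` augmented copies. Each copy draws its pitch
#' shift, time shift and noise SNR independently and uniformly from the
#' spec's ranges under the seeded generator. Pitch shifting is implemented
#' by resampling at factor `2^(semitones/12)` (trimmed/zero-padded back to
#' the original length); time shifting zero-fills the vacated region; noise
#' is white Gaussian scaled so `10*log10(P_signal/P_noise)` equals the drawn
#' SNR.
#'
#' @param u An `imemd_utterance` (typically a 3 s segment).
#' @param spec An [augment_spec()].
#' @return List of `copies_per_file` augmented `imemd_utterance` objects.
#' @export
augment <- function(u, spec = augment_spec()) {
  stopifnot(inherits(u, "imemd_utterance"))
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
  set.seed(spec$seed)
  lapply(seq_len(spec$copies_per_file), function(j) {
    v <- u$signal$samples
    rate <- u$signal$rate
    n <- length(v)
    if ("pitch" %in% spec$apply) {
      semi <- stats::runif(1, spec$pitch_semitones[1], spec$pitch_semitones[2])
      v <- pitch_shift_resample(v, semi)
    }
    if ("shift" %in% spec$apply) {
      sh <- stats::runif(1, spec$time_shift_s[1], spec$time_shift_s[2])
      v <- time_shift_zero(v, round(sh * rate))
    }
    if ("noise" %in% spec$apply) {
      snr <- if (all(is.finite(spec$noise_snr_db)))
        stats::runif(1, spec$noise_snr_db[1], spec$noise_snr_db[2]) else Inf
      if (is.finite(snr)) {
        p_sig <- mean(v^2)
        if (p_sig > 0) {
          p_noise <- p_sig / 10^(snr / 10)
          v <- v + stats::rnorm(n, sd = sqrt(p_noise))
        }
      }
    }
    utterance(imemd_signal(v, rate), u$label, u$speaker_id,
              sprintf("%s~aug%02d", u$source_id, j))
  })
}

# Resampling pitch shift: read the waveform at a stretched rate, then trim or
# zero-pad back to the original length. Changes pitch by 2^(semi/12); the
# duration of the voiced content changes accordingly (recorded design choice).
pitch_shift_resample <- function(v, semitones) {
  n <- length(v)
  if (semitones == 0) return(v)
  factor <- 2^(semitones / 12)
  src <- seq(1, n, by = factor)
  out <- stats::approx(seq_len(n), v, xout = src, rule = 2)$y
  if (length(out) >= n) out[seq_len(n)] else c(out, numeric(n - length(out)))
}

time_shift_zero <- function(v, k) {
  n <- length(v)
  k <- max(min(k, n), -n)
  if (k == 0) return(v)
  if (k > 0) c(numeric(k), v[seq_len(n - k)])
  else c(v[(1 - k):n], numeric(-k))
}
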