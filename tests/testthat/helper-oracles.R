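# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: the spline oracle solves the natural-cubic
# system directly, the MFCC oracle is a literal second implementation, and
# the delta oracle evaluates the three-branch derivative formula term by
# term.

# --- natural cubic spline (tridiagonal solve), independent of splinefun ----
oracle_natural_spline <- function(xk, yk, xout) {
  n <- length(xk)
  h <- diff(xk)
  # second derivatives M: natural boundary M1 = Mn = 0
  if (n == 2L) {
    M <- c(0, 0)
  } else {
    a <- h[-(n - 1L)]                     # sub-diagonal
    b <- 2 * (h[-(n - 1L)] + h[-1L])      # diagonal
    cc <- h[-1L]                          # super-diagonal
    d <- 6 * ((yk[-(1:2)] - yk[-c(1L, n)]) / h[-1L] -
                (yk[-c(1L, n)] - yk[-c(n - 1L, n)]) / h[-(n - 1L)])
    m <- length(d)
    for (i in seq_len(m - 1L)) {          # forward elimination
      w <- a[i + 1L] / b[i]
      b[i + 1L] <- b[i + 1L] - w * cc[i]
      d[i + 1L] <- d[i + 1L] - w * d[i]
    }
    Mi <- numeric(m)
    Mi[m] <- d[m] / b[m]
    for (i in rev(seq_len(m - 1L)))
      Mi[i] <- (d[i] - cc[i] * Mi[i + 1L]) / b[i]
    M <- c(0, Mi, 0)
  }
  vapply(xout, function(x) {
    j <- findInterval(x, xk, all.inside = TRUE)
    t1 <- xk[j + 1L] - x
    t2 <- x - xk[j]
    hj <- h[j]
    (M[j] * t1^3 + M[j + 1L] * t2^3) / (6 * hj) +
      (yk[j] / hj - M[j] * hj / 6) * t1 +
      (yk[j + 1L] / hj - M[j + 1L] * hj / 6) * t2
  }, numeric(1))
}

# mirror extension matching the documented envelope contract (2 extrema
# reflected about each end), reimplemented literally
oracle_extend <- function(idx, val, n, depth = 2L) {
  k <- length(idx)
  take_l <- seq_len(min(depth, k))
  take_r <- seq.int(k, by = -1L, length.out = min(depth, k))
  all_idx <- c(2L - idx[take_l], idx, 2L * n - idx[take_r])
  all_val <- c(val[take_l], val, val[take_r])
  ord <- order(all_idx)
  keep <- !duplicated(all_idx[ord])
  list(idx = all_idx[ord][keep], val = all_val[ord][keep])
}

# --- literal three-branch temporal-derivative formula ----------------------
oracle_delta <- function(x, Q = 2L) {
  n <- length(x)
  out <- numeric(n)
  for (phi in seq_len(n)) {
    if (phi <= Q) {
      out[phi] <- x[phi + 1L] - x[phi]
    } else if (phi <= n - Q) {
      num <- 0
      for (q in seq_len(Q)) num <- num + q * (x[phi + q] - x[phi - q])
      out[phi] <- num / (2 * sum((seq_len(Q))^2))
    } else {
      out[phi] <- x[phi] - x[phi - 1L]
    }
  }
  out
}

# --- independent MFCC implementation (explicit loops, own mel bank) --------
oracle_mfcc <- function(v, rate, frame_len, hop, n_filters = 26L,
                        n_coef = 12L, log_floor = 1e-10) {
  n_frames <- (length(v) - frame_len) %/% hop + 1L
  nfft <- 2^ceiling(log2(frame_len))
  mel <- function(f) 2595 * log10(1 + f / 700)
  imel <- function(m) 700 * (10^(m / 2595) - 1)
  pts <- imel(seq(mel(0), mel(rate / 2), length.out = n_filters + 2L))
  bins <- floor((nfft + 1) * pts / rate)
  out <- matrix(0, n_coef, n_frames)
  win <- 0.54 - 0.46 * cos(2 * pi * (0:(frame_len - 1L)) / (frame_len - 1L))
  for (ph in seq_len(n_frames)) {
    fr <- v[((ph - 1L) * hop + 1L):((ph - 1L) * hop + frame_len)] * win
    fr <- c(fr, numeric(nfft - frame_len))
    pw <- Mod(fft(fr))[1:(nfft / 2 + 1L)]^2 / nfft
    fe <- numeric(n_filters)
    for (m in seq_len(n_filters)) {
      acc <- 0
      lo <- bins[m]; ce <- bins[m + 1L]; hi <- bins[m + 2L]
      for (k in lo:hi) {
        w <- if (k <= ce) {
          if (ce > lo) (k - lo) / (ce - lo) else 0
        } else {
          if (hi > ce) (hi - k) / (hi - ce) else 0
        }
        acc <- acc + w * pw[k + 1L]
      }
      fe[m] <- log(max(acc, log_floor))
    }
    for (cf in seq_len(n_coef)) {
      s <- 0
      for (m in seq_len(n_filters))
        s <- s + fe[m] * cos(pi * cf * (m - 0.5) / n_filters)
      out[cf, ph] <- s * sqrt(2 / n_filters)
    }
  }
  out
}

# --- misc helpers -----------------------------------------------------------
fft_peak_freqs <- function(v, thresh = 0.15) {
  sp <- Mod(stats::fft(v))[seq_len(length(v) %/% 2)]
  loc <- which(diff(sign(diff(sp))) == -2) + 1L
  loc <- loc[sp[loc] > thresh * max(sp)]
  (loc - 1) / length(v)
}

quiet_imemd <- function(x, cfg = imemd_config(), ...) {
  suppressWarnings(imemd(x, cfg, ...))
}

two_tone <- function(f_high = 0.25, f_low = 0.15, phase_low = 0.7,
                     t = 0:500) {
  list(signal = imemd_signal(sin(2 * pi * f_high * t) +
                               sin(2 * pi * f_low * t + phase_low), 1),
       high = sin(2 * pi * f_high * t),
       low = sin(2 * pi * f_low * t + phase_low))
}
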