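test_that("find_extrema locates interleaved extrema, plateaus and degenerate inputs", {
  # exhaustive-by-hand case: samples [0, 2, 1, 3, 0]
  ex <- find_extrema(c(0, 2, 1, 3, 0))
  expect_equal(ex$max_idx, c(2L, 4L))
  expect_equal(ex$min_idx, 3L)
  expect_equal(ex$max_val, c(2, 3))

  # one full sine period: exactly one max, one min
  s <- sin(2 * pi * seq(0, 1, length.out = 100))
  ex <- find_extrema(s)
  expect_length(ex$max_idx, 1L)
  expect_length(ex$min_idx, 1L)

  # constant and monotonic inputs have no extrema
  expect_length(find_extrema(rep(1, 50))$max_idx, 0L)
  expect_length(find_extrema(seq_len(50))$min_idx, 0L)

  # plateau yields a single midpoint extremum
  ex <- find_extrema(c(0, 1, 2, 2, 2, 1, 0))
  expect_equal(ex$max_idx, 4L)

  # property: interior extrema strictly interleave for random smooth signals
  set.seed(11)
  for (i in 1:20) {
    v <- as.vector(stats::filter(rnorm(200), rep(1 / 8, 8), sides = 2))
    v <- v[!is.na(v)]
    ex <- find_extrema(v)
    pos <- sort(c(ex$max_idx, ex$min_idx))
    types <- ifelse(pos %in% ex$max_idx, "M", "m")
    expect_true(all(types[-1] != types[-length(types)]),
                info = sprintf("iteration %d", i))
  }
})

test_that("envelope_mean matches an independent natural-spline oracle and basic identities", {
  # many-period sine: interior mean envelope is small
  t <- seq(0, 20, by = 0.01)
  s <- sin(2 * pi * t)
  e <- envelope_mean(s)
  interior <- 200:1800
  expect_lt(max(abs(e[interior])), 0.05)

  # additive constant shifts the mean envelope
  e2 <- envelope_mean(s + 3)
  expect_equal(mean(e2[interior]), 3, tolerance = 0.05)

  # oracle check on the two-tone benchmark signal, sample for sample
  mm <- make_mode_mixing_signal()
  v <- mm$signal$samples
  ex <- find_extrema(v)
  e_pkg <- envelope_mean(v, ex)
  n <- length(v)
  up <- oracle_extend(ex$max_idx, ex$max_val, n)
  lo <- oracle_extend(ex$min_idx, ex$min_val, n)
  e_oracle <- (oracle_natural_spline(up$idx, up$val, seq_len(n)) +
                 oracle_natural_spline(lo$idx, lo$val, seq_len(n))) / 2
  expect_equal(e_pkg, e_oracle, tolerance = 1e-10)

  # too few extrema signals the monotonic condition
  expect_error(envelope_mean(seq_len(20)), class = "imemd_monotonic")
})

test_that("sift honors the iteration contract and the IMF criterion", {
  t <- 0:500
  tone <- sin(2 * pi * 0.1 * t)
  # a pure tone is already an IMF: relative change < 1e-3
  out <- sift(tone)
  expect_lt(rrmse(tone, out), 1e-3)

  # one iteration is exactly one envelope subtraction
  mix <- sin(2 * pi * 0.25 * t) + sin(2 * pi * 0.05 * t)
  out1 <- sift(mix, sift_config(max_sift_iters = 1))
  expect_equal(out1, mix - envelope_mean(mix), tolerance = 1e-12)

  # first sift of a 0.25/0.05 mixture is dominated by the fast tone
  out <- sift(mix)
  expect_equal(fft_peak_freqs(out, 0.5), 0.25, tolerance = 0.01)

  # idempotence: re-sifting a sifted pure tone changes nothing material
  once <- sift(tone)
  expect_lt(rrmse(once, sift(once)), 1e-3)

  expect_error(sift(seq_len(30)), class = "imemd_monotonic")
})

test_that("emd decomposes tone mixtures and satisfies completeness and ordering", {
  t <- 0:500
  mix <- sin(2 * pi * 0.25 * t) + sin(2 * pi * 0.05 * t)
  d <- emd(imemd_signal(mix, 1))
  expect_gte(n_imfs(d), 2L)
  interior <- 21:481
  expect_lt(rrmse(sin(2 * pi * 0.25 * t)[interior], d$imfs[[1]][interior]), 0.1)

  # monotonic ramp: no IMFs
  dr <- emd(imemd_signal(seq(0, 1, length.out = 50), 1))
  expect_identical(n_imfs(dr), 0L)
  expect_equal(dr$residue, seq(0, 1, length.out = 50))

  # completeness over random band-limited signals
  set.seed(23)
  for (i in 1:100) {
    n <- 256L
    spec <- c(stats::rnorm(30), numeric(n - 30))
    v <- Re(stats::fft(stats::fft(spec), inverse = TRUE)) / n
    v <- v / max(abs(v))
    d <- emd(imemd_signal(v, 1))
    expect_lt(rrmse(v, reconstruct(d)$samples), 1e-10)
  }

  # ordering: amplitude-weighted mean frequency non-increasing across IMFs
  d <- emd(imemd_signal(mix, 1))
  wf <- vapply(d$imfs, function(c_k) {
    tr <- analytic_track(c_k, 1)
    a <- tr$amplitude
    sum(a * pmax(tr$frequency, 0)) / sum(a)
  }, numeric(1))
  expect_true(all(diff(wf) <= 1e-6))
})

test_that("emd1 equals the first sift and mode-mixes octave-spaced tones", {
  t <- 0:500
  tone <- sin(2 * pi * 0.1 * t)
  expect_gt(cor(emd1(tone), tone), 0.999)

  # within-an-octave pair: both tones present in the first IMF
  pk <- fft_peak_freqs(emd1(sin(2 * pi * 0.25 * t) + sin(2 * pi * 0.15 * t)))
  expect_true(any(abs(pk - 0.25) < 0.01) && any(abs(pk - 0.15) < 0.01))

  expect_error(emd1(numeric(100)), class = "imemd_monotonic")
})

test_that("analytic_track recovers amplitude and frequency of closed-form signals", {
  rate <- 100
  t <- seq(0, 10, by = 1 / rate)
  for (f in c(5, 12)) {
    a <- 2.5
    tr <- analytic_track(a * cos(2 * pi * f * t), rate)
    interior <- 100:(length(t) - 100)
    expect_lt(max(abs(tr$amplitude[interior] - a)) / a, 0.01)
    expect_lt(max(abs(tr$frequency[interior] - f)) / f, 0.01)
  }

  # amplitude is nonnegative for arbitrary input
  set.seed(3)
  tr <- analytic_track(rnorm(64), 8)
  expect_true(all(tr$amplitude >= 0))

  # linear chirp: interior instantaneous frequency increases
  f0 <- 2; f1 <- 10
  ph <- 2 * pi * (f0 * t + (f1 - f0) * t^2 / 20)
  tr <- analytic_track(cos(ph), rate)
  interior <- 100:(length(t) - 100)
  expect_true(all(diff(tr$frequency[interior]) > -0.05))
  expect_gt(stats::cor(tr$frequency[interior], t[interior]), 0.99)

  expect_error(analytic_track(1:4, 1), "too short")
})
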