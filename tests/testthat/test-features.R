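test_that("frame_grid arithmetic matches the 25 ms / 10 ms convention", {
  # 3 s at 16 kHz: floor((48000 - 400) / 160) + 1 = 298 frames
  g <- frame_grid(48000, 16000)
  expect_identical(g$frame_len, 400L)
  expect_identical(g$hop, 160L)
  expect_identical(g$n_frames, 298L)

  # default fixture rate keeps the grid integral
  g8 <- frame_grid(2400, 800)
  expect_identical(g8$frame_len, 20L)
  expect_identical(g8$n_frames, 298L)

  expect_error(frame_grid(10, 16000), "shorter than one frame")
})

test_that("frame_summaries computes per-frame amplitude means and weighted centroids", {
  rate <- 800
  t <- seq(0, 3, by = 1 / rate)[-1]
  f <- 100
  d <- structure(list(imfs = list(sin(2 * pi * f * t)), residue = 0 * t,
                      rate = rate, source_length = length(t)),
                 class = "imemd_decomposition")
  g <- frame_grid(length(t), rate)
  s <- frame_summaries(d, g)
  interior <- 10:(g$n_frames - 10)
  expect_true(all(abs(s$f_ce[1, interior] - f) / f < 0.02))

  # homogeneity: halving the amplitude halves E_me, leaves F_ce unchanged
  d2 <- d; d2$imfs[[1]] <- d$imfs[[1]] / 2
  s2 <- frame_summaries(d2, g)
  expect_equal(s2$e_me, s$e_me / 2, tolerance = 1e-12)
  expect_equal(s2$f_ce, s$f_ce, tolerance = 1e-10)
})

test_that("hilbert spectrum features reproduce hand-evaluated weighted moments", {
  # hand case: E = [1, 3], F = [100, 200] -> SC = 175, SP = 1875
  s <- structure(list(e_me = matrix(c(1, 3), 2, 1),
                      f_ce = matrix(c(100, 200), 2, 1), n_frames = 1L),
                 class = "imemd_frame_summary")
  hs <- hilbert_spectrum_features(s)
  expect_equal(unname(hs["SC", 1]), 175)
  expect_equal(unname(hs["SP", 1]), 1875)

  # single IMF: SC = F_ce, SP = SK = SU = 0 by guard
  s1 <- structure(list(e_me = matrix(2, 1, 1), f_ce = matrix(120, 1, 1),
                       n_frames = 1L), class = "imemd_frame_summary")
  hs1 <- hilbert_spectrum_features(s1)
  expect_equal(unname(hs1[, 1]), c(120, 0, 0, 0))

  # mirroring F about SC flips SK and preserves SU
  set.seed(4)
  e <- runif(5, 0.5, 2); f <- runif(5, 50, 300)
  sA <- structure(list(e_me = matrix(e), f_ce = matrix(f), n_frames = 1L),
                  class = "imemd_frame_summary")
  hsA <- hilbert_spectrum_features(sA)
  sB <- sA; sB$f_ce <- matrix(2 * hsA["SC", 1] - f)
  hsB <- hilbert_spectrum_features(sB)
  expect_equal(hsB["SK", 1], -hsA["SK", 1], tolerance = 1e-10)
  expect_equal(hsB["SU", 1], hsA["SU", 1], tolerance = 1e-10)
  expect_equal(hsB["SP", 1], hsA["SP", 1], tolerance = 1e-10)

  # weighted-mean boundedness of SC
  expect_true(hsA["SC", 1] >= min(f) && hsA["SC", 1] <= max(f))
})

test_that("delta operator matches the literal three-branch oracle and is linear", {
  set.seed(9)
  x <- rnorm(10)
  expect_equal(as.vector(delta_features(x)), oracle_delta(x), tolerance = 1e-12)

  # constants vanish, ramps give unit interior slope
  expect_true(all(delta_features(rep(3, 12)) == 0))
  ramp <- delta_features(seq_len(12))
  expect_true(all(abs(ramp[1, 3:10] - 1) < 1e-12))

  # linearity
  u <- rnorm(15); v <- rnorm(15)
  expect_equal(as.vector(delta_features(2 * u - 3 * v)),
               2 * oracle_delta(u) - 3 * oracle_delta(v), tolerance = 1e-12)

  expect_error(delta_features(1:4, Q = 2), "too short")
})

test_that("hilbert contour features apply the shared derivative operator to SE", {
  e_me <- rbind(seq(0.1, 1, length.out = 12), seq(1, 0.1, length.out = 12))
  s <- structure(list(e_me = e_me, f_ce = e_me * 0 + 100, n_frames = 12L),
                 class = "imemd_frame_summary")
  hc <- hilbert_contour_features(s)
  expect_equal(unname(hc["SE", ]), apply(e_me, 2, max))
  expect_equal(unname(hc["dSE", ]), oracle_delta(apply(e_me, 2, max)),
               tolerance = 1e-12)
  expect_equal(unname(hc["d2SE", ]),
               oracle_delta(oracle_delta(apply(e_me, 2, max))),
               tolerance = 1e-12)

  # constant SE: derivatives vanish
  sc <- structure(list(e_me = matrix(1, 1, 8), f_ce = matrix(50, 1, 8),
                       n_frames = 8L), class = "imemd_frame_summary")
  hcc <- hilbert_contour_features(sc)
  expect_true(all(hcc[c("dSE", "d2SE"), ] == 0))
})

test_that("signal_trend recovers additive low-frequency trends", {
  rate <- 100
  t <- seq(0, 5, by = 1 / rate)[-1]
  ramp <- 0.8 * t
  x <- imemd_signal(sin(2 * pi * 10 * t) + ramp, rate)
  d <- emd(x)
  tr <- signal_trend(d)
  expect_gt(cor(tr, ramp), 0.99)

  # threshold 0: residue only
  expect_equal(signal_trend(d, 0), d$residue)

  # pure tone: nothing to remove
  xt <- imemd_signal(sin(2 * pi * 10 * t), rate)
  dt <- emd(xt)
  expect_lt(rrmse(xt$samples, xt$samples - signal_trend(dt)), 0.05)
})

test_that("smfcc matches the independent reference implementation", {
  rate <- 800
  t <- seq(0, 1.5, by = 1 / rate)[-1]
  v <- sin(2 * pi * 100 * t) * (1 + 0.3 * sin(2 * pi * 3 * t)) +
    0.4 * sin(2 * pi * 220 * t)
  x <- imemd_signal(v, rate)
  d <- emd(x)
  g <- frame_grid(length(v), rate)
  sm <- smfcc(x, d, g)
  expect_identical(nrow(sm), 12L)

  recon <- v - signal_trend(d)
  ref <- oracle_mfcc(recon, rate, g$frame_len, g$hop)
  expect_lt(max(abs(sm - ref)), 1e-6)

  # all-zero signal: defined, all-finite coefficients via the log floor
  d0 <- structure(list(imfs = list(numeric(1200) + 0), residue = numeric(1200),
                       rate = rate, source_length = 1200L),
                  class = "imemd_decomposition")
  sm0 <- smfcc(imemd_signal(numeric(1200), rate), d0, frame_grid(1200, rate))
  expect_true(all(is.finite(sm0)))
})

test_that("extract_features produces the fixed 43-row stack with scale equivariances", {
  fx <- make_emotion_fixtures(n_per_class = 1, seed = 21)
  x <- normalize_max(fx[[1]])$signal
  cfg <- imemd_config(n_p = 4)
  fm <- suppressWarnings(extract_features(x, cfg))
  expect_identical(dim(fm), c(43L, 298L))
  expect_true(all(is.finite(fm)))
  expect_identical(rownames(fm)[1:7], c("SC", "SP", "SK", "SU", "SE", "dSE", "d2SE"))
  expect_identical(sum(startsWith(rownames(fm), "SMFCC")), 12L)
  expect_identical(sum(startsWith(rownames(fm), "dSMFCC")), 12L)
  expect_identical(sum(startsWith(rownames(fm), "d2SMFCC")), 12L)

  # scaling the input scales SE rows and leaves SC rows unchanged
  d <- quiet_imemd(x, cfg)
  d3 <- d; d3$imfs <- lapply(d$imfs, function(ck) 3 * ck); d3$residue <- 3 * d$residue
  x3 <- imemd_signal(3 * x$samples, x$rate)
  fm3 <- extract_features(x3, cfg, d = d3)
  expect_equal(fm3["SE", ], 3 * fm["SE", ], tolerance = 1e-8)
  expect_equal(fm3["SC", ], fm["SC", ], tolerance = 1e-6)
})
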