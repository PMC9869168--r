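# imemd

Masking-signal empirical mode decomposition with adaptively derived mask
parameters, a 43-dimensional Hilbert-spectral/cepstral feature set for
speech emotion recognition, and a convolutional-recurrent classifier — all
implemented in base scientific R and exercisable entirely on in-package
synthetic signals.

## The problem

Empirical mode decomposition (EMD) splits a non-stationary signal x(t) into
intrinsic mode functions (IMFs) plus a residue,

    x(t) = Σ_k c_k(t) + r_es(t),

by iteratively subtracting the mean of cubic-spline envelopes through the
local extrema (sifting). EMD suffers from *mode mixing*: intermittent
components and tone pairs whose frequencies lie within one octave end up
smeared across IMFs, which destroys the physical interpretability that
speech-emotion features depend on.

The masking-signal remedy adds a sinusoid v(t) = ξ sin(2π f̄ t + θ) to the
signal before extracting the first IMF, so that sifting's dyadic filter is
anchored at the mask frequency. This package implements an *improved*
masking EMD (IMEMD) in which the mask parameters are derived from the
signal itself at every extraction step k:

* amplitude ξ_k = ξ0 · mean(A_k), with A_k(t) the instantaneous amplitude
  of a probe IMF extracted by plain EMD_1 from the current residual
  (default ξ0 = 1.5);
* frequency f̄_1 = 2 f_1 and f̄_k = f_{k−1} + f_k for k > 1, where
  f_k = Σ A_k F_k / Σ A_k is the amplitude-weighted mean instantaneous
  frequency of the probe;
* n_p masks with phases 2π(i−1)/n_p, i = 1…n_p (default n_p = 64), whose
  first IMFs are averaged so the mask cancels exactly and deterministically.

Extraction stops once the residual energy falls 30 dB (ε1) below the input
energy or the residual is monotonic. Each step additionally keeps whichever
of the masked average and the plain probe has the smaller energy-weighted
instantaneous-frequency dispersion — masking counters mode mixing, and when
the residual already holds a single clean mode the unmasked extraction is
the cleaner one (see the methods vignette for the rationale and evidence).

On top of the decomposition the package provides the full
speech-emotion-recognition stack: 25 ms / 10 ms frame-wise features
(spectral centroid/spread/skewness/kurtosis of per-IMF centroid
frequencies, envelope-peak contours with regression deltas, and 12
trend-removed MFCCs with Δ and Δ² — 43 rows total), utterance segmentation,
peak normalization and augmentation (pitch shift, time shift, noise at a
drawn SNR), a CRNN (four conv blocks → three bidirectional GRUs → three
dense layers, Adam, cross-entropy) written in base R with
numerically-verified backpropagation, unweighted accuracy and LOSO /
stratified k-fold cross-validation, plus synthetic benchmarks.

## Worked example

```r
library(imemd)

mm <- make_mode_mixing_signal()   # sustained 0.15 Hz tone + gapped 0.25 Hz tone
mm$signal
#> <imemd_signal> 501 samples @ 1 Hz (501.000 s)

d <- imemd(mm$signal, imemd_config())   # n_p = 64, xi0 = 1.5, eps1 = 30 dB
d
#> <imemd_decomposition> 2 IMF(s) + residue, 501 samples @ 1 Hz

rrmse(mm$signal$samples, reconstruct(d)$samples)
#> [1] 4.041146e-17

interior <- 21:481
cor(d$imfs[[1]][interior], mm$component_high[interior])  # gapped 0.25 Hz tone
#> [1] 0.954
cor(d$imfs[[2]][interior], mm$component_low[interior])   # sustained 0.15 Hz tone
#> [1] 0.999

n_imfs(emd(mm$signal))   # plain EMD needs more modes and mixes the tones
#> [1] 5
```

The decomposition recovers exactly two IMFs — one per physical component —
with machine-precision reconstruction, where plain EMD mode-mixes. Feature
extraction on a synthetic "emotion" utterance:

```r
fx <- make_emotion_fixtures(n_per_class = 2, seed = 1)
fm <- extract_features(normalize_max(fx[[1]])$signal, imemd_config(n_p = 8))
dim(fm)
#> [1]  43 298
round(fm[1:5, 1:3], 2)
#>      [,1]   [,2]   [,3]
#> SC 123.47 124.53 123.79
#> SP 184.51 132.85 124.01
#> SK  -7.05  -7.54  -7.15
#> SU  53.18  61.58  55.19
#> SE   0.80   0.73   0.67
```

The spectral centroid (SC) sits near the class's 120 Hz carrier; rows 8–43
hold the cepstral block. See `cross_validate()` for training the CRNN on a
labeled corpus.

## Command-line interface

```sh
Rscript inst/cli/imemd-cli.R decompose synthetic:modemix --np 64 --out run
Rscript inst/cli/imemd-cli.R features utterance.wav --out feats.csv
Rscript inst/cli/imemd-cli.R bench modemix --np-grid 2,4,8,16,32,64 --out bench.csv
Rscript inst/cli/imemd-cli.R fixtures make --classes 2 --n 100 --seed 7 --out corpus/
Rscript inst/cli/imemd-cli.R train --manifest corpus/manifest.csv --scheme loso --out run/
```

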