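# epifd

Seizure onset detection from multichannel EEG (and single-channel ECG) by
tracking the Higuchi fractal dimension of independent components.

## The science

During an epileptic seizure the EEG shifts from chaotic broadband activity
to large periodic spike discharges. The Higuchi fractal dimension (FD)
quantifies that shift directly in the time domain: for a series
X(1),…,X(N) and stride k, the mean normalized curve length over the k
subsampled phases,

    L_m(k) = (1/k) [ Σ_{i=1..p} |X(m+ik) − X(m+(i−1)k)| ] (N−1)/(pk),
    p = ⌊(N−m)/k⌋,   L(k) = mean_m L_m(k),

scales as L(k) ∝ k^(−D_f); the dimension D_f (1 for a smooth curve, → 2
for a plane-filling one) is the least-squares slope of ln L(k) on
ln(1/k), reported with regression standard errors. Tracked in 2048-sample
windows (16 s at 128 Hz, 50% overlap), the FD of the seizure-carrying
signal holds a stable high preictal plateau, declines ahead of the
seizure, and is minimal at the ictal onset.

Because scalp channels are linear mixtures x = As of latent sources, the
FD stage is preceded by FastICA blind source separation (eigenvalue
whitening + one-unit deflation with Gram–Schmidt decorrelation), and
optionally by a (2k+1)-point moving-average prefilter that suppresses the
high-frequency noise the Higuchi estimator is most sensitive to:

* **Method 1**: center → whiten → FastICA → windowed FD → select the
  highest-mean-FD ("main") component → FD-drop onset detection.
* **Method 2** (default): averaging filter on every channel, then the
  same chain.

The onset estimate is the time of the global FD minimum after the
baseline windows; an earlier alarm fires at the first sustained drop
below `baseline_mean − alpha·baseline_sd`.

Seeded synthetic generators with attached ground truth cover everything
the method needs to be checked against: fractional Gaussian noise / fBm
with known Hurst exponent H (theoretical FD = 2 − H), non-Gaussian source
mixtures for separation benchmarks, and seizure-like recordings with a
known onset.

## Worked example

```r
library(epifd)

# a 480 s, 4-channel synthetic recording, seizure onset at 240 s
sz  <- gen_seizure_recording(fs = 128, duration_s = 480, onset_s = 240,
                             n_channels = 4, seed = 1)
fit <- seizure_fd(sz$recording, method = 2, seed = 1)
fit
#> <seizure_fd> method 2, 4 channel(s), 4 component(s), 59 window(s)
#>   main component: IC3 (mean FD 1.787)
#> <onset_detection> onset at 240.0 s (window 30)
#>   alarm at 152.0 s (window 19), threshold 1.926
```

The main component is the independent component with the highest mean
fractal dimension — here the one carrying the synthetic epileptic source.
Its FD plateaus near 1.95, declines through the transition, and bottoms
out at 240 s, matching the generator's true onset exactly; the sustained
drop below the baseline threshold raises the alarm 88 s earlier.
`plot(fit)` draws the FD time-courses with onset and alarm marked;
`summary(fit)` lists per-component mean FDs.

Single series work too:

```r
fbm <- gen_fbm(H = 0.5, n = 8192, seed = 1)
higuchi_fd(fbm$x, k_max = 64)
#> <higuchi_fd> Df = 1.506813 (SD 0.00103), b = 8.7925 (SD 0.00343)
#>   N = 8192 samples, k = 1..64 (64 values)
```

(theory: FD = 2 − H = 1.5).

A command-line interface wraps the same functions:

```sh
inst/cli/epifd simulate --kind seizure --duration 480 --onset 240 --out rec
inst/cli/epifd run --input rec.csv --out results --method 2 --seed 1
inst/cli/epifd fd --input rec.csv --channel 1
```

`run` writes `fd.csv` (the windowed FD time-course) and `report.json`
(selected component, onset and alarm times, baseline statistics, full
config echo). Recordings are read from plain CSV (one column per channel,
`# fs=…` header) or 16-bit EDF.

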