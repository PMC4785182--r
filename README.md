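# stepconn

Movement-locked EEG spectral perturbation and directed connectivity.

## The problem

During rhythmic limb movement (e.g. recumbent stepping at a paced cadence),
cortical activity is organized by the movement cycle: spectral power in
theta/alpha/beta/gamma bands waxes and wanes within each limb extension,
and the *effective connectivity* between cortical areas — who drives whom —
fluctuates at the cadence and its harmonics. Quantifying this from
high-density EEG requires a long chain of signal processing, and each link
has failure modes that are invisible without ground truth. `stepconn`
implements the full chain as a tested R package, together with a synthetic
source-network generator whose coupling structure is known exactly, so
every stage can be validated end to end without any raw recordings.

It is intended for researchers analysing cyclic-movement EEG (gait,
stepping, cycling, viewed movement) and for methodologists who want a
ground-truth-known testbed for time-varying connectivity estimators.

## What it computes

* **Preprocessing** — zero-phase 1 Hz high-pass, artifact channel/window
  rejection with logged criteria, common average reference; for the
  connectivity branch, Fourier resampling to 128 Hz and piecewise linear
  detrending (330 ms windows every 82.5 ms).
* **Decomposition** — natural-gradient infomax ICA
  (`x = A s`, `u = W x`), per-component spatial-fixedness quality scores,
  and k-means clustering of component feature vectors with a
  subjects-per-cluster retention rule.
* **ERSP** — movement-cycle epochs (full extension to next full extension
  of the same limb), Morlet spectrograms (3–8 cycles over 3–80 Hz), linear
  time-warping of event latencies onto across-trial medians, and the
  event-related spectral perturbation
  `ERSP(f,t) = mean_trials 10 log10 P(f,t) - mean_t [.]`, with a
  within-trial time-resampling bootstrap mask (non-significant cells set
  to 0 dB).
* **MVAR/DTF** — sliding-window (200 ms / 54.7 ms) vector autoregression
  `x_t = sum_k A_k x_{t-k} + e_t` fitted by the Vieira–Morf lattice with
  trials pooled per window; AIC/SBC/HQ order tables; companion-matrix
  stability; a Ljung–Box / Box–Pierce / McLeod–Li / ACF residual-whiteness
  battery; and the normalized directed transfer function
  `DTF(i<-j, f) = |H_ij(f)| / sqrt(sum_m |H_im(f)|^2)`, `H = A(f)^{-1}`,
  with a trial bootstrap for the significance of connectivity
  fluctuations.
* **Network statistics** — suprathreshold pairs (maximum connectivity at
  least one sd above the pooled pair/condition mean) and the fluctuation
  spectrum of connectivity over time (mean-removed, 128-sample zero-padded
  FFT, averaged over pairs and frequencies), with harmonic peaks detected
  at 0.5/1/1.5/2 x the movement frequency.
* **Synthetic data** — coupled stochastic resonators whose directed gains
  are modulated by a stride-locked profile at 70 extensions/min, per-limb
  extension events for 4 limbs, scalp mixing with sensor noise and
  transient artifacts, all with stored ground truth.

File formats: delimited text (exact, diffable) and minimal 16-bit EDF for
recordings; BIDS-style `events.tsv` for events; YAML configs for
`run_pipeline()`; a thin CLI lives at `inst/cli/stepconn`.

## Worked example

Two minutes of the default 7-source stepping network, through the
connectivity branch:

```r
library(stepconn)

ss <- synthetic_dataset(duration_s = 120, seed = 42)
print(ss)
#> <source_set> 7 sources x 61440 samples @ 512 Hz, 6 edges

rec  <- recording(ss$sources, ss$fs, ss$labels)
conn <- piecewise_detrend(downsample(rec, 128))
ep   <- epoch_recording(conn, ss$events, cycles = 2)   # stride-locked trials
wins <- lapply(seq(1, dim(ep)[2] - 25, by = 14),
               function(s) ep[, s:(s + 25), , drop = FALSE])
sel  <- select_model_order(wins, candidates = 1:6, fs = 128)
print(sel)
#> <order_selection> order 2 (stable + white)
#>   order  logdet       aic     sbc       hq stable_frac white_frac
#> 1     1 10.1013 10.158150 10.3130 10.21545           1     0.0000
#> 2     2 -0.2233 -0.104970  0.2153  0.01376           1     0.8571
#> 3     3 -0.2650 -0.079701  0.4177  0.10507           1     0.7143
#> ...

dtf <- sliding_window_dtf(conn$data, 128, order = sel$order, n_boot = 0)
fl  <- fluctuation_spectrum(dtf, nfft = 128, fmax = 18)
print(detect_harmonic_peaks(fl, f0 = 70 / 60))
#> <harmonic_peaks> f0 = 1.167 Hz; dominant peak at 1.143 Hz
#>   multiple target_hz   freq power
#> 1      0.5    0.5833 0.5714 4.514
#> 2      1.0    1.1667 1.1429 5.612
#> 3      1.5    1.7500 1.8571 3.865
#> 4      2.0    2.3333 2.2857 3.739
```

Reading the output: an order-2 model is the smallest that is stable in all
windows and leaves white residuals in most of them (`white_frac` 0.86 at
order 2, 0 at order 1), matching the generating network, which is an exact
VAR(2) at 128 Hz. The connectivity-fluctuation spectrum — how fast the
DTF values change over the recording — peaks at the grid bin nearest the
1.17 Hz per-limb stepping rate (the grid spacing is 18.29/128 ≈ 0.14 Hz,
so the nearest bin is 1.143 Hz), with labelled harmonic peaks at 0.5, 1,
1.5 and 2 times the movement frequency: the cortical network's coupling
strengths fluctuate in lockstep with the movement, which is the package's
central quantitative claim.

The same chain runs from a YAML config, including scalp mixing, artifact
rejection, ICA and clustering:

```r
run_pipeline(list(seed = 1, out_dir = "results/demo",
                  synthetic = list(duration_s = 120, n_channels = 16,
                                   sensor_noise_sd = 1),
                  cluster = list(min_subjects = 1)))
```

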