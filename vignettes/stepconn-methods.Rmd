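---
title: "Movement-locked EEG spectral power and directed connectivity: methods"
author: "stepconn"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Movement-locked EEG spectral power and directed connectivity: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stepconn)
```

# Scope

`stepconn` implements an analysis pipeline for high-density EEG recorded
during paced rhythmic limb movement (recumbent stepping, and passive viewing
of stepping): cleaning and conditioning, infomax independent component
analysis (ICA) with k-means component clustering, movement-cycle epoching
with linear time-warping and event-related spectral perturbation (ERSP),
sliding-window multivariate autoregressive (MVAR) modelling with directed
transfer function (DTF) effective connectivity, and two network-level
statistics: suprathreshold connectivity pairs and the harmonic analysis of
connectivity fluctuation. Because raw recordings of this kind are rarely
shareable, the package includes a first-class synthetic source-network
generator with known ground truth; every stage is tested against it.

This vignette records the model assumptions, the tunable parameters and
their defaults, the genuinely open design choices and how they were
resolved, and the limitations of what the passing test suite demonstrates.

# The movement paradigm and its time scales

Subjects move to visual cues at a cadence of 70 full extensions per minute
*per limb* (`pipeline_params()$cadence`). Each cue square shades at
~1.16 Hz and the two squares are 180 degrees out of phase, so the same-limb
movement cycle — the epoch used throughout — has period 60/70 s ≈ 0.857 s
and fundamental ≈ 1.17 Hz. Opposite limbs are half a cycle apart, and the
right arm extends together with the left leg (the stepper's handles and
pedals are coupled). Two consecutive cycles (one left plus one right
extension) form the full stride, period ≈ 1.71 s: structure that repeats
per stride but alternates per cycle appears at *half-integer* multiples of
the 1.17 Hz cycle rate, which is why connectivity fluctuation is examined
at 0.5, 1, 1.5 and 2 times the movement frequency.

# The synthetic source network

`source_network_spec()` defines a network of cortical source signals:

* **Intrinsic dynamics.** Each source is a stochastic second-order
  resonator: an AR(2) process with poles at centre frequency `center_freq`
  (defaults spread over theta-alpha, 6-12 Hz, one per source) and
  `bandwidth` 4 Hz, driven by unit-variance Gaussian innovations. A 4 Hz
  bandwidth gives a clearly damped, realistic ongoing rhythm (pole radius
  0.91 at 128 Hz) rather than a near-sinusoid.
* **Directed coupling.** Each edge adds `g(t) * x_from(t - lag)` to its
  receiver. The default network has seven sources labelled after the
  cortical areas a stepping study localizes (right/middle/left premotor and
  supplementary motor, anterior and posterior cingulate, parietal), with
  the right premotor source driving the network: four outgoing hub edges
  plus two secondary edges. Baseline gains are 0.15-0.25, coupling delay
  16 ms (2 samples at 128 Hz) — the scale of cortico-cortical conduction.
* **Stride-locked gain modulation.** `g(t) = g0 + depth * profile(phase)`,
  where [stride_profile()] is a periodic function of the movement-cycle
  phase with period two cycles: two *asymmetric* smooth bumps, one per
  alternating limb extension (widths 0.16 and 0.24 cycles). Asymmetry puts
  energy at all half-integer multiples of the cycle rate — the harmonic
  structure under test — without hard-coding any single spectral line; the
  bump widths keep the modulation slow relative to the 200 ms analysis
  window, consistent with connectivity fluctuation concentrated below
  ~3 Hz. Modulation depths default to 60-75% of the baseline gains.
* **Events.** `generate_events()` produces per-limb full-extension events
  at the cadence with optional Gaussian onset jitter (20 ms by default in
  the packaged dataset — the scale of human pacing variability).

Two structural decisions matter for everything downstream:

* **The recursion runs at the connectivity rate.** The network is defined
  at `fs_network = 128` Hz and, when 512 Hz output is requested, is
  Fourier-interpolated (ideal band-limited upsampling). A vector
  autoregression observed at a *lower* rate than it was generated is a
  VARMA process, not a VAR; defining the dynamics at the rate the MVAR
  stage uses keeps the ground truth an exact low-order VAR there, which is
  precisely the statistical structure the analysis assumes (and which the
  original recordings evidently had, since low orders passed the whiteness
  checks). `downsample()` (see below) inverts the interpolation exactly.
* **No additive observation noise on sources.** `background_frac` defaults
  to 0 for the same reason: a VAR plus white noise is again VARMA, and no
  finite AR order makes its residuals white. Broadband noise realism lives
  at the scalp instead: `mix_to_scalp()` adds white sensor noise and
  optional transient artifact bursts after projecting the sources through
  a (default random smooth) mixing matrix, which is what ICA is there to
  undo. Setting `background_frac > 0` is supported as a robustness probe.

**What the generator does not emulate:** 1/f broadband spectra, eye and
muscle artifact morphology (bursts are generic Hann-windowed noise),
volume-conduction head geometry, inter-subject variability, and any
event-locked change in *source power* (only coupling gains are modulated).
Passing tests therefore demonstrate that the estimators recover the
structure they target under their own assumptions — not that those
assumptions hold in any particular real recording.

# Preprocessing

Order of operations follows the analysis protocol: high-pass, artifact
rejection, common average reference at the acquisition rate (the spectral
branch); then downsample to 128 Hz and piecewise detrend (the connectivity
branch).

* `highpass_filter()`: zero-phase (forward-backward) 4th-order Butterworth,
  1 Hz cutoff. Zero-phase filtering everywhere: phase integrity matters for
  time-locked ERSP and MVAR.
* `reject_artifacts()`: the published criteria family with explicit,
  configurable cutoffs, since the study altered its thresholds without
  printing them. A channel is rejected when its sd exceeds 3 times the
  median channel sd or its best correlation with any other channel is
  below 0.4; windows (1 s scan) are excised when the cross-channel mean
  |z| exceeds 5 at any sample. Every rejection is logged with the
  criterion value that triggered it. Excision shifts later event onsets
  (`adjust_events_for_excision()`). Rejected channels are dropped, not
  interpolated.
* `downsample()`: Fourier-domain resampling — the spectrum is truncated at
  the new Nyquist and inverse-transformed at the reduced length. An ideal
  cutoff *at* Nyquist matters here: a steep IIR decimator with the usual
  0.8 x Nyquist corner leaves an attenuation notch below the new Nyquist,
  and broadband noise passed through it is serially correlated in a way no
  low-order AR can whiten, which would poison the order-selection stage.
* `piecewise_detrend()`: local straight-line fits in 330 ms windows every
  82.5 ms, blended with a triangular cross-fade (the description of the
  protocol leaves the blending open; the cross-fade avoids step
  discontinuities between windows). A globally linear trend maps to ~0;
  10 Hz oscillations pass within 10%. The detrender necessarily leaves
  small (|r| ~ 0.04) negative residual autocorrelations — every local
  detrend does — which the whiteness design below must accommodate.

# ICA and component clustering

`infomax_ica()` is the natural-gradient infomax rule (logistic
nonlinearity with bias) on PCA-sphered data, with learning-rate annealing
and blow-up restarts. It is the classical estimator for parsing EEG into
spatially fixed, temporally independent components; separation quality on
known mixtures is checked with the Amari index.

Equivalent-dipole fitting is out of scope (it needs a head model), so the
"percent variance explained by a single dipole" exclusion rule is replaced
by a reconstruction-quality analog: for component i, take the data minus
the back-projection of all *other* components; the quality score is the
top-eigenvalue share of that residual's channel covariance — 1 when the
component is perfectly spatially fixed. Components below
`ica_quality_threshold = 0.85` (the same numeric level as the dipole rule)
are flagged excluded.

`cluster_components()` runs k-means (multiple restarts, lowest
within-cluster SSQ) on per-component feature vectors. Feature blocks —
source coordinates (from the generator sidecar for synthetic data, or
topography centroids), scalp map, log spectrum — are standardized
column-wise and equally weighted, since no weights are published. `k`
defaults to the expected source count (7) and is configurable; no value of
k is published. The retention rule keeps clusters with components from at
least `min_subjects_per_cluster = 5` subjects: the Methods text excludes
clusters with "five or fewer" subjects (retain at 6+), but the Results and
the cluster table report clusters with *at least 5 of 10* subjects,
including one with exactly 5; the default follows the Results (>= 5) and
the threshold is configurable. Single-recording pipeline runs set it to 1,
where the subject rule is moot.

# Movement-cycle ERSP

`make_warped_epochs()` epochs one component activation from each full
extension of the reference limb to the next extension of the same limb.
Single-trial spectrograms use Morlet wavelets with cycles increasing
linearly from 3 (at 3 Hz) to 8 (at 80 Hz) on a 40-point log frequency grid,
200 output time points per cycle; the estimator is not printed in the
protocol, and this parameterization is the standard choice of the toolbox
family it used. Because cycle durations and within-cycle event timing
vary, each trial's time axis is piecewise-linearly warped so that the other
limbs' extension latencies land on the across-trial *median* latencies
(the warp target is unspecified in the protocol; the median is robust and
leaves typical trials nearly unwarped).

`compute_ersp()` averages log spectrograms over trials and subtracts each
frequency's time mean — so the pre-mask matrix has exactly 0 dB row means,
always. Significance is a within-trial time-resampling bootstrap: each
draw picks one random latency per trial and averages, building the null
spread of trial-mean log power at a baseline time point; cells inside the
two-tailed `alpha` interval are set to exactly 0 dB. Defaults:
`n_boot_ersp = 200` (200 is printed only for the connectivity bootstrap;
the ERSP count is configurable), `alpha = 0.05`, no multiple-comparison
correction — matching the original analysis, which applied none. On null
data the flagged fraction is approximately `alpha`; it is mildly
anti-conservative and varies by dataset (roughly 0.04-0.09 at 200 trials)
because neighbouring cells share wavelet support, so each frequency offers
few effective degrees of freedom.

`grand_mean_spectrum()` provides Welch-averaged log spectra on a
0.026 Hz grid (zero-padded FFT of length `round(fs / 0.026)`), and
`compare_conditions_wilcoxon()` the two-sided rank-sum band comparisons:
exact for <= 10 observations per group without ties, normal approximation
with tie correction otherwise. The sampling unit for the band tests is the
per-component band-mean log power within a condition, unpaired — the unit
of observation is not stated in the protocol and this is the recorded
interpretation. The theta band defaults to 4-8 Hz (the text's value; a
table header says 3-8 Hz); band edges are configurable.

# Sliding-window MVAR and DTF

`fit_mvar_vieira_morf()` is the multichannel lattice
(Levinson-Whittle-Wiggins-Robinson) recursion whose reflection
coefficients use the Vieira-Morf geometric-mean normalization of the
forward/backward partial covariances; multi-trial data are pooled by
accumulating those covariances across trials at each stage. On long
stationary data it agrees with least squares to 1e-2 at N = 1e4 (tested);
near-singular covariances are jittered and flagged. Windows are 200 ms
advanced every 54.7 ms with sample counts defined as
`round(duration * fs)` — 26 and 7 samples at 128 Hz — so rounding can
never drift across stages.

Stability is the companion-matrix spectral radius (< 1). The whiteness
battery (`test_whiteness()`) computes Ljung-Box and Box-Pierce portmanteau
statistics on each channel's residual autocorrelations and each pair's
cross-correlations (chi-square, `h - p` degrees of freedom, default
`h = 12`), McLeod-Li (Ljung-Box on squared residuals) per channel, and an
ACF-bound check whose critical exceedance count is exact binomial (the
normal approximation is badly discrete at 12 lags). Each test type passes
at a Bonferroni-corrected `alpha` across series; the overall flag requires
all four.

`select_model_order()` searches candidates 1..10 in ascending order
(orders 1-3 sufficed in the original analysis) and returns the smallest
candidate that is stable in every window and passes whiteness in at least
70% of windows, alongside the AIC/SBC/HQ table
(`ln det Sigma + penalty`, with the pooled residual count as N). Two
deliberate calibration choices:

* The per-window battery uses the residuals of a fixed number of trials
  (24, about 550 samples). A portmanteau test fed an ever-growing N will
  eventually reject *any* realizable pipeline's output, because filtering
  and detrending leave benign ~0.04 correlations; capping N fixes the
  detectable-correlation floor at ~1.96/sqrt(N) ≈ 0.08, above the artifact
  floor and far below genuine lag-misfit correlations (0.3+), and makes
  the selected order independent of recording length.
* The 70% window-majority rule reflects the battery's realized false-alarm
  rate (10-20% per window at the artifact floor, with the four tests run
  at `alpha/4` each): an adequate order passes in most windows, a misfit
  order in essentially none, so any threshold in a wide band separates
  them; 0.7 sits in the middle of that band.

`compute_dtf()` evaluates `A(f) = I - sum_k A_k exp(-i 2 pi f k / fs)`,
`H = A(f)^{-1}`, and the normalized DTF
`|H_ij| / sqrt(sum_m |H_im|^2)` — the standard row (inflow) normalization
including the diagonal, which the protocol's citation defines and whose
values lie in [0,1] as the published colour scales imply. The
normalization identity `sum_j DTF^2 = 1` is tested exactly.

`sliding_window_dtf()` applies this per window. For epoched input the
significance of connectivity *fluctuations* uses a trial-resampling
bootstrap of each (pair, frequency, window) value's deviation from its own
time average, masked where the two-sided interval covers zero. Raw DTF is
non-negative, so a zero-value null would be degenerate; the
deviation-from-time-mean null is the recorded interpretation of
"significance of the connectivity fluctuations" (plain percentile
intervals remain available by reading `values` directly). Trials are the
resampling unit, and trials are pooled (ensemble-style) within windows —
both unstated in the protocol, both the convention of the toolbox family
it used. Epoching for MVAR takes a fixed sample count from each epoch
onset (`resample = FALSE`): rescaling each trial's time axis would perturb
the sample-exact lag structure autoregression depends on.

# Network statistics

`suprathreshold_pairs()` pools the per-pair/per-condition maximum
connectivity values and flags combinations at least one standard deviation
(sample, n-1 — the pooled tables are small) above the pooled mean.

`fluctuation_spectrum()` quantifies how fast connectivity changes: each
(pair, frequency) connectivity-over-time series is mean-removed, cut into
128-sample zero-padded windows, FFT'd, and the squared magnitudes are
averaged over windows, frequencies and pairs. The series is sampled at the
window-step rate 128/7 ≈ 18.29 Hz, so its Nyquist is ≈ 9.14 Hz; the
protocol reports "0 to 18 Hz", which is not estimable from a 18.29 Hz
step rate, so the implementation reports up to the Nyquist and notes that
all harmonics of interest lie below 3 Hz. The time mean is removed because
the quantity of interest is fluctuation; otherwise the 0 Hz term dominates
the average. Raw (unmasked) connectivity enters the FFT — whether the
original analysis used masked values is not stated.

`detect_harmonic_peaks()` reports local maxima within one grid bin
(18.29/128 ≈ 0.143 Hz) of each requested multiple of the movement
frequency, plus the globally dominant non-DC peak.

# Numerical conventions and degenerate inputs

Time is always seconds, sample indices 0-based, windows half-open; window
sample counts are `round(duration * fs)`. All stochastic operations take
integer seeds; equal seeds give byte-identical pipeline outputs
(`run_pipeline()` writes a manifest that is compared verbatim in the
tests). Delimited text I/O prints doubles at full precision, so
write-read round-trips are bit-exact; EDF is 16-bit and exact only to its
quantization step. Singular window covariances are jittered
(1e-10 x mean diagonal) and flagged `regularized`; `A(f)` singular at a
frequency skips that frequency with a warning; all-equal suprathreshold
tables warn and flag everything; empty event tables, single channels, too
few trials, and out-of-range cutoffs raise errors with the offending
quantity named.

# Problem sizes used by the tests and acceptance script

The packaged study condition is one 5-minute recording of the 7-source
network at 70 extensions/min (about 349 cycles), the duration of one
condition in the motivating design. The test suite exercises estimator
properties at reduced sizes (20-240 s, 2-4 channels) chosen so each block
answers its statistical question in seconds; Monte-Carlo assertions state
their tolerances next to the replication counts. The acceptance script
regenerates the full 5-minute condition from scratch, selects the model
order on stride-locked windows, computes the continuous sliding-window DTF
(about 5,500 windows) and its fluctuation spectrum, and runs the 200-epoch
ERSP null calibration.

# Known limitations

* The ERSP bootstrap is approximately calibrated; its realized
  false-positive fraction varies by dataset (see above).
* Single-trial 26-sample MVAR fits (the continuous sliding branch) are
  noisy and frequently unstable; the fluctuation analysis tolerates this —
  the modulation is coherent across windows while estimation noise is
  not — but per-window DTF values from that branch should not be
  interpreted individually.
* The whiteness battery's calibration is tied to the stated trial budget;
  feeding it arbitrarily large residual sets restores the textbook
  behaviour (reject everything slightly imperfect).
* Dipole fitting, head modelling and electrode geometry are out of scope;
  the clustering feature vector substitutes generator coordinates or
  topography centroids for dipole locations.
* The EDF reader/writer covers the minimal uniform-rate 16-bit subset this
  pipeline needs, not the full standard.
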