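#' Morlet wavelet spectrogram
#'
#' Complex Morlet wavelet transform of a single time series. The number of
#' wavelet cycles grows linearly with frequency (default 3 cycles at 3 Hz to
#' 8 cycles at 80 Hz), trading temporal precision at low frequencies for
#' spectral precision at high ones. Convolution is done in the frequency
#' domain over the whole series; each wavelet has unit energy so relative
#' power across time is scale-free.
#'
#' @param x Numeric vector (one channel or component activation).
#' @param fs Sampling rate (Hz).
#' @param freqs Analysis frequencies (Hz).
#' @param cycles Wavelet cycles per frequency (default: linear 3..8 over
#'   3..80 Hz, clamped to a minimum of 2).
#' @return A list: `power` (freq x samples matrix), `freqs`, `fs`.
#' @export
morlet_spectrogram <- function(x, fs,
                               freqs = exp(seq(log(3), log(80), length.out = 40)),
                               cycles = NULL) {
  if (!length(x)) stop("empty input")
  cycles <- cycles %||% pmax(2, 3 + (8 - 3) * (freqs - 3) / (80 - 3))
  N <- length(x)
  sigma_t <- cycles / (2 * pi * freqs)
  half <- ceiling(3 * max(sigma_t) * fs)
  nfft <- stats::nextn(N + 2 * half + 1, 2)
  Xf <- stats::fft(c(x, rep(0, nfft - N)))
  pow <- matrix(0, length(freqs), N)
  for (k in seq_along(freqs)) {
    h <- ceiling(3 * sigma_t[k] * fs)
    tt <- (-h:h) / fs
    w <- exp(-tt^2 / (2 * sigma_t[k]^2)) * exp(2i * pi * freqs[k] * tt)
    w <- w / sqrt(sum(abs(w)^2))
    wpad <- complex(length.out = nfft)
    wpad[1:(h + 1)] <- w[(h + 1):(2 * h + 1)]        # centre at index 1
    wpad[(nfft - h + 1):nfft] <- w[1:h]
    conv <- stats::fft(Xf * stats::fft(wpad), inverse = TRUE) / nfft
    pow[k, ] <- Mod(conv[1:N])^2
  }
  list(power = pow, freqs = freqs, fs = fs)
}

#' Movement-cycle epochs with linear time-warping
#'
#' Epochs run from one full extension of the reference limb to the next full
#' extension of the same limb. A single-trial log-power spectrogram is
#' computed for each epoch on a common relative time base (cycle fraction
#' 0..1, `n_times` points). Because cycle durations and within-cycle event
#' timing vary, each trial's time axis is then piecewise-linearly warped so
#' that the latencies of the other limbs' extension events map onto the
#' across-trial median latencies.
#'
#' @param activation Numeric vector: one component activation or channel.
#' @param fs Sampling rate of `activation` (Hz).
#' @param events An [event_table()].
#' @param ref_limb Reference limb defining the cycle; default `"right_arm"`
#'   if present, else the most frequent limb.
#' @param params A [pipeline_params()] (frequencies and output resolution).
#' @return An object of class `warped_trials`: `logpow` (freq x time x
#'   trial array, dB), `freqs`, `times` (cycle fraction), `anchors`
#'   (per-trial original anchor fractions), `targets` (median anchor
#'   fractions), `durations_s`, `ref_limb`.
#' @export
make_warped_epochs <- function(activation, fs, events, ref_limb = NULL,
                               params = pipeline_params()) {
  if (is.null(ref_limb)) {
    ref_limb <- if ("right_arm" %in% events$limb) "right_arm" else
      names(which.max(table(events$limb)))
  }
  ons <- limb_onsets(events, ref_limb)
  if (length(ons) < 2) stop("need at least two reference-limb events")
  n_tr <- length(ons) - 1L
  n_t <- params$ersp_times
  freqs <- params$ersp_freqs
  sg <- morlet_spectrogram(activation, fs, freqs)
  logp <- 10 * log10(pmax(sg$power, 1e-300))
  frac <- (seq_len(n_t) - 0.5) / n_t

  other <- setdiff(intersect(unique(events$limb), limb_labels()), ref_limb)
  anchors <- matrix(NA_real_, n_tr, length(other),
                    dimnames = list(NULL, other))
  raw <- array(NA_real_, c(length(freqs), n_t, n_tr))
  for (k in seq_len(n_tr)) {
    t0 <- ons[k]; t1 <- ons[k + 1L]
    tq <- t0 + frac * (t1 - t0)
    idx <- tq * fs + 1                      # fractional sample position
    i0 <- pmax(1L, pmin(length(activation) - 1L, floor(idx)))
    wgt <- idx - i0
    raw[, , k] <- logp[, i0, drop = FALSE] * rep(1 - wgt, each = length(freqs)) +
      logp[, i0 + 1L, drop = FALSE] * rep(wgt, each = length(freqs))
    for (lb in other) {
      e <- limb_onsets(events, lb)
      inside <- e[e >= t0 & e < t1]
      if (length(inside) == 1L) anchors[k, lb] <- (inside - t0) / (t1 - t0)
    }
  }
  use <- colSums(!is.na(anchors)) == n_tr    # anchor limbs seen in every trial
  anchors <- anchors[, use, drop = FALSE]
  targets <- apply(anchors, 2, stats::median)
  out <- raw
  if (length(targets)) {
    ordt <- order(targets)
    targets <- targets[ordt]
    anchors <- anchors[, ordt, drop = FALSE]
    for (k in seq_len(n_tr)) {
      # sample original fractions at the inverse warp of the common grid
      u <- stats::approx(x = c(0, targets, 1), y = c(0, anchors[k, ], 1),
                         xout = frac, rule = 2)$y
      pos <- u * n_t + 0.5                   # back to fractional column index
      j0 <- pmax(1L, pmin(n_t - 1L, floor(pos)))
      wj <- pos - j0
      out[, , k] <- raw[, j0, k] * rep(1 - wj, each = length(freqs)) +
        raw[, j0 + 1L, k] * rep(wj, each = length(freqs))
    }
  }
  structure(list(logpow = out, freqs = freqs, times = frac,
                 anchors = anchors, targets = targets,
                 durations_s = diff(ons), ref_limb = ref_limb),
            class = "warped_trials")
}

#' Event-related spectral perturbation with bootstrap mask
#'
#' Averages single-trial log spectrograms over trials, subtracts each
#' frequency's mean over time (the within-epoch log baseline), and masks
#' cells whose trial-average does not differ from the baseline distribution.
#' The null distribution is built by resampling: each draw picks one random
#' time point per trial and averages over trials, giving the spread of
#' trial-mean log power expected at a baseline time point. Cells inside the
#' two-tailed `alpha` percentile interval are set to exactly 0 dB.
#'
#' @param trials A `warped_trials` object (or a freq x time x trial array
#'   of log power in dB).
#' @param alpha Two-tailed significance level.
#' @param n_boot Number of bootstrap draws.
#' @param seed Integer seed.
#' @param min_trials Minimum trials required for a meaningful bootstrap.
#' @return An object of class `ersp_result`: `ersp` (masked dB matrix),
#'   `premask` (baseline-subtracted, unmasked), `mask` (logical), `baseline`
#'   (per-frequency dB), `alpha`, `n_boot`, `n_trials`, `freqs`, `times`.
#' @export
compute_ersp <- function(trials, alpha = 0.05, n_boot = 200, seed = 1,
                         min_trials = 8) {
  arr <- if (inherits(trials, "warped_trials")) trials$logpow else trials
  n_tr <- dim(arr)[3]
  if (n_tr < min_trials) {
    stop(sprintf("only %d trials; need >= %d for the bootstrap", n_tr, min_trials))
  }
  nf <- dim(arr)[1]; nt <- dim(arr)[2]
  mean_tf <- apply(arr, c(1, 2), mean)
  baseline <- rowMeans(mean_tf)
  premask <- mean_tf - baseline
  set.seed(seed)
  null <- matrix(0, nf, n_boot)
  for (b in seq_len(n_boot)) {
    cols <- sample.int(nt, n_tr, replace = TRUE)
    acc <- matrix(0, nf, n_tr)
    for (k in seq_len(n_tr)) acc[, k] <- arr[, cols[k], k]
    null[, b] <- rowMeans(acc)
  }
  lo <- apply(null, 1, stats::quantile, probs = alpha / 2, names = FALSE)
  hi <- apply(null, 1, stats::quantile, probs = 1 - alpha / 2, names = FALSE)
  mask <- mean_tf < lo | mean_tf > hi
  ersp <- premask
  ersp[!mask] <- 0
  structure(list(ersp = ersp, premask = premask, mask = mask,
                 baseline = baseline, alpha = alpha, n_boot = n_boot,
                 n_trials = n_tr,
                 freqs = if (inherits(trials, "warped_trials")) trials$freqs else NULL,
                 times = if (inherits(trials, "warped_trials")) trials$times else NULL),
            class = "ersp_result")
}

#' @export
print.ersp_result <- function(x, ...) {
  cat(sprintf("<ersp_result> %d x %d cells, %d trials, %.1f%% significant (alpha %.2f)\n",
              nrow(x$ersp), ncol(x$ersp), x$n_trials,
              100 * mean(x$mask), x$alpha))
  invisible(x)
}

#' Grand-mean log power spectrum
#'
#' Welch-style averaged log power spectrum on a fine fixed grid: Hann
#' windowed segments with 50% overlap are zero-padded to
#' `round(fs / resolution)` points, so the grid spacing equals `resolution`
#' (up to one-sample rounding of the FFT length).
#'
#' @param x Numeric vector (component activation).
#' @param fs Sampling rate (Hz).
#' @param resolution Output grid spacing (Hz).
#' @param seg_s Segment length (s), shortened to the data length if needed.
#' @return A list: `freq` (Hz), `log_power` (dB), `resolution` (achieved
#'   spacing, Hz), `n_segments`.
#' @export
grand_mean_spectrum <- function(x, fs, resolution = 0.026, seg_s = 4) {
  if (!length(x)) stop("empty input")
  nfft <- round(fs / resolution)
  seg <- min(length(x), round(seg_s * fs))
  step <- max(1L, seg %/% 2L)
  starts <- seq(1L, length(x) - seg + 1L, by = step)
  win <- 0.5 - 0.5 * cos(2 * pi * seq_len(seg) / (seg + 1))
  acc <- numeric(nfft)
  for (s in starts) {
    xd <- x[s:(s + seg - 1L)] * win
    acc <- acc + Mod(stats::fft(c(xd, rep(0, nfft - seg))))^2
  }
  acc <- acc / length(starts)
  nkeep <- nfft %/% 2L + 1L
  list(freq = (seq_len(nkeep) - 1) * fs / nfft,
       log_power = 10 * log10(pmax(acc[seq_len(nkeep)], 1e-300)),
       resolution = fs / nfft,
       n_segments = length(starts))
}

#' Mean log power in a frequency band
#'
#' @param spectrum Output of [grand_mean_spectrum()].
#' @param band Numeric length-2 vector of band edges (Hz).
#' @return Mean of `log_power` over grid points in `[band[1], band[2])`.
#' @export
band_mean_log_power <- function(spectrum, band) {
  sel <- spectrum$freq >= band[1] & spectrum$freq < band[2]
  if (!any(sel)) stop("band outside the spectrum grid")
  mean(spectrum$log_power[sel])
}

#' Wilcoxon rank-sum comparison of two condition samples
#'
#' Two-sided rank-sum test of per-component band power between two
#' conditions: exact when both samples have at most 10 observations and no
#' ties occur, otherwise the normal approximation with tie correction.
#'
#' @param samples_a,samples_b Numeric vectors (e.g. per-component band-mean
#'   log power under two conditions).
#' @param band Optional band label for the report.
#' @param edges Optional numeric band edges (Hz) for the report.
#' @return An object of class `band_comparison`: `band`, `edges`,
#'   `statistic` (rank-sum W), `p_value`, `direction` (`"A>B"`, `"B>A"` or
#'   `"A=B"`, from sample medians), `n_a`, `n_b`, `exact`.
#' @export
compare_conditions_wilcoxon <- function(samples_a, samples_b,
                                        band = NA_character_, edges = NULL) {
  if (!length(samples_a) || !length(samples_b)) stop("empty sample")
  ties <- anyDuplicated(c(samples_a, samples_b)) > 0
  exact <- length(samples_a) <= 10 && length(samples_b) <= 10 && !ties
  wt <- suppressWarnings(
    stats::wilcox.test(samples_a, samples_b, exact = exact, correct = !exact))
  da <- stats::median(samples_a); db <- stats::median(samples_b)
  direction <- if (da > db) "A>B" else if (db > da) "B>A" else "A=B"
  structure(list(band = band, edges = edges,
                 statistic = unname(wt$statistic), p_value = wt$p.value,
                 direction = direction,
                 n_a = length(samples_a), n_b = length(samples_b),
                 exact = exact),
            class = "band_comparison")
}

#' @export
print.band_comparison <- function(x, ...) {
  cat(sprintf("<band_comparison> %s: W = %g, p = %.3g, %s (n = %d/%d, %s)\n",
              x$band, x$statistic, x$p_value, x$direction, x$n_a, x$n_b,
              if (x$exact) "exact" else "normal approx."))
  invisible(x)
}
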