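#' Suprathreshold connectivity pairs
#'
#' Implements the suprathreshold rule: pool the maximum connectivity values
#' of all pair/condition combinations, and flag the combinations whose
#' maximum is at least one (sample, n-1 denominator) standard deviation
#' above the pooled mean.
#'
#' @param max_table `data.frame` with columns `pair`, `condition` and
#'   `max_dtf` (one row per pair/condition combination), or a bare numeric
#'   vector of maxima.
#' @return An object of class `suprathreshold_report`: `table` (input plus
#'   `flagged`), `mean`, `sd`, `threshold`.
#' @export
suprathreshold_pairs <- function(max_table) {
  if (is.numeric(max_table)) {
    max_table <- data.frame(pair = sprintf("p%02d", seq_along(max_table)),
                            condition = NA_character_,
                            max_dtf = as.numeric(max_table))
  }
  if (nrow(max_table) < 2) stop("need at least 2 pair/condition entries")
  x <- max_table$max_dtf
  mu <- mean(x)
  sdv <- stats::sd(x)
  thr <- mu + sdv
  if (sdv == 0) warning("all maxima identical; threshold degenerates to the mean")
  max_table$flagged <- x >= thr
  structure(list(table = max_table, mean = mu, sd = sdv, threshold = thr),
            class = "suprathreshold_report")
}

#' @export
print.suprathreshold_report <- function(x, ...) {
  cat(sprintf("<suprathreshold_report> mean %.4g + sd %.4g = threshold %.4g; %d/%d flagged\n",
              x$mean, x$sd, x$threshold, sum(x$table$flagged), nrow(x$table)))
  invisible(x)
}

#' Per-pair maxima of a DTF tensor
#'
#' Maximum connectivity over frequency and time for every directed pair
#' (off-diagonal), the input to [suprathreshold_pairs()].
#'
#' @param dtf A `dtf_tensor`.
#' @param labels Optional channel labels.
#' @param condition Condition tag to attach.
#' @return `data.frame` with columns `pair`, `condition`, `max_dtf`.
#' @export
dtf_pair_maxima <- function(dtf, labels = NULL, condition = NA_character_) {
  M <- dim(dtf$values)[1]
  labels <- labels %||% sprintf("s%02d", seq_len(M))
  rows <- list()
  for (i in seq_len(M)) for (j in seq_len(M)) {
    if (i == j) next
    rows[[length(rows) + 1]] <- data.frame(
      pair = sprintf("%s<-%s", labels[i], labels[j]),
      condition = condition,
      max_dtf = max(dtf$values[i, j, , ], na.rm = TRUE))
  }
  do.call(rbind, rows)
}

#' Fluctuation spectrum of connectivity over time
#'
#' Quantifies how fast connectivity changes: for each connectivity series
#' (one per pair and spectral frequency), the time mean is removed, the
#' series is cut into consecutive `nfft`-sample windows (zero-padded), and
#' the squared FFT magnitude is averaged over windows; the resulting power
#' spectra are then averaged over spectral frequencies and pairs. The
#' frequency axis is the window-step rate divided over `nfft` bins,
#' reported up to `min(step-rate Nyquist, fmax)`.
#'
#' @param dtf_time_series A `dtf_tensor`, or a numeric matrix whose rows are
#'   connectivity-over-time series, or a single numeric series.
#' @param step_rate Sampling rate of the series (Hz); for a `dtf_tensor`
#'   this is derived from its window step.
#' @param nfft Zero-padded FFT length.
#' @param fmax Upper frequency limit of the report (Hz).
#' @param exclude_diagonal For tensors, drop self-connections (default TRUE).
#' @return Object of class `fluctuation_spectrum`: `freq` (Hz), `power`,
#'   `step_rate`, `nfft`, `n_series`.
#' @export
fluctuation_spectrum <- function(dtf_time_series, step_rate = NULL,
                                 nfft = 128, fmax = 18,
                                 exclude_diagonal = TRUE) {
  if (inherits(dtf_time_series, "dtf_tensor")) {
    x <- dtf_time_series
    step_rate <- x$fs / x$step_samples
    d <- dim(x$values)
    keep <- which(if (exclude_diagonal)
      row(diag(d[1])) != col(diag(d[1])) else matrix(TRUE, d[1], d[2]))
    S <- matrix(NA_real_, length(keep) * d[3], d[4])
    r <- 1
    for (f in seq_len(d[3])) {
      sl <- matrix(x$values[, , f, ], d[1] * d[2], d[4])
      S[r:(r + length(keep) - 1), ] <- sl[keep, , drop = FALSE]
      r <- r + length(keep)
    }
  } else if (is.matrix(dtf_time_series)) {
    S <- dtf_time_series
  } else {
    S <- matrix(dtf_time_series, nrow = 1)
  }
  if (is.null(step_rate)) stop("step_rate required for plain series input")
  if (ncol(S) < 2) stop("connectivity series must have length >= 2")
  S <- S[stats::complete.cases(S), , drop = FALSE]
  n_seg <- max(1L, ncol(S) %/% nfft)
  acc <- numeric(nfft)
  for (r in seq_len(nrow(S))) {
    s <- S[r, ] - mean(S[r, ])
    for (g in seq_len(n_seg)) {
      seg <- s[((g - 1) * nfft + 1):min(g * nfft, length(s))]
      acc <- acc + Mod(stats::fft(c(seg, rep(0, nfft - length(seg)))))^2
    }
  }
  acc <- acc / (nrow(S) * n_seg)
  nyq <- step_rate / 2
  nk <- nfft %/% 2 + 1
  freq <- (seq_len(nk) - 1) * step_rate / nfft
  sel <- freq <= min(nyq, fmax) + 1e-12
  structure(list(freq = freq[sel], power = acc[seq_len(nk)][sel],
                 step_rate = step_rate, nfft = nfft, n_series = nrow(S)),
            class = "fluctuation_spectrum")
}

#' @export
print.fluctuation_spectrum <- function(x, ...) {
  cat(sprintf("<fluctuation_spectrum> %d series, grid 0..%.2f Hz by %.4f Hz\n",
              x$n_series, max(x$freq), x$freq[2] - x$freq[1]))
  invisible(x)
}

#' Detect harmonic peaks in a fluctuation spectrum
#'
#' Searches for local maxima within one grid bin of each requested multiple
#' of the movement frequency `f0`, and reports the globally dominant peak.
#'
#' @param spectrum A `fluctuation_spectrum` (or list with `freq`, `power`).
#' @param f0 Movement frequency (Hz), > 0.
#' @param multiples Harmonic multiples to search.
#' @return List of class `harmonic_peaks`: `peaks` (`data.frame` with
#'   `multiple`, `target_hz`, `freq`, `power`; one row per detected
#'   harmonic) and `dominant` (frequency/power of the tallest non-DC local
#'   maximum, or `NA` if none).
#' @export
detect_harmonic_peaks <- function(spectrum, f0,
                                  multiples = c(0.5, 1, 1.5, 2)) {
  if (f0 <= 0) stop("f0 must be positive")
  fr <- spectrum$freq; pw <- spectrum$power
  if (!length(fr)) stop("empty spectrum")
  df <- fr[2] - fr[1]
  if (any(multiples * f0 > max(fr) + df)) {
    stop("requested multiple lies outside the frequency grid")
  }
  n <- length(pw)
  is_peak <- c(FALSE, pw[2:(n - 1)] > pw[1:(n - 2)] &
                 pw[2:(n - 1)] > pw[3:n], FALSE)
  rows <- list()
  for (m in multiples) {
    tgt <- m * f0
    bin <- which.min(abs(fr - tgt))
    cand <- intersect(max(1, bin - 1):min(n, bin + 1), which(is_peak))
    if (length(cand)) {
      best <- cand[which.max(pw[cand])]
      rows[[length(rows) + 1]] <- data.frame(
        multiple = m, target_hz = tgt, freq = fr[best], power = pw[best])
    }
  }
  peaks <- if (length(rows)) do.call(rbind, rows) else
    data.frame(multiple = numeric(0), target_hz = numeric(0),
               freq = numeric(0), power = numeric(0))
  dom_idx <- which(is_peak & fr > 0)
  dominant <- if (length(dom_idx)) {
    i <- dom_idx[which.max(pw[dom_idx])]
    list(freq = fr[i], power = pw[i])
  } else list(freq = NA_real_, power = NA_real_)
  structure(list(peaks = peaks, dominant = dominant, f0 = f0),
            class = "harmonic_peaks")
}

#' @export
print.harmonic_peaks <- function(x, ...) {
  cat(sprintf("<harmonic_peaks> f0 = %.3f Hz; dominant peak at %.3f Hz\n",
              x$f0, x$dominant$freq))
  if (nrow(x$peaks)) print(x$peaks, digits = 4)
  invisible(x)
}
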