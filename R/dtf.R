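#' Directed transfer function of one MVAR model
#'
#' Computes `A(f) = I - sum_k A_k exp(-i 2 pi f k / fs)`, the transfer
#' matrix `H(f) = A(f)^-1`, and the normalized DTF
#' `DTF(i<-j, f) = |H_ij(f)| / sqrt(sum_m |H_im(f)|^2)` (inflow
#' normalization including the diagonal), so that for every sink `i` and
#' frequency the squared DTF values over sources sum to one.
#'
#' @param model An `mvar_model` (must be stable; a warning is issued
#'   otherwise).
#' @param freq_grid Frequencies (Hz) at which to evaluate.
#' @param fs Sampling rate (Hz); defaults to the rate stored on the model.
#' @return An array `dtf[sink, source, frequency]` in `[0, 1]` with
#'   attribute `"freqs"`. Frequencies where `A(f)` is numerically singular
#'   are reported as `NA` with a warning.
#' @export
compute_dtf <- function(model, freq_grid, fs = model$fs) {
  if (is.na(fs)) stop("sampling rate required (set fs)")
  M <- model$M; p <- model$order
  st <- check_stability(model)
  if (!st$stable) {
    warning(sprintf("model is unstable (spectral radius %.3f); DTF may be invalid",
                    st$spectral_radius))
  }
  out <- array(NA_real_, c(M, M, length(freq_grid)))
  for (k in seq_along(freq_grid)) {
    Af <- diag(M) + 0i
    for (l in seq_len(p)) {
      Af <- Af - model$A[, , l] * exp(-2i * pi * freq_grid[k] * l / fs)
    }
    H <- tryCatch(solve(Af), error = function(e) NULL)
    if (is.null(H)) {
      warning(sprintf("A(f) singular at %.3g Hz; frequency skipped", freq_grid[k]))
      next
    }
    aH <- Mod(H)
    out[, , k] <- aH / sqrt(rowSums(aH^2))
  }
  attr(out, "freqs") <- freq_grid
  out
}

#' Cut a recording into equal-length movement-cycle epochs
#'
#' Epochs span `cycles` consecutive full extensions of the reference limb
#' (1 = the movement cycle, 2 = the full left/right stride). Each epoch is
#' linearly resampled to the median epoch length so trials can be pooled
#' sample-by-sample.
#'
#' @param rec A [recording].
#' @param events An [event_table()].
#' @param ref_limb Reference limb (default as in [make_warped_epochs()]).
#' @param cycles Reference-limb cycles per epoch.
#' @param resample If `TRUE`, linearly rescale each epoch's time axis to the
#'   common length (cycle-fraction alignment). If `FALSE` (default), take
#'   the common length verbatim from each epoch onset: sample-exact lag
#'   structure is preserved, which autoregressive fitting relies on.
#' @return An M x L x n_trials array with attributes `fs`, `epoch_s`
#'   (median epoch duration) and `ref_limb`.
#' @export
epoch_recording <- function(rec, events, ref_limb = NULL, cycles = 1,
                            resample = FALSE) {
  if (is.null(ref_limb)) {
    ref_limb <- if ("right_arm" %in% events$limb) "right_arm" else
      names(which.max(table(events$limb)))
  }
  ons <- limb_onsets(events, ref_limb)
  starts <- ons[seq(1, length(ons) - cycles, by = cycles)]
  ends <- ons[seq(1 + cycles, length(ons), by = cycles)]
  ends <- ends[seq_along(starts)]
  keep <- !is.na(ends) & ends * rec$fs <= ncol(rec$data)
  starts <- starts[keep]; ends <- ends[keep]
  if (!length(starts)) stop("no complete epochs inside the recording")
  L <- round(stats::median(ends - starts) * rec$fs)
  M <- nrow(rec$data)
  if (!resample) {
    i0 <- round(starts * rec$fs) + 1L
    ok <- i0 + L - 1L <= ncol(rec$data)
    i0 <- i0[ok]
    out <- array(0, c(M, L, length(i0)))
    for (k in seq_along(i0)) {
      out[, , k] <- rec$data[, i0[k]:(i0[k] + L - 1L), drop = FALSE]
    }
  } else {
    out <- array(0, c(M, L, length(starts)))
    for (k in seq_along(starts)) {
      pos <- (starts[k] + (seq_len(L) - 0.5) / L * (ends[k] - starts[k])) * rec$fs + 1
      i0 <- pmax(1L, pmin(ncol(rec$data) - 1L, floor(pos)))
      w <- pos - i0
      out[, , k] <- rec$data[, i0, drop = FALSE] * rep(1 - w, each = M) +
        rec$data[, i0 + 1L, drop = FALSE] * rep(w, each = M)
    }
  }
  attr(out, "fs") <- rec$fs
  attr(out, "epoch_s") <- L / rec$fs
  attr(out, "ref_limb") <- ref_limb
  out
}

#' Sliding-window DTF with bootstrap fluctuation mask
#'
#' Fits one Vieira-Morf MVAR model per 200 ms window (advanced every
#' 54.7 ms; sample counts are `round(duration * fs)`), pooling trials when
#' the input is epoched, and evaluates the DTF on `freqs`. With epoched
#' input and `n_boot > 0`, the significance of the connectivity
#' *fluctuations* is assessed by a trial-resampling bootstrap of each
#' (pair, frequency, window) value's deviation from its own time average:
#' a cell is significant when the two-sided `(1 - alpha)` bootstrap interval
#' of that deviation excludes zero. Raw DTF is non-negative, so a
#' zero-deviation null (rather than a zero-value null) is the meaningful
#' reference.
#'
#' @param data M x N matrix (continuous recording: single realization per
#'   window, no bootstrap) or M x L x trials array from
#'   [epoch_recording()].
#' @param fs Sampling rate (Hz).
#' @param order MVAR model order.
#' @param params A [pipeline_params()] (window/step durations, DTF grid).
#' @param freqs DTF frequency grid (Hz); default `params$dtf_freqs`.
#' @param n_boot Bootstrap resamples (0 disables masking).
#' @param alpha Two-sided level of the bootstrap interval.
#' @param seed Integer seed for the bootstrap.
#' @return An object of class `dtf_tensor`: `values` (sink x source x
#'   frequency x window), `deviation` (values minus their time mean),
#'   `mask` (logical, `NULL` without bootstrap), `freqs`, `times` (window
#'   centres, s), `order`, `n_boot`, `alpha`, `stable_frac`.
#' @export
sliding_window_dtf <- function(data, fs, order, params = pipeline_params(),
                               freqs = params$dtf_freqs,
                               n_boot = 0, alpha = params$alpha, seed = 1) {
  epoched <- is.array(data) && length(dim(data)) == 3L
  M <- dim(data)[1]
  N <- if (epoched) dim(data)[2] else ncol(data)
  wl <- round(params$mvar_window * fs)
  st <- round(params$mvar_step * fs)
  if (wl > N) stop("MVAR window longer than the epoch")
  n_win <- floor((N - wl) / st) + 1L
  starts <- (seq_len(n_win) - 1L) * st + 1L
  win_data <- function(d, w) {
    idx <- starts[w]:(starts[w] + wl - 1L)
    if (epoched) d[, idx, , drop = FALSE] else d[, idx, drop = FALSE]
  }
  nf <- length(freqs)
  vals <- array(NA_real_, c(M, M, nf, n_win))
  stable <- logical(n_win)
  for (w in seq_len(n_win)) {
    fit <- fit_mvar_vieira_morf(win_data(data, w), order, fs = fs,
                                center_time = (starts[w] - 1 + wl / 2) / fs)
    stable[w] <- check_stability(fit)$stable
    vals[, , , w] <- suppressWarnings(compute_dtf(fit, freqs, fs))
  }
  tmean <- apply(vals, c(1, 2, 3), mean)
  dev <- vals - array(tmean, dim(vals))
  mask <- NULL
  if (epoched && n_boot > 0 && dim(data)[3] >= 2) {
    set.seed(seed)
    n_tr <- dim(data)[3]
    lo <- array(Inf, dim(vals)); hi <- array(-Inf, dim(vals))
    devs <- array(NA_real_, c(length(vals), n_boot))
    for (b in seq_len(n_boot)) {
      pick <- sample.int(n_tr, n_tr, replace = TRUE)
      vb <- array(NA_real_, c(M, M, nf, n_win))
      for (w in seq_len(n_win)) {
        fit <- fit_mvar_vieira_morf(win_data(data, w)[, , pick, drop = FALSE],
                                    order, fs = fs)
        vb[, , , w] <- suppressWarnings(compute_dtf(fit, freqs, fs))
      }
      tb <- apply(vb, c(1, 2, 3), mean)
      devs[, b] <- as.vector(vb - array(tb, dim(vb)))
    }
    qs <- apply(devs, 1, stats::quantile,
                probs = c(alpha / 2, 1 - alpha / 2), names = FALSE,
                na.rm = TRUE)
    mask <- array(qs[1, ] > 0 | qs[2, ] < 0, dim(vals))
  }
  structure(list(values = vals, deviation = dev, mask = mask,
                 freqs = freqs, times = (starts - 1 + wl / 2) / fs,
                 order = order, n_boot = if (epoched) n_boot else 0,
                 alpha = alpha, stable_frac = mean(stable), fs = fs,
                 window_samples = wl, step_samples = st),
            class = "dtf_tensor")
}

#' @export
print.dtf_tensor <- function(x, ...) {
  cat(sprintf("<dtf_tensor> %d x %d pairs, %d freqs, %d windows (order %d, %.0f%% stable)\n",
              dim(x$values)[1], dim(x$values)[2], length(x$freqs),
              dim(x$values)[4], x$order, 100 * x$stable_frac))
  invisible(x)
}

#' Long-format table of a DTF tensor
#'
#' @param dtf A `dtf_tensor`.
#' @param labels Optional channel labels.
#' @return `data.frame` with columns sink, source, freq, time, value,
#'   significant.
#' @export
dtf_long <- function(dtf, labels = NULL) {
  d <- dim(dtf$values)
  labels <- labels %||% sprintf("s%02d", seq_len(d[1]))
  g <- expand.grid(sink = seq_len(d[1]), source = seq_len(d[2]),
                   freq = dtf$freqs, time = dtf$times,
                   KEEP.OUT.ATTRS = FALSE)
  data.frame(sink = labels[g$sink], source = labels[g$source],
             freq = g$freq, time = g$time,
             value = as.vector(dtf$values),
             significant = if (is.null(dtf$mask)) NA else as.vector(dtf$mask))
}
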