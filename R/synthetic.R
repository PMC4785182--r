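#' Generate paced full-extension events
#'
#' Events emulate visually paced stepping: each limb produces full-extension
#' events at `cadence_per_min` per minute (period `60/cadence` s). Paired
#' limbs move 180 degrees out of phase (left/right arm, left/right leg), and
#' the right arm extends together with the left leg, as on a coupled
#' recumbent stepper. Optional Gaussian jitter perturbs each onset
#' independently.
#'
#' @param cadence_per_min Full extensions per minute per limb (> 0).
#' @param duration_s Recording duration in seconds (>= 0).
#' @param limbs Character vector of limbs to generate (subset of
#'   [limb_labels()]).
#' @param phase_jitter_sd Standard deviation of per-onset Gaussian jitter (s),
#'   >= 0.
#' @param seed Optional integer seed (only used when jitter > 0).
#' @return An [event_table()].
#' @examples
#' ev <- generate_events(70, 60, c("left_arm", "right_arm"))
#' nrow(ev)  # 140: 70 per limb
#' @export
generate_events <- function(cadence_per_min = 70, duration_s = 300,
                            limbs = limb_labels(), phase_jitter_sd = 0,
                            seed = NULL) {
  if (cadence_per_min <= 0) stop("cadence must be positive")
  if (duration_s < 0) stop("duration must be non-negative")
  if (phase_jitter_sd < 0) stop("negative jitter sd")
  if (!is.null(seed)) set.seed(seed)
  period <- 60 / cadence_per_min
  # phase offsets in s: right arm & left leg together, opposite pair at T/2
  offsets <- c(right_arm = 0, left_leg = 0,
               left_arm = period / 2, right_leg = period / 2)
  onset <- numeric(0); limb <- character(0)
  for (lb in limbs) {
    t0 <- offsets[[lb]]
    if (duration_s <= t0) next
    # onsets strictly inside [0, duration): robust to floating-point edge hits
    k_max <- floor((duration_s - t0) / period - 1e-9)
    ons <- t0 + period * (0:max(0, k_max))
    ons <- ons[ons < duration_s]
    if (phase_jitter_sd > 0) {
      ons <- ons + stats::rnorm(length(ons), 0, phase_jitter_sd)
      ons <- pmin(pmax(ons, 0), duration_s - 1e-9)
    }
    onset <- c(onset, ons)
    limb <- c(limb, rep(lb, length(ons)))
  }
  event_table(onset, limb)
}

#' Stride modulation profile
#'
#' Periodic modulation of coupling gain as a function of movement-cycle
#' phase. The profile has period two cycles of the reference limb and
#' consists of two asymmetric smooth bumps (one per alternating limb
#' extension), so its Fourier series carries energy at 0.5, 1, 1.5 and 2
#' times the per-limb cadence. It is normalized to zero mean and unit
#' maximum absolute value over the period.
#'
#' @param u Cycle phase in units of reference-limb cycles (any real; the
#'   profile has period 2).
#' @return Numeric vector of modulation values in `[-1, 1]`.
#' @export
stride_profile <- function(u) {
  v <- u %% 2
  # two asymmetric wrapped-Gaussian bumps, centres and widths in cycles
  bump <- function(v, centre, width, amp) {
    d <- (v - centre + 1) %% 2 - 1
    amp * exp(-0.5 * (d / width)^2)
  }
  raw <- bump(v, 0.30, 0.16, 1.0) + bump(v, 1.25, 0.24, 0.65)
  # zero-mean, max-abs-one normalization (constants from the period integral)
  grid <- seq(0, 2, length.out = 4096L)[-4096L]
  rawg <- bump(grid, 0.30, 0.16, 1.0) + bump(grid, 1.25, 0.24, 0.65)
  ctr <- raw - mean(rawg)
  ctr / max(abs(rawg - mean(rawg)))
}

#' Specify a synthetic cortical source network
#'
#' Each source is a stochastic second-order resonator (an AR(2) process with
#' poles at the given centre frequency and bandwidth) driven by unit-variance
#' innovations. Directed coupling edges add a lagged, gain-scaled copy of the
#' sender to the receiver; each edge's gain is modulated around its baseline
#' by the [stride_profile()] evaluated at the movement-cycle phase:
#' `g(t) = g0 + depth * profile(phase(t) + phase_offset)`.
#'
#' The default network has seven sources, labelled after the cortical areas
#' a stepping study localizes (premotor/supplementary motor, cingulate,
#' parietal), with the right premotor source driving the network.
#'
#' @param n_sources Number of sources.
#' @param center_freq Per-source resonance frequency (Hz).
#' @param bandwidth Per-source resonance bandwidth (Hz); smaller = more
#'   oscillatory.
#' @param edges `data.frame` with columns `from`, `to` (source indices),
#'   `lag_s` (coupling delay, s), `g0` (baseline gain), `depth` (modulation
#'   depth), `phase` (profile offset in cycles).
#' @param innovation_sd Per-source innovation standard deviation.
#' @param background_frac Optional additive broadband background on each
#'   source, as a fraction of that source's intrinsic oscillation standard
#'   deviation. The default is 0: additive observation noise turns a vector
#'   autoregression into a VARMA process, destroying the low-order-MVAR
#'   adequacy that this analysis family assumes (and that the original
#'   recordings exhibited). Set it above 0 only to study robustness of the
#'   connectivity stages against that assumption being violated.
#' @param fs_network Rate (Hz) at which the network recursion is defined.
#'   Source dynamics are band-limited to `fs_network / 2`; requesting output
#'   at a higher rate interpolates. Defining the dynamics at the rate the
#'   connectivity analysis uses keeps the ground truth a genuine low-order
#'   vector autoregression at that rate.
#' @param cadence Extensions per minute of the paced movement.
#' @param labels Source labels.
#' @return A list of class `source_network_spec`.
#' @export
source_network_spec <- function(n_sources = 7,
                                center_freq = c(10, 9, 11, 6, 7, 8, 12)[seq_len(n_sources)],
                                bandwidth = rep(4, n_sources),
                                edges = default_edges(n_sources),
                                innovation_sd = rep(1, n_sources),
                                background_frac = 0,
                                fs_network = 128,
                                cadence = 70,
                                labels = default_source_labels(n_sources)) {
  spec <- structure(list(n_sources = n_sources,
                         center_freq = center_freq,
                         bandwidth = bandwidth,
                         edges = edges,
                         innovation_sd = rep_len(innovation_sd, n_sources),
                         background_frac = background_frac,
                         fs_network = fs_network,
                         cadence = cadence,
                         labels = labels),
                    class = "source_network_spec")
  if (nrow(edges) && any(edges$depth < 0)) stop("modulation depth must be >= 0")
  if (nrow(edges) && any(edges$lag_s <= 0)) stop("edge lags must be positive")
  spec
}

default_source_labels <- function(n) {
  base <- c("R_PMC_SMA", "M_PMC_SMA", "L_PMC_SMA", "M_ACC", "R_ACC",
            "M_PCC", "M_PAR")
  if (n <= length(base)) base[seq_len(n)] else sprintf("SRC%02d", seq_len(n))
}

default_edges <- function(n_sources = 7) {
  if (n_sources < 2) {
    return(data.frame(from = integer(0), to = integer(0), lag_s = numeric(0),
                      g0 = numeric(0), depth = numeric(0), phase = numeric(0)))
  }
  e <- data.frame(
    from  = c(1, 1, 1, 1, 5, 7),
    to    = c(2, 3, 4, 6, 6, 5),
    lag_s = 0.016,
    g0    = c(0.25, 0.25, 0.20, 0.20, 0.18, 0.15),
    depth = c(0.18, 0.18, 0.15, 0.15, 0.12, 0.10),
    phase = c(0.00, 0.25, 0.50, 0.10, 0.30, 0.60))
  e[e$from <= n_sources & e$to <= n_sources, , drop = FALSE]
}

# AR(2) coefficients of a resonator with pole radius set by bandwidth
resonator_coef <- function(f0, bw, fs) {
  r <- exp(-pi * bw / fs)
  c(2 * r * cos(2 * pi * f0 / fs), -r * r)
}

# time-averaged VAR coefficient blocks of a spec at rate fs
spec_mean_var <- function(spec, fs) {
  lags <- if (nrow(spec$edges)) pmax(1L, as.integer(round(spec$edges$lag_s * fs))) else integer(0)
  p <- max(2L, lags)
  M <- spec$n_sources
  A <- array(0, c(M, M, p))
  for (i in seq_len(M)) {
    a <- resonator_coef(spec$center_freq[i], spec$bandwidth[i], fs)
    A[i, i, 1] <- a[1]; A[i, i, 2] <- a[2]
  }
  if (nrow(spec$edges)) {
    for (e in seq_len(nrow(spec$edges))) {
      A[spec$edges$to[e], spec$edges$from[e], lags[e]] <-
        A[spec$edges$to[e], spec$edges$from[e], lags[e]] + spec$edges$g0[e]
    }
  }
  list(A = A, lags = lags, p = p)
}

#' Movement-cycle phase from an event table
#'
#' Piecewise-linear phase in units of reference-limb cycles: phase advances
#' by exactly 1 between consecutive full extensions of the reference limb
#' and is extrapolated with the mean period outside the observed events.
#'
#' @param times Numeric vector of times (s).
#' @param events An [event_table()].
#' @param ref_limb Reference limb; default the limb with most events.
#' @return Numeric phase vector (same length as `times`).
#' @export
cycle_phase <- function(times, events, ref_limb = NULL) {
  if (is.null(ref_limb)) {
    ref_limb <- if ("right_arm" %in% events$limb) "right_arm" else
      names(which.max(table(events$limb)))
  }
  ons <- limb_onsets(events, ref_limb)
  if (length(ons) < 2) stop("need at least two reference-limb events")
  stats::approx(x = ons, y = seq_along(ons) - 1, xout = times,
                rule = 2)$y +
    ifelse(times < ons[1], (times - ons[1]) / mean(diff(ons)),
           ifelse(times > ons[length(ons)],
                  (times - ons[length(ons)]) / mean(diff(ons)), 0))
}

#' Simulate the source network
#'
#' Runs the time-varying vector-autoregressive recursion defined by `spec`
#' at the network rate `spec$fs_network`: each source follows its resonator
#' dynamics plus gain-modulated lagged input from incoming edges plus
#' Gaussian innovations, topped with broadband background activity. The
#' time-averaged coefficient set must be stable (companion spectral
#' radius < 1). When `fs` exceeds the network rate the sources are
#' band-limited-interpolated (Fourier upsampling) to `fs`, so downsampling
#' back to the network rate in the analysis recovers the generating process
#' exactly.
#'
#' @param spec A [source_network_spec()].
#' @param events An [event_table()] defining the movement-cycle phase.
#' @param fs Output sampling rate (Hz); an integer multiple of
#'   `spec$fs_network` (equal is fine) and at least twice the highest
#'   resonance frequency.
#' @param duration_s Length of the output (s).
#' @param seed Integer seed.
#' @param burn_s Burn-in discarded before t = 0 (s).
#' @return A list of class `source_set`: `sources` (n_sources x samples at
#'   `fs`), `fs`, `gains` (edges x samples matrix of the true g(t), at
#'   `fs`), `events`, `spec`, `labels`.
#' @export
simulate_source_network <- function(spec, events, fs = 512, duration_s = 300,
                                    seed = 1, burn_s = 2) {
  fsn <- spec$fs_network %||% fs
  if (fsn > fs) stop("output rate below the network rate")
  q <- fs / fsn
  if (abs(q - round(q)) > 1e-9) {
    stop("fs must be an integer multiple of spec$fs_network")
  }
  if (fsn < 2 * max(spec$center_freq)) {
    stop("network rate too low for the specified resonance frequencies")
  }
  mv <- spec_mean_var(spec, fsn)
  rad <- companion_spectral_radius(mv$A)
  if (rad >= 1) {
    stop(sprintf("unstable source spec: companion spectral radius %.3f >= 1", rad))
  }
  set.seed(seed)
  M <- spec$n_sources
  nb <- round(burn_s * fsn)
  N <- round(duration_s * fsn)
  NT <- N + nb
  tgrid <- (seq_len(NT) - 1 - nb) / fsn
  E <- matrix(stats::rnorm(M * NT), M, NT) * spec$innovation_sd
  a1 <- numeric(M); a2 <- numeric(M)
  for (i in seq_len(M)) {
    a <- resonator_coef(spec$center_freq[i], spec$bandwidth[i], fsn)
    a1[i] <- a[1]; a2[i] <- a[2]
  }
  ne <- nrow(spec$edges)
  gains <- matrix(0, max(ne, 1), NT)
  if (ne) {
    ph <- cycle_phase(tgrid, events)
    for (e in seq_len(ne)) {
      gains[e, ] <- spec$edges$g0[e] +
        spec$edges$depth[e] * stride_profile(ph + spec$edges$phase[e])
    }
  }
  lags <- mv$lags
  x <- matrix(0, M, NT)
  maxlag <- max(2L, if (ne) max(lags) else 2L)
  efrom <- spec$edges$from; eto <- spec$edges$to
  for (t in seq((maxlag + 1L), NT)) {
    xt <- a1 * x[, t - 1L] + a2 * x[, t - 2L] + E[, t]
    if (ne) {
      for (e in seq_len(ne)) {
        xt[eto[e]] <- xt[eto[e]] + gains[e, t] * x[efrom[e], t - lags[e]]
      }
    }
    x[, t] <- xt
  }
  bg <- spec$background_frac %||% 0
  if (bg > 0) {
    # broadband background on top of the oscillatory network: amplitude is a
    # fixed fraction of each source's intrinsic (uncoupled) stationary sd
    sd_int <- vapply(seq_len(M), function(i) {
      a <- resonator_coef(spec$center_freq[i], spec$bandwidth[i], fsn)
      sqrt(spec$innovation_sd[i]^2 * (1 - a[2]) /
             ((1 + a[2]) * ((1 - a[2])^2 - a[1]^2)))
    }, 0)
    x <- x + matrix(stats::rnorm(M * NT), M, NT) * (bg * sd_int)
  }
  keep <- (nb + 1L):NT
  x <- x[, keep, drop = FALSE]
  gains <- gains[, keep, drop = FALSE]
  if (q > 1) {
    x <- t(apply(x, 1L, upsample_fft, q = as.integer(round(q))))
    tout <- (seq_len(ncol(x)) - 1) / fs
    gains <- t(vapply(seq_len(nrow(gains)), function(e)
      stats::approx((seq_len(N) - 1) / fsn, gains[e, ], xout = tout,
                    rule = 2)$y, numeric(ncol(x))))
  }
  structure(list(sources = x, fs = fs, gains = gains,
                 events = events, spec = spec, labels = spec$labels),
            class = "source_set")
}

# ideal band-limited interpolation by an integer factor
upsample_fft <- function(x, q) {
  N <- length(x)
  Y <- stats::fft(x)
  M <- N * q
  Yu <- complex(length.out = M)
  half <- N %/% 2
  Yu[1:(half + 1)] <- Y[1:(half + 1)]
  if (half > 1) Yu[(M - (N - half - 2)):M] <- Y[(half + 2):N]
  if (N %% 2 == 0) {
    # split the Nyquist bin to keep the interpolant real and symmetric
    Yu[half + 1] <- Y[half + 1] / 2
    Yu[M - half + 1] <- Conj(Y[half + 1]) / 2
  }
  q * Re(stats::fft(Yu, inverse = TRUE)) / M
}

#' @export
print.source_set <- function(x, ...) {
  cat(sprintf("<source_set> %d sources x %d samples @ %g Hz, %d edges\n",
              nrow(x$sources), ncol(x$sources), x$fs, nrow(x$spec$edges)))
  invisible(x)
}

#' Random smooth scalp mixing matrix
#'
#' @param n_channels Number of scalp channels.
#' @param n_sources Number of sources.
#' @param seed Integer seed.
#' @return `n_channels x n_sources` matrix with unit-norm columns.
#' @export
default_mixing <- function(n_channels, n_sources, seed = 1) {
  set.seed(seed)
  M <- matrix(stats::rnorm(n_channels * n_sources), n_channels, n_sources)
  sweep(M, 2, sqrt(colSums(M^2)), "/") * sqrt(n_channels / n_sources)
}

#' Mix sources to scalp channels
#'
#' Forward model: `channels = mixing %*% sources + sensor noise`, plus
#' optional transient high-amplitude artifact bursts (Hann-windowed noise)
#' on chosen channels and time windows, logged as ground truth.
#'
#' @param sources A `source_set` or an n_sources x samples matrix.
#' @param mixing_matrix n_channels x n_sources matrix.
#' @param sensor_noise_sd White sensor noise sd (same units as sources).
#' @param artifact_spec Optional `data.frame` with columns `channel`,
#'   `start_s`, `end_s`, `amplitude`.
#' @param seed Integer seed.
#' @param fs Sampling rate; taken from the source set when available.
#' @param condition Condition label stored on the output recording.
#' @return A [recording] with attribute `"artifact_log"` (the realized
#'   artifact table, possibly empty).
#' @export
mix_to_scalp <- function(sources, mixing_matrix, sensor_noise_sd = 0,
                         artifact_spec = NULL, seed = 1, fs = NULL,
                         condition = NA_character_) {
  if (inherits(sources, "source_set")) {
    fs <- sources$fs
    src <- sources$sources
  } else {
    src <- as.matrix(sources)
    if (is.null(fs)) stop("fs required when sources is a bare matrix")
  }
  if (ncol(mixing_matrix) != nrow(src)) {
    stop(sprintf("mixing has %d columns but there are %d sources",
                 ncol(mixing_matrix), nrow(src)))
  }
  set.seed(seed)
  n_ch <- nrow(mixing_matrix); N <- ncol(src)
  data <- mixing_matrix %*% src
  if (sensor_noise_sd > 0) {
    data <- data + matrix(stats::rnorm(n_ch * N, 0, sensor_noise_sd), n_ch, N)
  }
  log <- data.frame(channel = integer(0), start_s = numeric(0),
                    end_s = numeric(0), amplitude = numeric(0))
  if (!is.null(artifact_spec) && nrow(artifact_spec)) {
    for (k in seq_len(nrow(artifact_spec))) {
      ch <- artifact_spec$channel[k]
      i0 <- max(1L, round(artifact_spec$start_s[k] * fs) + 1L)
      i1 <- min(N, round(artifact_spec$end_s[k] * fs))
      if (i1 <= i0) next
      n <- i1 - i0 + 1L
      env <- 0.5 - 0.5 * cos(2 * pi * seq_len(n) / (n + 1))
      data[ch, i0:i1] <- data[ch, i0:i1] +
        artifact_spec$amplitude[k] * env * stats::rnorm(n)
      log <- rbind(log, data.frame(channel = ch, start_s = (i0 - 1) / fs,
                                   end_s = i1 / fs,
                                   amplitude = artifact_spec$amplitude[k]))
    }
  }
  rec <- recording(data, fs, sprintf("EEG%03d", seq_len(n_ch)),
                   condition = condition)
  attr(rec, "artifact_log") <- log
  rec
}

#' Default synthetic dataset
#'
#' Generates the study conditions used throughout the documentation and
#' tests: a 7-source network with stride-modulated coupling, four limbs
#' paced at 70 extensions/min, sampled at 512 Hz.
#'
#' @param duration_s Duration (s); default 300 (one 5-minute condition).
#' @param seed Integer seed.
#' @param fs Sampling rate (Hz).
#' @param phase_jitter_sd Event-onset jitter sd (s).
#' @return A `source_set`.
#' @export
synthetic_dataset <- function(duration_s = 300, seed = 1, fs = 512,
                              phase_jitter_sd = 0.02) {
  spec <- source_network_spec()
  ev <- generate_events(spec$cadence, duration_s, limb_labels(),
                        phase_jitter_sd = phase_jitter_sd, seed = seed)
  simulate_source_network(spec, ev, fs = fs, duration_s = duration_s,
                          seed = seed + 1L)
}
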