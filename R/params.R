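#' Pipeline parameters
#'
#' Every numeric constant used by the pipeline lives here, so a run is fully
#' described by one parameter object. Defaults follow the analysis protocol:
#' 512 Hz acquisition, 1 Hz high-pass, downsampling to 128 Hz for
#' connectivity, piecewise linear detrending with a 330 ms window every
#' 82.5 ms, MVAR estimation in 200 ms windows every 54.7 ms with candidate
#' orders 1..10, 200 bootstrap resamples, a stepping cadence of 70
#' extensions/min per limb (cue rate 1.16 Hz), a 128-sample zero-padded FFT
#' for connectivity fluctuation up to 18 Hz, and 0.026 Hz resolution for
#' grand-mean spectra.
#'
#' Window sample counts are defined as `round(duration * fs)`: at 128 Hz the
#' 200 ms MVAR window is 26 samples and the 54.7 ms step is 7 samples.
#'
#' @param ... Named overrides of any default listed below.
#' @return A list of class `pipeline_params`.
#' @examples
#' p <- pipeline_params(n_boot_ersp = 100)
#' p$mvar_window * p$fs_mvar   # ~26 samples
#' @export
pipeline_params <- function(...) {
  p <- list(
    fs_raw = 512,              # Hz, acquisition rate
    highpass_cutoff = 1,       # Hz
    fs_mvar = 128,             # Hz, connectivity branch rate
    detrend_window = 0.330,    # s
    detrend_step = 0.0825,     # s
    mvar_window = 0.200,       # s
    mvar_step = 0.0547,        # s
    order_candidates = 1:10,
    n_boot_connectivity = 200,
    n_boot_ersp = 200,
    alpha = 0.05,
    cadence = 70,              # full extensions per minute, per limb
    cue_rate = 1.16,           # Hz, pacing-cue shading rate
    fluct_nfft = 128,
    fluct_fmax = 18,           # Hz, upper display limit (capped at Nyquist)
    spectrum_resolution = 0.026,  # Hz
    min_subjects_per_cluster = 5,
    ica_quality_threshold = 0.85,
    whiteness_lags = 12,
    dtf_freqs = seq(2, 48, by = 2),   # Hz, DTF evaluation grid
    ersp_freqs = exp(seq(log(3), log(80), length.out = 40)),  # Hz
    ersp_times = 200,          # output time points per warped epoch
    bands = list(theta = c(4, 8), alpha = c(8, 13),
                 beta = c(13, 30), gamma = c(30, 80))
  )
  over <- list(...)
  unknown <- setdiff(names(over), names(p))
  if (length(unknown)) stop("unknown parameter(s): ",
                            paste(unknown, collapse = ", "))
  p[names(over)] <- over
  validate_params(p)
  structure(p, class = "pipeline_params")
}

validate_params <- function(p) {
  durs <- c(p$detrend_window, p$detrend_step, p$mvar_window, p$mvar_step)
  if (any(durs <= 0)) stop("all window durations must be positive")
  if (p$detrend_step > p$detrend_window) {
    stop("detrend_step must not exceed detrend_window")
  }
  if (p$mvar_step > p$mvar_window) stop("mvar_step must not exceed mvar_window")
  if (p$alpha <= 0 || p$alpha >= 1) stop("alpha must lie in (0, 1)")
  if (p$fs_mvar >= p$fs_raw) stop("fs_mvar must be below fs_raw")
  if (p$highpass_cutoff >= p$fs_raw / 2) stop("high-pass cutoff above Nyquist")
  invisible(p)
}
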