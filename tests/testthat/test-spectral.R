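test_that("equal-length cycles make the warp the identity", {
  p <- pipeline_params()
  ev <- generate_events(70, 30, c("right_arm", "left_arm"))  # no jitter
  set.seed(1)
  x <- stats::rnorm(30 * 512)
  wt <- make_warped_epochs(x, 512, ev, params = p)
  # anchors identical across trials: warping must not move anything
  expect_equal(apply(wt$anchors, 2, stats::sd), c(left_arm = 0))
  ra <- limb_onsets(ev, "right_arm")
  raw <- make_warped_epochs(x, 512, event_table(ra, rep("right_arm", length(ra))),
                            params = p)
  # same reference events, no anchors at all -> same epochs
  expect_equal(wt$logpow, raw$logpow, tolerance = 1e-10)
})

test_that("a stretched cycle is compressed onto the common time base", {
  p <- pipeline_params()
  # 20 regular cycles then one 10% longer; the anchor event always comes a
  # fixed 0.5 * T after the cycle start, so the long cycle's anchor sits at
  # fraction 0.5/1.1 and must be warped onto the common 0.5 target
  T <- 60 / 70
  ref <- c(seq(0, 19 * T, by = T), 19 * T + 1.1 * T, 19 * T + 2.1 * T)
  mid <- utils::head(ref, -1) + 0.5 * T
  ev <- event_table(c(ref, mid),
                    c(rep("right_arm", length(ref)), rep("left_arm", length(mid))))
  # a brief 10 Hz burst around every anchor event
  N <- ceiling(max(ref) * 512) + 512
  tt <- (0:(N - 1)) / 512
  x <- stats::rnorm(N, 0, 0.01)
  for (m in mid) {
    sel <- tt >= m - 0.05 & tt <= m + 0.05
    x[sel] <- x[sel] + sin(2 * pi * 10 * tt[sel])
  }
  wt <- make_warped_epochs(x, 512, ev, params = p)
  expect_equal(unname(wt$targets), 0.5, tolerance = 1e-6)
  expect_equal(unname(wt$anchors[20, 1]), 0.5 / 1.1, tolerance = 1e-6)
  # after warping, the long trial's burst peaks at the common 50% latency
  f10 <- which.min(abs(wt$freqs - 10))
  peak_col <- which.max(wt$logpow[f10, , 20])
  expect_equal(wt$times[peak_col], 0.5, tolerance = 0.03)

  # trial count arithmetic: N reference events give N - 1 epochs
  ev60 <- generate_events(70, 60, c("right_arm", "left_arm"),
                          phase_jitter_sd = 0.01, seed = 3)
  x60 <- stats::rnorm(60 * 512)
  wt60 <- make_warped_epochs(x60, 512, ev60, params = p)
  expect_equal(dim(wt60$logpow)[3], 69)
  expect_error(make_warped_epochs(x, 512, event_table(0.1, "right_arm")),
               "at least two")
})

test_that("warping preserves per-trial total log power", {
  p <- pipeline_params()
  # small jitter: the piecewise-linear remap is then close to the identity
  # and total log power per trial is preserved to interpolation accuracy
  ev <- generate_events(70, 40, c("right_arm", "left_arm"),
                        phase_jitter_sd = 0.005, seed = 4)
  set.seed(5)
  x <- stats::rnorm(40 * 512)
  wt <- make_warped_epochs(x, 512, ev, params = p)
  # compare to the unwarped epochs of the reference limb alone
  ra <- limb_onsets(ev, "right_arm")
  raw <- make_warped_epochs(x, 512, event_table(ra, rep("right_arm", length(ra))),
                            params = p)
  for (k in c(1, 10, 20)) {
    # 2% covers the two linear interpolation passes plus the near-identity map
    expect_equal(mean(wt$logpow[, , k]), mean(raw$logpow[, , k]),
                 tolerance = 0.02)
  }
})

test_that("ERSP baseline, masking and analytic step behave as defined", {
  p <- pipeline_params()
  # constant-power signal: pre-mask ERSP ~ 0 everywhere
  ev <- generate_events(70, 30, "right_arm")
  tt <- (0:(30 * 512 - 1)) / 512
  wt_const <- make_warped_epochs(sin(2 * pi * 10 * tt), 512, ev, params = p)
  er_const <- compute_ersp(wt_const, n_boot = 50, seed = 1)
  f10 <- which.min(abs(er_const$freqs - 10))
  expect_lt(max(abs(er_const$premask[f10, 10:190])), 0.2)
  # per-frequency time-mean of the pre-mask matrix is exactly 0 dB
  expect_lt(max(abs(rowMeans(er_const$premask))), 1e-9)
  # masked cells are exactly 0 in the report
  expect_true(all(er_const$ersp[!er_const$mask] == 0))

  # amplitude A for half the cycle, 2A for the other: -3.01 / +3.01 dB
  ph <- cycle_phase(tt, ev, "right_arm") %% 1
  x_step <- ifelse(ph < 0.5, 1, 2) * sin(2 * pi * 10 * tt)
  er_step <- compute_ersp(make_warped_epochs(x_step, 512, ev, params = p),
                          n_boot = 50, seed = 2)
  lo <- mean(er_step$premask[f10, 40:80])
  hi <- mean(er_step$premask[f10, 140:180])
  expect_equal(lo, -10 * log10(4) / 2, tolerance = 0.35)
  expect_equal(hi, 10 * log10(4) / 2, tolerance = 0.35)

  expect_error(compute_ersp(wt_const$logpow[, , 1:5, drop = FALSE]), "trials")
})

test_that("grand-mean spectra sit on the 0.026 Hz grid and find tones", {
  fs <- 512
  tt <- (0:(fs * 30 - 1)) / fs
  set.seed(6)
  gs <- grand_mean_spectrum(sin(2 * pi * 10 * tt) + stats::rnorm(fs * 30, 0, 0.1),
                            fs)
  expect_equal(gs$resolution, 0.026, tolerance = 0.001)
  expect_equal(gs$freq[which.max(gs$log_power)], 10, tolerance = 0.026)
  # white noise: flat log spectrum over the analysis range
  gw <- grand_mean_spectrum(stats::rnorm(fs * 60), fs)
  sel <- gw$freq >= 4 & gw$freq <= 40
  expect_lt(stats::sd(gw$log_power[sel]), 1.5)
  expect_lt(abs(mean(gw$log_power[sel] ) - mean(gw$log_power[gw$freq >= 40 & gw$freq <= 80])), 0.5)
  expect_error(grand_mean_spectrum(numeric(0), fs), "empty")
  expect_lt(abs(band_mean_log_power(gw, c(4, 8)) - band_mean_log_power(gw, c(8, 13))), 1)
})

test_that("rank-sum comparisons match exact enumeration and detect shifts", {
  expect_gt(compare_conditions_wilcoxon(c(1, 2, 3), c(1, 2, 3))$p_value, 0.99)
  w <- compare_conditions_wilcoxon(c(1, 2, 3), c(10, 11, 12), band = "alpha")
  expect_equal(w$p_value, 0.1)   # 2 of choose(6,3)=20 arrangements, two-sided
  expect_true(w$exact)
  expect_equal(w$direction, "B>A")
  expect_error(compare_conditions_wilcoxon(numeric(0), 1:3), "empty")

  set.seed(7)
  rej <- replicate(200, {
    a <- stats::rnorm(20); b <- stats::rnorm(20, 2)
    compare_conditions_wilcoxon(a, b)$p_value < 0.05
  })
  expect_gt(mean(rej), 0.9)
})
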