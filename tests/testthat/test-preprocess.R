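test_that("high-pass removes drift and preserves the passband", {
  fs <- 512; N <- fs * 20
  tt <- (0:(N - 1)) / fs
  rec <- recording(rbind(rep(5, N),
                         sin(2 * pi * 10 * tt),
                         sin(2 * pi * 0.1 * tt)), fs)
  hp <- highpass_filter(rec, 1)
  core <- (2 * fs):(N - 2 * fs)                # away from filter edges
  expect_lt(abs(mean(hp$data[1, core])) / 5, 0.001)
  amp10 <- max(abs(hp$data[2, core]))
  expect_equal(amp10, 1, tolerance = 0.01)
  amp01 <- max(abs(hp$data[3, core]))
  expect_lt(amp01, 10^(-20 / 20))              # >= 20 dB down at 0.1 Hz
  expect_error(highpass_filter(rec, 300), "Nyquist")
})

test_that("artifact rejection finds the planted channel and window", {
  ss <- small_network_128(duration_s = 30, seed = 11)
  M <- default_mixing(10, 7, seed = 1)
  rec <- mix_to_scalp(ss$ss, M, sensor_noise_sd = 0.5, seed = 2)
  # clean toy: empty log
  rj0 <- reject_artifacts(rec)
  expect_equal(nrow(rj0$log$channels), 0)
  expect_equal(nrow(rj0$log$windows), 0)

  # one channel at ~10x the sd of the others: exactly that channel goes
  bad <- rec
  set.seed(3)
  bad$data[4, ] <- stats::rnorm(ncol(bad$data), 0,
                                10 * stats::median(apply(rec$data, 1, stats::sd)))
  rj1 <- reject_artifacts(bad)
  expect_identical(rj1$log$channels$label, bad$channel_labels[4])
  expect_gt(rj1$log$channels$sd_ratio, 3)

  # planted burst window (hitting all channels, as movement artifact does)
  # is excised and logged where the generator put it
  art <- data.frame(channel = 1:10, start_s = 12, end_s = 13, amplitude = 60)
  reca <- mix_to_scalp(ss$ss, M, sensor_noise_sd = 0.5, artifact_spec = art,
                       seed = 2)
  rj2 <- reject_artifacts(reca)
  expect_gte(nrow(rj2$log$windows), 1)
  expect_true(any(rj2$log$windows$start_s <= 12 & rj2$log$windows$end_s >= 13))
  # events in/after the excised windows are remapped onto the cleaned data
  ev2 <- adjust_events_for_excision(ss$events, rj2$log)
  cut <- sum(rj2$log$windows$end_s - rj2$log$windows$start_s)
  expect_equal(max(ev2$onset), max(ss$events$onset) - cut, tolerance = 1)

  # refusing to reject everything
  allbad <- recording(matrix(stats::rnorm(4 * 256), 4), 128)
  expect_error(reject_artifacts(allbad, channel_min_corr = 1.01), "every channel")
})

test_that("common average referencing zeroes the channel mean and is idempotent", {
  set.seed(4)
  rec <- recording(matrix(stats::rnorm(6 * 500), 6) + 1:6, 128)
  car <- rereference_common_average(rec)
  expect_lt(max(abs(colMeans(car$data))), 1e-9)
  expect_equal(rereference_common_average(car)$data, car$data)
  # two-channel closed form
  ab <- recording(rbind(a = c(1, 2, 3), b = c(5, 4, 0)), 128)
  expect_equal(rereference_common_average(ab)$data,
               unname(rbind((c(1, 2, 3) - c(5, 4, 0)) / 2,
                            (c(5, 4, 0) - c(1, 2, 3)) / 2)))
  expect_error(rereference_common_average(recording(matrix(1:5, 1), 128)),
               "2 channels")
})

test_that("downsampling keeps the passband and annihilates aliases", {
  fs <- 512; N <- fs * 10
  tt <- (0:(N - 1)) / fs
  rec <- recording(rbind(sin(2 * pi * 10 * tt), sin(2 * pi * 100 * tt)), fs)
  d <- downsample(rec, 128)
  expect_equal(ncol(d$data), N / 4)
  expect_equal(d$fs, 128)
  expect_equal(max(abs(d$data[1, ])), 1, tolerance = 0.01)
  expect_lt(max(abs(d$data[2, ])), 0.01)       # >= 40 dB down
  expect_error(downsample(rec, 512), "below")
  expect_error(downsample(rec, 100), "integer")
})

test_that("piecewise detrending removes lines and keeps oscillations", {
  fs <- 128; N <- fs * 30
  ramp <- seq(0, 100, length.out = N)
  tt <- (0:(N - 1)) / fs
  set.seed(5)
  rec <- recording(rbind(ramp,
                         stats::rnorm(N),
                         sin(2 * pi * 10 * tt)), fs)
  dt <- piecewise_detrend(rec)
  interior <- (2 * fs):(N - 2 * fs)
  expect_lt(max(abs(dt$data[1, interior])) / 100, 1e-6)
  expect_equal(stats::var(dt$data[2, interior]), 1, tolerance = 0.15)
  expect_equal(max(abs(dt$data[3, interior])), 1, tolerance = 0.1)
  expect_error(piecewise_detrend(recording(matrix(1:100, 1), 128),
                                 window = 0.001), "2 samples")
})
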