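test_that("paced events have the prescribed cadence, pairing and jitter", {
  ev <- generate_events(70, 60, c("left_arm", "right_arm"))
  ra <- limb_onsets(ev, "right_arm"); la <- limb_onsets(ev, "left_arm")
  expect_length(ra, 70)
  expect_length(la, 70)
  expect_equal(diff(ra), rep(60 / 70, 69), tolerance = 1e-9)
  # opposite limbs half a period apart
  expect_equal(la[1] - ra[1], 30 / 70)
  # right arm and left leg extend together
  ev4 <- generate_events(70, 10, limb_labels())
  expect_equal(limb_onsets(ev4, "right_arm"), limb_onsets(ev4, "left_leg"))

  expect_equal(nrow(generate_events(70, 0)), 0)
  expect_error(generate_events(70, 60, phase_jitter_sd = -1), "jitter")

  # successive-interval deviations have sd ~ sqrt(2) * jitter sd
  evj <- generate_events(70, 1300, "right_arm", phase_jitter_sd = 0.02,
                         seed = 42)
  dev <- diff(limb_onsets(evj, "right_arm")) - 60 / 70
  expect_equal(stats::sd(dev), sqrt(2) * 0.02, tolerance = 0.1)
})

test_that("stride profile is periodic, centred, and carries the first four harmonics", {
  u <- seq(0, 2, length.out = 2048)[-2048]
  v <- stride_profile(u)
  expect_equal(stride_profile(u + 2), v)        # period two cycles
  expect_lt(abs(mean(v)), 1e-3)                 # zero mean
  expect_equal(max(abs(v)), 1, tolerance = 1e-3)
  co <- Mod(stats::fft(v))[2:9] / length(v)     # harmonics k/2 * f0, k = 1..8
  # energy concentrated in the multiples {0.5, 1, 1.5, 2} x f0
  expect_gt(sum(co[1:4]^2) / sum(co^2), 0.95)
  expect_true(all(co[1:4] > 0.01))
})

test_that("source network honours its coupling ground truth", {
  ev <- generate_events(70, 240, limb_labels(), seed = 1)
  # all gains zero: sources mutually independent (narrowband sources have
  # long correlation times, so a few minutes are needed for a 0.05 bound)
  spec0 <- source_network_spec(edges = default_edges()[0, ])
  ss0 <- simulate_source_network(spec0, ev, fs = 128, duration_s = 240, seed = 2)
  cm <- stats::cor(t(ss0$sources))
  expect_lt(max(abs(cm[upper.tri(cm)])), 0.05)

  # a sender is unaffected by its outgoing edge (no reverse influence)
  spec1 <- source_network_spec(
    n_sources = 2, center_freq = c(10, 8), bandwidth = c(4, 4),
    edges = data.frame(from = 1, to = 2, lag_s = 0.016, g0 = 0.4,
                       depth = 0, phase = 0))
  spec_none <- source_network_spec(n_sources = 2, center_freq = c(10, 8),
                                   bandwidth = c(4, 4),
                                   edges = default_edges(1))
  s1 <- simulate_source_network(spec1, ev, fs = 128, duration_s = 20, seed = 3)
  s0 <- simulate_source_network(spec_none, ev, fs = 128, duration_s = 20, seed = 3)
  expect_equal(s1$sources[1, ], s0$sources[1, ])
  expect_false(isTRUE(all.equal(s1$sources[2, ], s0$sources[2, ])))
  # stored gains follow g0 + depth * profile
  expect_equal(unique(s1$gains[1, ]), 0.4)

  # unstable specification is refused
  bad <- source_network_spec(
    n_sources = 2, center_freq = c(10, 8), bandwidth = c(4, 4),
    edges = data.frame(from = c(1, 2), to = c(2, 1), lag_s = 0.016,
                       g0 = c(1.5, 1.5), depth = 0, phase = 0))
  expect_error(simulate_source_network(bad, ev, fs = 128, duration_s = 10),
               "unstable")
  # sampling rate below the resonances is refused
  expect_error(
    simulate_source_network(source_network_spec(fs_network = 16), ev,
                            fs = 16, duration_s = 10),
    "too low")
})

test_that("512 Hz output downsamples back to the native network process", {
  ev <- generate_events(70, 20, limb_labels(), seed = 1)
  spec <- source_network_spec()
  hi <- simulate_source_network(spec, ev, fs = 512, duration_s = 20, seed = 4)
  lo <- simulate_source_network(spec, ev, fs = 128, duration_s = 20, seed = 4)
  back <- downsample(recording(hi$sources, 512), 128)
  err <- max(abs(back$data - lo$sources)) / stats::sd(lo$sources)
  expect_lt(err, 0.05)
})

test_that("scalp mixing matches the forward model and logs artifacts", {
  ss <- small_network_128(duration_s = 4, seed = 5)
  # identity mixing, no noise: channels equal sources
  rec_id <- mix_to_scalp(ss$ss, diag(7), sensor_noise_sd = 0, seed = 1)
  expect_equal(rec_id$data, unname(ss$ss$sources))

  expect_error(mix_to_scalp(ss$ss, matrix(0, 8, 5)), "sources")

  # channel covariance ~ M Cov(S) M' + sigma^2 I over 60 s
  set.seed(6)
  src <- matrix(stats::rnorm(7 * 128 * 60), 7)
  M <- default_mixing(16, 7, seed = 7)
  rec <- mix_to_scalp(src, M, sensor_noise_sd = 0.5, seed = 8, fs = 128)
  emp <- stats::cov(t(rec$data))
  theo <- M %*% stats::cov(t(src)) %*% t(M) + 0.25 * diag(16)
  expect_lt(max(abs(emp - theo)) / max(abs(theo)), 0.05)

  # one injected burst: present only on the chosen channel, and logged
  art <- data.frame(channel = 5, start_s = 1, end_s = 1.5, amplitude = 50)
  reca <- mix_to_scalp(src, M, sensor_noise_sd = 0, artifact_spec = art,
                       seed = 9, fs = 128)
  clean <- mix_to_scalp(src, M, sensor_noise_sd = 0, seed = 9, fs = 128)
  d <- abs(reca$data - clean$data)
  expect_true(all(d[-5, ] == 0))
  expect_gt(max(d[5, 129:192]), 0)
  log <- attr(reca, "artifact_log")
  expect_equal(log$channel, 5)
  expect_equal(log$start_s, 1, tolerance = 0.01)
})
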