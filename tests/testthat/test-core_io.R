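test_that("delimited recordings round-trip bit-for-bit", {
  set.seed(1)
  rec <- recording(matrix(rnorm(4 * 1024), 4), 512, c("C3", "C4", "Cz", "Pz"),
                   subject_id = "S01", condition = "active_arms")
  path <- withr::local_tempfile(fileext = ".tsv")
  write_recording(rec, path)
  r2 <- read_recording(path)
  expect_identical(r2$data, rec$data)
  expect_identical(r2$channel_labels, rec$channel_labels)
  expect_identical(r2$fs, rec$fs)
  expect_identical(r2$condition, "active_arms")
})

test_that("malformed delimited files and recordings are rejected", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("#fs\t512", "a\tb\tc", "1\t2\t3\t4"), path)
  expect_error(read_recording(path), "labels")
  expect_error(recording(matrix(0, 2, 4), fs = -1), "positive")
  expect_error(recording(matrix(0, 2, 4), 512, c("a", "b", "c")), "labels")
  expect_error(recording(matrix(0, 2, 4), 512, condition = "jumping"),
               "condition")
  expect_error(read_recording(withr::local_tempfile()), "not found")
})

test_that("EDF written by the generator reads back with matching fs and data", {
  ss <- small_network_128(duration_s = 4, seed = 3)
  rec <- mix_to_scalp(ss$ss, default_mixing(8, 7, seed = 1),
                      sensor_noise_sd = 0.5, seed = 2)
  path <- withr::local_tempfile(fileext = ".edf")
  write_recording(rec, path)
  r2 <- read_recording(path)
  expect_equal(r2$fs, rec$fs)
  expect_equal(dim(r2$data), dim(rec$data))
  # EDF is 16-bit: exact to the quantization step of the amplitude range
  step <- (max(rec$data) - min(rec$data)) / 65534
  expect_lt(max(abs(r2$data - rec$data)), step)
})

test_that("events.tsv round-trips, sorts, and validates trial types", {
  ev <- event_table(c(0.857, 0), c("left_arm", "right_arm"))
  expect_equal(ev$onset, c(0, 0.857))     # sorted on construction
  path <- withr::local_tempfile(fileext = ".tsv")
  write_events(ev, path)
  e2 <- read_events(path)
  expect_equal(e2$onset, ev$onset)
  expect_identical(e2$limb, ev$limb)

  bad <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("onset\tduration\ttrial_type", "0.1\t0\thead"), bad)
  expect_error(read_events(bad), "trial_type")
  neg <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("onset\tduration\ttrial_type", "-0.1\t0\tright_arm"), neg)
  expect_error(read_events(neg), "negative")
  # unsorted file comes back sorted
  uns <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("onset\tduration\ttrial_type",
               "1.0\t0\tright_arm", "0.2\t0\tleft_arm"), uns)
  expect_equal(read_events(uns)$onset, c(0.2, 1.0))
})

test_that("pipeline runs are seed-deterministic and check stage dependencies", {
  out1 <- withr::local_tempdir(); out2 <- withr::local_tempdir()
  cfg <- list(seed = 7,
              stages = c("simulate", "preprocess"),
              synthetic = list(duration_s = 20, n_channels = 8,
                               sensor_noise_sd = 1))
  suppressMessages(run_pipeline(cfg, out_dir = out1))
  suppressMessages(run_pipeline(cfg, out_dir = out2))
  for (f in list.files(out1)) {
    expect_identical(readLines(file.path(out1, f), warn = FALSE),
                     readLines(file.path(out2, f), warn = FALSE),
                     label = paste("file", f))
  }
  expect_true(all(c("recording.tsv", "events.tsv", "clean_raw.tsv",
                    "manifest.json") %in% list.files(out1)))
  expect_error(
    suppressMessages(
      run_pipeline(list(seed = 1, stages = "connectivity"),
                   out_dir = withr::local_tempdir())),
    "requires")
  expect_error(
    suppressMessages(
      run_pipeline(list(seed = 1, stages = "fly"),
                   out_dir = withr::local_tempdir())),
    "unknown stage")
})

test_that("pipeline parameter container validates its invariants", {
  p <- pipeline_params()
  expect_equal(round(p$mvar_window * p$fs_mvar), 26)
  expect_equal(round(p$mvar_step * p$fs_mvar), 7)
  expect_error(pipeline_params(alpha = 1.2), "alpha")
  expect_error(pipeline_params(detrend_step = 0.5), "detrend_step")
  expect_error(pipeline_params(nonsense = 1), "unknown parameter")
})
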