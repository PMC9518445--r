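test_that("resampling is the identity at 100 Hz and rejects upsampling", {
  x <- rnorm(500)
  expect_identical(resample_to_100hz(x, 100), x)
  expect_error(resample_to_100hz(x, 50), "upsampling")
})

test_that("integer-factor decimation preserves the passband", {
  t <- seq(0, 10 - 1 / 200, by = 1 / 200)
  x <- sin(2 * pi * 5 * t)                  # 5 Hz, well inside the 40 Hz band
  y <- resample_to_100hz(x, 200)
  expect_length(y, 1000)
  # oracle: ideal resampling of a band-limited tone is the tone itself
  ideal <- sin(2 * pi * 5 * (seq_len(1000) - 1) / 100)
  core <- 101:900                           # ignore filter edge transients
  expect_lt(max(abs(y[core] - ideal[core])), 0.02)
  expect_lt(abs(max(y[core]) - 1), 0.02)
})

test_that("energy above the cut-off is strongly attenuated", {
  t <- seq(0, 10 - 1 / 200, by = 1 / 200)
  hi <- sin(2 * pi * 90 * t)                # above the 40 Hz cut-off
  y <- resample_to_100hz(hi, 200)
  expect_lt(sqrt(mean(y^2)) / sqrt(mean(hi^2)), 0.05)

  # >= 20 dB attenuation at 45 Hz relative to a passband tone
  lo <- sin(2 * pi * 10 * t)
  edge <- sin(2 * pi * 45 * t)
  r_lo <- sqrt(mean(resample_to_100hz(lo, 200)^2))
  r_edge <- sqrt(mean(resample_to_100hz(edge, 200)^2))
  expect_gt(20 * log10(r_lo / r_edge), 20)
})

test_that("rational-ratio resampling keeps passband tones intact", {
  for (fs in c(128, 512)) {
    t <- seq(0, 10 - 1 / fs, by = 1 / fs)
    x <- sin(2 * pi * 5 * t)
    y <- resample_to_100hz(x, fs)
    expect_length(y, floor(length(x) * 100 / fs))
    ideal <- sin(2 * pi * 5 * (seq_along(y) - 1) / 100)
    core <- 101:(length(y) - 100)
    expect_lt(max(abs(y[core] - ideal[core])), 0.03)
  }
})

test_that("standardize centres, scales, is idempotent and rejects constants", {
  x <- rnorm(1000, 5, 3)
  z <- standardize(x)
  expect_lt(abs(mean(z)), 1e-9)
  expect_lt(abs(sd(z) - 1), 1e-9)
  expect_equal(standardize(z), z, tolerance = 1e-12)
  expect_error(standardize(rep(2, 10)), "constant")
})

test_that("windowing counts, indexing and labels follow the contract", {
  rec <- preprocess_recording(tiny_recording(seed = 7, duration_s = 30))
  w1 <- make_windows(rec, 1)
  expect_length(w1$y, 30)
  w10 <- make_windows(rec, 10)
  expect_length(w10$y, 21)                   # N - T + 1
  expect_equal(dim(w10$x[[1]]), c(21, 10, 100))

  # window i (0-based label epoch) holds raw samples [100*(i-T+1), 100*(i+1))
  i <- 5                                     # 6th window, label epoch 14
  lab_epoch <- w10$epoch[i + 1]
  seg <- rec$signals[(100 * (lab_epoch - 10 + 1) + 1):(100 * (lab_epoch + 1)), 2]
  expect_equal(as.numeric(t(w10$x[[2]][i + 1, , ])), as.numeric(seg))
  expect_equal(w10$y, rec$labels[10:30])

  # shorter than T: empty window set
  expect_length(make_windows(rec, 31)$y, 0)
})

test_that("labels stay aligned with windows across sampling rates", {
  p200 <- cap_sim_params(duration_s = 60, fs = 200, seed = 13)
  rec <- generate_recording(p200, 1)
  w <- make_windows(preprocess_recording(rec), 3)
  expect_equal(w$y, rec$labels[3:60])
  # the burst gain is visible in the windowed variance of labelled epochs
  v <- apply(w$x[[1]], 1, function(m) mean(m[3, ]^2))
  expect_gt(mean(v[w$y == 1]), 2 * mean(v[w$y == 0]))
})

test_that("annotation files parse into per-second labels", {
  f <- withr::local_tempfile(fileext = ".txt")
  writeLines(c(
    "Synthetic CAP scoring fixture",
    "Sleep Stage\tPosition\tTime [hh:mm:ss]\tEvent\tDuration[s]\tLocation",
    "SLEEP-S2\tN\t23:00:10\tMCAP-A1\t5\tFp2-F4",
    "SLEEP-S2\tN\t23:00:30\tMCAP-A3\t3\tF4-C4",
    "SLEEP-S2\tN\t23:01:00\tSLEEP-S2\t30\tFp2-F4"), f)
  lab <- read_cap_annotations(f, 120, start_time = "23:00:00")
  expect_equal(which(lab == 1) - 1L, c(10:14, 30:32))
  # plain-seconds time column needs no start time
  f2 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("Time,Event,Duration", "7,A2,2", "20,B-phase,4"), f2)
  expect_equal(which(read_cap_annotations(f2, 30) == 1) - 1L, 7:8)
})
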