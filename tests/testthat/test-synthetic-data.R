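test_that("generator honours prevalence, determinism and event bounds", {
  p <- cap_sim_params(duration_s = 600, prevalence = 0.15, seed = 1)
  rec <- generate_recording(p, 1)

  # prevalence within one maximum-event share of the target
  expect_lt(abs(mean(rec$labels) - 0.15), 60 / 600)
  # determinism: bit-identical on repeat
  rec2 <- generate_recording(p, 1)
  expect_identical(rec, rec2)
  # different subjects differ
  expect_false(identical(rec$signals, generate_recording(p, 2)$signals))
  # all event durations within the CAP validity bounds
  expect_true(all(rec$events[, "duration"] >= 2 & rec$events[, "duration"] <= 60))
  # channel/label shape invariants
  expect_equal(ncol(rec$signals), 3)
  expect_equal(length(rec$labels), floor(nrow(rec$signals) / rec$fs))
  expect_true(all(rec$labels %in% 0:1))
})

test_that("zero prevalence yields all-zero labels and untouched background", {
  rec <- generate_recording(cap_sim_params(duration_s = 60, prevalence = 0,
                                           seed = 3), 1)
  expect_true(all(rec$labels == 0))
  expect_equal(nrow(rec$events), 0)
})

test_that("labels and events are mutually consistent", {
  for (seed in 1:3) {
    rec <- generate_recording(cap_sim_params(duration_s = 300, seed = seed), 1)
    ev <- rec$events
    # every labelled second overlaps an event
    for (s in which(rec$labels == 1) - 1L) {
      ov <- pmin(ev[, 1] + ev[, 2], s + 1) - pmax(ev[, 1], s)
      expect_true(any(ov >= 0.5))
    }
    # every event covers at least 2 labelled seconds
    for (k in seq_len(nrow(ev))) {
      a <- ev[k, 1]; b <- a + ev[k, 2]
      secs <- floor(a):(ceiling(b) - 1)
      expect_gte(sum(rec$labels[secs + 1] == 1), 2)
    }
  }
})

test_that("mean prevalence over many seeds tracks the target within 10%", {
  prev <- vapply(1:10, function(s) {
    mean(generate_recording(cap_sim_params(duration_s = 600, prevalence = 0.15,
                                           seed = s), 1)$labels)
  }, 0)
  expect_lt(abs(mean(prev) - 0.15) / 0.15, 0.10)
})

test_that("impossible prevalence demands fail with an informative error", {
  # 15 event-seconds cannot fit in 20 s under the 2 s gap rule
  set.seed(1)
  expect_error(capfuse:::place_events(20, 15, c(2, 3)), "prevalence")
  expect_error(cap_sim_params(prevalence = 0.6), "prevalence")
  expect_error(cap_sim_params(fs = 50), "fs")
  expect_error(cap_sim_params(event_duration_range_s = c(1, 60)), "\\[2, 60\\]")
})

test_that("cohorts are balanced two-group with higher SDP-like prevalence", {
  cohort <- generate_cohort(cap_sim_params(n_subjects = 4, duration_s = 120,
                                           seed = 2))
  expect_length(cohort, 4)
  groups <- vapply(cohort, function(r) r$group, "")
  expect_equal(sum(groups == "FND-like"), 2)
  expect_equal(sum(groups == "SDP-like"), 2)
  expect_length(unique(vapply(cohort, function(r) r$subject_id, "")), 4)

  # empirical group prevalences over 10 seeded cohorts
  fnd <- sdp <- numeric(0)
  for (s in 1:10) {
    co <- generate_cohort(cap_sim_params(n_subjects = 4, duration_s = 300,
                                         seed = 100 + s))
    g <- vapply(co, function(r) r$group, "")
    pv <- vapply(co, function(r) mean(r$labels), 0)
    fnd <- c(fnd, pv[g == "FND-like"]); sdp <- c(sdp, pv[g == "SDP-like"])
  }
  expect_gt(mean(sdp), mean(fnd))
})

test_that("recordings and generator parameters round-trip through text files", {
  dir <- withr::local_tempdir()
  rec <- tiny_recording(seed = 9, duration_s = 30)
  hdr <- write_recording(rec, dir)
  back <- read_recording(hdr)
  expect_equal(back$labels, rec$labels)
  expect_equal(back$fs, rec$fs)
  expect_equal(back$subject_id, rec$subject_id)
  expect_equal(unname(back$signals), unname(rec$signals), tolerance = 1e-5)

  p <- cap_sim_params(duration_s = 300, prevalence = 0.2, seed = 42)
  f <- file.path(dir, "params.yaml")
  write_sim_params(p, f)
  expect_equal(read_sim_params(f), p)
})
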