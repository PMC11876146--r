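test_that("flat-segment detection finds exactly the constant runs", {
  expect_equal(nrow(detect_blanking(1:100)), 0L)
  iv <- detect_blanking(c(1, 1, 1, 1, 2, 3), min_run = 3)
  expect_equal(iv, data.frame(start = 1L, end = 4L))
  # run shorter than min_run is ignored
  expect_equal(nrow(detect_blanking(c(1, 1, 2, 3, 4), min_run = 3)), 0L)
  # two separate runs
  iv2 <- detect_blanking(c(5, 5, 5, 9, 2, 2, 2, 2, 7), min_run = 3)
  expect_equal(iv2, data.frame(start = c(1L, 5L), end = c(3L, 8L)))
  expect_error(detect_blanking(numeric(1)), "length")
  expect_error(detect_blanking(1:10, min_run = 1), "min_run")
})

test_that("detection recovers injected blanks exactly (round trip)", {
  cfg <- synthetic_config(duration = 30, n_channels = 1, seed = 17)
  rec <- generate_record(cfg)
  blanks <- list(
    blank_spec(onset = 500, blank_duration = 25),
    blank_spec(onset = 2000, blank_duration = 250),
    blank_spec(onset = 5000, blank_duration = 60)
  )
  stim <- inject_stimulation(rec, blanks)
  iv <- detect_blanking(stim$samples[, 1], min_run = 3)
  expect_equal(iv$start, c(500L, 2000L, 5000L))
  expect_equal(iv$end, c(524L, 2249L, 5059L))
})

test_that("artifact excision removes blank plus recovery and keeps books", {
  sig <- rnorm(22500)
  iv <- data.frame(start = 1001L, end = 1100L)
  out <- remove_artifacts(sig, iv, recovery_samples = 125)
  expect_s3_class(out, "clean_channel")
  expect_length(out$samples, 22500 - 100 - 125)
  expect_equal(out$original_length, 22500L)
  # identity on empty interval list
  out0 <- remove_artifacts(sig, detect_blanking(seq_along(sig)))
  expect_identical(out0$samples, sig)
  # clipping at the signal end
  sig2 <- rnorm(1000)
  out2 <- remove_artifacts(sig2, data.frame(start = 851L, end = 950L),
                           recovery_samples = 125)
  expect_length(out2$samples, 850)
  # bookkeeping invariant
  removed <- sum(out$removed_intervals$end - out$removed_intervals$start + 1)
  expect_equal(length(out$samples) + removed, length(sig))
})

test_that("deletions closer than the recovery window are merged", {
  sig <- rnorm(1000)
  iv <- data.frame(start = c(101L, 261L), end = c(200L, 360L))
  out <- remove_artifacts(sig, iv, recovery_samples = 125)
  expect_equal(nrow(out$removed_intervals), 1L)
  expect_equal(out$removed_intervals$start, 101L)
  expect_equal(out$removed_intervals$end, 485L)
  expect_length(out$samples, 1000 - 385)
})

test_that("malformed intervals are rejected", {
  sig <- rnorm(100)
  expect_error(remove_artifacts(sig, data.frame(start = 10L, end = 5L)),
               "end > start")
  expect_error(remove_artifacts(sig, data.frame(start = 90L, end = 120L)),
               "range")
  expect_error(
    remove_artifacts(sig, data.frame(start = c(10L, 5L), end = c(20L, 8L))),
    "sorted"
  )
})

test_that("z-scoring matches direct computation and rejects degenerates", {
  z <- zscore_normalize(c(1, 2, 3))
  expect_equal(z, c(-1, 0, 1) * sqrt(3 / 2), tolerance = 1e-12)
  expect_equal(z[2], 0)
  expect_equal(mean(z), 0, tolerance = 1e-12)
  expect_equal(sqrt(mean(z^2)), 1, tolerance = 1e-12)
  # idempotence up to tolerance
  x <- rnorm(500)
  z1 <- zscore_normalize(x)
  expect_equal(zscore_normalize(z1), z1, tolerance = 1e-10)
  expect_error(zscore_normalize(rep(4, 10)), "degenerate")
})

test_that("preprocessing a blanked record leaves no long constant run", {
  cfg <- synthetic_config(duration = 30, seed = 23)
  rec <- generate_record(cfg)
  rec <- inject_stimulation(rec, list(
    blank_spec(onset = 1000, blank_duration = 100),
    blank_spec(onset = 4000, blank_duration = 30)
  ))
  clean <- preprocess_record(rec)
  expect_s3_class(clean, "clean_record")
  for (ch in clean$channels) {
    expect_equal(nrow(detect_blanking(ch$samples, min_run = 3)), 0L)
    expect_equal(length(ch$samples) +
                   sum(ch$removed_intervals$end -
                         ch$removed_intervals$start + 1),
                 ch$original_length)
    expect_equal(mean(ch$samples), 0, tolerance = 1e-10)
  }
})
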