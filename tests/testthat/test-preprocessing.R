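test_that("select_channels resolves aliases, orders, and errors on missing", {
  rec <- make_test_recording(n_channels = 21)
  # vendor-style labels, shuffled order, plus extra channels
  set.seed(9)
  raw_names <- c(paste0("EEG ", toupper(default_montage()), "-REF"),
                 "ECG EKG-REF", "EEG 26-REF", "PHOTIC-REF",
                 paste0("EEG X", 1:8, "-LE"))
  perm <- sample(length(raw_names))
  sig <- matrix(stats::rnorm(length(raw_names) * 500), length(raw_names))
  rec32 <- new_eeg_recording(sig, 250, raw_names)
  rec32$signal <- rec32$signal[perm, ]
  rec32$channel_names <- raw_names[perm]
  out <- select_channels(rec32)
  expect_identical(out$channel_names, default_montage())
  expect_equal(nrow(out$signal), 21)
  # rows really follow montage order: compare against the alias map
  src <- match(default_montage(),
               normalize_channel_names(rec32$channel_names))
  expect_equal(out$signal, rec32$signal[src, ], ignore_attr = TRUE)

  # identity case
  out2 <- select_channels(rec)
  expect_identical(out2$signal, rec$signal)

  # missing channel named in the error (set-difference oracle)
  rec_miss <- rec
  rec_miss$signal <- rec$signal[-5, ]
  rec_miss$channel_names <- rec$channel_names[-5]
  missing_name <- setdiff(default_montage(), rec_miss$channel_names)
  expect_error(select_channels(rec_miss), missing_name, fixed = TRUE)
})

test_that("crop keeps exactly seconds 60..180", {
  rec <- make_test_recording(rate = 250, duration = 300)
  out <- crop_recording(rec)
  expect_equal(ncol(out$signal), 30000)
  # content equals samples 15001..45000 of the source (start sample 15000,
  # 0-based)
  expect_equal(out$signal, rec$signal[, 15001:45000])

  rec180 <- make_test_recording(rate = 100, duration = 180)
  expect_equal(ncol(crop_recording(rec180)$signal), 12000)

  rec90 <- make_test_recording(rate = 100, duration = 90)
  expect_error(crop_recording(rec90), "180")
})

test_that("clip_amplitude clamps to +-800 and keeps in-range values", {
  rec <- make_test_recording(n_channels = 2, rate = 100, duration = 180)
  rec$signal[1, 1] <- 900
  rec$signal[2, 2] <- -1000
  rec$signal[1, 3] <- 100
  out <- clip_amplitude(rec)
  expect_equal(out$signal[1, 1], 800)
  expect_equal(out$signal[2, 2], -800)
  expect_equal(out$signal[1, 3], 100)
  inside <- abs(rec$signal) <= 800
  expect_equal(out$signal[inside], rec$signal[inside])
})

test_that("resample_to preserves duration and dominant frequency", {
  rec <- make_test_recording(rate = 250, duration = 120 + 60)
  out <- resample_to(rec, 100)
  expect_equal(out$rate, 100)
  expect_equal(ncol(out$signal), ncol(rec$signal) * 100 / 250)

  # no-op at target rate
  rec100 <- make_test_recording(rate = 100, duration = 180)
  expect_identical(resample_to(rec100, 100)$signal, rec100$signal)

  # FFT-peak oracle: 10 Hz sinusoid stays at 10 Hz after 250 -> 100 Hz
  t <- seq_len(250 * 40) / 250
  pure <- new_eeg_recording(matrix(sin(2 * pi * 10 * t), 1), 250, "Cz")
  rs <- resample_to(pure, 100)
  spec <- Mod(stats::fft(rs$signal[1, ]))
  half <- seq_len(length(spec) %/% 2)
  peak_hz <- (which.max(spec[half]) - 1) * 100 / ncol(rs$signal)
  expect_lt(abs(peak_hz - 10), 100 / ncol(rs$signal) + 1e-9)  # one bin

  expect_error(resample_to(rec, -5), "positive")
})

test_that("scale_amplitude divides by 30", {
  rec <- make_test_recording(n_channels = 1, rate = 100, duration = 180)
  rec$signal[1, 1:3] <- c(600, 0, 800)
  out <- scale_amplitude(rec)
  expect_equal(out$signal[1, 1:3], c(20, 0, 800 / 30))
  expect_error(scale_amplitude(rec, 0), "nonzero")
})

test_that("extract_windows enumerates stride-aligned complete windows", {
  rec <- make_test_recording(rate = 100, duration = 120)
  stopifnot(ncol(rec$signal) == 12000)
  ws <- extract_windows(rec)
  # floor((12000-1200)/519)+1 = 21, last start 20*519 = 10380
  expect_equal(n_windows(ws), 21)
  expect_equal(ws$starts[21], 10380)
  expect_equal(diff(ws$starts), rep(519, 20))
  expect_true(all(ws$starts + 1200 <= 12000))
  # window contents match the signal slices
  expect_equal(ws$windows[4, , ], rec$signal[, (ws$starts[4] + 1):(ws$starts[4] + 1200)])

  one <- rec; one$signal <- one$signal[, 1:1200]
  expect_equal(n_windows(extract_windows(one)), 1)
  sub <- rec; sub$signal <- sub$signal[, 1:1199]
  expect_warning(ws0 <- extract_windows(sub), "empty")
  expect_equal(n_windows(ws0), 0)

  # right-aligned extra window on request
  wsr <- extract_windows(rec, right_align = TRUE)
  expect_equal(utils::tail(wsr$starts, 1), 12000 - 1200)
})

test_that("preprocess equals the stage composition and is deterministic", {
  rec <- make_test_recording(rate = 250, duration = 300, seed = 21)
  ws <- preprocess(rec)
  expect_equal(dim(ws$windows), c(21, 21, 1200))
  # stage-by-stage oracle (with the documented post-resample re-clamp)
  manual <- scale_amplitude(clip_amplitude(resample_to(
    clip_amplitude(crop_recording(select_channels(rec))))))
  ws2 <- extract_windows(manual)
  expect_equal(ws$windows, ws2$windows)
  # bit-identical on repeated calls
  expect_identical(preprocess(rec)$windows, ws$windows)
  # stage errors carry the stage name
  short <- make_test_recording(rate = 100, duration = 60)
  expect_error(preprocess(short), "crop_recording")
})

test_that("clipping before scaling bounds the chain output by 800/30", {
  rec <- make_test_recording(rate = 250, duration = 300, seed = 3)
  rec$signal[7, 20000:26000] <- 10000     # strong artifact plateau
  rec$signal[2, 30000:31000] <- -10000
  ws <- preprocess(rec)
  expect_equal(max(abs(ws$windows)), 800 / 30)
})
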