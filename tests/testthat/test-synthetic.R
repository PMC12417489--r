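test_that("event and class specs validate their domains", {
  expect_error(event_spec("oscillation", center_freq = 60, channels = "Cz",
                          amplitude = 10), "center_freq")
  expect_error(event_spec("oscillation", center_freq = 10, channels = "XX",
                          amplitude = 10), "outside montage")
  expect_error(corpus_spec(duration = 100), "duration")
  expect_s3_class(event_spec("sharp_wave", center_freq = 6,
                             channels = c("T3", "T5"), amplitude = 40),
                  "event_spec")
})

test_that("the beta class elevates 14-30 Hz band power on central channels", {
  spec <- corpus_spec(n_recordings = 4)
  rec <- generate_recording(default_classes()$abnormal_beta, seed = 101,
                            spec = spec)
  central <- c("C3", "Cz", "C4")
  bp_c <- band_power(rec, c(14, 30), central)
  bp_o <- band_power(rec, c(14, 30), setdiff(default_montage(), central))
  expect_gte(10 * log10(bp_c / bp_o), 3)
})

test_that("the normal class has its pooled spectral peak in the alpha band", {
  spec <- corpus_spec(n_recordings = 4)
  rec <- generate_recording(default_classes()$normal_alpha, seed = 102,
                            spec = spec)
  pool <- 0
  for (ch in seq_len(nrow(rec$signal))) {
    pool <- pool + welch_psd(rec$signal[ch, ], rec$rate)$power
  }
  f <- welch_psd(rec$signal[1, ], rec$rate)$freq
  sel <- f >= 1    # above the acquisition high-pass floor
  peak <- f[sel][which.max(pool[sel])]
  expect_gte(peak, 8)
  expect_lte(peak, 12)
})

test_that("injected event frequency is recoverable before and after preprocessing", {
  spec <- corpus_spec(n_recordings = 4)
  rec <- generate_recording(default_classes()$abnormal_beta, seed = 103,
                            spec = spec)
  ev <- attr(rec, "ground_truth")[[1]]
  peak_on <- function(x, rate, fmin = 12) {
    psd <- welch_psd(x, rate)
    sel <- psd$freq >= fmin
    psd$freq[sel][which.max(psd$power[sel])]
  }
  # raw signal, event channel
  cz <- which(rec$channel_names == "Cz")
  expect_lt(abs(peak_on(rec$signal[cz, ], rec$rate) - ev$center_freq), 2)
  # after the full chain (resampling preserves the peak)
  ws <- preprocess(rec)
  czw <- which(default_montage() == "Cz")
  win <- ws$windows[5, czw, ]
  expect_lt(abs(peak_on(win, 100) - ev$center_freq), 2)
})

test_that("sharp-wave events concentrate energy at their repetition rate", {
  # no background rhythm: isolate the sharp-wave waveform itself
  spec <- corpus_spec(n_recordings = 4, background = list())
  cls <- synthetic_class(
    name = "sharp", pathological = TRUE,
    events = list(event_spec("sharp_wave", center_freq = 6,
                             channels = c("T3", "T5"), amplitude = 60,
                             duty = 0.7)),
    impression = "Left temporal sharp waves",
    description = "Sharp waves with a frequency of 6 Hz")
  rec <- generate_recording(cls, seed = 104, spec = spec)
  t3 <- which(rec$channel_names == "T3")
  psd <- welch_psd(rec$signal[t3, ], rec$rate)
  sel <- psd$freq >= 4 & psd$freq <= 10
  peak <- psd$freq[sel][which.max(psd$power[sel])]
  expect_lt(abs(peak - 6), 1)
  # lateralized: T3/T5 dominate the right temporal channels in broad power
  expect_gt(band_power(rec, c(4, 10), c("T3", "T5")),
            band_power(rec, c(4, 10), c("T4", "T6")))
})

test_that("generate_corpus balances classes and derives consistent labels", {
  corpus <- memo("corpus20", function()
    generate_corpus(corpus_spec(n_recordings = 20, seed = 2)))
  man <- corpus$manifest
  counts <- table(man$class)
  expect_lte(max(counts) - min(counts), 1)
  # text/label consistency: medication keyword iff the class templates has it
  expect_true(all(man$medication[man$class == "abnormal_beta"]))
  expect_false(any(man$medication[man$class == "normal_alpha"]))
  expect_equal(man$pathological, man$class == "abnormal_beta")
  # all durations >= 180 s: preprocessing excludes nothing
  prep <- prepare_paired_data(corpus)
  expect_equal(length(prep$pairs$recording_ids), 20)
  expect_equal(n_pairs(prep$pairs), 20 * 21)
})

test_that("the generator is reproducible and corpus text round-trips to labels", {
  spec <- corpus_spec(n_recordings = 4)
  a <- generate_recording(default_classes()$abnormal_beta, 77, spec)
  b <- generate_recording(default_classes()$abnormal_beta, 77, spec)
  expect_identical(a$signal, b$signal)
  expect_identical(a$report_text, b$report_text)
  expect_identical(a$subject_meta, b$subject_meta)
  lab <- derive_labels(a$subject_meta, parse_report(a$report_text))
  expect_true(lab$medication)
  expect_true(lab$pathological)
})

test_that("plain-text corpus export round-trips recordings", {
  dir <- withr::local_tempdir()
  corpus <- generate_corpus(corpus_spec(n_recordings = 2, seed = 3))
  write_corpus(corpus, dir)
  man <- utils::read.csv(file.path(dir, "manifest.csv"))
  expect_equal(nrow(man), 2)
  rec <- corpus$recordings[[1]]
  back <- read_recording_csv(file.path(dir, paste0(rec$id, ".csv")))
  expect_equal(back$signal, rec$signal, tolerance = 1e-6, ignore_attr = TRUE)
  expect_equal(back$rate, rec$rate)
  expect_identical(back$channel_names, rec$channel_names)
  expect_equal(back$subject_meta$age, rec$subject_meta$age)
})
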