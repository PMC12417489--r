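#' Spectral/spatial event specification
#'
#' Describes one class-defining EEG event family injected by the synthetic
#' generator: either a band-limited `"oscillation"` (burst spindle-like
#' activity with a Hann envelope) or periodic `"sharp_wave"` transients
#' (raised-cosine rise, exponential decay) recurring at `center_freq`.
#'
#' @param kind `"oscillation"` or `"sharp_wave"`.
#' @param center_freq event frequency in Hz, in (0, 50).
#' @param bandwidth frequency jitter width in Hz (oscillations).
#' @param channels montage channels carrying the event.
#' @param amplitude peak amplitude in microvolts (> 0).
#' @param duty fraction of the recording covered by event bursts, in (0, 1].
#' @param role `"event"` or `"background"` (background rhythms such as a
#'   posterior alpha boost are modeled with the same machinery).
#' @return list of class `event_spec`.
#' @export
event_spec <- function(kind = c("oscillation", "sharp_wave"), center_freq,
                       bandwidth = 1, channels, amplitude, duty = 0.5,
                       role = "event", burst_sec = 1) {
  kind <- match.arg(kind)
  stopifnot(center_freq > 0, center_freq < 50, amplitude > 0,
            duty > 0, duty <= 1)
  bad <- setdiff(channels, default_montage())
  if (length(bad)) stop("event channels outside montage: ",
                        paste(bad, collapse = ", "))
  structure(list(kind = kind, center_freq = center_freq,
                 bandwidth = bandwidth, channels = channels,
                 amplitude = amplitude, duty = duty, role = role,
                 burst_sec = burst_sec),
            class = "event_spec")
}

#' Synthetic class definition
#'
#' Bundles the events, report templates and metadata distributions of one
#' recording class. Template sentences fill the three highest-coverage
#' report sections (impression, description, clinical history) plus the
#' medications section; distractor sentences shared across classes are
#' appended by the generator so text length alone cannot separate classes.
#'
#' @param name class label.
#' @param events list of [event_spec()].
#' @param impression,description,history,medications template sentences
#'   (character vectors; one is drawn per recording).
#' @param pathological class-level pathological flag.
#' @param age_range inclusive integer range ages are drawn from.
#' @param p_female probability of gender `"F"`.
#' @return list of class `synthetic_class`.
#' @export
synthetic_class <- function(name, events, impression, description,
                            history = "Routine outpatient EEG.",
                            medications = "None.",
                            pathological = FALSE,
                            age_range = c(18, 85), p_female = 0.5) {
  structure(list(name = name, events = events, impression = impression,
                 description = description, history = history,
                 medications = medications, pathological = pathological,
                 age_range = age_range, p_female = p_female),
            class = "synthetic_class")
}

#' Default two-class synthetic world
#'
#' The stock corpus used for end-to-end testing: an *abnormal* class with
#' 20 Hz beta-spindle bursts over the central electrodes (C3, Cz, C4) and a
#' seizure-medication report, versus a *normal* class with no events. Both
#' classes share the same background -- 1/f-shaped Gaussian noise (exponent
#' 1, 30 uV RMS, white floor) plus a sustained posterior-dominant 10 Hz
#' alpha rhythm (see [corpus_spec()]) -- so the beta event is the *only*
#' class-discriminative EEG feature and the model cannot shortcut through
#' background differences. Amplitudes keep the preprocessed signal near
#' unit variance and give the beta event >= 3 dB of 14--30 Hz central band
#' power over non-event channels.
#'
#' @return list of two `synthetic_class` objects.
#' @export
default_classes <- function() {
  list(
    abnormal_beta = synthetic_class(
      name = "abnormal_beta",
      events = list(event_spec("oscillation", center_freq = 20,
                               bandwidth = 2,
                               channels = c("C3", "Cz", "C4"),
                               amplitude = 50, duty = 0.6)),
      impression = "This is an abnormal recording",
      description = "20 Hz beta spindles in central regions",
      medications = "Keppra.",
      pathological = TRUE
    ),
    normal_alpha = synthetic_class(
      name = "normal_alpha",
      events = list(),          # background rhythms only
      impression = "This is a normal recording",
      description = "The posterior background consists of a well regulated alpha rhythm",
      medications = "Aspirin.",
      pathological = FALSE
    )
  )
}

# distractor sentences shared by every class
shared_distractors <- function() {
  list(history = "The patient was awake throughout the recording session.",
       description = "Technically satisfactory record without excessive artifact.")
}

#' Synthetic corpus specification
#'
#' @param n_recordings total recordings (default 200, balanced over classes
#'   to within one recording).
#' @param classes list of [synthetic_class()] (>= 2 for contrastive use).
#' @param rate sampling rate in Hz (default 100).
#' @param duration recording length in seconds (>= 180 so the standard crop
#'   applies; default 180).
#' @param noise list with `exponent` (1/f slope, default 1), `white`
#'   (relative white-noise floor, default 0.05) and `rms` (background RMS in
#'   microvolts, default 30 so the /30 rescaling lands near unit variance).
#' @param background list of [event_spec()] applied to *every* recording
#'   regardless of class; the default is a sustained posterior-dominant
#'   10 Hz alpha rhythm (70 uV posterior, 25 uV widespread), the normal
#'   waking background of clinical EEG.
#' @param seed master seed.
#' @return list of class `corpus_spec`.
#' @export
corpus_spec <- function(n_recordings = 200, classes = default_classes(),
                        rate = 100, duration = 180,
                        noise = list(exponent = 1, white = 0.05, rms = 30),
                        background = default_background(),
                        seed = 1L) {
  stopifnot(n_recordings >= 2, length(classes) >= 2, duration >= 180)
  structure(list(n_recordings = n_recordings, classes = classes,
                 rate = rate, duration = duration, noise = noise,
                 background = background, seed = as.integer(seed)),
            class = "corpus_spec")
}

#' Default shared background rhythms
#'
#' The sustained posterior-dominant alpha rhythm added to every synthetic
#' recording: 10 Hz, 70 uV over posterior electrodes with a 25 uV
#' widespread component, overlap-added 4 s pieces with 1.5 Hz jitter.
#'
#' @return list of [event_spec()] with role `"background"`.
#' @export
default_background <- function() {
  posterior <- c("O1", "O2", "P3", "Pz", "P4", "T5", "T6")
  list(
    event_spec("oscillation", center_freq = 10, bandwidth = 1.5,
               channels = posterior, amplitude = 70, duty = 0.8,
               role = "background", burst_sec = 4),
    event_spec("oscillation", center_freq = 10, bandwidth = 1.5,
               channels = setdiff(default_montage(), posterior),
               amplitude = 25, duty = 0.8,
               role = "background", burst_sec = 4)
  )
}

# 1/f-shaped Gaussian background, one channel per row, target RMS in uV.
pink_background <- function(n_channels, S, rate, exponent, white, rms) {
  f <- c(0, seq_len(S - 1)) * rate / S
  f <- pmin(f, rate - f)                     # two-sided frequency axis
  # 1 Hz floor emulates the acquisition high-pass of clinical EEG hardware
  shape <- 1 / pmax(f, 1)^(exponent / 2) + white
  shape[1] <- 0                              # no DC
  out <- matrix(0, n_channels, S)
  for (c in seq_len(n_channels)) {
    W <- stats::fft(stats::rnorm(S)) * shape
    x <- Re(stats::fft(W, inverse = TRUE)) / S
    out[c, ] <- x / stats::sd(x) * rms
  }
  out
}

# one burst waveform of an event at sample rate `rate`
event_burst <- function(ev, len, rate) {
  t <- seq_len(len) / rate
  if (ev$kind == "oscillation") {
    f <- ev$center_freq + stats::runif(1, -ev$bandwidth / 2, ev$bandwidth / 2)
    carrier <- sin(2 * pi * f * t + stats::runif(1, 0, 2 * pi))
    env <- 0.5 * (1 - cos(2 * pi * seq_len(len) / len))   # Hann
    ev$amplitude * carrier * env
  } else {
    # periodic asymmetric transients at center_freq
    period <- max(1L, round(rate / ev$center_freq))
    rise <- max(2L, round(0.02 * rate))
    decay_len <- max(2L, round(0.06 * rate))
    proto <- c(0.5 * (1 - cos(pi * seq_len(rise) / rise)),
               exp(-seq_len(decay_len) / (0.02 * rate)))
    wave <- numeric(len)
    starts <- seq.int(1L, len - length(proto), by = period)
    for (s in starts) {
      wave[s:(s + length(proto) - 1L)] <- wave[s:(s + length(proto) - 1L)] + proto
    }
    env <- 0.5 * (1 - cos(2 * pi * seq_len(len) / len))
    ev$amplitude * wave * env
  }
}

# add an event's bursts onto the signal matrix (in place value semantics).
# role = "event": sparse bursts at random onsets covering ~duty of the record.
# role = "background": a sustained rhythm, realized as 50%-overlapping Hann
# pieces (constant-overlap-add) with per-piece frequency jitter, scaled by
# duty -- the morphology of a posterior dominant rhythm rather than spindles.
add_event <- function(signal, ev, rate, montage) {
  S <- ncol(signal)
  ch_idx <- match(ev$channels, montage)
  burst_len <- round(ev$burst_sec * rate)
  if (identical(ev$role, "background")) {
    onsets <- seq.int(1L, S - burst_len + 1L, by = max(1L, burst_len %/% 2L))
    amp_scale <- ev$duty
  } else {
    n_bursts <- max(1L, round(ev$duty * S / burst_len))
    slots <- max(n_bursts, floor(S / burst_len))
    onsets <- (sample(slots, n_bursts) - 1L) * burst_len + 1L
    amp_scale <- 1
  }
  for (on in onsets) {
    len <- min(burst_len, S - on + 1L)
    if (len < rate / 4) next
    w <- amp_scale * event_burst(ev, len, rate)
    gain <- stats::runif(length(ch_idx), 0.85, 1)
    for (k in seq_along(ch_idx)) {
      rows <- on:(on + len - 1L)
      signal[ch_idx[k], rows] <- signal[ch_idx[k], rows] + gain[k] * w
    }
  }
  signal
}

#' Generate one synthetic recording with its report
#'
#' Fully reproducible from `seed`: background 1/f noise per channel, class
#' events added on their target channels, report text assembled from the
#' class templates under canonical section headers, metadata sampled from
#' the class distributions. The injected events are attached as attribute
#' `"ground_truth"`.
#'
#' @param class_def a [synthetic_class()].
#' @param seed integer seed.
#' @param spec a [corpus_spec()] supplying rate, duration and noise model.
#' @param id recording identifier.
#' @return an `eeg_recording`.
#' @export
generate_recording <- function(class_def, seed,
                               spec = corpus_spec(), id = NULL) {
  set.seed(seed)
  montage <- default_montage()
  S <- round(spec$duration * spec$rate)
  sig <- pink_background(length(montage), S, spec$rate,
                         spec$noise$exponent, spec$noise$white,
                         spec$noise$rms)
  for (ev in c(spec$background, class_def$events)) {
    sig <- add_event(sig, ev, spec$rate, montage)
  }
  dist <- shared_distractors()
  rep_obj <- new_clinical_report(list(
    clinical_history = paste(sample(class_def$history, 1),
                             dist$history),
    medications = sample(class_def$medications, 1),
    description_of_the_record = paste(sample(class_def$description, 1),
                                      dist$description),
    impression = sample(class_def$impression, 1)
  ))
  age <- sample(class_def$age_range[1]:class_def$age_range[2], 1)
  gender <- if (stats::runif(1) < class_def$p_female) "F" else "M"
  rec <- new_eeg_recording(
    signal = sig, rate = spec$rate, channel_names = montage,
    subject_meta = list(age = age, gender = gender,
                        pathological = class_def$pathological),
    report_text = render_report(rep_obj),
    id = id
  )
  attr(rec, "ground_truth") <- class_def$events
  attr(rec, "class_name") <- class_def$name
  rec
}

#' Generate a paired synthetic corpus
#'
#' Round-robin class assignment (balance within one recording), one derived
#' seed per recording, and a manifest linking recording, report and derived
#' labels. Every recording is at least 180 s, so the standard preprocessing
#' chain applies without exclusions.
#'
#' @param spec a [corpus_spec()].
#' @return list of class `synthetic_corpus` with `recordings` (list of
#'   `eeg_recording`), `manifest` (data.frame of id, class, age, gender,
#'   pathological, medication), and `spec`.
#' @export
generate_corpus <- function(spec = corpus_spec()) {
  classes <- spec$classes
  k <- length(classes)
  recs <- vector("list", spec$n_recordings)
  man <- vector("list", spec$n_recordings)
  for (i in seq_len(spec$n_recordings)) {
    cls <- classes[[((i - 1L) %% k) + 1L]]
    seed_i <- (spec$seed * 7919 + i * 104729) %% 2147483647
    id <- sprintf("rec%04d", i)
    rec <- generate_recording(cls, seed = seed_i, spec = spec, id = id)
    recs[[i]] <- rec
    lab <- derive_labels(rec$subject_meta, rec$report_text)
    man[[i]] <- data.frame(
      id = id, class = cls$name,
      age = rec$subject_meta$age, gender = rec$subject_meta$gender,
      pathological = lab$pathological, age_over_50 = lab$age_over_50,
      medication = lab$medication, stringsAsFactors = FALSE
    )
  }
  structure(list(recordings = stats::setNames(recs, vapply(recs, `[[`, "", "id")),
                 manifest = do.call(rbind, man), spec = spec),
            class = "synthetic_corpus")
}

#' @export
print.synthetic_corpus <- function(x, ...) {
  cat(sprintf("<synthetic_corpus: %d recordings, classes: %s>\n",
              length(x$recordings),
              paste(names(table(x$manifest$class)), collapse = ", ")))
  invisible(x)
}

#' Preprocess a corpus into paired training data
#'
#' Runs the standard preprocessing chain on every recording, pairs the
#' resulting windows with each recording's report under `selection`, and
#' returns the paired dataset together with the manifest. Raw signals are
#' released as they are consumed to bound memory.
#'
#' @param corpus a `synthetic_corpus` (or any list with `recordings` and
#'   `manifest` of the same shape).
#' @param config a [preproc_config()].
#' @param selection report sections used as pairing text.
#' @return list with `pairs` ([make_pairs()] result) and `manifest`.
#' @export
prepare_paired_data <- function(corpus, config = preproc_config(),
                                selection = "all") {
  ids <- names(corpus$recordings)
  reports <- list()
  wsets <- vector("list", length(ids))
  for (i in seq_along(ids)) {
    rec <- corpus$recordings[[i]]
    wsets[[i]] <- preprocess(rec, config)
    reports[[ids[i]]] <- rec$report_text
    corpus$recordings[[i]] <- list(id = rec$id)   # release raw signal
  }
  pairs <- make_pairs(wsets, reports, selection)
  list(pairs = pairs, manifest = corpus$manifest)
}

#' Write a corpus to a plain-text directory layout
#'
#' One signal CSV and one report text file per recording plus a
#' `manifest.csv`; the text-based stand-in for binary EDF export.
#'
#' @param corpus a `synthetic_corpus`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_corpus <- function(corpus, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (rec in corpus$recordings) {
    write_recording_csv(rec, file.path(dir, paste0(rec$id, ".csv")))
    writeLines(rec$report_text, file.path(dir, paste0(rec$id, ".txt")))
  }
  utils::write.csv(corpus$manifest, file.path(dir, "manifest.csv"),
                   row.names = FALSE)
  invisible(dir)
}

#' Welch power spectral density
#'
#' Mean periodogram over half-overlapping Hann-windowed segments; the
#' spectral oracle used to verify injected events and band power.
#'
#' @param x numeric vector.
#' @param rate sampling rate in Hz.
#' @param seg segment length in samples (default 512).
#' @return list with `freq` (Hz) and `power` (density per Hz).
#' @export
welch_psd <- function(x, rate, seg = 512) {
  step <- seg %/% 2
  starts <- seq.int(1L, length(x) - seg + 1L, by = step)
  win <- 0.5 * (1 - cos(2 * pi * seq_len(seg) / (seg + 1)))
  acc <- numeric(seg %/% 2 + 1)
  for (s in starts) {
    xs <- x[s:(s + seg - 1L)] * win
    P <- abs(stats::fft(xs))^2 / (sum(win^2) * rate)
    acc <- acc + P[seq_len(seg %/% 2 + 1)]
  }
  list(freq = (seq_len(seg %/% 2 + 1) - 1) * rate / seg,
       power = acc / length(starts))
}

#' Band power of selected channels
#'
#' @param rec an `eeg_recording` (or channels x samples matrix with
#'   attribute-free rate given explicitly).
#' @param band numeric length-2 frequency band in Hz.
#' @param channels channel names (default all).
#' @param rate required if `rec` is a bare matrix.
#' @return mean band power (uV^2) over the selected channels.
#' @export
band_power <- function(rec, band, channels = NULL, rate = NULL) {
  if (inherits(rec, "eeg_recording")) {
    sig <- rec$signal
    rate <- rec$rate
    idx <- if (is.null(channels)) seq_len(nrow(sig)) else
      match(channels, rec$channel_names)
  } else {
    sig <- rec
    idx <- seq_len(nrow(sig))
    if (is.null(rate)) stop("rate required for bare matrices")
  }
  pw <- vapply(idx, function(c) {
    psd <- welch_psd(sig[c, ], rate)
    sel <- psd$freq >= band[1] & psd$freq <= band[2]
    sum(psd$power[sel]) * (psd$freq[2] - psd$freq[1])
  }, 0)
  mean(pw)
}
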