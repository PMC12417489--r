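#' Default 21-electrode clinical montage
#'
#' The standard 10-20 electrode subset present in all recordings of the large
#' clinical archives this pipeline targets (TUH naming convention, including
#' the ear references A1/A2 and the older T3/T4/T5/T6 temporal labels).
#'
#' @return character vector of 21 canonical channel names.
#' @export
default_montage <- function() {
  c("Fp1", "Fp2", "F7", "F3", "Fz", "F4", "F8",
    "T3", "C3", "Cz", "C4", "T4",
    "T5", "P3", "Pz", "P4", "T6",
    "O1", "O2", "A1", "A2")
}

#' Normalize clinical channel labels
#'
#' Maps vendor/archive channel labels onto canonical 10-20 names:
#' strips an `"EEG "` prefix and a reference suffix (`"-REF"`, `"-LE"`,
#' `"-AVG"`), and canonicalizes case (`"EEG FP1-REF"` -> `"Fp1"`).
#' Labels that do not resolve to a montage name are returned title-cased
#' but otherwise untouched.
#'
#' @param names character vector of raw channel labels.
#' @return character vector of normalized labels.
#' @export
normalize_channel_names <- function(names) {
  x <- toupper(trimws(names))
  x <- sub("^EEG\\s+", "", x)
  x <- sub("-(REF|LE|AVG)$", "", x)
  canon <- default_montage()
  idx <- match(x, toupper(canon))
  out <- ifelse(is.na(idx), names, canon[idx])
  # unmatched labels: keep original spelling
  as.character(out)
}

#' Select and order montage channels
#'
#' Restricts a recording to the electrodes of a montage, in montage order.
#' Raw labels are alias-normalized first, so `"EEG FP1-REF"` satisfies a
#' request for `"Fp1"`.
#'
#' @param rec an `eeg_recording`.
#' @param montage ordered character vector of channel names
#'   (default [default_montage()]).
#' @return an `eeg_recording` with exactly the montage channels.
#' @export
select_channels <- function(rec, montage = default_montage()) {
  have <- normalize_channel_names(rec$channel_names)
  idx <- match(montage, have)
  if (anyNA(idx)) {
    missing <- montage[is.na(idx)]
    stop("montage channel(s) not present in recording: ",
         paste(missing, collapse = ", "))
  }
  rec$signal <- rec$signal[idx, , drop = FALSE]
  rec$channel_names <- montage
  rec
}

#' Crop a recording to its analysis segment
#'
#' Discards the first minute (setup artifacts, electrode settling) and keeps
#' exactly the next two minutes: seconds `[60, 180)` of the recording.
#' Recordings shorter than 180 s are rejected rather than padded.
#'
#' @param rec an `eeg_recording` of at least 180 s.
#' @return the cropped `eeg_recording` (120 s long).
#' @export
crop_recording <- function(rec) {
  dur <- recording_duration(rec)
  if (dur < 180) {
    stop("recording excluded: duration ", round(dur, 3),
         " s is shorter than the required 180 s")
  }
  from <- floor(60 * rec$rate) + 1L   # first sample at t = 60 s
  to <- floor(180 * rec$rate)         # last sample before t = 180 s
  rec$signal <- rec$signal[, from:to, drop = FALSE]
  rec
}

#' Clip amplitudes to a symmetric bound
#'
#' Clamps every sample into `[-bound, +bound]` microvolts to suppress strong
#' artifacts; in-range values pass through unchanged.
#'
#' @param rec an `eeg_recording`.
#' @param bound positive clipping bound in microvolts (default 800).
#' @return the clipped `eeg_recording`.
#' @export
clip_amplitude <- function(rec, bound = 800) {
  rec$signal[rec$signal > bound] <- bound
  rec$signal[rec$signal < -bound] <- -bound
  rec
}

# FFT-based resampling of the rows of a matrix to n_out samples.
# Equivalent to Fourier resampling: truncate (or zero-pad) the spectrum and
# inverse-transform, scaling by n_out/n_in. Assumes band-limited content;
# acceptance of this stage is the FFT-peak property, not bit-level equality
# with any particular polyphase implementation.
resample_rows_fft <- function(x, n_out) {
  n_in <- ncol(x)
  if (n_out == n_in) return(x)
  X <- stats::mvfft(t(x))                       # n_in x C, column-wise FFT
  Y <- matrix(0i, nrow = n_out, ncol = ncol(X))
  n_keep <- min(n_in, n_out)
  h <- n_keep %/% 2
  pos <- seq_len(h + 1L)                        # DC .. +Nyquist of smaller grid
  Y[pos, ] <- X[pos, ]
  if (h > 1) {
    neg <- seq_len(h - 1L + (n_keep %% 2))
    Y[n_out - rev(neg) + 1L, ] <- X[n_in - rev(neg) + 1L, ]
  }
  if (n_keep %% 2 == 0 && h >= 1) {
    # shared Nyquist bin: split between the two conjugate positions
    Y[h + 1L, ] <- X[h + 1L, ] / 2
    Y[n_out - h + 1L, ] <- Conj(X[h + 1L, ]) / 2 + Y[n_out - h + 1L, ]
  }
  y <- Re(stats::mvfft(Y, inverse = TRUE)) / n_in
  t(y) * 1  # C x n_out
}

#' Resample a recording to a target rate
#'
#' Fourier-domain resampling of every channel to `target` Hz. Duration is
#' preserved to within one sample. Intended for downsampling clinical EEG to
#' the 100 Hz model rate; upsampling works but is not the designed use.
#'
#' @param rec an `eeg_recording`.
#' @param target target rate in Hz (default 100).
#' @return the resampled `eeg_recording` with `rate == target`.
#' @export
resample_to <- function(rec, target = 100) {
  if (!is.numeric(target) || length(target) != 1L || target <= 0) {
    stop("target rate must be a positive scalar")
  }
  if (rec$rate == target) return(rec)
  n_out <- as.integer(round(ncol(rec$signal) * target / rec$rate))
  rec$signal <- resample_rows_fft(rec$signal, n_out)
  rec$rate <- target
  rec
}

#' Rescale amplitudes toward unit variance
#'
#' Divides every sample by a fixed divisor (default 30) so that typical
#' clinical EEG, after clipping, sits near unit variance for the encoder.
#'
#' @param rec an `eeg_recording`.
#' @param divisor nonzero scale divisor (default 30).
#' @return the rescaled `eeg_recording`.
#' @export
scale_amplitude <- function(rec, divisor = 30) {
  if (divisor == 0) stop("divisor must be nonzero")
  rec$signal <- rec$signal / divisor
  rec
}

#' Cut a recording into fixed-length windows
#'
#' Emits complete windows of `length` samples starting at
#' `0, stride, 2*stride, ...`; a trailing fragment shorter than `length` is
#' dropped (optionally a final right-aligned window can be added instead).
#' The defaults (1200 samples, stride 519 at 100 Hz) give 12 s windows laid
#' out so a four-block conv-pool encoder covers all timesteps without gaps.
#'
#' @param rec an `eeg_recording`.
#' @param length window length in samples (default 1200).
#' @param stride hop between window starts in samples (default 519).
#' @param right_align if `TRUE`, append one final window flush with the end
#'   of the signal when the last stride-aligned window does not reach it.
#' @return a `window_set`; empty (with a warning) if the signal is shorter
#'   than one window.
#' @export
extract_windows <- function(rec, length = 1200, stride = 519,
                            right_align = FALSE) {
  S <- ncol(rec$signal)
  C <- nrow(rec$signal)
  id <- if (is.null(rec$id)) NA else rec$id
  if (S < length) {
    warning("signal shorter than one window (", S, " < ", length,
            "); returning empty window_set")
    return(new_window_set(array(0, dim = c(0, C, length)),
                          recording_ids = rep(id, 0), rate = rec$rate,
                          starts = integer(0)))
  }
  starts <- seq.int(0L, S - length, by = stride)
  if (right_align && starts[base::length(starts)] != S - length) {
    starts <- c(starts, S - length)
  }
  n <- base::length(starts)
  w <- array(0, dim = c(n, C, length))
  for (i in seq_len(n)) {
    w[i, , ] <- rec$signal[, (starts[i] + 1L):(starts[i] + length)]
  }
  new_window_set(w, recording_ids = rep(id, n), rate = rec$rate,
                 starts = as.integer(starts))
}

#' Preprocessing configuration
#'
#' @param montage channel montage (default [default_montage()]).
#' @param clip_bound clipping bound in microvolts.
#' @param target_rate model sampling rate in Hz.
#' @param scale_divisor amplitude divisor.
#' @param window_length window length in samples at `target_rate`.
#' @param window_stride window stride in samples.
#' @param right_align see [extract_windows()].
#' @return a list of class `preproc_config`.
#' @export
preproc_config <- function(montage = default_montage(), clip_bound = 800,
                           target_rate = 100, scale_divisor = 30,
                           window_length = 1200, window_stride = 519,
                           right_align = FALSE) {
  structure(list(montage = montage, clip_bound = clip_bound,
                 target_rate = target_rate, scale_divisor = scale_divisor,
                 window_length = window_length, window_stride = window_stride,
                 right_align = right_align),
            class = "preproc_config")
}

#' Full preprocessing chain
#'
#' Deterministic composition
#' select channels -> crop to seconds 60..180 -> clip to +-800 uV ->
#' resample to 100 Hz -> divide by 30 -> window (1200 samples, stride 519).
#' Clipping is applied in microvolts *before* scaling, so the post-chain
#' amplitude bound is exactly `clip_bound / scale_divisor` (800/30 by
#' default). Same input and config always give bit-identical output.
#'
#' @param rec an `eeg_recording`.
#' @param config a [preproc_config()].
#' @return a `window_set`.
#' @export
preprocess <- function(rec, config = preproc_config()) {
  stage <- function(name, f) {
    tryCatch(f(), error = function(e) {
      stop("preprocess stage '", name, "': ", conditionMessage(e),
           call. = FALSE)
    })
  }
  rec <- stage("select_channels", function()
    select_channels(rec, config$montage))
  rec <- stage("crop_recording", function() crop_recording(rec))
  rec <- stage("clip_amplitude", function()
    clip_amplitude(rec, config$clip_bound))
  rec <- stage("resample_to", function()
    resample_to(rec, config$target_rate))
  # Fourier resampling can overshoot the clip bound by ringing; re-clamp so
  # the chain's stated amplitude bound is exact.
  rec <- stage("clip_amplitude", function()
    clip_amplitude(rec, config$clip_bound))
  rec <- stage("scale_amplitude", function()
    scale_amplitude(rec, config$scale_divisor))
  stage("extract_windows", function()
    extract_windows(rec, config$window_length, config$window_stride,
                    config$right_align))
}
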