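#' Input gradient of a text-alignment score
#'
#' Gradient, with respect to the raw EEG window, of the cosine similarity
#' between the window's projection and a prompt's projection (for
#' `clip_model`), or of a plain linear functional `sum(W * x)` (for a
#' [linear_scorer()] surrogate used as an analytic oracle). Computed in
#' inference mode; one independent gradient per window.
#'
#' @param model a `clip_model` or `linear_scorer`.
#' @param windows `n x C x T` array or `window_set`.
#' @param prompt prompt string (ignored by linear scorers).
#' @return `n x C x T` array of gradients.
#' @export
input_gradient <- function(model, windows, prompt = NULL) {
  UseMethod("input_gradient")
}

#' @export
input_gradient.clip_model <- function(model, windows, prompt = NULL) {
  if (is.null(prompt) || !nzchar(trimws(prompt))) stop("prompt is empty")
  x <- if (inherits(windows, "window_set")) windows$windows else windows
  if (dim(x)[1] < 1L) stop("need at least one window")
  p <- as.numeric(model_embed_text(model, prompt))
  emb <- model$eeg_encoder$forward(x, training = FALSE)
  px <- model$head_x$forward(emb, training = FALSE)
  cx <- l2_normalize_rows(px, warn = FALSE)
  # d/dpx of sum_i <cx_i, p>: every window contributes independently
  dcx <- matrix(p, nrow = nrow(px), ncol = length(p), byrow = TRUE)
  dpx <- l2_normalize_backward(dcx, cx)
  demb <- model$head_x$backward(dpx)
  g <- model$eeg_encoder$backward(demb, need_input_grad = TRUE)
  zero_grads(c(model$main_params, model$text_params))   # discard side effects
  g
}

#' Linear read-out surrogate
#'
#' A degenerate "encoder" whose score is the inner product of the window
#' with a fixed channels x samples weight array. Its input gradient is the
#' weight array itself, which makes it the analytic oracle for attribution
#' correctness (e.g. a weight reading a single channel's pure cosine at
#' bin frequency f concentrates all spectral mass at (channel, f)).
#'
#' @param W `C x T` numeric weight matrix.
#' @return object of class `linear_scorer`.
#' @export
linear_scorer <- function(W) {
  structure(list(W = as.matrix(W)), class = "linear_scorer")
}

#' @export
input_gradient.linear_scorer <- function(model, windows, prompt = NULL) {
  x <- if (inherits(windows, "window_set")) windows$windows else windows
  n <- dim(x)[1]
  g <- array(0, dim = dim(x))
  for (i in seq_len(n)) g[i, , ] <- model$W
  g
}

#' Frequency-domain gradient attribution
#'
#' Re-parameterizes every window by its unitary real-FFT coefficients per
#' channel (the time-domain signal being the inverse transform inside the
#' computation graph) and computes the gradient of the alignment score with
#' respect to those coefficients: for an input gradient `g` this is
#' `w_k * FFT(g)_k / sqrt(T)` per channel, with `w_k = 2` for interior bins
#' and `1` at DC/Nyquist. Per-bin complex gradients are reduced to
#' magnitudes (or signed real parts) and averaged across windows.
#'
#' @param model a `clip_model` or [linear_scorer()].
#' @param windows `n x C x T` array or `window_set` (the evaluation split's
#'   windows, typically).
#' @param prompt the text prompt whose alignment is attributed.
#' @param signed if `TRUE`, `per_channel` holds the signed real part of the
#'   coefficient gradient instead of its magnitude; the pooled spectrum is
#'   always the channel-mean of the magnitude view.
#' @param rate sampling rate in Hz (default 100, Nyquist 50).
#' @param channel_names optional channel labels for the rows.
#' @return object of class `spectral_attribution`: `grid` (Hz,
#'   `T/2 + 1` bins), `per_channel` (`C x F`), `pooled` (length `F`,
#'   nonnegative), `prompt`, `n_windows`, `signed`.
#' @export
frequency_gradients <- function(model, windows, prompt = NULL,
                                signed = FALSE, rate = 100,
                                channel_names = NULL) {
  g <- input_gradient(model, windows, prompt)
  d <- dim(g)
  n <- d[1]; C <- d[2]; T <- d[3]
  nf <- T %/% 2 + 1L
  w <- c(1, rep(2, nf - 2L), if (T %% 2 == 0) 1 else 2)
  mag <- matrix(0, C, nf)
  sgn <- matrix(0, C, nf)
  for (i in seq_len(n)) {
    Fg <- stats::mvfft(t(matrix(g[i, , ], C, T)))[seq_len(nf), , drop = FALSE]
    Gk <- Fg * w / sqrt(T)
    mag <- mag + t(Mod(Gk))
    sgn <- sgn + t(Re(Gk))
  }
  mag <- mag / n
  sgn <- sgn / n
  if (!is.null(channel_names)) {
    rownames(mag) <- rownames(sgn) <- channel_names
  }
  structure(list(
    grid = (seq_len(nf) - 1) * rate / T,
    per_channel = if (signed) sgn else mag,
    pooled = colMeans(mag),
    prompt = prompt,
    n_windows = n,
    signed = signed
  ), class = "spectral_attribution")
}

#' @export
print.spectral_attribution <- function(x, ...) {
  pk <- x$grid[which.max(x$pooled)]
  cat(sprintf(
    "<spectral_attribution: %d channels x %d bins (0..%g Hz), %d windows, pooled peak %.2f Hz>\n",
    nrow(x$per_channel), length(x$grid), max(x$grid), x$n_windows, pk))
  invisible(x)
}

#' Channel x frequency attribution heatmap
#'
#' Base-graphics rendering of the electrode-resolved attribution map.
#'
#' @param x a `spectral_attribution`.
#' @param fmax upper frequency limit of the display (Hz).
#' @param ... passed to [graphics::image()].
#' @return `x` invisibly.
#' @export
plot_attribution <- function(x, fmax = 50, ...) {
  sel <- x$grid <= fmax
  graphics::image(x = x$grid[sel], y = seq_len(nrow(x$per_channel)),
                  z = t(x$per_channel[, sel]),
                  xlab = "frequency (Hz)", ylab = "channel",
                  yaxt = "n", ...)
  labs <- rownames(x$per_channel)
  if (!is.null(labs)) {
    graphics::axis(2, at = seq_along(labs), labels = labs, las = 2,
                   cex.axis = 0.6)
  }
  invisible(x)
}
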