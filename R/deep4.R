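#' Four-block convolutional EEG encoder
#'
#' A deep ConvNet for raw EEG in the Deep4 lineage: a first block that
#' factorizes the spatio-temporal filter into a temporal convolution
#' (applied to every electrode with shared weights) followed by a spatial
#' convolution across electrodes, then three conv--max-pool blocks, all with
#' batch normalization, ELU activations, max pooling of width 3 and dropout
#' before each later convolution. The dense softmax classifier of the
#' original design is replaced by flatten + linear to a `embedding_dim`
#' vector (default 128), the representation consumed by projection heads and
#' probes.
#'
#' With the default 21 channels x 1200 samples input and kernel 10 / pool 3,
#' the temporal axis contracts 1200 -> 1191 -> 397 -> 388 -> 129 -> 120 ->
#' 40 -> 31 -> 10, giving a `widths[4] * 10` flattened feature vector.
#'
#' @param n_channels number of electrodes (default 21).
#' @param input_samples window length in samples (default 1200).
#' @param widths integer vector of 4 block widths (default
#'   `c(25, 50, 100, 200)`). Smaller widths give a proportionally cheaper
#'   model for CPU-bound experiments.
#' @param kernel temporal kernel length (default 10).
#' @param pool max-pool width and stride (default 3).
#' @param dropout dropout probability before blocks 2--4 (default 0.5).
#' @param embedding_dim output embedding dimension (default 128).
#' @return an encoder object (class `deep4_encoder`) with closures
#'   `forward(x, training)` mapping an `n x C x T` array to `n x
#'   embedding_dim`, and `backward(dE)` returning the input gradient
#'   `n x C x T`; `$params` lists all trainable parameters.
#' @export
deep4_encoder <- function(n_channels = 21, input_samples = 1200,
                          widths = c(25, 50, 100, 200), kernel = 10,
                          pool = 3, dropout = 0.5, embedding_dim = 128) {
  stopifnot(length(widths) == 4, all(widths >= 1))
  self <- new.env()
  self$config <- list(n_channels = n_channels, input_samples = input_samples,
                      widths = widths, kernel = kernel, pool = pool,
                      dropout = dropout, embedding_dim = embedding_dim)
  F1 <- widths[1]
  self$conv_t <- nn_conv1d(1, F1, kernel, name = "conv_time")
  self$conv_s <- nn_conv1d(F1 * n_channels, F1, 1, name = "conv_spat")
  block1_tail <- list(nn_batchnorm(F1, name = "bn1"), nn_elu(), nn_maxpool(pool))
  t_len <- function(t) (t - kernel + 1L) %/% pool
  blocks <- list()
  Tcur <- t_len(input_samples)
  Fprev <- F1
  for (b in 2:4) {
    Fb <- widths[b]
    blocks <- c(blocks, list(
      nn_dropout(dropout),
      nn_conv1d(Fprev, Fb, kernel, name = paste0("conv", b)),
      nn_batchnorm(Fb, name = paste0("bn", b)),
      nn_elu(),
      nn_maxpool(pool)
    ))
    Tcur <- t_len(Tcur)
    Fprev <- Fb
  }
  self$trunk <- nn_sequential(c(block1_tail, blocks))
  self$flat_dim <- widths[4] * Tcur
  if (Tcur < 1) stop("input too short for this architecture")
  self$head <- nn_linear(self$flat_dim, embedding_dim, name = "embed")
  self$params <- c(self$conv_t$params, self$conv_s$params,
                   self$trunk$params, self$head$params)

  # layout "nct": x is (n, C, T); layout "tcn": x is already (T, C, n),
  # the internal order, letting batch assembly skip one large permute.
  self$forward <- function(x, training = TRUE, layout = "nct") {
    d <- dim(x)
    if (layout == "nct") {
      if (length(d) != 3 || d[2] != n_channels || d[3] != input_samples) {
        stop("expected windows shaped n x ", n_channels, " x ", input_samples,
             ", got ", paste(d, collapse = " x "))
      }
      n <- d[1]
      # (n, C, T) -> one single-channel series per (electrode, sample) pair
      x1 <- aperm(x, c(3, 2, 1))
    } else {
      if (d[1] != input_samples || d[2] != n_channels) {
        stop("tcn layout expects ", input_samples, " x ", n_channels, " x n")
      }
      n <- d[3]
      x1 <- x
    }
    self$n <- n
    dim(x1) <- c(1, input_samples, n_channels * n)
    h <- self$conv_t$forward(x1, training)          # (F1, T1, C*n)
    T1 <- dim(h)[2]
    self$T1 <- T1
    h <- cpp_gather_spatial(h, F1, T1, n_channels, n)
    dim(h) <- c(F1 * n_channels, T1, n)             # electrodes into channels
    h <- self$conv_s$forward(h, training)           # (F1, T1, n)
    h <- self$trunk$forward(h, training)            # (F4, T4, n)
    self$trunk_out_dim <- dim(h)
    hm <- h
    dim(hm) <- c(prod(dim(h)[1:2]), n)
    self$head$forward(t(hm), training)              # (n, embedding_dim)
  }

  self$backward <- function(dE, need_input_grad = FALSE) {
    n <- self$n
    dflat <- self$head$backward(dE)                 # (n, F4*T4)
    dh <- t(dflat)
    dim(dh) <- self$trunk_out_dim
    dh <- self$trunk$backward(dh)                   # (F1, T1, n)
    dh <- self$conv_s$backward(dh)                  # (F1*C, T1, n)
    T1 <- self$T1
    dh <- cpp_scatter_spatial(dh, F1, T1, n_channels, n)
    dim(dh) <- c(F1, T1, n_channels * n)
    dx1 <- self$conv_t$backward(dh, need_dx = need_input_grad)
    if (!need_input_grad) return(invisible(NULL))
    dim(dx1) <- c(input_samples, n_channels, n)     # (1, T, C*n) reshaped
    aperm(dx1, c(3, 2, 1))                          # (n, C, T)
  }
  class(self) <- c("deep4_encoder", "nn_layer")
  self
}

#' Encode EEG windows to embeddings
#'
#' Runs the EEG encoder in inference mode (no dropout, batch-norm running
#' statistics), so the result is a pure function of windows and parameters.
#'
#' @param encoder a [deep4_encoder()].
#' @param windows a `window_set` or an `n x C x T` array.
#' @return `n x embedding_dim` matrix.
#' @export
eeg_encode <- function(encoder, windows) {
  x <- if (inherits(windows, "window_set")) windows$windows else windows
  encoder$forward(x, training = FALSE)
}
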