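#' Three-layer MLP projection head
#'
#' Maps an encoder embedding into the shared contrastive space: three
#' fully-connected layers with ReLU activations between them, the last
#' outputting `out_dim` (64 by default). The two hidden layers are batch
#' normalized before the ReLU (the SimCLR-style head): without this,
#' small-data contrastive training reliably collapses -- the head's
#' outputs grow a dominant shared-mean direction, cosine similarities
#' become uniform, and the normalization's 1/norm factor freezes all
#' encoder gradients. Rows are *not* L2-normalized here; the model
#' normalizes projections onto the unit sphere where cosine similarity is
#' taken (see [project_embedding()]).
#'
#' @param in_dim input embedding width.
#' @param out_dim projection width (default 64; configurable, e.g. 32--512).
#' @param hidden hidden width of the two inner layers (default 128).
#' @param name parameter name prefix.
#' @return an `nn_layer` with `forward`/`backward`/`params`.
#' @export
projection_head <- function(in_dim, out_dim = 64, hidden = 128,
                            name = "proj") {
  nn_sequential(list(
    nn_linear(in_dim, hidden, name = paste0(name, ".fc1")),
    nn_batchnorm_mat(hidden, name = paste0(name, ".bn1")),
    nn_relu_mat(),
    nn_linear(hidden, hidden, name = paste0(name, ".fc2")),
    nn_batchnorm_mat(hidden, name = paste0(name, ".bn2")),
    nn_relu_mat(),
    nn_linear(hidden, out_dim, name = paste0(name, ".fc3"))
  ))
}

#' Project embeddings into the shared space
#'
#' Applies a projection head in inference mode and L2-normalizes the rows.
#' An all-zero pre-normalization row maps to the zero vector with a warning
#' rather than NaN.
#'
#' @param head a [projection_head()].
#' @param emb `n x in_dim` embedding matrix.
#' @return `n x out_dim` matrix with unit-norm (or zero) rows.
#' @export
project_embedding <- function(head, emb) {
  l2_normalize_rows(head$forward(emb, training = FALSE))$y
}

#' Dual-encoder EEG--text alignment model
#'
#' Assembles the EEG encoder, a text encoder satisfying the contract, and
#' the two projection heads into one trainable model with a learnable
#' softmax logit scale (inverse temperature), initialized at `1/0.07` and
#' clamped to `[1e-3, 100]` in the CLIP tradition.
#'
#' @param eeg_encoder a [deep4_encoder()].
#' @param text_encoder a text encoder (e.g. [hash_text_encoder()]).
#' @param projection_dim shared space width (default 64).
#' @param proj_hidden hidden width of the projection heads.
#' @param temperature_init initial logit scale (default `1/0.07`).
#' @param symmetric use the symmetric two-direction loss (default `TRUE`).
#' @return an object of class `clip_model`.
#' @export
clip_model <- function(eeg_encoder, text_encoder, projection_dim = 64,
                          proj_hidden = 128, temperature_init = 1 / 0.07,
                          symmetric = TRUE) {
  self <- new.env()
  self$eeg_encoder <- eeg_encoder
  self$text_encoder <- text_encoder
  self$symmetric <- symmetric
  self$projection_dim <- projection_dim
  self$head_x <- projection_head(eeg_encoder$config$embedding_dim,
                                 projection_dim, proj_hidden, name = "proj_x")
  self$head_y <- projection_head(text_encoder$dim,
                                 projection_dim, proj_hidden, name = "proj_y")
  self$log_scale <- new_param(log(temperature_init), decay = FALSE,
                              name = "log_scale")
  # main parameter group: EEG encoder, both heads, logit scale;
  # text group: the text encoder's own parameters (LR-ratio scaled).
  self$main_params <- c(eeg_encoder$params, self$head_x$params,
                        self$head_y$params, list(self$log_scale))
  self$text_params <- text_encoder$params
  class(self) <- "clip_model"
  self
}

#' @export
print.clip_model <- function(x, ...) {
  np <- sum(vapply(c(x$main_params, x$text_params),
                   function(p) length(p$val), 0))
  cat(sprintf(
    "<clip_model: %s-d shared space, %s text encoder, %d parameters>\n",
    x$projection_dim, x$text_encoder$kind, np))
  invisible(x)
}

# current clamped logit scale (inverse temperature)
model_scale <- function(model) {
  min(max(exp(model$log_scale$val), 1e-3), 100)
}

#' Model temperature
#' @param model a `clip_model`.
#' @return the softmax temperature `tau = 1 / logit_scale`.
#' @export
model_temperature <- function(model) 1 / model_scale(model)

#' EEG windows to shared-space projections
#' @param model a `clip_model`.
#' @param windows `window_set` or `n x C x T` array.
#' @param space `"projection"` (64-d, normalized) or `"embedding"`
#'   (raw encoder output, default width 128).
#' @return matrix of per-window vectors.
#' @export
model_embed_eeg <- function(model, windows, space = c("projection", "embedding")) {
  space <- match.arg(space)
  emb <- eeg_encode(model$eeg_encoder, windows)
  if (space == "embedding") return(emb)
  l2_normalize_rows(model$head_x$forward(emb, training = FALSE))$y
}

#' Texts to shared-space projections
#' @param model a `clip_model`.
#' @param texts character vector.
#' @return `length(texts) x projection_dim` matrix, unit-norm rows.
#' @export
model_embed_text <- function(model, texts) {
  emb <- model$text_encoder$encode(as.character(texts), training = FALSE)
  l2_normalize_rows(model$head_y$forward(emb, training = FALSE))$y
}

# One optimization step's forward+backward over a matched batch.
# Returns the scalar loss; parameter gradients are accumulated in place.
# x may be (n, C, T) [layout "nct"] or pre-permuted (T, C, n) ["tcn"].
model_train_step <- function(model, x, texts, layout = "nct") {
  emb_x <- model$eeg_encoder$forward(x, training = TRUE, layout = layout)
  emb_y <- model$text_encoder$encode(texts, training = TRUE)
  px <- model$head_x$forward(emb_x, training = TRUE)
  py <- model$head_y$forward(emb_y, training = TRUE)
  cx <- l2_normalize_rows(px, warn = FALSE)
  cy <- l2_normalize_rows(py, warn = FALSE)
  sim <- tcrossprod(cx$y, cy$y)
  tau <- 1 / model_scale(model)
  lg <- contrastive_loss(sim, symmetric = model$symmetric, tau = tau,
                         grad = TRUE)
  # backward
  dzx <- lg$grad_sim %*% cy$y
  dzy <- t(lg$grad_sim) %*% cx$y
  dpx <- l2_normalize_backward(dzx, cx)
  dpy <- l2_normalize_backward(dzy, cy)
  demb_x <- model$head_x$backward(dpx)
  demb_y <- model$head_y$backward(dpy)
  model$eeg_encoder$backward(demb_x)
  model$text_encoder$backward(demb_y)
  # logit scale gradient, zeroed at the clamp boundary
  sc <- exp(model$log_scale$val)
  if (sc > 1e-3 && sc < 100) {
    model$log_scale$grad <- model$log_scale$grad + lg$grad_log_scale
  }
  lg$loss
}

#' Save / load a model checkpoint
#'
#' Serializes parameter values plus the full architectural configuration
#' (encoder widths, projection dimension, text-encoder kind and vocabulary,
#' temperature, montage and preprocessing constants) into a versioned file,
#' and reconstructs a functionally identical model from it. Pretrained
#' external text encoders cannot be serialized; saving such a model stores
#' the contract metadata and `load_checkpoint()` requires the encoder to be
#' supplied again.
#'
#' @param model a `clip_model`.
#' @param path file path.
#' @param preproc optional [preproc_config()] to store alongside.
#' @return `load_checkpoint` returns a `clip_model`.
#' @export
save_checkpoint <- function(model, path, preproc = NULL) {
  enc <- model$text_encoder
  txt_meta <- list(kind = enc$kind, dim = enc$dim,
                   max_tokens = enc$max_tokens,
                   vocab = if (enc$kind == "avg_embedding") enc$vocab)
  obj <- list(
    format = "eegalign-checkpoint",
    version = 1L,
    eeg_config = model$eeg_encoder$config,
    projection_dim = model$projection_dim,
    symmetric = model$symmetric,
    log_scale = model$log_scale$val,
    text = txt_meta,
    preproc = preproc,
    eeg_params = lapply(model$eeg_encoder$params, function(p) p$val),
    head_x_params = lapply(model$head_x$params, function(p) p$val),
    head_y_params = lapply(model$head_y$params, function(p) p$val),
    text_params = lapply(model$text_params, function(p) p$val),
    bn_stats = lapply(collect_bn_layers(model), function(b)
      list(mean = b$running_mean, var = b$running_var))
  )
  saveRDS(obj, path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @param text_encoder required when the checkpoint was built around an
#'   unserializable (pretrained/external) text encoder.
#' @export
load_checkpoint <- function(path, text_encoder = NULL) {
  obj <- readRDS(path)
  if (!identical(obj$format, "eegalign-checkpoint")) {
    stop("not an eegalign checkpoint: ", path)
  }
  cfg <- obj$eeg_config
  enc <- do.call(deep4_encoder, cfg)
  txt <- text_encoder
  if (is.null(txt)) {
    txt <- switch(obj$text$kind,
      hash = hash_text_encoder(obj$text$dim, obj$text$max_tokens),
      avg_embedding = avg_embedding_text_encoder(
        obj$text$vocab, obj$text$dim, obj$text$max_tokens),
      stop("checkpoint uses a '", obj$text$kind,
           "' text encoder; pass text_encoder= to load_checkpoint()")
    )
    if (obj$text$kind == "avg_embedding") txt$vocab <- obj$text$vocab
  }
  model <- clip_model(enc, txt, projection_dim = obj$projection_dim,
                         symmetric = obj$symmetric)
  restore <- function(params, vals) {
    stopifnot(length(params) == length(vals))
    for (i in seq_along(params)) params[[i]]$val <- vals[[i]]
  }
  restore(model$eeg_encoder$params, obj$eeg_params)
  restore(model$head_x$params, obj$head_x_params)
  restore(model$head_y$params, obj$head_y_params)
  restore(model$text_params, obj$text_params)
  if (!is.null(obj$bn_stats)) {
    bns <- collect_bn_layers(model)
    stopifnot(length(bns) == length(obj$bn_stats))
    for (i in seq_along(bns)) {
      bns[[i]]$running_mean <- obj$bn_stats[[i]]$mean
      bns[[i]]$running_var <- obj$bn_stats[[i]]$var
    }
  }
  model$log_scale$val <- obj$log_scale
  model$preproc <- obj$preproc
  model
}
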