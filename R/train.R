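#' Pair EEG windows with their recording's report text
#'
#' Every window of a recording is paired with the (section-selected) text
#' of that same recording's report: one report serves all of its windows.
#' Recordings whose selected text is empty are dropped, with the dropped
#' pair count reported via `message()`.
#'
#' @param windows a `window_set`, or a list of `window_set` (one per
#'   recording); window `recording_ids` must resolve into `reports`.
#' @param reports named list (by recording id) of `clinical_report` objects
#'   or raw report strings.
#' @param selection section keys passed to [select_sections()], or `"all"`.
#' @return a `paired_dataset`: per-recording window arrays plus the shared
#'   text of each recording.
#' @export
make_pairs <- function(windows, reports, selection = "all") {
  if (inherits(windows, "window_set")) windows <- list(windows)
  win_by_rec <- list()
  for (ws in windows) {
    stopifnot(inherits(ws, "window_set"))
    for (id in unique(ws$recording_ids)) {
      sel <- ws$recording_ids == id
      arr <- ws$windows[sel, , , drop = FALSE]
      key <- as.character(id)
      win_by_rec[[key]] <- if (is.null(win_by_rec[[key]])) arr else {
        abind_first(win_by_rec[[key]], arr)
      }
    }
  }
  ids <- names(win_by_rec)
  missing <- ids[!ids %in% names(reports)]
  if (length(missing)) {
    stop("no report for recording(s): ", paste(missing, collapse = ", "))
  }
  texts <- vapply(ids, function(id) {
    r <- reports[[id]]
    if (!inherits(r, "clinical_report")) r <- parse_report(as.character(r))
    select_sections(r, selection)
  }, "")
  empty <- !nzchar(trimws(texts))
  if (any(empty)) {
    n_drop <- sum(vapply(win_by_rec[empty], function(a) dim(a)[1], 0L))
    message("dropping ", n_drop, " window pair(s) from ", sum(empty),
            " recording(s) with empty selected text")
    win_by_rec <- win_by_rec[!empty]
    texts <- texts[!empty]
    ids <- ids[!empty]
  }
  structure(list(recording_ids = ids,
                 windows = win_by_rec,
                 texts = texts),
            class = "paired_dataset")
}

# bind two (n, C, T) arrays along the first axis
abind_first <- function(a, b) {
  da <- dim(a); db <- dim(b)
  stopifnot(all(da[-1] == db[-1]))
  out <- array(0, dim = c(da[1] + db[1], da[2], da[3]))
  if (da[1]) out[seq_len(da[1]), , ] <- a
  if (db[1]) out[da[1] + seq_len(db[1]), , ] <- b
  out
}

#' @export
print.paired_dataset <- function(x, ...) {
  n <- sum(vapply(x$windows, function(a) dim(a)[1], 0L))
  cat(sprintf("<paired_dataset: %d window-text pairs over %d recordings>\n",
              n, length(x$recording_ids)))
  invisible(x)
}

#' Number of window-text pairs
#' @param pairs a `paired_dataset`.
#' @return integer.
#' @export
n_pairs <- function(pairs) {
  sum(vapply(pairs$windows, function(a) dim(a)[1], 0L))
}

#' Contrastive training configuration
#'
#' Defaults follow the reference training recipe: Adam, learning rate
#' `5e-3`, weight decay `5e-4`, 20 epochs, batch size 64, text-encoder
#' learning rate `lr * text_lr_ratio` with ratio `1e-3`.
#'
#' @param lr main learning rate.
#' @param weight_decay L2 penalty added to the Adam gradient.
#' @param epochs training epochs.
#' @param batch_size recordings (or pairs) per batch.
#' @param text_lr_ratio text-encoder LR as a fraction of `lr`.
#' @param section_selection report sections used as training text.
#' @param seed master seed driving initialization, shuffling and sampling.
#' @param projection_dim shared-space width.
#' @param eeg_widths Deep4 block widths.
#' @param embedding_dim EEG embedding width.
#' @param proj_hidden projection-head hidden width.
#' @param temperature_init initial logit scale.
#' @param symmetric symmetric loss (see [contrastive_loss()]).
#' @param one_window_per_recording if `TRUE` (default) a batch holds at most
#'   one window per recording, sampled uniformly, so in-batch negatives
#'   never share a report.
#' @param bn_recalibrate refresh batch-norm running statistics with one
#'   full training-mode pass after the last epoch (see [calibrate_bn()]).
#' @return list of class `train_config`.
#' @export
train_config <- function(lr = 5e-3, weight_decay = 5e-4, epochs = 20,
                         batch_size = 64, text_lr_ratio = 1e-3,
                         section_selection = "all", seed = 1L,
                         projection_dim = 64,
                         eeg_widths = c(25, 50, 100, 200),
                         embedding_dim = 128, proj_hidden = 128,
                         temperature_init = 1 / 0.07, symmetric = TRUE,
                         one_window_per_recording = TRUE,
                         bn_recalibrate = TRUE) {
  stopifnot(lr > 0, weight_decay >= 0, epochs >= 1, batch_size >= 2,
            text_lr_ratio >= 0, projection_dim >= 1)
  structure(as.list(environment()), class = "train_config")
}

#' Train the contrastive EEG--text model
#'
#' Full training loop: batches of matched (window, report-text) pairs are
#' pushed through both encoders and projection heads, the InfoNCE loss and
#' its gradients are computed, and Adam updates two parameter groups -- the
#' EEG side (encoder, both projection heads, logit scale) at `lr`, and the
#' text encoder's own parameters at `lr * text_lr_ratio`. With the default
#' batch policy each batch contains at most one window per recording so
#' that in-batch negatives never share a report.
#'
#' Reproducibility: the whole trajectory is a deterministic function of
#' (`pairs`, `cfg`, the initial model) for a fixed `cfg$seed`.
#'
#' @param pairs a [make_pairs()] dataset with at least 2 recordings.
#' @param cfg a [train_config()].
#' @param model optionally a pre-built [clip_model()]; by default one is
#'   constructed from `cfg` with a hashing text encoder.
#' @param text_encoder text encoder used when `model` is `NULL`.
#' @param verbose print per-epoch losses.
#' @return list of class `clip_fit` with `model`, `loss_history`
#'   (per-epoch mean loss), `cfg`.
#' @export
train_clip <- function(pairs, cfg = train_config(), model = NULL,
                          text_encoder = NULL, verbose = FALSE) {
  stopifnot(inherits(pairs, "paired_dataset"))
  ids <- pairs$recording_ids
  if (length(ids) < 2L) {
    stop("contrastive training requires at least 2 distinct recordings")
  }
  set.seed(cfg$seed)
  if (is.null(model)) {
    if (is.null(text_encoder)) text_encoder <- hash_text_encoder()
    d <- dim(pairs$windows[[1]])
    enc <- deep4_encoder(n_channels = d[2], input_samples = d[3],
                         widths = cfg$eeg_widths,
                         embedding_dim = cfg$embedding_dim)
    model <- clip_model(enc, text_encoder,
                           projection_dim = cfg$projection_dim,
                           proj_hidden = cfg$proj_hidden,
                           temperature_init = cfg$temperature_init,
                           symmetric = cfg$symmetric)
  }
  opt <- nn_adam(list(
    list(params = model$main_params, lr = cfg$lr,
         weight_decay = cfg$weight_decay),
    list(params = model$text_params, lr = cfg$lr * cfg$text_lr_ratio,
         weight_decay = cfg$weight_decay)
  ))
  nw <- vapply(pairs$windows, function(a) dim(a)[1], 0L)
  loss_history <- numeric(cfg$epochs)
  for (epoch in seq_len(cfg$epochs)) {
    if (cfg$one_window_per_recording) {
      order_rec <- sample(length(ids))
      pick <- vapply(nw[order_rec], function(k) sample.int(k, 1L), 0L)
      item_rec <- order_rec
      item_win <- pick
    } else {
      all_rec <- rep(seq_along(ids), nw)
      all_win <- unlist(lapply(nw, seq_len), use.names = FALSE)
      ord <- sample(length(all_rec))
      item_rec <- all_rec[ord]
      item_win <- all_win[ord]
    }
    n_items <- length(item_rec)
    starts <- seq.int(1L, n_items, by = cfg$batch_size)
    losses <- numeric(0)
    for (s in starts) {
      idx <- s:min(s + cfg$batch_size - 1L, n_items)
      if (length(idx) < 2L) next   # a single pair has no negatives
      dwin <- dim(pairs$windows[[1]])
      bx <- array(0, dim = c(dwin[3], dwin[2], length(idx)))   # (T, C, n)
      for (j in seq_along(idx)) {
        cpp_fill_batch(bx, pairs$windows[[item_rec[idx[j]]]][item_win[idx[j]], , ],
                       dwin[3], dwin[2], j - 1L)
      }
      btxt <- unname(pairs$texts[item_rec[idx]])
      opt$zero()
      losses <- c(losses, model_train_step(model, bx, btxt, layout = "tcn"))
      opt$step()
    }
    loss_history[epoch] <- mean(losses)
    if (verbose) {
      cat(sprintf("epoch %d/%d  mean loss %.4f\n",
                  epoch, cfg$epochs, loss_history[epoch]))
    }
  }
  if (isTRUE(cfg$bn_recalibrate)) calibrate_bn(model, pairs)
  structure(list(model = model, loss_history = loss_history, cfg = cfg),
            class = "clip_fit")
}

#' Recalibrate batch-normalization statistics
#'
#' Replaces every batch-norm layer's running statistics with the statistics
#' of one full training-mode pass over the dataset (one window per
#' recording, dropout disabled). During contrastive training the running
#' averages lag behind the fast-moving parameters -- especially around the
#' plateau-escape phase -- which can leave inference-mode projections
#' collapsed while training-mode projections are well separated. A single
#' recalibration pass after training closes that gap. Called automatically
#' at the end of [train_clip()] (config flag `bn_recalibrate`).
#'
#' @param model a `clip_model`.
#' @param pairs the training `paired_dataset`.
#' @param max_recordings cap on the calibration batch (memory guard).
#' @return the model, invisibly (statistics updated in place).
#' @export
calibrate_bn <- function(model, pairs, max_recordings = 512L) {
  bns <- collect_bn_layers(model)
  drops <- collect_dropout_layers(model)
  old_mom <- lapply(bns, function(b) b$momentum)
  old_p <- lapply(drops, function(d) d$p)
  on.exit({
    for (i in seq_along(bns)) bns[[i]]$momentum <- old_mom[[i]]
    for (i in seq_along(drops)) drops[[i]]$p <- old_p[[i]]
  })
  for (b in bns) b$momentum <- 1
  for (d in drops) d$p <- 0
  ids <- pairs$recording_ids
  if (length(ids) > max_recordings) ids <- sample(ids, max_recordings)
  d <- dim(pairs$windows[[1]])
  bx <- array(0, dim = c(d[3], d[2], length(ids)))
  for (j in seq_along(ids)) {
    k <- sample.int(dim(pairs$windows[[ids[j]]])[1], 1L)
    cpp_fill_batch(bx, pairs$windows[[ids[j]]][k, , ], d[3], d[2], j - 1L)
  }
  emb <- model$eeg_encoder$forward(bx, training = TRUE, layout = "tcn")
  invisible(model$head_x$forward(emb, training = TRUE))
  ty <- model$text_encoder$encode(unname(pairs$texts[ids]), training = FALSE)
  invisible(model$head_y$forward(ty, training = TRUE))
  invisible(model)
}

#' @export
print.clip_fit <- function(x, ...) {
  cat(sprintf("<clip_fit: %d epochs, final mean loss %.4f>\n",
              length(x$loss_history), utils::tail(x$loss_history, 1)))
  invisible(x)
}
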