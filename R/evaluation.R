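#' Balanced accuracy
#'
#' Mean of the per-class recalls for a binary task; insensitive to class
#' imbalance (a constant predictor scores 0.5). Errors if the label vector
#' does not contain both classes.
#'
#' @param preds predicted classes (logical, or coercible to character).
#' @param labels true classes, same length.
#' @return scalar in `[0, 1]`.
#' @export
balanced_accuracy <- function(preds, labels) {
  stopifnot(length(preds) == length(labels))
  labels <- as.character(labels)
  preds <- as.character(preds)
  classes <- sort(unique(labels))
  if (length(classes) != 2L) {
    stop("labels must contain exactly two classes (got ",
         length(classes), ")")
  }
  recalls <- vapply(classes, function(cl) {
    mean(preds[labels == cl] == cl)
  }, 0)
  mean(recalls)
}

#' Aggregate window vectors into one recording vector
#'
#' Mean of the per-window embeddings of one recording; when the vectors
#' live in the cosine (projection) space the mean is re-normalized onto the
#' unit sphere.
#'
#' @param model a `clip_model`.
#' @param rec_windows `window_set` or `n x C x T` array with `n >= 1`.
#' @param space `"projection"` or `"embedding"`.
#' @return a single numeric vector.
#' @export
recording_embedding <- function(model, rec_windows,
                                space = c("projection", "embedding")) {
  space <- match.arg(space)
  x <- if (inherits(rec_windows, "window_set")) rec_windows$windows else rec_windows
  if (dim(x)[1] < 1L) stop("recording has no windows")
  v <- colMeans(model_embed_eeg(model, x, space))
  if (space == "projection") {
    nrm <- sqrt(sum(v^2))
    if (nrm > 1e-12) v <- v / nrm
  }
  v
}

#' Zero-shot classification from text prompt prototypes
#'
#' Embeds the two class prompts of a task as prototypes in the shared
#' space and assigns every recording to the class whose prompt projection
#' is most cosine-similar to the recording's aggregated projection. No
#' task labels are used. Exact ties go to class A with a warning.
#'
#' @param model a trained `clip_model`.
#' @param recordings named list of per-recording window arrays (or
#'   `window_set`s).
#' @param task task name passed to [build_prompts()]; ignored if `prompts`
#'   is given.
#' @param prompts optional named character vector `c(A = ..., B = ...)`.
#' @return named logical vector: `TRUE` where class B wins.
#' @export
zero_shot_classify <- function(model, recordings, task = NULL,
                               prompts = NULL) {
  if (is.null(prompts)) {
    if (is.null(task)) stop("give either task or prompts")
    prompts <- build_prompts(task)
  }
  stopifnot(all(c("A", "B") %in% names(prompts)))
  if (any(!nzchar(trimws(prompts)))) stop("empty prompt")
  proto <- model_embed_text(model, unname(prompts[c("A", "B")]))
  out <- vapply(recordings, function(w) {
    v <- recording_embedding(model, w, space = "projection")
    s <- as.numeric(proto %*% v)
    if (s[1] == s[2]) {
      warning("zero-shot similarity tie; assigning class A")
      return(FALSE)
    }
    s[2] > s[1]
  }, TRUE)
  names(out) <- names(recordings)
  out
}

#' Window-level embeddings grouped by recording
#'
#' @param model a `clip_model`.
#' @param windows named list of per-recording window arrays.
#' @param space `"embedding"` (default: the 128-d encoder output feeds
#'   downstream probes) or `"projection"`.
#' @return named list of `n_i x d` matrices.
#' @export
embed_by_recording <- function(model, windows,
                               space = c("embedding", "projection")) {
  space <- match.arg(space)
  lapply(windows, function(w) model_embed_eeg(model, w, space))
}

#' Fit a classification head on frozen embeddings
#'
#' The two probe families used to assess representation quality: ridge
#' logistic regression (`"logreg"`) and a small 3-layer MLP (`"mlp"`,
#' hidden width 64, ReLU). No gradient reaches the encoder: probes see
#' only the embedding matrix.
#'
#' @param emb `n x d` embedding matrix (window-level).
#' @param y logical vector of length `n` (both classes present).
#' @param head `"logreg"` or `"mlp"`.
#' @param seed seed for the MLP initialization/optimization.
#' @param mlp_iters full-batch Adam iterations for the MLP head.
#' @return object of class `probe_fit` with a `$predict(emb)` closure
#'   returning class-B probabilities.
#' @export
probe_fit <- function(emb, y, head = c("logreg", "mlp"), seed = 1L,
                      mlp_iters = 300L) {
  head <- match.arg(head)
  y <- as.logical(y)
  if (length(unique(y)) < 2L) stop("probe training labels need both classes")
  if (head == "logreg") {
    fit <- glmnet::glmnet(emb, factor(y), family = "binomial", alpha = 0,
                          lambda = 1e-3, standardize = TRUE)
    predict_fn <- function(newx) {
      as.numeric(stats::predict(fit, newx = newx, type = "response"))
    }
  } else {
    set.seed(seed)
    net <- nn_sequential(list(
      nn_linear(ncol(emb), 64, name = "probe.fc1"), nn_relu_mat(),
      nn_linear(64, 64, name = "probe.fc2"), nn_relu_mat(),
      nn_linear(64, 1, name = "probe.fc3")
    ))
    opt <- nn_adam(list(list(params = net$params, lr = 1e-2,
                             weight_decay = 5e-4)))
    yv <- as.numeric(y)
    for (it in seq_len(mlp_iters)) {
      opt$zero()
      z <- net$forward(emb, training = TRUE)
      p <- 1 / (1 + exp(-z))
      dz <- (p - yv) / length(yv)
      net$backward(dz)
      opt$step()
    }
    predict_fn <- function(newx) {
      as.numeric(1 / (1 + exp(-net$forward(newx, training = FALSE))))
    }
  }
  structure(list(predict = predict_fn, head = head), class = "probe_fit")
}

# recording-level class-B probability: mean window probability
predict_recordings <- function(fit, emb_by_rec) {
  vapply(emb_by_rec, function(E) mean(fit$predict(E)), 0)
}

#' Frozen-embedding probe evaluated at the recording level
#'
#' Trains a head on window-level embeddings of the training recordings and
#' reports balanced accuracy over the evaluation recordings, where a
#' recording's score is its mean window probability.
#'
#' @param train_emb,eval_emb named lists of per-recording embedding
#'   matrices ([embed_by_recording()]).
#' @param train_labels,eval_labels named logical vectors (recording level).
#' @param head `"logreg"` or `"mlp"`.
#' @param seed passed to [probe_fit()].
#' @return list of class `eval_result`: `balanced_accuracy`, `method`,
#'   `preds`.
#' @export
probe_evaluate <- function(train_emb, train_labels, eval_emb, eval_labels,
                           head = "logreg", seed = 1L) {
  ids <- names(train_emb)
  emb <- do.call(rbind, train_emb[ids])
  y <- rep(as.logical(train_labels[ids]),
           vapply(train_emb[ids], nrow, 0L))
  fit <- probe_fit(emb, y, head = head, seed = seed)
  prob <- predict_recordings(fit, eval_emb)
  preds <- prob > 0.5
  structure(list(
    balanced_accuracy = balanced_accuracy(preds,
                                          as.logical(eval_labels[names(eval_emb)])),
    method = paste0("clip_", head), preds = preds, prob = prob
  ), class = "eval_result")
}

#' Supervised EEG classifier (task-specific baseline)
#'
#' A Deep4-style encoder plus linear logit head trained end-to-end with
#' binary cross-entropy on window-level labels inherited from the
#' recording. This is the from-scratch upper-bound baseline; with
#' `freeze_encoder = TRUE` and a pre-built encoder it becomes the
#' transfer setting (head-only training).
#'
#' @param windows named list of per-recording window arrays.
#' @param labels named logical vector (recording level).
#' @param epochs,batch_size,lr,weight_decay optimizer budget.
#' @param widths,embedding_dim encoder architecture.
#' @param seed seed for initialization and shuffling.
#' @param encoder optional existing encoder to reuse.
#' @param freeze_encoder train only the head.
#' @return list of class `supervised_fit` with `encoder`, `head`,
#'   `$predict(windows_list)` returning recording-level probabilities.
#' @export
train_supervised <- function(windows, labels, epochs = 10, batch_size = 32,
                             lr = 5e-3, weight_decay = 5e-4,
                             widths = c(25, 50, 100, 200),
                             embedding_dim = 128, seed = 1L,
                             encoder = NULL, freeze_encoder = FALSE) {
  ids <- names(windows)
  y_rec <- as.logical(labels[ids])
  stopifnot(!anyNA(y_rec))
  set.seed(seed)
  d <- dim(windows[[1]])
  if (is.null(encoder)) {
    encoder <- deep4_encoder(n_channels = d[2], input_samples = d[3],
                             widths = widths, embedding_dim = embedding_dim)
  }
  head <- nn_linear(encoder$config$embedding_dim, 1, name = "cls")
  params <- if (freeze_encoder) head$params else c(encoder$params, head$params)
  opt <- nn_adam(list(list(params = params, lr = lr,
                           weight_decay = weight_decay)))
  nw <- vapply(windows, function(a) dim(a)[1], 0L)
  all_rec <- rep(seq_along(ids), nw)
  all_win <- unlist(lapply(nw, seq_len), use.names = FALSE)
  losses <- numeric(epochs)
  for (ep in seq_len(epochs)) {
    ord <- sample(length(all_rec))
    bl <- numeric(0)
    for (s in seq.int(1L, length(ord), by = batch_size)) {
      take <- ord[s:min(s + batch_size - 1L, length(ord))]
      if (length(take) < 2L) next
      bx <- array(0, dim = c(length(take), d[2], d[3]))
      for (j in seq_along(take)) {
        bx[j, , ] <- windows[[all_rec[take[j]]]][all_win[take[j]], , ]
      }
      by <- as.numeric(y_rec[all_rec[take]])
      opt$zero()
      emb <- encoder$forward(bx, training = !freeze_encoder)
      z <- head$forward(emb, training = TRUE)
      # stable BCE-with-logits
      loss <- mean(pmax(z, 0) - z * by + log1p(exp(-abs(z))))
      p <- 1 / (1 + exp(-z))
      dz <- (p - by) / length(by)
      demb <- head$backward(dz)
      if (!freeze_encoder) encoder$backward(demb)
      opt$step()
      bl <- c(bl, loss)
    }
    losses[ep] <- mean(bl)
  }
  predict_fn <- function(wlist) {
    vapply(wlist, function(w) {
      emb <- eeg_encode(encoder, w)
      mean(1 / (1 + exp(-head$forward(emb, training = FALSE))))
    }, 0)
  }
  structure(list(encoder = encoder, head = head, predict = predict_fn,
                 loss_history = losses),
            class = "supervised_fit")
}

#' Task-specific and alternative-task baselines
#'
#' `task_specific`: the encoder is trained end-to-end on the target task.
#' `alternative_task`: an encoder pretrained (supervised) on a *different*
#' task is frozen, and only a logistic-regression head is fit on its
#' embeddings for the target task. When the alternative task equals the
#' target task this degenerates to a frozen variant of the task-specific
#' model.
#'
#' @param train_windows,train_labels training recordings and target labels.
#' @param eval_windows,eval_labels evaluation recordings/labels.
#' @param pretrained_encoder encoder from the alternative-task pretraining
#'   (required for `method = "alternative_task"`).
#' @param method baseline flavor.
#' @param epochs,widths,seed budget and architecture for the from-scratch
#'   model.
#' @return `eval_result` with balanced accuracy on the evaluation split.
#' @export
baseline_evaluate <- function(train_windows, train_labels,
                              eval_windows, eval_labels,
                              method = c("task_specific", "alternative_task"),
                              pretrained_encoder = NULL,
                              epochs = 10, widths = c(25, 50, 100, 200),
                              seed = 1L) {
  method <- match.arg(method)
  if (method == "task_specific") {
    fit <- train_supervised(train_windows, train_labels, epochs = epochs,
                            widths = widths, seed = seed)
    prob <- fit$predict(eval_windows)
  } else {
    if (is.null(pretrained_encoder)) {
      stop("alternative_task needs a pretrained encoder")
    }
    emb_tr <- lapply(train_windows, function(w) eeg_encode(pretrained_encoder, w))
    emb_ev <- lapply(eval_windows, function(w) eeg_encode(pretrained_encoder, w))
    ids <- names(emb_tr)
    fitp <- probe_fit(do.call(rbind, emb_tr),
                      rep(as.logical(train_labels[ids]),
                          vapply(emb_tr, nrow, 0L)),
                      head = "logreg", seed = seed)
    prob <- predict_recordings(fitp, emb_ev)
  }
  preds <- prob > 0.5
  structure(list(
    balanced_accuracy = balanced_accuracy(preds,
                                          as.logical(eval_labels[names(eval_windows)])),
    method = method, preds = preds, prob = prob
  ), class = "eval_result")
}

#' Recording-level split plan for the evaluation protocols
#'
#' Partitions recordings (stratified by label when given) into 60%
#' contrastive-pretraining, 20% few-shot pool and 20% evaluation, with the
#' few-shot fractions 1/2, 1/5, 1/10, 1/20, 1/50 applied to the pool only.
#' The three splits are disjoint at the recording level by construction and
#' re-asserted here.
#'
#' @param ids recording identifiers.
#' @param labels optional named vector for stratification.
#' @param seed split seed.
#' @param props numeric length-3 proportions summing to 1.
#' @param fractions few-shot fractions of the pool.
#' @return list of class `split_plan` with `contrastive_train`,
#'   `fewshot_pool`, `eval`, `fractions`, `seed`.
#' @export
split_plan <- function(ids, labels = NULL, seed = 1L,
                       props = c(0.6, 0.2, 0.2),
                       fractions = c(1/2, 1/5, 1/10, 1/20, 1/50)) {
  stopifnot(abs(sum(props) - 1) < 1e-9, length(props) == 3)
  set.seed(seed)
  ids <- as.character(ids)
  groups <- if (is.null(labels)) list(ids) else split(ids, labels[ids])
  parts <- list(character(0), character(0), character(0))
  for (g in groups) {
    g <- sample(g)
    n <- length(g)
    n1 <- round(props[1] * n)
    n2 <- round(props[2] * n)
    parts[[1]] <- c(parts[[1]], g[seq_len(n1)])
    parts[[2]] <- c(parts[[2]], g[n1 + seq_len(n2)])
    parts[[3]] <- c(parts[[3]], g[(n1 + n2 + 1):n])
  }
  plan <- structure(list(contrastive_train = parts[[1]],
                         fewshot_pool = parts[[2]], eval = parts[[3]],
                         fractions = fractions, seed = seed),
                    class = "split_plan")
  assert_disjoint(plan)
  plan
}

#' Assert recording-level disjointness of a split plan
#' @param plan a `split_plan`.
#' @return `TRUE` invisibly; errors on overlap.
#' @export
assert_disjoint <- function(plan) {
  all_ids <- c(plan$contrastive_train, plan$fewshot_pool, plan$eval)
  if (anyDuplicated(all_ids)) {
    stop("split plan is not disjoint at the recording level")
  }
  invisible(TRUE)
}

#' Stratified fractional subset of a pool
#'
#' Samples `ceiling(fraction * n_class)` recordings per class (at least one
#' each), deterministically for a given `(fraction, seed)` so that all
#' compared methods receive identical subsets.
#'
#' @param pool_ids candidate recording ids.
#' @param labels named vector of class labels.
#' @param fraction fraction of the pool, in (0, 1].
#' @param seed sampling seed.
#' @return character vector of sampled ids, with attribute `"hash"`.
#' @export
sample_fraction <- function(pool_ids, labels, fraction, seed) {
  stopifnot(fraction > 0, fraction <= 1)
  set.seed(seed + round(1e6 * fraction))
  out <- character(0)
  for (g in split(as.character(pool_ids), labels[pool_ids])) {
    k <- max(1L, ceiling(fraction * length(g)))
    out <- c(out, sample(g, k))
  }
  out <- sort(out)
  attr(out, "hash") <- subset_hash(out)
  out
}

#' Deterministic hash of an id set
#' @param ids character vector.
#' @return integer-valued hash (order-insensitive).
#' @export
subset_hash <- function(ids) fnv1a(paste(sort(as.character(ids)), collapse = "|"))

#' Few-shot fractional evaluation protocol
#'
#' For every (method, fraction, seed): draw the stratified subset of the
#' few-shot pool (identical across methods -- asserted by subset hash),
#' train the method on it, and report balanced accuracy on the evaluation
#' split. Contrastive-model probes use frozen embeddings from the supplied model,
#' which must have been pretrained only on the plan's contrastive split.
#'
#' @param plan a [split_plan()].
#' @param windows named list of all per-recording window arrays.
#' @param labels named logical vector for the target task.
#' @param model trained `clip_model` (for the probe methods).
#' @param methods subset of `c("clip_logreg", "clip_mlp",
#'   "task_specific", "alternative_task")`.
#' @param seeds seeds per cell (default `1:5`).
#' @param alt_encoder pretrained encoder for `alternative_task`.
#' @param sup_epochs,sup_widths budget of the from-scratch baseline.
#' @return data.frame (method, fraction, seed, balanced_accuracy,
#'   subset_hash).
#' @export
few_shot_protocol <- function(plan, windows, labels, model = NULL,
                              methods = c("clip_logreg", "task_specific"),
                              seeds = 1:5, alt_encoder = NULL,
                              sup_epochs = 10,
                              sup_widths = c(25, 50, 100, 200)) {
  assert_disjoint(plan)
  eval_ids <- plan$eval
  pool_ids <- plan$fewshot_pool
  emb_cache <- NULL
  if (any(startsWith(methods, "clip"))) {
    stopifnot(!is.null(model))
    emb_cache <- embed_by_recording(model, windows[c(pool_ids, eval_ids)],
                                    space = "embedding")
  }
  rows <- list()
  for (fraction in plan$fractions) {
    for (seed in seeds) {
      subset <- sample_fraction(pool_ids, labels, fraction, seed)
      h <- attr(subset, "hash")
      for (method in methods) {
        res <- switch(method,
          clip_logreg = probe_evaluate(
            emb_cache[subset], labels, emb_cache[eval_ids], labels,
            head = "logreg", seed = seed),
          clip_mlp = probe_evaluate(
            emb_cache[subset], labels, emb_cache[eval_ids], labels,
            head = "mlp", seed = seed),
          task_specific = baseline_evaluate(
            windows[subset], labels, windows[eval_ids], labels,
            method = "task_specific", epochs = sup_epochs,
            widths = sup_widths, seed = seed),
          alternative_task = baseline_evaluate(
            windows[subset], labels, windows[eval_ids], labels,
            method = "alternative_task", pretrained_encoder = alt_encoder,
            seed = seed),
          stop("unknown method ", method)
        )
        rows[[length(rows) + 1L]] <- data.frame(
          method = method, fraction = fraction, seed = seed,
          balanced_accuracy = res$balanced_accuracy, subset_hash = h,
          stringsAsFactors = FALSE)
      }
    }
  }
  do.call(rbind, rows)
}

#' Percentile confidence bands over few-shot seeds
#'
#' @param results data.frame from [few_shot_protocol()].
#' @param level band coverage (default 0.8, i.e. the 10th--90th
#'   percentiles over seeds).
#' @return data.frame (method, fraction, mean, lower, upper, n_seeds).
#' @export
summarize_fewshot <- function(results, level = 0.8) {
  a <- (1 - level) / 2
  agg <- split(results, list(results$method, results$fraction), drop = TRUE)
  out <- lapply(agg, function(d) {
    data.frame(method = d$method[1], fraction = d$fraction[1],
               mean = mean(d$balanced_accuracy),
               lower = as.numeric(stats::quantile(d$balanced_accuracy, a)),
               upper = as.numeric(stats::quantile(d$balanced_accuracy, 1 - a)),
               n_seeds = nrow(d))
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out[order(out$method, -out$fraction), ]
}
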