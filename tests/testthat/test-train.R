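test_that("make_pairs pairs every window with its recording's text", {
  rec <- make_test_recording(rate = 100, duration = 180, seed = 31)
  rec$id <- "r1"
  ws <- preprocess(rec)
  reports <- list(r1 = "IMPRESSION: Normal.\nMEDICATIONS: None.")
  pairs <- make_pairs(ws, reports)
  expect_equal(n_pairs(pairs), 21)            # all windows share one text
  expect_equal(length(pairs$texts), 1)
  expect_match(pairs$texts[["r1"]], "Normal")

  # additivity over recordings
  rec2 <- make_test_recording(rate = 100, duration = 180, seed = 32)
  rec2$id <- "r2"
  ws2 <- preprocess(rec2)
  pairs2 <- make_pairs(list(ws, ws2), list(r1 = reports$r1, r2 = reports$r1))
  expect_equal(n_pairs(pairs2), n_pairs(pairs) + 21)

  # empty selected section drops the recording's pairs, with a message
  expect_message(
    pairs3 <- make_pairs(list(ws, ws2),
                         list(r1 = "IMPRESSION: Abnormal.",
                              r2 = "MEDICATIONS: Keppra."),
                         selection = "impression"),
    "dropping 21")
  expect_equal(pairs3$recording_ids, "r1")
  expect_error(make_pairs(ws, list(other = "x")), "no report")
})

test_that("training reduces the contrastive loss on a separable corpus", {
  prep <- tiny_corpus_prep()
  fit <- train_clip(prep$pairs, tiny_train_cfg(epochs = 6, seed = 3))
  expect_length(fit$loss_history, 6)
  expect_lt(utils::tail(fit$loss_history, 1), fit$loss_history[1])
})

test_that("text_lr_ratio = 0 leaves the text encoder bit-unchanged", {
  prep <- tiny_corpus_prep()
  set.seed(1)
  txt <- avg_embedding_text_encoder(prep$pairs$texts, dim = 8)
  before <- lapply(txt$params, function(p) p$val)
  fit <- train_clip(prep$pairs,
                       tiny_train_cfg(epochs = 2, text_lr_ratio = 0),
                       text_encoder = txt)
  after <- lapply(fit$model$text_params, function(p) p$val)
  expect_identical(before, after)
  # with a positive ratio the same parameters move
  set.seed(1)
  txt2 <- avg_embedding_text_encoder(prep$pairs$texts, dim = 8)
  fit2 <- train_clip(prep$pairs,
                        tiny_train_cfg(epochs = 2, text_lr_ratio = 0.5),
                        text_encoder = txt2)
  expect_false(identical(before, lapply(fit2$model$text_params,
                                        function(p) p$val)))
})

test_that("optimizer groups partition the trainable parameters", {
  prep <- tiny_corpus_prep()
  set.seed(2)
  d <- dim(prep$pairs$windows[[1]])
  enc <- deep4_encoder(n_channels = d[2], input_samples = d[3],
                       widths = c(4, 8, 8, 8))
  txt <- avg_embedding_text_encoder(prep$pairs$texts, dim = 8)
  m <- clip_model(enc, txt, projection_dim = 16, proj_hidden = 32)
  main_ids <- vapply(m$main_params, function(p) p$name, "")
  text_ids <- vapply(m$text_params, function(p) p$name, "")
  expect_length(intersect(main_ids, text_ids), 0)
  all_known <- c(enc$params, m$head_x$params, m$head_y$params,
                 list(m$log_scale), txt$params)
  expect_setequal(vapply(all_known, function(p) p$name, ""),
                  c(main_ids, text_ids))
})

test_that("batch size larger than the corpus gives one full batch", {
  prep <- tiny_corpus_prep()
  fit <- train_clip(prep$pairs, tiny_train_cfg(epochs = 1,
                                                  batch_size = 500))
  expect_length(fit$loss_history, 1)
  expect_true(is.finite(fit$loss_history))
})

test_that("single-recording corpora are rejected", {
  prep <- tiny_corpus_prep()
  solo <- prep$pairs
  solo$recording_ids <- solo$recording_ids[1]
  solo$windows <- solo$windows[1]
  solo$texts <- solo$texts[1]
  expect_error(train_clip(solo, tiny_train_cfg()), "at least 2")
})

test_that("same seed and data reproduce the loss trajectory", {
  prep <- tiny_corpus_prep()
  f1 <- train_clip(prep$pairs, tiny_train_cfg(epochs = 2, seed = 7))
  f2 <- train_clip(prep$pairs, tiny_train_cfg(epochs = 2, seed = 7))
  expect_identical(f1$loss_history, f2$loss_history)
})

test_that("alignment margin: within-pair beats between-class cosine after convergence", {
  prep <- easy_corpus_prep(n = 16, seed = 8)
  for (seed in 1:3) {
    fit <- train_clip(prep$pairs, tiny_train_cfg(epochs = 60, seed = seed,
                                                    temperature_init = 5))
    m <- fit$model
    ids <- prep$pairs$recording_ids
    px <- t(vapply(ids, function(id)
      recording_embedding(m, prep$pairs$windows[[id]]), numeric(16)))
    py <- model_embed_text(m, unname(prep$pairs$texts[ids]))
    sim <- tcrossprod(px, py)
    within <- mean(diag(sim))
    classes <- prep$manifest$class[match(ids, prep$manifest$id)]
    between <- mean(sim[outer(classes, classes, "!=")])
    expect_gt(within - between, 0.2)
  }
})
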