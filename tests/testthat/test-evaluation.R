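test_that("balanced accuracy is the mean of per-class recalls", {
  y <- rep(c(TRUE, FALSE), c(6, 4))
  expect_equal(balanced_accuracy(y, y), 1)
  # constant predictor on 60/40 labels
  expect_equal(balanced_accuracy(rep(TRUE, 10), y), 0.5)
  # hand-computed confusion: TP=8 FN=2 TN=5 FP=5 -> (0.8 + 0.5)/2
  labels <- rep(c(TRUE, FALSE), c(10, 10))
  preds <- c(rep(TRUE, 8), rep(FALSE, 2), rep(TRUE, 5), rep(FALSE, 5))
  expect_equal(balanced_accuracy(preds, labels), 0.65)
  expect_error(balanced_accuracy(y, rep(TRUE, 10)), "two classes")
})

test_that("recording_embedding averages windows (renormalized in cosine space)", {
  prep <- tiny_corpus_prep()
  set.seed(4)
  d <- dim(prep$pairs$windows[[1]])
  enc <- deep4_encoder(n_channels = d[2], input_samples = d[3],
                       widths = c(4, 8, 8, 8))
  m <- clip_model(enc, hash_text_encoder(dim = 32),
                     projection_dim = 16, proj_hidden = 32)
  w <- prep$pairs$windows[[1]]
  # identical windows: aggregation equals the single-window direction
  wrep <- w[c(1, 1, 1), , , drop = FALSE]
  v1 <- recording_embedding(m, w[1, , , drop = FALSE])
  expect_equal(recording_embedding(m, wrep), v1, tolerance = 1e-12)
  # embedding space: plain mean (mean oracle)
  E <- model_embed_eeg(m, w, space = "embedding")
  expect_equal(recording_embedding(m, w, space = "embedding"), colMeans(E))
  # projection space: unit norm
  expect_equal(sum(recording_embedding(m, w)^2), 1, tolerance = 1e-9)
  expect_error(recording_embedding(m, w[0, , , drop = FALSE]), "no windows")
})

test_that("probes separate separable embeddings and sit at chance under permutation", {
  set.seed(10)
  n <- 80
  y <- rep(c(TRUE, FALSE), each = n / 2)
  emb <- matrix(stats::rnorm(n * 8), n) + outer(as.numeric(y) * 3, rep(1, 8))
  fit <- probe_fit(emb, y, head = "logreg")
  expect_equal(balanced_accuracy(fit$predict(emb) > 0.5, y), 1)

  nulls <- vapply(1:5, function(sd) {
    set.seed(sd)
    yp <- sample(y)
    f <- probe_fit(emb[1:60, ], yp[1:60], head = "logreg")
    balanced_accuracy(f$predict(emb[61:80, ]) > 0.5, yp[61:80])
  }, 0)
  expect_lt(abs(mean(nulls) - 0.5), 0.15)

  # XOR-structured embeddings: the MLP head must beat logistic regression
  set.seed(11)
  xy <- matrix(stats::runif(400 * 2, -1, 1), 400)
  yx <- xy[, 1] * xy[, 2] > 0
  emb_xor <- cbind(xy, matrix(stats::rnorm(400 * 2, sd = 0.05), 400))
  tr <- 1:300; ev <- 301:400
  f_lin <- probe_fit(emb_xor[tr, ], yx[tr], head = "logreg")
  f_mlp <- probe_fit(emb_xor[tr, ], yx[tr], head = "mlp", seed = 2,
                     mlp_iters = 500)
  acc_lin <- balanced_accuracy(f_lin$predict(emb_xor[ev, ]) > 0.5, yx[ev])
  acc_mlp <- balanced_accuracy(f_mlp$predict(emb_xor[ev, ]) > 0.5, yx[ev])
  expect_gte(acc_mlp, acc_lin)
  expect_gt(acc_mlp, 0.8)
})

test_that("split plan is disjoint, stratified and fraction sampling is deterministic", {
  ids <- sprintf("r%03d", 1:100)
  labels <- stats::setNames(rep(c(TRUE, FALSE), 50), ids)
  plan <- split_plan(ids, labels, seed = 3)
  expect_length(plan$contrastive_train, 60)
  expect_length(plan$fewshot_pool, 20)
  expect_length(plan$eval, 20)
  expect_true(assert_disjoint(plan))
  # stratification carries both classes into every split
  for (part in list(plan$contrastive_train, plan$fewshot_pool, plan$eval)) {
    expect_setequal(unique(labels[part]), c(TRUE, FALSE))
  }
  # fraction 1/2 of a 20-recording pool: 10 recordings, class-stratified
  sub <- sample_fraction(plan$fewshot_pool, labels, 1 / 2, seed = 1)
  expect_length(sub, 10)
  expect_equal(sum(labels[sub]), 5)
  # identical subsets across calls (hash equality)
  sub2 <- sample_fraction(plan$fewshot_pool, labels, 1 / 2, seed = 1)
  expect_identical(as.character(sub), as.character(sub2))
  expect_equal(attr(sub, "hash"), attr(sub2, "hash"))
  # degenerate fraction keeps one recording per class
  tiny <- sample_fraction(plan$fewshot_pool, labels, 1 / 50, seed = 2)
  expect_length(tiny, 2)
  expect_setequal(unique(labels[tiny]), c(TRUE, FALSE))
})

test_that("confidence bands tighten with more seeds", {
  set.seed(12)
  fake <- do.call(rbind, lapply(1:20, function(sd) {
    data.frame(method = "m", fraction = 0.5, seed = sd,
               balanced_accuracy = stats::rnorm(1, 0.8, 0.05),
               subset_hash = 1)
  }))
  s5 <- summarize_fewshot(fake[fake$seed <= 5, ])
  s20 <- summarize_fewshot(fake)
  expect_true(s20$upper - s20$lower <= s5$upper - s5$lower + 0.05)
  expect_equal(s20$n_seeds, 20)
})

test_that("zero-shot classification picks the nearest prompt prototype", {
  prep <- tiny_corpus_prep()
  set.seed(5)
  d <- dim(prep$pairs$windows[[1]])
  enc <- deep4_encoder(n_channels = d[2], input_samples = d[3],
                       widths = c(4, 8, 8, 8))
  m <- clip_model(enc, hash_text_encoder(dim = 32),
                     projection_dim = 16, proj_hidden = 32)
  preds <- zero_shot_classify(m, prep$pairs$windows[1:4],
                              task = "pathological")
  expect_type(preds, "logical")
  expect_length(preds, 4)
  expect_error(zero_shot_classify(m, prep$pairs$windows[1:2],
                                  prompts = c(A = "", B = "x")), "empty")
})

test_that("supervised baselines behave on separable data", {
  prep <- easy_corpus_prep(n = 16, seed = 8)
  wins <- prep$pairs$windows
  patho <- stats::setNames(prep$manifest$pathological, prep$manifest$id)
  ids <- names(wins)
  tr <- ids[1:10]
  ev <- ids[11:16]
  accs <- sapply(1:2, function(sd) {
    ts <- baseline_evaluate(wins[tr], patho, wins[ev], patho,
                            method = "task_specific", epochs = 8,
                            widths = c(4, 8, 8, 8), seed = sd)
    # pretext encoder trained on labels unrelated to pathology
    set.seed(sd + 100)
    pretext <- stats::setNames(sample(c(TRUE, FALSE), length(tr), TRUE), tr)
    pre <- train_supervised(wins[tr], pretext, epochs = 8,
                            widths = c(4, 8, 8, 8), seed = sd)
    alt <- baseline_evaluate(wins[tr], patho, wins[ev], patho,
                             method = "alternative_task",
                             pretrained_encoder = pre$encoder, seed = sd)
    c(ts = ts$balanced_accuracy, alt = alt$balanced_accuracy)
  })
  # end-to-end supervised training solves the separable world...
  expect_gt(mean(accs["ts", ]), 0.9)
  # ...and transfer from an unrelated pretext task never beats it here
  # (at this scale the two can tie: random-encoder features + a linear head
  # are already sufficient for this strongly separable world)
  expect_gte(mean(accs["ts", ]), mean(accs["alt", ]))
  # degenerate configuration: alternative task == target task still valid
  pre2 <- train_supervised(wins[tr], patho, epochs = 3,
                           widths = c(4, 8, 8, 8), seed = 1)
  same <- baseline_evaluate(wins[tr], patho, wins[ev], patho,
                            method = "alternative_task",
                            pretrained_encoder = pre2$encoder, seed = 1)
  expect_true(same$balanced_accuracy >= 0 && same$balanced_accuracy <= 1)
  expect_error(baseline_evaluate(wins[tr], patho, wins[ev], patho,
                                 method = "alternative_task"),
               "pretrained")
})
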