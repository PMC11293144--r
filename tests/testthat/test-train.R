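test_that("evaluation matches hand-computed contingencies", {
  gold <- list(span_tbl(c(1L, 4L, 7L), c(1L, 5L, 7L),
                        c("Growth", "Binding", "Growth")))
  pred <- list(span_tbl(c(1L, 4L, 9L), c(1L, 5L, 9L),
                        c("Growth", "Binding", "Growth")))
  rep <- evaluate_triggers(gold, pred, "micro")
  expect_equal(rep$tp, 2L); expect_equal(rep$fp, 1L); expect_equal(rep$fn, 1L)
  expect_equal(rep$precision, 100 * 2 / 3, tolerance = 1e-10)
  expect_equal(rep$recall, 100 * 2 / 3, tolerance = 1e-10)
  expect_equal(rep$f1, 100 * 2 / 3, tolerance = 1e-10)
  # perfect agreement
  rep2 <- evaluate_triggers(gold, gold, "micro")
  expect_equal(c(rep2$precision, rep2$recall, rep2$f1), c(100, 100, 100))
  # type mismatch on the same extent is both a FP and a FN
  pred3 <- list(span_tbl(1L, 1L, "Binding"))
  rep3 <- evaluate_triggers(list(span_tbl(1L, 1L, "Growth")), pred3, "micro")
  expect_equal(c(rep3$tp, rep3$fp, rep3$fn), c(0L, 1L, 1L))
  expect_error(evaluate_triggers(gold, list()), "aligned")
})

test_that("micro scores match a set-intersection oracle on random cases", {
  withr::local_seed(51)
  for (rep in 1:200) {
    n_sent <- sample(1:4, 1L)
    gold <- lapply(seq_len(n_sent), function(i) random_spans(8L, schema2$types))
    pred <- lapply(seq_len(n_sent), function(i) random_spans(8L, schema2$types))
    r <- evaluate_triggers(gold, pred, "micro")
    gk <- unlist(lapply(seq_len(n_sent), function(i) {
      g <- gold[[i]]
      if (nrow(g)) paste(i, g$start, g$end, g$type) else character(0)
    }))
    pk <- unlist(lapply(seq_len(n_sent), function(i) {
      p <- pred[[i]]
      if (nrow(p)) paste(i, p$start, p$end, p$type) else character(0)
    }))
    tp <- length(intersect(gk, pk))
    expect_equal(r$tp, tp)
    expect_equal(r$fp, length(pk) - tp)
    expect_equal(r$fn, length(gk) - tp)
  }
})

test_that("macro averages per-type F1 over types present in gold", {
  gold <- list(span_tbl(c(1L, 3L), c(1L, 3L), c("Growth", "Binding")))
  pred <- list(span_tbl(1L, 1L, "Growth"))
  r <- evaluate_triggers(gold, pred, "macro")
  # Growth: P=R=F1=100; Binding: 0; macro F1 = 50
  expect_equal(r$f1, 50)
  # a type absent from gold does not enter the macro mean
  r2 <- evaluate_triggers(gold, pred, "macro",
                          schema = event_schema(c("Growth", "Binding", "Death")))
  expect_equal(r2$f1, 50)
})

test_that("configuration defaults and ablation switches are consistent", {
  cfg <- trigger_config()
  expect_equal(cfg$alpha, 0.5)
  expect_equal(cfg$lr, 5e-5)
  expect_equal(cfg$epochs, 100L)
  expect_equal(cfg$max_len, 256L)
  expect_true(cfg$use_lcar && cfg$use_ltar && cfg$use_joint_encoding)
  ab <- ablate(cfg, "lsrl")
  expect_false(ab$use_lcar || ab$use_ltar)
  ab2 <- ablate(cfg, "joint_encoding")
  expect_false(ab2$use_joint_encoding)
  expect_error(trigger_config(nonsense = 1), "unknown config")
  # YAML round trip
  f <- withr::local_tempfile(fileext = ".yaml")
  yaml::write_yaml(list(profile = "tiny", alpha = 0.3, epochs = 4L), f)
  cfg3 <- read_trigger_config(f)
  expect_equal(cfg3$alpha, 0.3)
  expect_equal(cfg3$epochs, 4L)
  expect_equal(cfg3$lr, 2e-3)
})

test_that("one epoch of training lowers the loss and logs it", {
  corp <- tiny_corpus(n = 30L, seed = 61L)
  cfg <- tiny_cfg(epochs = 3L)
  m <- train_trigger_model(corp$sentences, corp$spec$schema, cfg)
  expect_s3_class(m, "trigger_model")
  expect_equal(nrow(m$log), 3L)
  expect_true(all(is.finite(m$log$loss)))
  expect_lt(m$log$loss[3], m$log$loss[1])
  expect_error(train_trigger_model(corp$sentences[0, ], corp$spec$schema, cfg),
               "empty")
})

test_that("training is reproducible under a fixed seed", {
  corp <- tiny_corpus(n = 20L, seed = 62L)
  cfg <- tiny_cfg(epochs = 2L)
  m1 <- train_trigger_model(corp$sentences, corp$spec$schema, cfg)
  m2 <- train_trigger_model(corp$sentences, corp$spec$schema, cfg)
  expect_equal(m1$log$loss, m2$log$loss, tolerance = 1e-12)
  expect_equal(m1$crf$T, m2$crf$T, tolerance = 1e-12)
})

test_that("checkpoint save/load round-trips predictions exactly", {
  corp <- tiny_corpus(n = 25L, seed = 63L)
  cfg <- tiny_cfg(epochs = 2L)
  m <- train_trigger_model(corp$sentences, corp$spec$schema, cfg)
  f <- withr::local_tempfile(fileext = ".rds")
  save_trigger_model(m, f)
  m2 <- load_trigger_model(f)
  p1 <- predict(m, corp$sentences)
  p2 <- predict(m2, corp$sentences)
  expect_identical(p1$pred_tags, p2$pred_tags)
  # repeated prediction is idempotent
  p3 <- predict(m, corp$sentences)
  expect_identical(p1$pred_tags, p3$pred_tags)
})

test_that("predictions from a masked CRF are always valid BIO", {
  corp <- tiny_corpus(n = 25L, seed = 64L)
  cfg <- tiny_cfg(epochs = 1L, mask_transitions = TRUE)
  m <- train_trigger_model(corp$sentences, corp$spec$schema, cfg)
  pr <- predict(m, corp$sentences)
  for (tags in pr$pred_tags) {
    prev <- "START"
    for (t in tags) {
      expect_true(is_valid_transition(prev, t, m$tagset))
      prev <- t
    }
  }
})

test_that("disabling the label representations makes emissions ignore H_L", {
  corp <- tiny_corpus(n = 10L, seed = 65L)
  toks <- corp$sentences$tokens[[1]]
  # with joint encoding the labels still interact with the sentence inside
  # the encoder, so the independence check uses separate encoding: then the
  # label encodings reach the emissions only through the (disabled)
  # attention and affinity terms
  cfg3 <- tiny_cfg(disable_lsrl = TRUE, disable_joint_encoding = TRUE)
  m3 <- trigtag:::new_trigger_model(corp$sentences, corp$spec$schema, cfg3)
  lab_ids <- unname(m3$vocab$index[m3$prompt$tokens])
  fwd3 <- trigtag:::model_forward(m3, toks)
  m4 <- m3
  m4$encoder$params$embed[lab_ids, ] <-
    m4$encoder$params$embed[lab_ids, ] + 5
  fwd4 <- trigtag:::model_forward(m4, toks)
  expect_equal(fwd4$x, fwd3$x, tolerance = 1e-12)
  # whereas the full model's emissions do depend on the label encodings
  cfg5 <- tiny_cfg(disable_joint_encoding = TRUE)
  m5 <- trigtag:::new_trigger_model(corp$sentences, corp$spec$schema, cfg5)
  fwd5 <- trigtag:::model_forward(m5, toks)
  m6 <- m5
  m6$encoder$params$embed[lab_ids, ] <-
    m6$encoder$params$embed[lab_ids, ] + 5
  fwd6 <- trigtag:::model_forward(m6, toks)
  expect_gt(max(abs(fwd6$x - fwd5$x)), 1e-6)
})

test_that("every ablation-flag combination trains without error", {
  corp <- tiny_corpus(n = 12L, seed = 66L)
  flags <- expand.grid(lsrl = c(FALSE, TRUE), lcar = c(FALSE, TRUE),
                       ltar = c(FALSE, TRUE), joint = c(FALSE, TRUE))
  for (r in seq_len(nrow(flags))) {
    cfg <- tiny_cfg(epochs = 1L,
                    disable_lsrl = flags$lsrl[r],
                    disable_lcar = flags$lcar[r],
                    disable_ltar = flags$ltar[r],
                    disable_joint_encoding = flags$joint[r])
    m <- train_trigger_model(corp$sentences, corp$spec$schema, cfg)
    expect_true(is.finite(m$log$loss[1]))
  }
})

test_that("an alpha grid of one value reduces to a single tagged run", {
  corp <- tiny_corpus(n = 20L, seed = 67L)
  te <- tiny_corpus(n = 10L, seed = 68L)
  cfg <- tiny_cfg(epochs = 1L)
  sw <- alpha_sweep(corp$sentences, corp$spec$schema, cfg, alphas = 0.5,
                    test = te$sentences)
  expect_equal(nrow(sw), 1L)
  expect_equal(sw$alpha, 0.5)
  expect_true(is.finite(sw$f1))
  # sweep is deterministic under the shared seed
  sw2 <- alpha_sweep(corp$sentences, corp$spec$schema, cfg, alphas = 0.5,
                     test = te$sentences)
  expect_equal(sw$f1, sw2$f1, tolerance = 1e-12)
  expect_error(alpha_sweep(corp$sentences, corp$spec$schema, cfg,
                           alphas = c(0.5, 1), test = te$sentences), "")
})

test_that("tidiers and autoplot produce well-formed output", {
  corp <- tiny_corpus(n = 15L, seed = 69L)
  cfg <- tiny_cfg(epochs = 2L)
  m <- train_trigger_model(corp$sentences, corp$spec$schema, cfg)
  td <- tidy(m)
  expect_named(td, c("epoch", "loss", "dev_f1"))
  gl <- glance(m)
  expect_equal(gl$epochs, 2L)
  expect_s3_class(autoplot(m), "ggplot")
  pr <- predict(m, corp$sentences)
  rep <- evaluate_triggers(corp$sentences$gold_spans, pr$pred_spans)
  expect_named(glance(rep),
               c("averaging", "precision", "recall", "f1", "tp", "fp", "fn"))
  expect_s3_class(tidy(rep), "tbl_df")
})

test_that("prediction writes standoff and CoNLL exports", {
  corp <- tiny_corpus(n = 10L, seed = 70L)
  cfg <- tiny_cfg(epochs = 1L)
  m <- train_trigger_model(corp$sentences, corp$spec$schema, cfg)
  pr <- predict(m, corp$sentences)
  d <- withr::local_tempdir()
  write_predictions(pr, pr$pred_spans, corp$spec$schema, d)
  expect_true(file.exists(file.path(d, "predictions.conll")))
  expect_true(any(grepl("\\.a2$", list.files(d))))
  cl <- readLines(file.path(d, "predictions.conll"))
  n_tok <- sum(vapply(corp$sentences$tokens, nrow, integer(1)))
  expect_equal(sum(nzchar(cl)), n_tok)
})
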