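#' Experiment configuration
#'
#' Defaults follow the full-scale recipe: mixing weight `alpha = 0.5`,
#' learning rate `5e-5`, at most 100 epochs, maximum joint-input length 256,
#' dropout probability 0.1 (drop, not keep), Adam optimisation. The `tiny`
#' profile, used throughout the test suite and for CPU desk runs, swaps in
#' the small trainable encoder with a larger learning rate and fewer epochs;
#' its values are part of the shipped test configuration.
#'
#' Ablation switches mirror the model's additive structure: `disable_lcar`
#' drops the label-context attention term (`x = X' + Xtilde`), `disable_ltar`
#' drops the affinity term (`x = X' + alpha * Xhat`), `disable_lsrl` drops
#' both (`x = X'`), and `disable_joint_encoding` encodes the sentence without
#' the label prompt (labels encoded separately).
#'
#' @param profile `"paper"` (full-scale defaults) or `"tiny"` (desk-scale).
#' @param ... Named overrides of any configuration field.
#' @return A list of class `trigger_config`.
#' @export
trigger_config <- function(profile = c("paper", "tiny"), ...) {
  profile <- match.arg(profile)
  cfg <- list(
    encoder = "tiny", d_model = 64L, n_layers = 2L, n_heads = 4L,
    d_ff = 128L, max_len = 256L,
    alpha = 0.5, lr = 5e-5, epochs = 100L, batch_size = 16L,
    dropout = 0.1, clip = 5, seed = 1L, patience = 3L,
    disable_lsrl = FALSE, disable_lcar = FALSE, disable_ltar = FALSE,
    disable_joint_encoding = FALSE,
    include_scale = TRUE, mask_transitions = FALSE,
    averaging = "micro", profile = profile)
  if (profile == "tiny") {
    cfg$lr <- 2e-3; cfg$epochs <- 20L; cfg$dropout <- 0; cfg$patience <- 2L
  }
  over <- list(...)
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown)) stop("unknown config field(s): ",
                            paste(unknown, collapse = ", "))
  cfg[names(over)] <- over
  cfg$use_lcar <- !cfg$disable_lsrl && !cfg$disable_lcar
  cfg$use_ltar <- !cfg$disable_lsrl && !cfg$disable_ltar
  cfg$use_joint_encoding <- !cfg$disable_joint_encoding
  structure(cfg, class = "trigger_config")
}

#' Ablate a configuration
#'
#' @param config A `trigger_config`.
#' @param what One or more of `"lsrl"`, `"lcar"`, `"ltar"`,
#'   `"joint_encoding"`.
#' @return The modified configuration.
#' @export
ablate <- function(config, what) {
  what <- match.arg(what, c("lsrl", "lcar", "ltar", "joint_encoding"),
                    several.ok = TRUE)
  over <- stats::setNames(as.list(rep(TRUE, length(what))),
                          paste0("disable_", what))
  fields <- config[setdiff(names(config),
                           c("use_lcar", "use_ltar", "use_joint_encoding",
                             "profile"))]
  do.call(trigger_config,
          c(list(profile = config$profile), modifyList(fields, over)))
}

#' Read / write a configuration YAML file
#' @param path File path.
#' @return `read_trigger_config()` a `trigger_config`.
#' @export
read_trigger_config <- function(path) {
  y <- yaml::read_yaml(path)
  profile <- if (is.null(y$profile)) "paper" else y$profile
  y$profile <- NULL
  do.call(trigger_config, c(list(profile = profile), y))
}

new_trigger_model <- function(sentences, schema, config) {
  vocab <- build_vocab(sentences, schema)
  tagset <- bio_tags(schema)
  k_tags <- length(tagset$tags)
  d <- config$d_model
  prompt <- build_label_prompt(schema, seed = config$seed)
  enc <- tiny_encoder(length(vocab$tokens), d_model = d,
                      n_layers = config$n_layers, n_heads = config$n_heads,
                      d_ff = config$d_ff, max_len = config$max_len,
                      seed = config$seed)
  lsrl <- list(lcar = lcar_params(d, include_scale = config$include_scale,
                                  seed = config$seed + 1L),
               ltar = ltar_params(d, seed = config$seed + 2L),
               heads = projection_heads(d, prompt$m, k_tags,
                                        seed = config$seed + 3L))
  mask <- if (config$mask_transitions) crf_transition_mask(tagset) else NULL
  crf <- crf_params(k_tags, mask = mask)
  structure(list(encoder = enc, lsrl = lsrl, crf = crf, vocab = vocab,
                 schema = schema, tagset = tagset, prompt = prompt,
                 config = config, log = NULL),
            class = "trigger_model")
}

#' Train a trigger-detection model
#'
#' Minimises the CRF negative log-likelihood of the gold BIO sequences with
#' Adam over mini-batches, shuffling sentence order each epoch under the
#' configuration seed. When a development set is supplied, span-level F1 is
#' computed each epoch, the best-scoring parameters are kept, and training
#' stops early once the score fails to improve for `patience` consecutive
#' epochs (or is perfect).
#'
#' @param sentences Sentence tibble (from [corpus_sentences()] or a
#'   `synthetic_corpus`'s `$sentences`) with gold spans.
#' @param schema An `event_schema`.
#' @param config A [trigger_config()].
#' @param dev Optional sentence tibble for epoch selection.
#' @param quiet Suppress the per-epoch message.
#' @return A fitted `trigger_model` (checkpoint: all parameters, schema,
#'   vocabulary, prompt permutation and seeds, plus the training log).
#' @export
train_trigger_model <- function(sentences, schema, config = trigger_config(),
                                dev = NULL, quiet = TRUE) {
  if (nrow(sentences) == 0L) stop("cannot train on an empty corpus")
  bad <- vapply(sentences$gold_spans, function(sp)
    nrow(sp) > 0 && !all(sp$type %in% schema$types), logical(1))
  if (any(bad)) stop("gold spans name types outside the schema")
  model <- new_trigger_model(sentences, schema, config)
  n <- nrow(sentences)
  tags_idx <- lapply(seq_len(n), function(i) {
    tags <- spans_to_tags(sentences$gold_spans[[i]],
                          nrow(sentences$tokens[[i]]), model$tagset)
    unname(model$tagset$index[tags])
  })
  params <- model_param_tree(model)
  opt <- NULL
  log_rows <- list()
  best <- list(score = -Inf, params = params, epoch = 0L)
  stale <- 0L
  with_seed(config$seed + 1000L, {
    for (epoch in seq_len(config$epochs)) {
      ord <- sample.int(n)
      total_nll <- 0; n_seen <- 0L
      for (b0 in seq(1L, n, by = config$batch_size)) {
        idx <- ord[b0:min(b0 + config$batch_size - 1L, n)]
        gsum <- NULL; bs <- 0L
        for (i in idx) {
          fwd <- model_forward(model, sentences$tokens[[i]], train = TRUE)
          if (is.null(fwd)) next
          y <- tags_idx[[i]][seq_len(fwd$n_words)]
          cg <- crf_nll_grad(fwd$x, y, model$crf)
          g <- model_backward(model, fwd, cg$dF)
          g$crf <- list(T = cg$dT)
          gsum <- tree_add(gsum, g)
          total_nll <- total_nll + cg$nll
          bs <- bs + 1L; n_seen <- n_seen + 1L
        }
        if (bs == 0L) next
        gsum <- tree_scale(gsum, 1 / bs)
        if (is.finite(config$clip) && config$clip > 0) {
          gn <- sqrt(tree_sq_norm(gsum))
          if (gn > config$clip) gsum <- tree_scale(gsum, config$clip / gn)
        }
        if (is.null(opt)) opt <- adam_init(gsum)
        st <- adam_step(params, gsum, opt, lr = config$lr)
        params <- st$params; opt <- st$state
        model <- model_set_params(model, params)
      }
      loss <- total_nll / max(n_seen, 1L)
      dev_f1 <- NA_real_
      if (!is.null(dev)) {
        pr <- predict(model, dev)
        dev_f1 <- evaluate_triggers(dev$gold_spans, pr$pred_spans,
                                    averaging = config$averaging,
                                    schema = schema)$f1
        if (dev_f1 > best$score + 1e-9) {
          best <- list(score = dev_f1, params = params, epoch = epoch)
          stale <- 0L
        } else stale <- stale + 1L
      }
      log_rows[[epoch]] <- tibble::tibble(epoch = epoch, loss = loss,
                                          dev_f1 = dev_f1)
      if (!quiet) message(sprintf("epoch %d  loss %.4f  dev F1 %s", epoch,
                                  loss, ifelse(is.na(dev_f1), "-",
                                               sprintf("%.2f", dev_f1))))
      if (!is.null(dev) && (best$score >= 100 - 1e-9 ||
                            stale >= config$patience)) break
    }
  })
  if (!is.null(dev) && best$epoch > 0L) {
    model <- model_set_params(model, best$params)
  }
  model$log <- dplyr::bind_rows(log_rows)
  model$best_epoch <- if (!is.null(dev)) best$epoch else nrow(model$log)
  model
}

#' @export
print.trigger_model <- function(x, ...) {
  cat("<trigger_model> ", length(x$schema$types), " types, d_model ",
      x$config$d_model, ", alpha ", x$config$alpha, ", ",
      if (is.null(x$log)) "untrained" else paste0(nrow(x$log), " epochs"),
      "\n", sep = "")
  invisible(x)
}

#' Predict trigger spans
#'
#' Runs the encoder and label-representation layers, Viterbi-decodes the
#' emissions and converts the BIO tags back to typed spans.
#'
#' @param object A fitted `trigger_model`.
#' @param sentences Sentence tibble.
#' @param ... Unused.
#' @return `sentences` with added list columns `pred_spans` and `pred_tags`.
#' @export
predict.trigger_model <- function(object, sentences, ...) {
  n <- nrow(sentences)
  spans <- vector("list", n); tags <- vector("list", n)
  for (i in seq_len(n)) {
    toks <- sentences$tokens[[i]]
    fwd <- model_forward(object, toks, train = FALSE)
    if (is.null(fwd)) {
      spans[[i]] <- empty_span_tbl(); tags[[i]] <- character(0)
      next
    }
    y <- crf_viterbi(fwd$x, object$crf, schema = object$tagset)
    y <- c(as.character(y), rep("O", nrow(toks) - fwd$n_words))
    spans[[i]] <- tags_to_spans(y, object$tagset)
    tags[[i]] <- y
  }
  out <- sentences
  out$pred_spans <- spans
  out$pred_tags <- tags
  out
}

#' Save / load a model checkpoint
#'
#' The checkpoint holds every parameter plus the schema, vocabulary, prompt
#' permutation, configuration and seeds, so `predict()` after a round-trip
#' reproduces identical output.
#'
#' @param model A `trigger_model`.
#' @param path File path (`.rds`).
#' @export
save_trigger_model <- function(model, path) {
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_trigger_model
#' @export
load_trigger_model <- function(path) {
  m <- readRDS(path)
  stopifnot(inherits(m, "trigger_model"))
  m
}

#' Sweep the mixing weight alpha
#'
#' Trains one model per alpha value with an otherwise shared configuration
#' and seed, and evaluates each on the test set.
#'
#' @param sentences,schema,config,dev As in [train_trigger_model()].
#' @param alphas Numeric grid, each strictly in (0, 1).
#' @param test Sentence tibble to evaluate on.
#' @return A tibble of class `trigger_alpha_sweep`: `alpha`, `precision`,
#'   `recall`, `f1`, `best_epoch`.
#' @export
alpha_sweep <- function(sentences, schema, config, alphas, test, dev = NULL) {
  stopifnot(all(alphas > 0 & alphas < 1))
  rows <- lapply(alphas, function(a) {
    cfg <- config; cfg$alpha <- a
    m <- train_trigger_model(sentences, schema, cfg, dev = dev)
    pr <- predict(m, test)
    rep <- evaluate_triggers(test$gold_spans, pr$pred_spans,
                             averaging = config$averaging, schema = schema)
    tibble::tibble(alpha = a, precision = rep$precision, recall = rep$recall,
                   f1 = rep$f1, best_epoch = m$best_epoch)
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("trigger_alpha_sweep", class(out))
  out
}

#' @export
tidy.trigger_model <- function(x, ...) x$log

#' @export
glance.trigger_model <- function(x, ...) {
  tibble::tibble(
    epochs = if (is.null(x$log)) 0L else nrow(x$log),
    best_epoch = if (is.null(x$best_epoch)) NA_integer_ else x$best_epoch,
    final_loss = if (is.null(x$log) || !nrow(x$log)) NA_real_
                 else x$log$loss[nrow(x$log)],
    best_dev_f1 = if (is.null(x$log) || all(is.na(x$log$dev_f1))) NA_real_
                  else max(x$log$dev_f1, na.rm = TRUE),
    alpha = x$config$alpha,
    n_types = length(x$schema$types))
}

#' Plot the training trajectory
#'
#' @param object A fitted `trigger_model`.
#' @param ... Unused.
#' @return A ggplot of per-epoch loss (and dev F1 when available).
#' @export
autoplot.trigger_model <- function(object, ...) {
  stopifnot(!is.null(object$log))
  p <- ggplot2::ggplot(object$log, ggplot2::aes(x = .data$epoch, y = .data$loss)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::labs(x = "epoch", y = "mean NLL per sentence",
                  title = "Training loss") +
    ggplot2::theme_minimal()
  p
}

#' Plot an alpha sweep
#'
#' @param object A `trigger_alpha_sweep`.
#' @param ... Unused.
#' @return A ggplot of precision/recall/F1 against alpha.
#' @export
autoplot.trigger_alpha_sweep <- function(object, ...) {
  df <- tibble::tibble(
    alpha = rep(object$alpha, 3L),
    metric = rep(c("precision", "recall", "f1"), each = nrow(object)),
    value = c(object$precision, object$recall, object$f1))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$alpha, y = .data$value,
                                   colour = .data$metric)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::labs(x = expression(alpha), y = "score (%)",
                  title = "Mixing-weight sweep") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @importFrom rlang .data
NULL
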