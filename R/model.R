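# Full-model plumbing: parameter trees, forward/backward through
# encoder -> label representations -> CRF, and the Adam optimiser.
# Parameters live in a nested list ("tree") whose numeric leaves are
# updated; gradients mirror the tree's shape.

tree_map2 <- function(a, b, f) {
  out <- a
  for (nm in names(b)) {
    if (is.list(b[[nm]])) {
      out[[nm]] <- tree_map2(a[[nm]], b[[nm]], f)
    } else if (is.numeric(b[[nm]])) {
      out[[nm]] <- f(a[[nm]], b[[nm]])
    }
  }
  out
}

tree_zero_like <- function(g) {
  out <- g
  for (nm in names(g)) {
    out[[nm]] <- if (is.list(g[[nm]])) tree_zero_like(g[[nm]]) else g[[nm]] * 0
  }
  out
}

tree_add <- function(a, b) if (is.null(a)) b else tree_map2(a, b, `+`)
tree_scale <- function(a, s) {
  for (nm in names(a)) {
    a[[nm]] <- if (is.list(a[[nm]])) tree_scale(a[[nm]], s) else a[[nm]] * s
  }
  a
}

tree_sq_norm <- function(g) {
  tot <- 0
  for (nm in names(g)) {
    tot <- tot + if (is.list(g[[nm]])) tree_sq_norm(g[[nm]]) else sum(g[[nm]]^2)
  }
  tot
}

adam_init <- function(grads) list(m = tree_zero_like(grads),
                                  v = tree_zero_like(grads), t = 0L)

adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  state$m <- tree_map2(state$m, grads, function(m, g) beta1 * m + (1 - beta1) * g)
  state$v <- tree_map2(state$v, grads, function(v, g) beta2 * v + (1 - beta2) * g^2)
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  upd <- tree_map2(state$m, state$v, function(m, v) {
    lr * (m / bc1) / (sqrt(v / bc2) + eps)
  })
  params <- tree_map2(params, upd, `-`)
  list(params = params, state = state)
}

# sentence-only input for the separate-encoding ablation:
# <[CLS], S, [SEP]> with word-initial subtoken positions
build_sentence_input <- function(words, vocab, max_len = 256L) {
  if (is.data.frame(words)) words <- words$surface
  ids <- vocab$index[["[CLS]"]]
  budget <- max_len - 2L
  word_pos <- integer(0); used <- 0L; n_words <- 0L; truncated <- FALSE
  for (w in words) {
    sub <- encode_word(vocab, w)
    take <- min(length(sub), budget - used)
    if (take < 1L) { truncated <- TRUE; break }
    if (take < length(sub)) truncated <- TRUE
    word_pos <- c(word_pos, length(ids) + 1L)
    ids <- c(ids, sub[seq_len(take)])
    used <- used + take
    n_words <- n_words + 1L
  }
  ids <- c(ids, vocab$index[["[SEP]"]])
  list(ids = ids, word_pos = word_pos, n_words = n_words,
       truncated = truncated)
}

label_only_input <- function(prompt, vocab) {
  ids <- c(vocab$index[["[CLS]"]], vocab_id(vocab, prompt$tokens),
           vocab$index[["[SEP]"]])
  list(ids = ids, label_pos = 1L + seq_len(prompt$m))
}

# forward pass for one sentence: words -> combined emission matrix
model_forward <- function(model, words, train = FALSE) {
  cfg <- model$config
  enc <- model$encoder
  if (cfg$use_joint_encoding) {
    ji <- build_joint_input(model$prompt, words, model$vocab, cfg$max_len)
    es <- encode_and_split(enc, ji, train = train, dropout = cfg$dropout)
    H_L <- es$H_L; H_S <- es$H_S
    enc_ctx <- list(mode = "joint", ji = ji, cache = es$cache,
                    len = length(ji$ids))
    n_words <- ji$n_words
  } else {
    li <- label_only_input(model$prompt, model$vocab)
    fwL <- encoder_forward(enc, li$ids, train = train, dropout = cfg$dropout)
    si <- build_sentence_input(words, model$vocab, cfg$max_len)
    fwS <- encoder_forward(enc, si$ids, train = train, dropout = cfg$dropout)
    H_L <- fwL$H[li$label_pos, , drop = FALSE]
    H_S <- fwS$H[si$word_pos, , drop = FALSE]
    enc_ctx <- list(mode = "separate", li = li, si = si,
                    cacheL = fwL$cache, cacheS = fwS$cache)
    n_words <- si$n_words
  }
  if (n_words < 1L) return(NULL)
  lf <- lsrl_forward(H_S, H_L, model$lsrl, alpha = cfg$alpha,
                     use_lcar = cfg$use_lcar, use_ltar = cfg$use_ltar)
  list(x = lf$x, lf = lf, enc_ctx = enc_ctx, n_words = n_words)
}

# backward pass: gradient of loss w.r.t. emissions -> full parameter tree
model_backward <- function(model, fwd, dF) {
  lb <- lsrl_backward(dF, fwd$lf, model$lsrl)
  ec <- fwd$enc_ctx
  d <- encoder_dim(model$encoder)
  if (ec$mode == "joint") {
    dH <- matrix(0, ec$len, d)
    dH[ec$ji$label_pos, ] <- dH[ec$ji$label_pos, ] + lb$dH_L
    dH[ec$ji$word_pos, ] <- dH[ec$ji$word_pos, ] + lb$dH_S
    enc_g <- encoder_backward(model$encoder, ec$cache, dH)
  } else {
    dHL <- matrix(0, length(ec$li$ids), d)
    dHL[ec$li$label_pos, ] <- lb$dH_L
    dHS <- matrix(0, length(ec$si$ids), d)
    dHS[ec$si$word_pos, ] <- lb$dH_S
    enc_g <- tree_add(encoder_backward(model$encoder, ec$cacheL, dHL),
                      encoder_backward(model$encoder, ec$cacheS, dHS))
  }
  list(enc = enc_g, lsrl = nest_lsrl_grads(lb$grads))
}

nest_lsrl_grads <- function(g) {
  list(lcar = list(Pq = g[["lcar.Pq"]], Pk = g[["lcar.Pk"]], Pv = g[["lcar.Pv"]]),
       ltar = list(W = g[["ltar.W"]], b = g[["ltar.b"]]),
       heads = list(h1 = list(W = g[["h1.W"]], b = g[["h1.b"]]),
                    h2 = list(W = g[["h2.W"]], b = g[["h2.b"]]),
                    h3 = list(W = g[["h3.W"]], b = g[["h3.b"]])))
}

model_param_tree <- function(model) {
  list(enc = model$encoder$params,
       lsrl = list(lcar = model$lsrl$lcar[c("Pq", "Pk", "Pv")],
                   ltar = model$lsrl$ltar,
                   heads = model$lsrl$heads),
       crf = list(T = model$crf$T))
}

model_set_params <- function(model, tree) {
  model$encoder$params <- tree$enc
  model$lsrl$lcar[c("Pq", "Pk", "Pv")] <- tree$lsrl$lcar[c("Pq", "Pk", "Pv")]
  model$lsrl$ltar <- tree$lsrl$ltar
  model$lsrl$heads <- tree$lsrl$heads
  model$crf$T <- tree$crf$T
  model
}
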