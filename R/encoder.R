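#' Encoders
#'
#' The joint-encoding stage is defined by a contract: an encoder maps a token
#' id sequence to one vector of dimension `d_model` per position, computed by
#' multi-head self-attention over the full concatenated input, deterministic
#' in evaluation mode. Two implementations ship: [tiny_encoder()], a small
#' trainable transformer (learned token + position embeddings, post-norm
#' multi-head self-attention and feed-forward blocks with residuals) sized
#' for CPU training, and [identity_encoder()], a stub whose output is exactly
#' its input embeddings, used to test the gather/split plumbing.
#'
#' @name encoders
NULL

#' Small trainable transformer encoder
#'
#' @param vocab_size Vocabulary size.
#' @param d_model Hidden width (per-position encoding dimension).
#' @param n_layers Number of transformer layers.
#' @param n_heads Attention heads (`d_model` must be divisible by `n_heads`).
#' @param d_ff Feed-forward inner width.
#' @param max_len Maximum input length (positions with learned embeddings).
#' @param seed Initialisation seed (recorded on the object).
#' @return An object of class `c("tiny_encoder", "trig_encoder")`.
#' @export
tiny_encoder <- function(vocab_size, d_model = 64L, n_layers = 2L,
                         n_heads = 4L, d_ff = 2L * d_model, max_len = 256L,
                         seed = 1L) {
  stopifnot(d_model %% n_heads == 0L)
  params <- with_seed(seed, {
    p <- list(embed = matrix(stats::rnorm(vocab_size * d_model, sd = 0.02),
                             vocab_size, d_model),
              pos = matrix(stats::rnorm(max_len * d_model, sd = 0.02),
                           max_len, d_model))
    for (l in seq_len(n_layers)) {
      pre <- function(nm) paste0("l", l, ".", nm)
      p[[pre("Wq")]] <- init_mat(d_model, d_model)
      p[[pre("Wk")]] <- init_mat(d_model, d_model)
      p[[pre("Wv")]] <- init_mat(d_model, d_model)
      p[[pre("Wo")]] <- init_mat(d_model, d_model)
      p[[pre("ln1_g")]] <- rep(1, d_model)
      p[[pre("ln1_b")]] <- rep(0, d_model)
      p[[pre("W1")]] <- init_mat(d_model, d_ff)
      p[[pre("b1")]] <- rep(0, d_ff)
      p[[pre("W2")]] <- init_mat(d_ff, d_model)
      p[[pre("b2")]] <- rep(0, d_model)
      p[[pre("ln2_g")]] <- rep(1, d_model)
      p[[pre("ln2_b")]] <- rep(0, d_model)
    }
    p
  })
  structure(list(params = params,
                 config = list(vocab_size = vocab_size, d_model = d_model,
                               n_layers = n_layers, n_heads = n_heads,
                               d_ff = d_ff, max_len = max_len, seed = seed)),
            class = c("tiny_encoder", "trig_encoder"))
}

#' Identity stub encoder
#'
#' Returns its input embeddings unchanged — the encoded vector at position i
#' is the embedding row of token i. Used to verify that splitting and
#' alignment are exact gathers.
#'
#' @param vocab_size Vocabulary size.
#' @param d_model Embedding width.
#' @param seed Initialisation seed.
#' @return An object of class `c("identity_encoder", "trig_encoder")`.
#' @export
identity_encoder <- function(vocab_size, d_model = 8L, seed = 1L) {
  params <- with_seed(seed, list(
    embed = matrix(stats::rnorm(vocab_size * d_model, sd = 1), vocab_size, d_model)))
  structure(list(params = params,
                 config = list(vocab_size = vocab_size, d_model = d_model,
                               n_layers = 0L, max_len = .Machine$integer.max,
                               seed = seed)),
            class = c("identity_encoder", "trig_encoder"))
}

encoder_dim <- function(enc) enc$config$d_model

#' Run an encoder over a token id sequence
#'
#' @param enc A `trig_encoder`.
#' @param ids Integer vector of token ids.
#' @param train Logical; enables dropout (when `dropout > 0`).
#' @param dropout Dropout probability applied to the attention and
#'   feed-forward block outputs during training.
#' @return List with `H` (length(ids) x d_model matrix) and `cache` for
#'   [encoder_backward()].
#' @export
encoder_forward <- function(enc, ids, train = FALSE, dropout = 0) {
  UseMethod("encoder_forward")
}

#' @export
encoder_forward.identity_encoder <- function(enc, ids, train = FALSE,
                                             dropout = 0) {
  list(H = enc$params$embed[ids, , drop = FALSE], cache = list(ids = ids))
}

ln_fwd <- function(X, g, b, eps = 1e-5) {
  mu <- rowMeans(X)
  xc <- X - mu
  inv <- 1 / sqrt(rowMeans(xc * xc) + eps)
  xhat <- xc * inv
  n <- nrow(X)
  list(Y = xhat * row_bcast(g, n) + row_bcast(b, n),
       xhat = xhat, inv = inv, g = g)
}

ln_bwd <- function(dY, cache) {
  n <- nrow(dY)
  dxhat <- dY * row_bcast(cache$g, n)
  dg <- colSums(dY * cache$xhat)
  db <- colSums(dY)
  m1 <- rowMeans(dxhat)
  m2 <- rowMeans(dxhat * cache$xhat)
  dX <- cache$inv * (dxhat - m1 - cache$xhat * m2)
  list(dX = dX, dg = dg, db = db)
}

mha_fwd <- function(X, Wq, Wk, Wv, Wo, n_heads) {
  d <- ncol(X); dh <- d %/% n_heads
  Q <- X %*% Wq; K <- X %*% Wk; V <- X %*% Wv
  O <- matrix(0, nrow(X), d)
  P_list <- vector("list", n_heads)
  for (h in seq_len(n_heads)) {
    idx <- ((h - 1L) * dh + 1L):(h * dh)
    S <- tcrossprod(Q[, idx, drop = FALSE], K[, idx, drop = FALSE]) / sqrt(dh)
    P <- softmax_rows(S)
    O[, idx] <- P %*% V[, idx, drop = FALSE]
    P_list[[h]] <- P
  }
  list(Y = O %*% Wo, Q = Q, K = K, V = V, O = O, P = P_list, X = X)
}

mha_bwd <- function(dY, cache, Wq, Wk, Wv, Wo, n_heads) {
  X <- cache$X; d <- ncol(X); dh <- d %/% n_heads
  dWo <- crossprod(cache$O, dY)
  dO <- tcrossprod(dY, Wo)
  dQ <- matrix(0, nrow(X), d); dK <- dQ; dV <- dQ
  for (h in seq_len(n_heads)) {
    idx <- ((h - 1L) * dh + 1L):(h * dh)
    P <- cache$P[[h]]
    dOh <- dO[, idx, drop = FALSE]
    dP <- tcrossprod(dOh, cache$V[, idx, drop = FALSE])
    dV[, idx] <- crossprod(P, dOh)
    dS <- P * (dP - rowSums(dP * P))
    dQ[, idx] <- dS %*% cache$K[, idx, drop = FALSE] / sqrt(dh)
    dK[, idx] <- crossprod(dS, cache$Q[, idx, drop = FALSE]) / sqrt(dh)
  }
  list(dX = tcrossprod(dQ, Wq) + tcrossprod(dK, Wk) + tcrossprod(dV, Wv),
       dWq = crossprod(X, dQ), dWk = crossprod(X, dK), dWv = crossprod(X, dV),
       dWo = dWo)
}

#' @export
encoder_forward.tiny_encoder <- function(enc, ids, train = FALSE, dropout = 0) {
  p <- enc$params; cfg <- enc$config
  Tn <- length(ids)
  if (Tn > cfg$max_len) stop("input of length ", Tn, " exceeds max_len ", cfg$max_len)
  X <- p$embed[ids, , drop = FALSE] + p$pos[seq_len(Tn), , drop = FALSE]
  layers <- vector("list", cfg$n_layers)
  use_drop <- train && dropout > 0
  for (l in seq_len(cfg$n_layers)) {
    pre <- function(nm) paste0("l", l, ".", nm)
    at <- mha_fwd(X, p[[pre("Wq")]], p[[pre("Wk")]], p[[pre("Wv")]],
                  p[[pre("Wo")]], cfg$n_heads)
    A <- at$Y
    m1 <- NULL
    if (use_drop) {
      m1 <- matrix(stats::rbinom(length(A), 1L, 1 - dropout), nrow(A)) / (1 - dropout)
      A <- A * m1
    }
    l1 <- ln_fwd(X + A, p[[pre("ln1_g")]], p[[pre("ln1_b")]])
    X1 <- l1$Y
    Z1 <- X1 %*% p[[pre("W1")]] + row_bcast(p[[pre("b1")]], Tn)
    Hrelu <- pmax(Z1, 0)
    Fo <- Hrelu %*% p[[pre("W2")]] + row_bcast(p[[pre("b2")]], Tn)
    m2 <- NULL
    if (use_drop) {
      m2 <- matrix(stats::rbinom(length(Fo), 1L, 1 - dropout), nrow(Fo)) / (1 - dropout)
      Fo <- Fo * m2
    }
    l2 <- ln_fwd(X1 + Fo, p[[pre("ln2_g")]], p[[pre("ln2_b")]])
    layers[[l]] <- list(at = at, m1 = m1, l1 = l1, X1 = X1, Z1 = Z1,
                        Hrelu = Hrelu, m2 = m2, l2 = l2)
    X <- l2$Y
  }
  list(H = X, cache = list(ids = ids, layers = layers))
}

#' Backpropagate through an encoder
#'
#' @param enc A `trig_encoder`.
#' @param cache Cache from [encoder_forward()].
#' @param dH Gradient of the loss w.r.t. the encoder output.
#' @return Named list of parameter gradients (same names/shapes as
#'   `enc$params`).
#' @export
encoder_backward <- function(enc, cache, dH) UseMethod("encoder_backward")

#' @export
encoder_backward.identity_encoder <- function(enc, cache, dH) {
  dE <- matrix(0, nrow(enc$params$embed), ncol(enc$params$embed))
  for (i in seq_along(cache$ids)) {
    dE[cache$ids[i], ] <- dE[cache$ids[i], ] + dH[i, ]
  }
  list(embed = dE)
}

#' @export
encoder_backward.tiny_encoder <- function(enc, cache, dH) {
  p <- enc$params; cfg <- enc$config
  ids <- cache$ids; Tn <- length(ids)
  g <- list()
  dX <- dH
  for (l in rev(seq_len(cfg$n_layers))) {
    pre <- function(nm) paste0("l", l, ".", nm)
    cc <- cache$layers[[l]]
    b2 <- ln_bwd(dX, cc$l2)
    g[[pre("ln2_g")]] <- b2$dg; g[[pre("ln2_b")]] <- b2$db
    dRes2 <- b2$dX                      # grad of (X1 + Fo)
    dFo <- dRes2
    if (!is.null(cc$m2)) dFo <- dFo * cc$m2
    g[[pre("W2")]] <- crossprod(cc$Hrelu, dFo)
    g[[pre("b2")]] <- colSums(dFo)
    dHrelu <- tcrossprod(dFo, p[[pre("W2")]])
    dZ1 <- dHrelu * (cc$Z1 > 0)
    g[[pre("W1")]] <- crossprod(cc$X1, dZ1)
    g[[pre("b1")]] <- colSums(dZ1)
    dX1 <- dRes2 + tcrossprod(dZ1, p[[pre("W1")]])
    b1 <- ln_bwd(dX1, cc$l1)
    g[[pre("ln1_g")]] <- b1$dg; g[[pre("ln1_b")]] <- b1$db
    dRes1 <- b1$dX                      # grad of (X + A)
    dA <- dRes1
    if (!is.null(cc$m1)) dA <- dA * cc$m1
    mb <- mha_bwd(dA, cc$at, p[[pre("Wq")]], p[[pre("Wk")]], p[[pre("Wv")]],
                  p[[pre("Wo")]], cfg$n_heads)
    g[[pre("Wq")]] <- mb$dWq; g[[pre("Wk")]] <- mb$dWk
    g[[pre("Wv")]] <- mb$dWv; g[[pre("Wo")]] <- mb$dWo
    dX <- dRes1 + mb$dX
  }
  dE <- matrix(0, nrow(p$embed), ncol(p$embed))
  for (i in seq_len(Tn)) dE[ids[i], ] <- dE[ids[i], ] + dX[i, ]
  dPos <- matrix(0, nrow(p$pos), ncol(p$pos))
  dPos[seq_len(Tn), ] <- dX
  g$embed <- dE
  g$pos <- dPos
  g
}

#' Build the label prompt
#'
#' The prompt is one dedicated label token per event type, in a random but
#' fixed order drawn once from `seed` (the order is recorded and reused for
#' the whole experiment, since tag-space projections index labels by prompt
#' position).
#'
#' @param schema An `event_schema`.
#' @param seed Permutation seed.
#' @return Object of class `label_prompt`: `types` (permuted), `tokens`
#'   (label token strings), `perm`, `seed`, `m`.
#' @export
build_label_prompt <- function(schema, seed = 1L) {
  k <- length(schema$types)
  perm <- with_seed(seed, sample.int(k))
  types <- schema$types[perm]
  structure(list(types = types, tokens = label_token(types),
                 perm = perm, seed = seed, m = k),
            class = "label_prompt")
}

#' Build the joint label-prompt + sentence input
#'
#' Lays out `[CLS], L, [SEP], S, [SEP]`: the label prompt first, then the
#' sentence subtokens. When the total exceeds `max_len`, sentence subtokens
#' are truncated from the tail — never the prompt — and words whose first
#' subtoken is cut are dropped from the word-level view.
#'
#' @param prompt A `label_prompt`.
#' @param words Character vector of sentence word surfaces (or a token tibble
#'   with a `surface` column).
#' @param vocab A `trig_vocab`.
#' @param max_len Maximum total input length (default 256).
#' @return Object of class `joint_input`: `ids`, `label_pos` (prompt-order
#'   positions), `word_pos` (first-subtoken position per retained word),
#'   `word_map` (list: word -> subtoken positions), `n_words`,
#'   `n_words_total`, `truncated`.
#' @export
build_joint_input <- function(prompt, words, vocab, max_len = 256L) {
  if (is.data.frame(words)) words <- words$surface
  m <- prompt$m
  if (m + 3L > max_len) {
    stop("label prompt of ", m, " tokens cannot fit in max_len ", max_len)
  }
  label_ids <- vocab_id(vocab, prompt$tokens)
  ids <- c(vocab$index[["[CLS]"]], label_ids, vocab$index[["[SEP]"]])
  label_pos <- 1L + seq_len(m)
  budget <- max_len - m - 3L
  word_pos <- integer(0); word_map <- list()
  used <- 0L; n_words <- 0L; truncated <- FALSE
  for (w in words) {
    sub <- encode_word(vocab, w)
    take <- min(length(sub), budget - used)
    if (take < 1L) { truncated <- TRUE; break }
    if (take < length(sub)) truncated <- TRUE
    pos0 <- length(ids)                   # position before appending
    ids <- c(ids, sub[seq_len(take)])
    n_words <- n_words + 1L
    word_pos <- c(word_pos, pos0 + 1L)
    word_map[[n_words]] <- pos0 + seq_len(take)
    used <- used + take
  }
  ids <- c(ids, vocab$index[["[SEP]"]])
  structure(list(ids = ids, label_pos = label_pos, word_pos = word_pos,
                 word_map = word_map, n_words = n_words,
                 n_words_total = length(words), truncated = truncated,
                 attention_mask = rep(1L, length(ids))),
            class = "joint_input")
}

#' Encode a joint input and split into label / sentence views
#'
#' Runs the encoder over the full concatenation, then gathers `H_L` (one row
#' per label, in prompt order) and `H_S` (one row per sentence word, taken
#' from the word's first subtoken).
#'
#' @param enc A `trig_encoder`.
#' @param ji A `joint_input`.
#' @param train,dropout Passed to [encoder_forward()].
#' @return List with `H_L` (m x d), `H_S` (n x d), full `H`, and `cache`.
#' @export
encode_and_split <- function(enc, ji, train = FALSE, dropout = 0) {
  fw <- encoder_forward(enc, ji$ids, train = train, dropout = dropout)
  list(H_L = fw$H[ji$label_pos, , drop = FALSE],
       H_S = fw$H[ji$word_pos, , drop = FALSE],
       H = fw$H, cache = fw$cache)
}
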