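# shared fixtures and independent oracles used across the suite

schema2 <- event_schema(c("Growth", "Binding"))
schema_ex <- event_schema(c("Positive_Regulation", "Growth", "Localization"))

span_tbl <- function(start, end, type) {
  tibble::tibble(start = start, end = end, type = type)
}

# random non-overlapping span set over n tokens (uniform over slots)
random_spans <- function(n, types, max_spans = 3L) {
  k <- sample.int(max_spans + 1L, 1L) - 1L
  starts <- integer(0); ends <- integer(0); tys <- character(0)
  free <- rep(TRUE, n)
  for (i in seq_len(k)) {
    open <- which(free)
    if (!length(open)) break
    s <- if (length(open) == 1L) open else sample(open, 1L)
    max_e <- s
    while (max_e < n && free[max_e + 1L]) max_e <- max_e + 1L
    e <- if (max_e == s) s else sample(s:max_e, 1L)
    starts <- c(starts, s); ends <- c(ends, e)
    tys <- c(tys, if (length(types) == 1L) types else sample(types, 1L))
    free[s:e] <- FALSE
  }
  span_tbl(starts, ends, tys)
}

sort_spans <- function(sp) {
  sp <- as.data.frame(sp)
  sp <- sp[order(sp$start), , drop = FALSE]
  rownames(sp) <- NULL
  sp
}

# brute-force CRF oracles: enumerate all K^n sequences
enumerate_scores <- function(F, params) {
  K <- params$k_tags; n <- nrow(F)
  grid <- expand.grid(rep(list(seq_len(K)), n))
  apply(grid, 1L, function(y) crf_score(F, as.integer(y), params))
}

enum_log_partition <- function(F, params) {
  s <- enumerate_scores(F, params)
  m <- max(s)
  m + log(sum(exp(s - m)))
}

random_crf_instance <- function(n, K, scale = 1) {
  F <- matrix(stats::rnorm(n * K, sd = scale), n, K)
  params <- crf_params(K)
  params$T[seq_len(K), seq_len(K)] <- stats::rnorm(K * K, sd = scale)
  params$T[params$start, seq_len(K)] <- stats::rnorm(K, sd = scale)
  params$T[seq_len(K), params$stop] <- stats::rnorm(K, sd = scale)
  list(F = F, params = params)
}

# tiny synthetic corpus shared by training smoke tests
tiny_corpus <- function(n = 40L, seed = 7L) {
  generate_corpus(synthetic_spec(), n, seed = seed)
}

tiny_cfg <- function(...) {
  trigger_config("tiny", d_model = 16L, n_layers = 1L, n_heads = 2L,
                 d_ff = 32L, epochs = 2L, seed = 1L, ...)
}
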