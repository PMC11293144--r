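#' Model vocabulary and subword encoding
#'
#' The encoder vocabulary holds the special tokens `[PAD]`, `[CLS]`, `[SEP]`,
#' `[UNK]`, one dedicated added special token per event type (so multi-word
#' label names like "Positive Regulation" occupy a single prompt position
#' with its own trainable embedding), every word form observed in the
#' training sentences (lower-cased), and the single characters needed to
#' decompose out-of-vocabulary words. A word is encoded as one id when known,
#' otherwise as its character subtokens (unknown characters map to `[UNK]`).
#'
#' @param sentences Sentence tibble from [corpus_sentences()] (or any tibble
#'   with a `tokens` list column of tibbles with a `surface` column).
#' @param schema An `event_schema`.
#' @param min_count Minimum corpus frequency for a word form to get its own
#'   id; rarer forms fall back to character subtokens.
#' @return An object of class `trig_vocab`.
#' @export
build_vocab <- function(sentences, schema, min_count = 1L) {
  words <- tolower(unlist(lapply(sentences$tokens, function(t) t$surface)))
  tab <- table(words)
  keep <- names(tab)[tab >= min_count]
  chars <- sort(unique(unlist(strsplit(c(keep, letters, as.character(0:9)), ""))))
  label_tokens <- label_token(schema$types)
  toks <- unique(c("[PAD]", "[CLS]", "[SEP]", "[UNK]", label_tokens,
                   sort(keep), chars))
  structure(list(tokens = toks,
                 index = stats::setNames(seq_along(toks), toks),
                 label_tokens = stats::setNames(label_tokens, schema$types),
                 schema = schema),
            class = "trig_vocab")
}

label_token <- function(types) paste0("[T:", types, "]")

#' @export
print.trig_vocab <- function(x, ...) {
  cat("<trig_vocab> ", length(x$tokens), " tokens (",
      length(x$label_tokens), " label tokens)\n", sep = "")
  invisible(x)
}

vocab_id <- function(vocab, token) {
  i <- vocab$index[token]
  i[is.na(i)] <- vocab$index[["[UNK]"]]
  unname(i)
}

#' Encode one word as subtoken ids
#'
#' @param vocab A `trig_vocab`.
#' @param word Word surface form.
#' @return Integer vector of subtoken ids (length 1 for in-vocabulary words).
#' @export
encode_word <- function(vocab, word) {
  w <- tolower(word)
  i <- vocab$index[w]
  if (!is.na(i)) return(unname(i))
  vocab_id(vocab, strsplit(w, "")[[1]])
}
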