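#' Synthetic trigger-detection corpora
#'
#' The generator plants the statistical structure the method exploits:
#' per-type trigger lexicons (word forms, including some two-token phrases,
#' that always signal one event type) and shared ambiguous trigger words that
#' can signal two or more types, disambiguated by a deterministic in-sentence
#' context cue word per candidate type — mirroring real corpora where, e.g.,
#' "proliferation" can trigger either a growth or a cell-proliferation event
#' depending on context. Sentences are filled slot-wise from a background
#' vocabulary, so gold spans never overlap by construction, and the full
#' generation log (every planted trigger and its resolution) is returned
#' next to the standoff documents.
#'
#' @param schema An `event_schema`; defaults to a 5-type schema
#'   (Growth, Cell_Proliferation, Localization, Binding, Regulation).
#' @param lexicon Named list: type -> character vector of unambiguous trigger
#'   forms (a form may contain spaces; it then occupies several tokens).
#' @param ambiguous List of entries `list(word =, types =, cues =)` where
#'   `cues` is a named character vector mapping each candidate type to its
#'   deterministic cue word.
#' @param n_background Background vocabulary size.
#' @param len_range Integer bounds of the uniform sentence-length draw.
#' @param trigger_density Probability that a sentence carries a trigger slot.
#' @param ambiguity_rate Probability that a planted trigger is ambiguous.
#' @param cue_noise Probability that an ambiguous trigger's cue is withheld
#'   (default 0: cues are deterministic, so a context-using classifier can be
#'   perfect).
#' @param sentences_per_doc Sentences per generated document.
#' @return An object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(schema = NULL, lexicon = NULL, ambiguous = NULL,
                           n_background = 200L, len_range = c(6L, 12L),
                           trigger_density = 0.6, ambiguity_rate = 0.3,
                           cue_noise = 0, sentences_per_doc = 5L) {
  if (is.null(schema)) schema <- default_synth_schema()
  if (is.null(lexicon)) lexicon <- default_synth_lexicon(schema)
  if (is.null(ambiguous)) ambiguous <- default_synth_ambiguous(schema)
  stopifnot(trigger_density >= 0, trigger_density <= 1,
            ambiguity_rate >= 0, ambiguity_rate <= 1,
            cue_noise >= 0, cue_noise <= 1,
            length(len_range) == 2L, len_range[1] >= 2L,
            all(schema$types %in% names(lexicon)))
  background <- sprintf("w%03d", seq_len(n_background))
  lex_tokens <- unlist(strsplit(unlist(lexicon), " ", fixed = TRUE))
  amb_words <- vapply(ambiguous, `[[`, character(1), "word")
  cues <- unlist(lapply(ambiguous, `[[`, "cues"))
  for (e in ambiguous) {
    if (anyDuplicated(unname(e$cues))) {
      stop("ambiguous word ", e$word, " has non-distinct cues")
    }
    if (!all(e$types %in% schema$types)) {
      stop("ambiguous word ", e$word, " names a type outside the schema")
    }
    if (!setequal(names(e$cues), e$types)) {
      stop("ambiguous word ", e$word, " needs one cue per candidate type")
    }
  }
  reserved <- c(lex_tokens, amb_words, cues)
  clash <- intersect(background, reserved)
  if (length(clash)) {
    stop("background vocabulary collides with trigger/cue words: ",
         paste(utils::head(clash, 3), collapse = ", "))
  }
  if (length(intersect(amb_words, lex_tokens))) {
    stop("ambiguous words must be disjoint from the unambiguous lexicon")
  }
  structure(list(schema = schema, lexicon = lexicon, ambiguous = ambiguous,
                 background = background, len_range = as.integer(len_range),
                 trigger_density = trigger_density,
                 ambiguity_rate = ambiguity_rate, cue_noise = cue_noise,
                 sentences_per_doc = as.integer(sentences_per_doc)),
            class = "synthetic_spec")
}

default_synth_schema <- function() {
  event_schema(c("Growth", "Cell_Proliferation", "Localization",
                 "Binding", "Regulation"))
}

default_synth_lexicon <- function(schema) {
  curated <- list(
    Growth = c("growth", "enlargement", "outgrowth", "expansion",
               "tissue thickening"),
    Cell_Proliferation = c("mitosis", "dividing", "replication",
                           "hyperplasia", "cell doubling"),
    Localization = c("secretion", "migration", "translocation", "release",
                     "membrane targeting"),
    Binding = c("binding", "attachment", "ligation", "docking",
                "complex formation"),
    Regulation = c("regulation", "modulation", "governing", "tuning",
                   "feedback control"))
  out <- list()
  for (i in seq_along(schema$types)) {
    t <- schema$types[i]
    out[[t]] <- if (t %in% names(curated)) curated[[t]] else {
      c(sprintf("proc%d_%d", i, 1:4), sprintf("proc%d_5a proc%d_5b", i, i))
    }
  }
  out
}

default_synth_ambiguous <- function(schema) {
  curated <- list(
    list(word = "proliferation",
         types = c("Growth", "Cell_Proliferation"),
         cues = c(Growth = "organism", Cell_Proliferation = "culture")),
    list(word = "accumulation",
         types = c("Localization", "Growth"),
         cues = c(Localization = "vesicle", Growth = "biomass")),
    list(word = "association",
         types = c("Binding", "Regulation"),
         cues = c(Binding = "receptor", Regulation = "pathway")))
  keep <- vapply(curated, function(e) all(e$types %in% schema$types), logical(1))
  out <- curated[keep]
  if (!length(out) && length(schema$types) >= 2L) {
    out <- list(list(word = "amb1", types = schema$types[1:2],
                     cues = stats::setNames(c("cue1a", "cue1b"),
                                            schema$types[1:2])))
  }
  out
}

#' Generate a synthetic corpus
#'
#' Deterministic given `(spec, n_sentences, seed)`. Every ambiguous planted
#' trigger's gold type is recoverable from its in-sentence cue (unless the
#' spec's `cue_noise` withheld it), and the generation log matches the
#' emitted annotations exactly.
#'
#' @param spec A [synthetic_spec()].
#' @param n_sentences Number of sentences.
#' @param seed Generation seed.
#' @return Object of class `synthetic_corpus`: `docs` (a `standoff_corpus`),
#'   `sentences` (tibble as from [corpus_sentences()]), `log` (tibble with
#'   one row per planted trigger: sentence row, surface form, type,
#'   `ambiguous`, `cue_given`), `spec`, `seed`.
#' @export
generate_corpus <- function(spec, n_sentences, seed = 1L) {
  stopifnot(inherits(spec, "synthetic_spec"))
  k <- length(spec$schema$types)
  sent_tokens <- vector("list", n_sentences)
  sent_spans <- vector("list", n_sentences)
  log_rows <- list()
  with_seed(seed, {
    for (s in seq_len(n_sentences)) {
      n <- sample(spec$len_range[1]:spec$len_range[2], 1L)
      toks <- sample(spec$background, n, replace = TRUE)
      spans <- empty_span_tbl()
      if (stats::runif(1) < spec$trigger_density) {
        amb <- length(spec$ambiguous) > 0 &&
          stats::runif(1) < spec$ambiguity_rate
        if (amb) {
          e <- spec$ambiguous[[sample.int(length(spec$ambiguous), 1L)]]
          type <- sample(e$types, 1L)
          pos <- sample.int(n, 1L)
          toks[pos] <- e$word
          cue_given <- stats::runif(1) >= spec$cue_noise
          if (cue_given) {
            cue_pos <- sample(setdiff(seq_len(n), pos), 1L)
            toks[cue_pos] <- unname(e$cues[[type]])
          }
          spans <- tibble::tibble(start = pos, end = pos, type = type)
          log_rows[[length(log_rows) + 1L]] <- tibble::tibble(
            sent = s, surface = e$word, type = type,
            ambiguous = TRUE, cue_given = cue_given)
        } else {
          type <- spec$schema$types[sample.int(k, 1L)]
          form <- sample(spec$lexicon[[type]], 1L)
          parts <- strsplit(form, " ", fixed = TRUE)[[1]]
          L <- length(parts)
          pos <- sample.int(n - L + 1L, 1L)
          toks[pos:(pos + L - 1L)] <- parts
          spans <- tibble::tibble(start = pos, end = pos + L - 1L, type = type)
          log_rows[[length(log_rows) + 1L]] <- tibble::tibble(
            sent = s, surface = form, type = type,
            ambiguous = FALSE, cue_given = NA)
        }
      }
      sent_tokens[[s]] <- toks
      sent_spans[[s]] <- spans
    }
  })
  # assemble standoff documents: sentences joined by newlines
  spd <- spec$sentences_per_doc
  n_docs <- ceiling(n_sentences / spd)
  docs <- vector("list", n_docs)
  sent_rows <- vector("list", n_sentences)
  for (d in seq_len(n_docs)) {
    idx <- ((d - 1L) * spd + 1L):min(d * spd, n_sentences)
    doc_id <- sprintf("synth%04d", d)
    offset <- 0L
    t_rows <- list(); e_rows <- list(); tcount <- 0L
    lines <- character(length(idx))
    for (j in seq_along(idx)) {
      s <- idx[j]
      toks <- sent_tokens[[s]]
      starts <- offset + c(0L, cumsum(nchar(toks) + 1L))[seq_along(toks)]
      ends <- starts + nchar(toks)
      lines[j] <- paste(toks, collapse = " ")
      sp <- sent_spans[[s]]
      if (nrow(sp)) for (r in seq_len(nrow(sp))) {
        tcount <- tcount + 1L
        t_rows[[tcount]] <- tibble::tibble(
          id = paste0("T", tcount), type = sp$type[r],
          start = starts[sp$start[r]], end = ends[sp$end[r]],
          surface = paste(toks[sp$start[r]:sp$end[r]], collapse = " "),
          source = "a2")
        e_rows[[tcount]] <- tibble::tibble(
          id = paste0("E", tcount), type = sp$type[r],
          trigger_id = paste0("T", tcount), args = "")
      }
      sent_rows[[s]] <- tibble::tibble(
        doc_id = doc_id, sent_index = j,
        tokens = list(tibble::tibble(surface = toks, start = starts,
                                     end = ends)),
        gold_spans = list(sp))
      offset <- ends[length(ends)] + 1L          # the newline
    }
    text <- paste(lines, collapse = "\n")
    docs[[d]] <- standoff_document(
      doc_id, text,
      t_ann = if (tcount) dplyr::bind_rows(t_rows) else empty_t_ann(),
      e_ann = if (tcount) dplyr::bind_rows(e_rows) else empty_e_ann())
  }
  log <- if (length(log_rows)) dplyr::bind_rows(log_rows) else {
    tibble::tibble(sent = integer(), surface = character(), type = character(),
                   ambiguous = logical(), cue_given = logical())
  }
  structure(list(docs = structure(docs, class = "standoff_corpus",
                                  schema = spec$schema),
                 sentences = dplyr::bind_rows(sent_rows),
                 log = log, spec = spec, seed = seed),
            class = "synthetic_corpus")
}

#' @export
print.synthetic_corpus <- function(x, ...) {
  cat("<synthetic_corpus> ", nrow(x$sentences), " sentences, ",
      nrow(x$log), " planted triggers (", sum(x$log$ambiguous),
      " ambiguous), seed ", x$seed, "\n", sep = "")
  invisible(x)
}

#' Context-blind lexicon baseline
#'
#' Fits a most-frequent-type lookup from trigger surface form to event type
#' on the training corpus's gold annotations (ties broken toward schema
#' order) and predicts every occurrence of a known form as a trigger of that
#' single type, ignoring context. Its score ceiling on corpora with
#' ambiguous triggers is below 1 by construction, which is the gap a
#' label-context-aware model is supposed to close.
#'
#' @param corpus A `synthetic_corpus` (fit set).
#' @param sentences Sentence tibble to score on (default: the corpus's own).
#' @return An `eval_report` (micro-averaged) with the fitted `lookup`
#'   attached as an attribute.
#' @export
lexicon_baseline <- function(corpus, sentences = corpus$sentences) {
  stopifnot(inherits(corpus, "synthetic_corpus"))
  schema <- corpus$spec$schema
  counts <- dplyr::count(corpus$log, .data$surface, .data$type)
  counts$type_ord <- match(counts$type, schema$types)
  counts <- counts[order(counts$surface, -counts$n, counts$type_ord), ]
  lookup <- counts[!duplicated(counts$surface), c("surface", "type")]
  lookup_map <- stats::setNames(lookup$type, lookup$surface)
  max_len <- max(lengths(strsplit(names(lookup_map), " ", fixed = TRUE)), 1L)
  pred <- lapply(sentences$tokens, function(toks) {
    words <- tolower(toks$surface)
    n <- length(words)
    start <- integer(0); end <- integer(0); type <- character(0)
    i <- 1L
    while (i <= n) {
      hit <- 0L
      for (L in rev(seq_len(min(max_len, n - i + 1L)))) {
        key <- paste(words[i:(i + L - 1L)], collapse = " ")
        if (!is.na(lookup_map[key])) { hit <- L; break }
      }
      if (hit) {
        start <- c(start, i); end <- c(end, i + hit - 1L)
        type <- c(type, unname(lookup_map[paste(words[i:(i + hit - 1L)],
                                                collapse = " ")]))
        i <- i + hit
      } else i <- i + 1L
    }
    tibble::tibble(start = start, end = end, type = type)
  })
  rep <- evaluate_triggers(sentences$gold_spans, pred, averaging = "micro",
                           schema = schema)
  attr(rep, "lookup") <- lookup_map
  attr(rep, "pred_spans") <- pred
  rep
}

#' Recall on the ambiguous trigger subset
#'
#' Fraction of gold trigger instances whose surface form is ambiguous in the
#' generator spec (i.e. genuinely context-dependent) that the predictions
#' recover with exact extent and type. This isolates how much a model uses
#' context: a context-blind lookup is capped near the majority share, while
#' a context-using model can reach 1.
#'
#' @param spec The `synthetic_spec` the corpus was generated from.
#' @param sentences Sentence tibble with `gold_spans`.
#' @param pred_spans List of predicted span tibbles, sentence-aligned.
#' @return List with `recall` (percent, `NA` if no ambiguous instances),
#'   `tp`, `n`.
#' @export
ambiguous_subset_recall <- function(spec, sentences, pred_spans) {
  amb_words <- vapply(spec$ambiguous, `[[`, character(1), "word")
  tp <- 0L; n <- 0L
  for (i in seq_len(nrow(sentences))) {
    g <- sentences$gold_spans[[i]]
    if (is.null(g) || !nrow(g)) next
    toks <- tolower(sentences$tokens[[i]]$surface)
    for (r in seq_len(nrow(g))) {
      if (g$start[r] == g$end[r] && toks[g$start[r]] %in% amb_words) {
        n <- n + 1L
        p <- pred_spans[[i]]
        if (!is.null(p) && nrow(p) &&
            any(p$start == g$start[r] & p$end == g$end[r] &
                  p$type == g$type[r])) {
          tp <- tp + 1L
        }
      }
    }
  }
  list(recall = if (n) 100 * tp / n else NA_real_, tp = tp, n = n)
}
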