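#' BioNLP standoff corpora
#'
#' A standoff corpus is a directory of matched basename triples: `<id>.txt`
#' (raw text), `<id>.a1` (entity `T` lines) and `<id>.a2` (trigger `T` lines
#' plus event `E` lines). Character offsets are 0-based, half-open, into the
#' raw text. `.a2` may be absent for unannotated test splits.
#'
#' @name standoff
NULL

#' Construct a standoff document
#'
#' @param doc_id Document identifier (file basename).
#' @param text Full document text.
#' @param t_ann Tibble of text-bound annotations: columns `id`, `type`,
#'   `start`, `end` (0-based half-open character offsets), `surface`, and
#'   `source` (`"a1"` or `"a2"`). `surface` must equal the text slice.
#' @param e_ann Tibble of event annotations: columns `id`, `type`,
#'   `trigger_id`, `args` (argument structure kept as an opaque string).
#' @return An object of class `standoff_document`.
#' @export
standoff_document <- function(doc_id, text,
                              t_ann = empty_t_ann(), e_ann = empty_e_ann()) {
  t_ann <- tibble::as_tibble(t_ann)
  e_ann <- tibble::as_tibble(e_ann)
  if (nrow(t_ann)) {
    got <- substring(text, t_ann$start + 1L, t_ann$end)
    bad <- which(got != t_ann$surface)
    if (length(bad)) {
      stop(sprintf("doc %s: annotation %s surface %s does not match text slice %s",
                   doc_id, t_ann$id[bad[1]],
                   dQuote(t_ann$surface[bad[1]]), dQuote(got[bad[1]])))
    }
    if (anyDuplicated(t_ann$id)) stop("doc ", doc_id, ": duplicate annotation ids")
  }
  structure(list(doc_id = doc_id, text = text, t_ann = t_ann, e_ann = e_ann),
            class = "standoff_document")
}

empty_t_ann <- function() {
  tibble::tibble(id = character(), type = character(), start = integer(),
                 end = integer(), surface = character(), source = character())
}
empty_e_ann <- function() {
  tibble::tibble(id = character(), type = character(),
                 trigger_id = character(), args = character())
}

#' @export
print.standoff_document <- function(x, ...) {
  cat("<standoff_document> ", x$doc_id, ": ", nchar(x$text), " chars, ",
      nrow(x$t_ann), " T, ", nrow(x$e_ann), " E\n", sep = "")
  invisible(x)
}

parse_t_line <- function(line, file, lineno, source) {
  parts <- strsplit(line, "\t", fixed = TRUE)[[1]]
  if (length(parts) < 2L) stop(file, ":", lineno, ": malformed T line")
  head <- strsplit(parts[2], " ", fixed = TRUE)[[1]]
  if (grepl(";", parts[2], fixed = TRUE)) {
    return(structure(list(), discontinuous = TRUE))
  }
  if (length(head) != 3L) stop(file, ":", lineno, ": malformed T line header")
  list(id = parts[1], type = head[1],
       start = as.integer(head[2]), end = as.integer(head[3]),
       surface = if (length(parts) >= 3L) parts[3] else "",
       source = source)
}

read_ann_file <- function(path, source, text, doc_id) {
  t_rows <- list(); e_rows <- list(); n_skip <- 0L
  if (!file.exists(path)) {
    return(list(t = empty_t_ann(), e = empty_e_ann(), skipped = 0L))
  }
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  for (i in seq_along(lines)) {
    ln <- lines[i]
    if (!nzchar(ln)) next
    if (startsWith(ln, "T")) {
      p <- parse_t_line(ln, path, i, source)
      if (isTRUE(attr(p, "discontinuous"))) {
        warning(path, ":", i, ": discontinuous annotation skipped", call. = FALSE)
        n_skip <- n_skip + 1L
        next
      }
      got <- substring(text, p$start + 1L, p$end)
      if (!identical(got, p$surface)) {
        stop(path, ":", i, ": surface ", dQuote(p$surface),
             " does not match text offsets [", p$start, ",", p$end, ") = ",
             dQuote(got))
      }
      t_rows[[length(t_rows) + 1L]] <- p
    } else if (startsWith(ln, "E")) {
      parts <- strsplit(ln, "\t", fixed = TRUE)[[1]]
      fields <- strsplit(parts[2], " ", fixed = TRUE)[[1]]
      tt <- strsplit(fields[1], ":", fixed = TRUE)[[1]]
      e_rows[[length(e_rows) + 1L]] <- list(
        id = parts[1], type = tt[1],
        trigger_id = if (length(tt) > 1L) tt[2] else NA_character_,
        args = paste(fields[-1], collapse = " "))
    }
    # other line kinds (A/M/R/*) carry no trigger information; ignored
  }
  list(t = dplyr::bind_rows(lapply(t_rows, tibble::as_tibble)),
       e = dplyr::bind_rows(lapply(e_rows, tibble::as_tibble)),
       skipped = n_skip)
}

#' Read a standoff corpus directory
#'
#' Parses every `<id>.txt` with its `.a1`/`.a2` companions. Offset/surface
#' mismatches are hard errors naming file and line; discontinuous annotations
#' (semicolon offset syntax) are skipped with a warning and counted in the
#' `n_discontinuous_skipped` attribute of the result.
#'
#' @param path Directory containing the triples.
#' @param schema Optional `event_schema`; retained on the result for
#'   downstream trigger identification.
#' @return A list of `standoff_document` objects (class `standoff_corpus`).
#' @export
read_standoff <- function(path, schema = NULL) {
  txts <- sort(list.files(path, pattern = "\\.txt$", full.names = TRUE))
  skipped <- 0L
  docs <- lapply(txts, function(f) {
    doc_id <- sub("\\.txt$", "", basename(f))
    text <- paste(readLines(f, warn = FALSE, encoding = "UTF-8"), collapse = "\n")
    a1 <- read_ann_file(sub("\\.txt$", ".a1", f), "a1", text, doc_id)
    a2 <- read_ann_file(sub("\\.txt$", ".a2", f), "a2", text, doc_id)
    skipped <<- skipped + a1$skipped + a2$skipped
    standoff_document(doc_id, text,
                      t_ann = dplyr::bind_rows(a1$t, a2$t),
                      e_ann = dplyr::bind_rows(a1$e, a2$e))
  })
  structure(docs, class = "standoff_corpus", schema = schema,
            n_discontinuous_skipped = skipped)
}

#' Write a standoff corpus
#'
#' Inverse of [read_standoff()]: emits `<id>.txt`, `<id>.a1` and `<id>.a2`
#' for every document (annotation files are written even when empty, so a
#' re-read restores the same document set).
#'
#' @param docs A `standoff_corpus` or list of `standoff_document`s.
#' @param path Output directory (created if needed).
#' @return `path`, invisibly.
#' @export
write_standoff <- function(docs, path) {
  ids <- vapply(docs, function(d) d$doc_id, character(1))
  if (anyDuplicated(ids)) {
    stop("colliding doc_ids: ", paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  for (d in docs) {
    writeLines(d$text, file.path(path, paste0(d$doc_id, ".txt")), useBytes = TRUE)
    fmt_t <- function(rows) {
      sprintf("%s\t%s %d %d\t%s", rows$id, rows$type, rows$start, rows$end,
              rows$surface)
    }
    a1 <- d$t_ann[d$t_ann$source == "a1", , drop = FALSE]
    a2 <- d$t_ann[d$t_ann$source == "a2", , drop = FALSE]
    writeLines(if (nrow(a1)) fmt_t(a1) else character(0),
               file.path(path, paste0(d$doc_id, ".a1")), useBytes = TRUE)
    e_lines <- if (nrow(d$e_ann)) {
      sprintf("%s\t%s:%s%s", d$e_ann$id, d$e_ann$type, d$e_ann$trigger_id,
              ifelse(nzchar(d$e_ann$args), paste0(" ", d$e_ann$args), ""))
    } else character(0)
    writeLines(c(if (nrow(a2)) fmt_t(a2) else character(0), e_lines),
               file.path(path, paste0(d$doc_id, ".a2")), useBytes = TRUE)
  }
  invisible(path)
}

#' Identify event-trigger annotations of a document
#'
#' A text-bound annotation is an event trigger iff its type is in the schema
#' and, when the document has `E` lines, some `E` line references it; for
#' corpora without event lines type membership alone decides.
#'
#' @param doc A `standoff_document`.
#' @param schema An `event_schema`.
#' @return The trigger subset of `doc$t_ann`.
#' @export
doc_triggers <- function(doc, schema) {
  t <- doc$t_ann[doc$t_ann$type %in% schema$types, , drop = FALSE]
  if (nrow(doc$e_ann)) {
    t <- t[t$id %in% doc$e_ann$trigger_id, , drop = FALSE]
  }
  t
}

split_sentence_offsets <- function(text) {
  # newline always splits; ". " followed by an uppercase letter also splits
  bounds <- c(0L)
  chars <- nchar(text)
  if (chars == 0L) return(integer(0))
  m <- gregexpr("\n|\\. +(?=[A-Z])", text, perl = TRUE)[[1]]
  if (m[1] != -1L) {
    lens <- attr(m, "match.length")
    for (i in seq_along(m)) {
      cut <- if (substring(text, m[i], m[i]) == "\n") m[i] else m[i] + lens[i] - 1L
      bounds <- c(bounds, cut)            # 0-based position after the separator
    }
  }
  bounds <- unique(c(bounds, chars))
  bounds
}

tokenize_offsets <- function(text, base, keep_period = TRUE) {
  # `text` is a sentence slice; `base` its 0-based offset in the document
  m <- gregexpr("\\S+", text)[[1]]
  if (m[1] == -1L) {
    return(tibble::tibble(surface = character(), start = integer(), end = integer()))
  }
  lens <- attr(m, "match.length")
  out_s <- character(0); out_a <- integer(0); out_b <- integer(0)
  open_p <- c("(", "[", "{", "\"", "'")
  close_p <- c(",", ";", ":", "!", "?", ")", "]", "}", "\"", "'")
  if (!keep_period) close_p <- c(close_p, ".")
  for (i in seq_along(m)) {
    s <- m[i]; e <- m[i] + lens[i] - 1L   # 1-based in slice
    while (s < e && substring(text, s, s) %in% open_p) {
      out_s <- c(out_s, substring(text, s, s))
      out_a <- c(out_a, base + s - 1L); out_b <- c(out_b, base + s)
      s <- s + 1L
    }
    trail <- character(0); trail_pos <- integer(0)
    while (e > s && substring(text, e, e) %in% close_p) {
      trail <- c(substring(text, e, e), trail)
      trail_pos <- c(e, trail_pos)
      e <- e - 1L
    }
    out_s <- c(out_s, substring(text, s, e))
    out_a <- c(out_a, base + s - 1L); out_b <- c(out_b, base + e)
    if (length(trail)) {
      out_s <- c(out_s, trail)
      out_a <- c(out_a, base + trail_pos - 1L)
      out_b <- c(out_b, base + trail_pos)
    }
  }
  tibble::tibble(surface = out_s, start = out_a, end = out_b)
}

#' Sentence-split and tokenize a corpus
#'
#' Offset-preserving rule-based splitting (newline always splits; a period
#' followed by whitespace and an uppercase letter splits) and tokenization
#' (whitespace plus punctuation; a trailing period stays attached to its word
#' when `keep_period = TRUE`, the default, so "metastasis." is one token).
#' Gold spans are token runs aligned with trigger character extents; a
#' trigger that crosses a token boundary is force-aligned to the smallest
#' covering token run and counted in the `n_forced_alignments` attribute.
#'
#' @param docs A `standoff_corpus` or list of `standoff_document`s.
#' @param schema An `event_schema` used to identify triggers (default: the
#'   schema attached to `docs`).
#' @param keep_period Keep a trailing period attached to its token.
#' @return A tibble with one row per sentence: `doc_id`, `sent_index`,
#'   `tokens` (list of tibbles `surface`/`start`/`end`) and `gold_spans`
#'   (list of tibbles `start`/`end`/`type`, token indices 1-based inclusive).
#' @export
corpus_sentences <- function(docs, schema = attr(docs, "schema"),
                             keep_period = TRUE) {
  n_forced <- 0L
  rows <- list()
  for (d in docs) {
    trig <- if (is.null(schema)) d$t_ann[0, ] else doc_triggers(d, schema)
    bounds <- split_sentence_offsets(d$text)
    si <- 0L
    if (length(bounds) >= 2L) for (b in seq_len(length(bounds) - 1L)) {
      lo <- bounds[b]; hi <- bounds[b + 1L]            # 0-based half-open
      slice <- substring(d$text, lo + 1L, hi)
      toks <- tokenize_offsets(slice, lo, keep_period)
      if (nrow(toks) == 0L) next
      si <- si + 1L
      sp <- trig[trig$start >= lo & trig$end <= hi, , drop = FALSE]
      gs <- empty_span_tbl()
      if (nrow(sp)) {
        g_start <- integer(0); g_end <- integer(0); g_type <- character(0)
        for (j in seq_len(nrow(sp))) {
          cover <- which(toks$end > sp$start[j] & toks$start < sp$end[j])
          if (!length(cover)) next
          a <- min(cover); z <- max(cover)
          exact <- toks$start[a] == sp$start[j] && toks$end[z] == sp$end[j]
          if (!exact) n_forced <- n_forced + 1L
          g_start <- c(g_start, a); g_end <- c(g_end, z)
          g_type <- c(g_type, sp$type[j])
        }
        gs <- tibble::tibble(start = g_start, end = g_end, type = g_type)
        gs <- gs[!duplicated(gs[, c("start", "end")]), , drop = FALSE]
      }
      rows[[length(rows) + 1L]] <- tibble::tibble(
        doc_id = d$doc_id, sent_index = si,
        tokens = list(toks), gold_spans = list(gs))
    }
  }
  out <- if (length(rows)) dplyr::bind_rows(rows) else {
    tibble::tibble(doc_id = character(), sent_index = integer(),
                   tokens = list(), gold_spans = list())
  }
  attr(out, "n_forced_alignments") <- n_forced
  attr(out, "schema") <- schema
  out
}

empty_span_tbl <- function() {
  tibble::tibble(start = integer(), end = integer(), type = character())
}

#' Corpus statistics
#'
#' Counts documents, sentences, trigger mentions (with a per-type breakdown)
#' and event instances (`E` lines). Trigger mentions and event instances can
#' differ when several events share one trigger; both are reported.
#'
#' @param docs A `standoff_corpus` or list of `standoff_document`s.
#' @param schema An `event_schema` (default: attached to `docs`).
#' @return A list of class `corpus_stats`: `n_documents`, `n_sentences`,
#'   `n_events` (trigger mentions), `n_event_instances` (`E` lines), and
#'   `per_type` (tibble `type`/`n`).
#' @export
corpus_stats <- function(docs, schema = attr(docs, "schema")) {
  sent <- corpus_sentences(docs, schema)
  types <- unlist(lapply(docs, function(d) doc_triggers(d, schema)$type))
  per_type <- tibble::tibble(type = schema$types,
                             n = vapply(schema$types,
                                        function(t) sum(types == t),
                                        integer(1), USE.NAMES = FALSE))
  structure(list(
    n_documents = length(docs),
    n_sentences = nrow(sent),
    n_events = length(types),
    n_event_instances = sum(vapply(docs, function(d) nrow(d$e_ann), integer(1))),
    per_type = per_type), class = "corpus_stats")
}

#' @export
print.corpus_stats <- function(x, ...) {
  cat("<corpus_stats> ", x$n_documents, " documents, ", x$n_sentences,
      " sentences, ", x$n_events, " trigger mentions (",
      x$n_event_instances, " event instances)\n", sep = "")
  print(x$per_type[x$per_type$n > 0, ])
  invisible(x)
}

#' Export predictions as standoff and CoNLL files
#'
#' Writes one `.a2`-style file of `T` lines per document and a two-column
#' CoNLL file (`token<TAB>tag`, blank line between sentences) for the whole
#' corpus.
#'
#' @param sentences Sentence tibble as from [corpus_sentences()].
#' @param pred_spans List of span tibbles parallel to `sentences` rows.
#' @param schema An `event_schema`.
#' @param path Output directory.
#' @return `path`, invisibly.
#' @export
write_predictions <- function(sentences, pred_spans, schema, path) {
  stopifnot(nrow(sentences) == length(pred_spans))
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  conll <- character(0)
  by_doc <- split(seq_len(nrow(sentences)), sentences$doc_id)
  for (doc_id in names(by_doc)) {
    lines <- character(0); tcount <- 0L
    for (i in by_doc[[doc_id]]) {
      toks <- sentences$tokens[[i]]
      sp <- pred_spans[[i]]
      tags <- spans_to_tags(sp, nrow(toks), schema)
      conll <- c(conll, paste0(toks$surface, "\t", tags), "")
      if (nrow(sp)) for (j in seq_len(nrow(sp))) {
        tcount <- tcount + 1L
        surf <- paste(toks$surface[sp$start[j]:sp$end[j]], collapse = " ")
        lines <- c(lines, sprintf("T%d\t%s %d %d\t%s", tcount, sp$type[j],
                                  toks$start[sp$start[j]], toks$end[sp$end[j]],
                                  surf))
      }
    }
    writeLines(lines, file.path(path, paste0(doc_id, ".a2")), useBytes = TRUE)
  }
  writeLines(conll, file.path(path, "predictions.conll"), useBytes = TRUE)
  invisible(path)
}
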