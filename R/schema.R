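#' Event-type schemas and the BIO tag set
#'
#' An event-type schema is the ordered set of pre-defined event types a corpus
#' annotates (e.g. 19 types for MLEE, 9 for the GENIA GE09/GE11 shared tasks),
#' together with a human-readable label word for each type. The label words
#' carry the semantics the model exploits; the order is fixed and serialised
#' with the schema because tag indices and prompt permutations refer to it.
#'
#' @param types Character vector of unique type identifiers. Identifiers use
#'   underscores internally (e.g. `"Positive_Regulation"`).
#' @param label_words Optional named character vector mapping each type to its
#'   display/prompt form (possibly multi-word, e.g. `"Positive Regulation"`).
#'   Defaults to the identifiers with underscores replaced by spaces.
#' @return An object of class `event_schema` with elements `types` and
#'   `label_words`.
#' @examples
#' sch <- event_schema(c("Growth", "Localization"))
#' bio_tags(sch)
#' @export
event_schema <- function(types, label_words = NULL) {
  types <- as.character(types)
  if (length(types) < 1L) stop("a schema needs at least one event type")
  if (anyDuplicated(types)) stop("event type identifiers must be unique")
  if (is.null(label_words)) {
    label_words <- stats::setNames(gsub("_", " ", types, fixed = TRUE), types)
  } else {
    if (!all(types %in% names(label_words))) {
      stop("label_words must name every type in the schema")
    }
    label_words <- stats::setNames(as.character(label_words[types]), types)
  }
  structure(list(types = types, label_words = label_words),
            class = "event_schema")
}

#' @export
print.event_schema <- function(x, ...) {
  cat("<event_schema> ", length(x$types), " types: ",
      paste(utils::head(x$types, 6), collapse = ", "),
      if (length(x$types) > 6) ", ..." else "", "\n", sep = "")
  invisible(x)
}

#' Built-in corpus schemas
#'
#' `builtin_schema("mlee")` returns the 19 event types of the MLEE corpus;
#' `"ge09"` and `"ge11"` return the 9 GENIA shared-task types (identical
#' inventories, distinct names for convenience).
#'
#' @param name One of `"mlee"`, `"ge09"`, `"ge11"`.
#' @return An `event_schema`.
#' @export
builtin_schema <- function(name = c("mlee", "ge09", "ge11")) {
  name <- match.arg(name)
  path <- system.file("extdata", "schemas", paste0(name, ".yaml"),
                      package = "trigtag")
  read_schema(path)
}

#' Read / write a schema file
#'
#' Schemas are serialised as YAML: an ordered list of `type` / `label` pairs.
#'
#' @param path File path.
#' @return `read_schema()` an `event_schema`; `write_schema()` `path`,
#'   invisibly.
#' @export
read_schema <- function(path) {
  y <- yaml::read_yaml(path)
  types <- vapply(y$types, function(e) e$type, character(1))
  labels <- vapply(y$types, function(e) {
    if (is.null(e$label)) gsub("_", " ", e$type, fixed = TRUE) else e$label
  }, character(1))
  event_schema(types, stats::setNames(labels, types))
}

#' @rdname read_schema
#' @param schema An `event_schema`.
#' @export
write_schema <- function(schema, path) {
  y <- list(types = lapply(schema$types, function(t) {
    list(type = t, label = unname(schema$label_words[[t]]))
  }))
  yaml::write_yaml(y, path)
  invisible(path)
}

#' BIO tag set of a schema
#'
#' For k event types the tag set has 2k + 1 tags: `"O"` first, then `B-t`,
#' `I-t` for each type t in schema order. Tag indices are 1-based in schema
#' order with `index("O") = 1`.
#'
#' @param schema An `event_schema`.
#' @return Object of class `bio_tagset`: list with `tags` (character),
#'   `index` (named integer map), and the originating `schema`.
#' @export
bio_tags <- function(schema) {
  stopifnot(inherits(schema, "event_schema"))
  tags <- c("O", as.vector(rbind(paste0("B-", schema$types),
                                 paste0("I-", schema$types))))
  structure(list(tags = tags,
                 index = stats::setNames(seq_along(tags), tags),
                 schema = schema),
            class = "bio_tagset")
}

as_tagset <- function(x) {
  if (inherits(x, "bio_tagset")) x
  else if (inherits(x, "event_schema")) bio_tags(x)
  else stop("expected an event_schema or bio_tagset")
}

tag_type <- function(tag) sub("^[BI]-", "", tag)
tag_kind <- function(tag) ifelse(tag == "O", "O", substr(tag, 1, 1))

#' Convert trigger spans to a BIO tag sequence
#'
#' Token indices are 1-based with inclusive `start` and `end` (a single-token
#' trigger has `start == end`). The token at `start` receives `B-type`,
#' subsequent span tokens `I-type`, all other tokens `"O"`. Overlapping spans
#' cannot be represented in BIO and are rejected.
#'
#' @param spans A data frame with columns `start`, `end`, `type` (one row per
#'   trigger span); zero-row input yields an all-`"O"` sequence.
#' @param n Number of tokens in the sentence.
#' @param schema An `event_schema` or `bio_tagset`.
#' @return Character vector of length `n` of BIO tags.
#' @examples
#' sch <- event_schema(c("Positive_Regulation", "Growth", "Localization"))
#' spans <- tibble::tibble(start = c(3, 5, 8), end = c(3, 5, 8),
#'                         type = c("Positive_Regulation", "Growth", "Localization"))
#' spans_to_tags(spans, 8, sch)
#' @export
spans_to_tags <- function(spans, n, schema) {
  ts <- as_tagset(schema)
  spans <- as.data.frame(spans)
  tags <- rep("O", n)
  if (nrow(spans) == 0L) return(tags)
  if (!all(spans$type %in% ts$schema$types)) {
    bad <- setdiff(unique(spans$type), ts$schema$types)
    stop("span type(s) not in schema: ", paste(bad, collapse = ", "))
  }
  if (any(spans$start < 1L | spans$end > n | spans$start > spans$end)) {
    stop("span out of range for a sentence of ", n, " tokens")
  }
  o <- order(spans$start)
  spans <- spans[o, , drop = FALSE]
  if (nrow(spans) > 1L) {
    prev_end <- spans$end[-nrow(spans)]
    nxt_start <- spans$start[-1L]
    bad <- which(nxt_start <= prev_end)
    if (length(bad)) {
      i <- bad[1L]
      stop(sprintf("overlapping spans cannot be BIO-encoded: [%d,%d,%s] and [%d,%d,%s]",
                   spans$start[i], spans$end[i], spans$type[i],
                   spans$start[i + 1L], spans$end[i + 1L], spans$type[i + 1L]))
    }
  }
  for (i in seq_len(nrow(spans))) {
    s <- spans$start[i]; e <- spans$end[i]; ty <- spans$type[i]
    tags[s] <- paste0("B-", ty)
    if (e > s) tags[(s + 1L):e] <- paste0("I-", ty)
  }
  tags
}

#' Recover trigger spans from a BIO tag sequence
#'
#' Maximal `B-t (I-t)*` runs become spans; adjacent same-type triggers stay
#' distinct because the second starts with `B`. Decoded sequences may be
#' ill-formed (stray `I-` after `O`, after a different type, or
#' sentence-initial); these are repaired with the begin-on-stray policy — a
#' stray `I-t` opens a new span as if it were `B-t` — so the output is always
#' a valid, non-overlapping span set.
#'
#' @param tags Character vector of BIO tags.
#' @param schema An `event_schema` or `bio_tagset`.
#' @return A tibble with columns `start`, `end`, `type` (1-based inclusive).
#' @export
tags_to_spans <- function(tags, schema) {
  ts <- as_tagset(schema)
  unknown <- setdiff(unique(tags), ts$tags)
  if (length(unknown)) stop("unknown tag(s): ", paste(unknown, collapse = ", "))
  start <- integer(0); end <- integer(0); type <- character(0)
  cur_start <- NA_integer_; cur_type <- NA_character_
  close_cur <- function(i) {
    if (!is.na(cur_start)) {
      start <<- c(start, cur_start); end <<- c(end, i); type <<- c(type, cur_type)
    }
    cur_start <<- NA_integer_; cur_type <<- NA_character_
  }
  for (i in seq_along(tags)) {
    tg <- tags[i]
    if (tg == "O") {
      close_cur(i - 1L)
    } else if (startsWith(tg, "B-")) {
      close_cur(i - 1L)
      cur_start <- i; cur_type <- tag_type(tg)
    } else {                                  # I-t
      ty <- tag_type(tg)
      if (is.na(cur_start) || !identical(cur_type, ty)) {
        close_cur(i - 1L)                     # begin-on-stray
        cur_start <- i; cur_type <- ty
      }
    }
  }
  close_cur(length(tags))
  tibble::tibble(start = start, end = end, type = type)
}

#' BIO transition validity
#'
#' A transition `a -> b` is invalid exactly when it breaks BIO structure:
#' `O -> I-t`, `B-t -> I-u` or `I-t -> I-u` with `t != u`, and
#' `START -> I-t`. Everything else — including any transition into `STOP` and
#' `START` into `O`/`B-t` — is valid. `START`/`STOP` are the virtual boundary
#' states of the CRF.
#'
#' @param a,b Tag identifiers (elements of the tag set, or `"START"`/`"STOP"`).
#' @param schema An `event_schema` or `bio_tagset`.
#' @return Logical scalar.
#' @export
is_valid_transition <- function(a, b, schema) {
  ts <- as_tagset(schema)
  ok <- c(ts$tags, "START", "STOP")
  if (!(a %in% ok) || !(b %in% ok)) {
    stop("unknown tag in transition: ", a, " -> ", b)
  }
  if (!startsWith(b, "I-")) return(TRUE)
  # b is I-t: valid only after B-t or I-t of the same type
  if (a %in% c("O", "START", "STOP")) return(FALSE)
  identical(tag_type(a), tag_type(b))
}
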