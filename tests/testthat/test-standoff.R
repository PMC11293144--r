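make_demo_doc <- function() {
  text <- "Angiogenesis is essential for growth and tumor metastasis."
  standoff_document(
    "demo", text,
    t_ann = tibble::tibble(
      id = c("T1", "T2", "T3"),
      type = c("Positive_Regulation", "Growth", "Localization"),
      start = c(16L, 30L, 47L), end = c(25L, 36L, 57L),
      surface = c("essential", "growth", "metastasis"),
      source = "a2"),
    e_ann = tibble::tibble(id = c("E1", "E2", "E3"),
                           type = c("Positive_Regulation", "Growth",
                                    "Localization"),
                           trigger_id = c("T1", "T2", "T3"), args = ""))
}

test_that("T lines parse into offset-checked annotations", {
  d <- withr::local_tempdir()
  writeLines("The growth was rapid", file.path(d, "x.txt"))
  writeLines("T1\tGrowth 4 10\tgrowth", file.path(d, "x.a2"))
  writeLines(character(0), file.path(d, "x.a1"))
  docs <- read_standoff(d, schema2)
  expect_length(docs, 1L)
  a <- docs[[1]]$t_ann
  expect_equal(a$type, "Growth")
  expect_equal(a$start, 4L)
  expect_equal(a$end, 10L)
  expect_equal(a$surface, "growth")
})

test_that("surface/offset mismatch is a hard error naming file and line", {
  d <- withr::local_tempdir()
  writeLines("The growth was rapid", file.path(d, "x.txt"))
  writeLines("T1\tGrowth 4 10\tshrink", file.path(d, "x.a2"))
  expect_error(read_standoff(d, schema2), "x\\.a2:1")
})

test_that("discontinuous annotations are skipped with a warning and counted", {
  d <- withr::local_tempdir()
  writeLines("The growth was rapid", file.path(d, "x.txt"))
  writeLines(c("T1\tGrowth 4 10;15 20\tgrowth rapid",
               "T2\tGrowth 4 10\tgrowth"), file.path(d, "x.a2"))
  expect_warning(docs <- read_standoff(d, schema2), "discontinuous")
  expect_equal(attr(docs, "n_discontinuous_skipped"), 1L)
  expect_equal(nrow(docs[[1]]$t_ann), 1L)
})

test_that("absent .a2 loads documents in prediction mode (no gold spans)", {
  d <- withr::local_tempdir()
  writeLines("The growth was rapid", file.path(d, "x.txt"))
  docs <- read_standoff(d, schema2)
  expect_equal(nrow(docs[[1]]$t_ann), 0L)
  sent <- corpus_sentences(docs, schema2)
  expect_equal(nrow(sent), 1L)
  expect_equal(nrow(sent$gold_spans[[1]]), 0L)
})

test_that("write then read restores the document set field for field", {
  corp <- tiny_corpus(n = 15L, seed = 21L)
  d <- withr::local_tempdir()
  write_standoff(corp$docs, d)
  back <- read_standoff(d, corp$spec$schema)
  expect_equal(length(back), length(corp$docs))
  for (i in seq_along(back)) {
    expect_equal(back[[i]]$doc_id, corp$docs[[i]]$doc_id)
    expect_equal(back[[i]]$text, corp$docs[[i]]$text)
    expect_equal(as.data.frame(back[[i]]$t_ann),
                 as.data.frame(corp$docs[[i]]$t_ann))
    expect_equal(as.data.frame(back[[i]]$e_ann),
                 as.data.frame(corp$docs[[i]]$e_ann))
  }
})

test_that("empty corpus writes no files; empty doc still emits its .a2", {
  d <- withr::local_tempdir()
  write_standoff(list(), d)
  expect_length(list.files(d), 0L)
  write_standoff(list(standoff_document("solo", "nothing here")), d)
  expect_setequal(list.files(d), c("solo.txt", "solo.a1", "solo.a2"))
  expect_length(readLines(file.path(d, "solo.a2")), 0L)
})

test_that("colliding doc ids are rejected", {
  doc <- standoff_document("dup", "text")
  expect_error(write_standoff(list(doc, doc), withr::local_tempdir()),
               "colliding")
})

test_that("the worked sentence tokenizes into 8 tokens keeping the period", {
  doc <- make_demo_doc()
  sent <- corpus_sentences(list(doc), schema_ex)
  expect_equal(nrow(sent), 1L)
  toks <- sent$tokens[[1]]
  expect_equal(toks$surface,
               c("Angiogenesis", "is", "essential", "for", "growth", "and",
                 "tumor", "metastasis."))
  # extents reconstruct the text
  expect_equal(substring(doc$text, toks$start + 1L, toks$end), toks$surface)
  # gold spans align to tokens 3, 5, 8
  gs <- sort_spans(sent$gold_spans[[1]])
  expect_equal(gs$start, c(3L, 5L, 8L))
  expect_equal(gs$type, c("Positive_Regulation", "Growth", "Localization"))
})

test_that("gold span surfaces equal the concatenation of their tokens", {
  corp <- tiny_corpus(n = 30L, seed = 22L)
  sent <- corpus_sentences(corp$docs)
  for (i in seq_len(nrow(sent))) {
    gs <- sent$gold_spans[[i]]
    if (!nrow(gs)) next
    toks <- sent$tokens[[i]]
    for (r in seq_len(nrow(gs))) {
      surf <- paste(toks$surface[gs$start[r]:gs$end[r]], collapse = " ")
      expect_true(surf %in% corp$docs[[1]]$t_ann$surface ||
                    surf %in% unlist(lapply(corp$docs,
                                            function(d) d$t_ann$surface)))
    }
  }
})

test_that("a trigger crossing a token boundary is force-aligned and counted", {
  text <- "The overgrowth was rapid"
  doc <- standoff_document(
    "m", text,
    t_ann = tibble::tibble(id = "T1", type = "Growth", start = 8L, end = 14L,
                           surface = "growth", source = "a2"))
  sent <- corpus_sentences(list(doc), schema2)
  expect_equal(attr(sent, "n_forced_alignments"), 1L)
  gs <- sent$gold_spans[[1]]
  expect_equal(gs$start, 2L)   # the covering token "overgrowth"
  expect_equal(gs$end, 2L)
})

test_that("empty text yields zero sentences", {
  doc <- standoff_document("e", "")
  expect_equal(nrow(corpus_sentences(list(doc), schema2)), 0L)
})

test_that("triggers require an E reference when event lines exist", {
  text <- "growth binds growth"
  doc <- standoff_document(
    "g", text,
    t_ann = tibble::tibble(id = c("T1", "T2"), type = "Growth",
                           start = c(0L, 13L), end = c(6L, 19L),
                           surface = "growth", source = "a2"),
    e_ann = tibble::tibble(id = "E1", type = "Growth", trigger_id = "T1",
                           args = ""))
  tr <- doc_triggers(doc, schema2)
  expect_equal(tr$id, "T1")
  # without E lines, type membership decides
  doc2 <- doc; doc2$e_ann <- doc2$e_ann[0, ]
  expect_equal(doc_triggers(doc2, schema2)$id, c("T1", "T2"))
})

test_that("corpus statistics match the generator's planted counts", {
  corp <- tiny_corpus(n = 50L, seed = 23L)
  st <- corpus_stats(corp$docs)
  expect_equal(st$n_documents, length(corp$docs))
  expect_equal(st$n_sentences, nrow(corp$sentences))
  expect_equal(st$n_events, nrow(corp$log))
  expect_equal(st$n_events, sum(st$per_type$n))
  expect_equal(st$n_event_instances, nrow(corp$log))
  for (t in corp$spec$schema$types) {
    expect_equal(st$per_type$n[st$per_type$type == t],
                 sum(corp$log$type == t))
  }
  # empty corpus gives zeros
  st0 <- corpus_stats(structure(list(), class = "standoff_corpus"),
                      schema = schema2)
  expect_equal(st0$n_documents, 0L)
  expect_equal(st0$n_events, 0L)
})
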