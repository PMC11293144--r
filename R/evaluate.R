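#' Span-level trigger evaluation
#'
#' Scores predictions against gold with the strictest matching rule: a
#' predicted span counts as correct iff its token extent and its event type
#' both match a gold span exactly. Micro averaging pools true/false
#' positives and false negatives globally; macro averaging takes the
#' unweighted mean of per-type F1 over the types present in gold (types the
#' gold corpus never uses are excluded, so no 0/0 terms arise).
#'
#' @param gold,pred Lists of span tibbles (`start`, `end`, `type`), one per
#'   sentence, sentence-aligned (equal length).
#' @param averaging `"micro"` or `"macro"`.
#' @param schema Optional `event_schema` to order the per-type breakdown.
#' @return Object of class `eval_report`: `precision`, `recall`, `f1` (in
#'   percent), `tp`/`fp`/`fn`, `averaging`, `per_type` tibble.
#' @examples
#' gold <- list(tibble::tibble(start = c(1, 4), end = c(1, 4),
#'                             type = c("Growth", "Binding")))
#' pred <- list(tibble::tibble(start = 1, end = 1, type = "Growth"))
#' evaluate_triggers(gold, pred)$f1
#' @export
evaluate_triggers <- function(gold, pred, averaging = c("micro", "macro"),
                              schema = NULL) {
  averaging <- match.arg(averaging)
  if (length(gold) != length(pred)) {
    stop("gold and pred must be sentence-aligned (", length(gold),
         " vs ", length(pred), " sentences)")
  }
  key <- function(sp, i) {
    if (is.null(sp) || nrow(sp) == 0L) return(character(0))
    sprintf("%d|%d|%d|%s", i, sp$start, sp$end, sp$type)
  }
  g_keys <- unlist(lapply(seq_along(gold), function(i) key(gold[[i]], i)))
  p_keys <- unlist(lapply(seq_along(pred), function(i) key(pred[[i]], i)))
  g_types <- sub("^.*\\|", "", g_keys)
  p_types <- sub("^.*\\|", "", p_keys)
  hit <- p_keys %in% g_keys
  types <- if (!is.null(schema)) schema$types else sort(unique(c(g_types, p_types)))
  per_type <- dplyr::bind_rows(lapply(types, function(t) {
    tp <- sum(hit & p_types == t)
    fp <- sum(!hit & p_types == t)
    fn <- sum(!(g_keys %in% p_keys) & g_types == t)
    tibble::tibble(type = t, n_gold = sum(g_types == t), tp = tp, fp = fp,
                   fn = fn, precision = prf(tp, tp + fp),
                   recall = prf(tp, tp + fn),
                   f1 = f1_of(prf(tp, tp + fp), prf(tp, tp + fn)))
  }))
  tp <- sum(hit); fp <- sum(!hit); fn <- sum(!(g_keys %in% p_keys))
  if (averaging == "micro") {
    precision <- prf(tp, tp + fp); recall <- prf(tp, tp + fn)
    f1 <- f1_of(precision, recall)
  } else {
    present <- per_type[per_type$n_gold > 0L, , drop = FALSE]
    precision <- mean(present$precision); recall <- mean(present$recall)
    f1 <- mean(present$f1)
  }
  structure(list(precision = precision, recall = recall, f1 = f1,
                 tp = tp, fp = fp, fn = fn, averaging = averaging,
                 per_type = per_type),
            class = "eval_report")
}

prf <- function(num, den) if (den == 0L) 0 else 100 * num / den
f1_of <- function(p, r) if (p + r == 0) 0 else 2 * p * r / (p + r)

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("<eval_report> %s P %.2f%% R %.2f%% F1 %.2f%% (TP %d FP %d FN %d)\n",
              x$averaging, x$precision, x$recall, x$f1, x$tp, x$fp, x$fn))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @export
tidy.eval_report <- function(x, ...) x$per_type

#' @export
glance.eval_report <- function(x, ...) {
  tibble::tibble(averaging = x$averaging, precision = x$precision,
                 recall = x$recall, f1 = x$f1, tp = x$tp, fp = x$fp, fn = x$fn)
}
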