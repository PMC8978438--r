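# Analysis of the SLL additive-attention weights: per-sentence records for
# visualization (subword weights aggregated to words) and the corpus-level
# global weight table — Porter-stemmed mean attention weight of the words
# within a small window around the two entity tags, where trigger words
# concentrate.

#' Extract a per-word attention record
#'
#' Runs a trained attention-summarizer model on one instance and maps the
#' per-subword attention weights to whitespace words by the word-id
#' alignment (summing the pieces of a word, which preserves the
#' sum-to-one property). The classification token, separator and padding
#' carry no weight; entity placeholder tags do.
#'
#' @param model an `sll_model` fine-tuned with the attention summarizer.
#' @param instance one row of a tagged relation corpus.
#' @return list of class `attention_record`: `id`, `words`, `weights`
#'   (per word, summing to 1 over the represented words), `entity_pos`
#'   (word indices of the two placeholder tags).
#' @export
extract_record <- function(model, instance) {
  assert_that(inherits(model, "sll_model") &&
                model$config$summarizer == "attention",
              "model must use the attention summarizer")
  tk <- tokenize(instance$sentence, model$tokenizer, model$max_len)
  ids <- matrix(tk$ids, 1L)
  mask <- matrix(tk$mask, 1L)
  fwd <- encoder_forward(model$encoder, ids, mask)
  top <- fwd$acts[[model$encoder$config$L + 1L]]
  inc <- include_mask(tk$ids, tk$mask, model$tokenizer)
  att <- attention_summarize(top, inc, model$head$summ$K)
  words <- strsplit(trimws(instance$sentence), "[ \t]+")[[1]]
  weights <- numeric(length(words))
  for (pos in which(inc)) {
    w <- tk$word_ids[pos]
    if (!is.na(w)) weights[w] <- weights[w] + att$alpha[pos]
  }
  structure(list(id = instance$id, words = words, weights = weights,
                 entity_pos = which(words %in% model$tokenizer$tags)),
            class = "attention_record")
}

#' @rdname extract_record
#' @param corpus a tagged relation corpus data frame.
#' @return `extract_records()`: a list of `attention_record`s.
#' @export
extract_records <- function(model, corpus) {
  lapply(seq_len(nrow(corpus)), function(i) {
    extract_record(model, corpus[i, , drop = FALSE])
  })
}

# Candidate word indices: within `window` words on each side of each
# entity tag, tags themselves excluded.
entity_window_candidates <- function(n_words, entity_pos, window) {
  cand <- integer(0)
  for (e in entity_pos) {
    cand <- c(cand, max(1L, e - window):min(n_words, e + window))
  }
  setdiff(sort(unique(cand)), entity_pos)
}

#' Corpus-level global attention weights
#'
#' Pools per-sentence attention records into a stem-level table: candidate
#' words are those within `window` words on each side of each of the two
#' entity tags (the tags themselves excluded); each candidate is reduced
#' to its Porter stem and the table value is the arithmetic mean of the
#' attention weights over all occurrences of that stem.
#'
#' @param records list of `attention_record`s from one corpus.
#' @param window words on each side of each entity tag (>= 0; default 3).
#' @param stemmer a function mapping a character vector of words to stems
#'   (default [porter_stem()]).
#' @return data frame of class `global_weight_table` with columns `stem`,
#'   `mean_weight`, `count`, sorted by mean weight (descending, ties
#'   lexicographic).
#' @export
compute_global_weights <- function(records, window = 3L,
                                   stemmer = porter_stem) {
  assert_that(length(records) > 0L, "empty record set")
  assert_that(window >= 0L, "window must be non-negative")
  sums <- new.env(parent = emptyenv())
  counts <- new.env(parent = emptyenv())
  for (rec in records) {
    cand <- entity_window_candidates(length(rec$words), rec$entity_pos,
                                     window)
    if (!length(cand)) next
    stems <- stemmer(rec$words[cand])
    for (j in seq_along(cand)) {
      st <- stems[j]
      sums[[st]] <- (sums[[st]] %||% 0) + rec$weights[cand[j]]
      counts[[st]] <- (counts[[st]] %||% 0L) + 1L
    }
  }
  stems <- ls(sums)
  out <- data.frame(
    stem = stems,
    mean_weight = vapply(stems, function(s) sums[[s]] / counts[[s]],
                         numeric(1)),
    count = vapply(stems, function(s) counts[[s]], integer(1)),
    stringsAsFactors = FALSE, row.names = NULL)
  out <- out[order(-out$mean_weight, out$stem), ]
  rownames(out) <- NULL
  class(out) <- c("global_weight_table", "data.frame")
  out
}

#' Top-k stems by global attention weight
#'
#' @param table a `global_weight_table`.
#' @param k number of stems (>= 1). If `k` exceeds the table size, all
#'   stems are returned with a warning.
#' @return character vector of stems, sorted by mean weight descending,
#'   ties broken lexicographically.
#' @export
top_k_stems <- function(table, k = 10L) {
  assert_that(k >= 1L, "k must be at least 1")
  if (k > nrow(table)) {
    warning(sprintf("k = %d exceeds table size %d; returning all stems",
                    k, nrow(table)), call. = FALSE)
    k <- nrow(table)
  }
  table$stem[seq_len(k)]
}

#' Export attention analyses
#'
#' `write_record_tsv()` writes one per-sentence record as a two-column
#' TSV (word, weight). `write_global_weights()` writes the stem table as
#' TSV (stem, mean_weight, count). `render_attention_html()` writes a
#' self-contained HTML heat-text rendering of a set of records, the
#' darkness of each word's background encoding its attention weight.
#'
#' @param record an `attention_record`.
#' @param path destination file.
#' @export
write_record_tsv <- function(record, path) {
  utils::write.table(
    data.frame(word = record$words, weight = record$weights),
    path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_record_tsv
#' @param table a `global_weight_table`.
#' @export
write_global_weights <- function(table, path) {
  utils::write.table(as.data.frame(table), path, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_record_tsv
#' @param records list of `attention_record`s.
#' @export
render_attention_html <- function(records, path) {
  esc <- function(x) {
    x <- gsub("&", "&amp;", x, fixed = TRUE)
    x <- gsub("<", "&lt;", x, fixed = TRUE)
    gsub(">", "&gt;", x, fixed = TRUE)
  }
  body <- vapply(records, function(rec) {
    mx <- max(rec$weights, 1e-12)
    spans <- sprintf(
      '<span style="background: rgba(178, 24, 43, %.3f); padding: 1px 2px;">%s</span>',
      0.85 * rec$weights / mx, esc(rec$words))
    sprintf("<p><b>%s</b><br/>%s</p>", esc(rec$id),
            paste(spans, collapse = " "))
  }, character(1))
  writeLines(c("<!DOCTYPE html><html><head><meta charset='utf-8'>",
               "<title>attention weights</title></head>",
               "<body style='font-family: sans-serif; line-height: 1.8;'>",
               body, "</body></html>"), path)
  invisible(path)
}
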