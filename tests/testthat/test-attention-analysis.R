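test_that("the Porter stemmer collapses inflected relation words", {
  expect_identical(porter_stem(c("activate", "activates", "activation")),
                   rep("activ", 3))
  # reference behaviour on classic examples of the algorithm
  expect_identical(
    porter_stem(c("caresses", "ponies", "hopping", "relational",
                  "rational", "oscillator", "concomitantly", "inhibit")),
    c("caress", "poni", "hop", "relat", "ration", "oscil",
      "concomitantli", "inhibit"))
  expect_identical(porter_stem(c("phosphorylation", "stimulates")),
                   c("phosphoryl", "stimul"))
  # short words and non-alphabetic tokens pass through
  expect_identical(porter_stem(c("as", "@DRUG$", "Binding")),
                   c("as", "@drug$", "bind"))
})

# A deliberately untrained attention model over a fixed corpus: the head is
# initialised but never updated, which is all the record plumbing needs.
frozen_attention_model <- function(corpus, seed = 2L) {
  scheme <- synthetic_corpus_spec(1L)$scheme
  stack <- tiny_stack(corpus$sentence, seed = seed)
  cfg <- sll_config("attention", max_len = 24L, epochs = 0L)
  fine_tune(stack$encoder, stack$tokenizer, corpus, corpus, scheme, cfg,
            seed = seed)
}

test_that("per-word records normalise, aggregate subwords and repeat exactly", {
  corpus <- tiny_corpus(10, seed = 61)
  model <- frozen_attention_model(corpus)
  rec <- extract_record(model, corpus[1, ])
  expect_s3_class(rec, "attention_record")
  expect_identical(rec$words,
                   strsplit(corpus$sentence[1], " ", fixed = TRUE)[[1]])
  expect_lt(abs(sum(rec$weights) - 1), 1e-5)
  expect_length(rec$entity_pos, 2L)
  expect_identical(extract_record(model, corpus[1, ]), rec)

  single <- data.frame(id = "one", sentence = "interaction",
                       label = "negative", group = "g")
  rec1 <- extract_record(model, single)
  expect_equal(rec1$weights, 1, tolerance = 1e-10)

  lstm_model <- model
  lstm_model$config$summarizer <- "lstm"
  expect_error(extract_record(lstm_model, corpus[1, ]),
               "attention summarizer")
})

test_that("window extraction agrees with a brute-force sentence re-scan", {
  set.seed(71)
  for (i in 1:1000) {
    n <- sample(5:15, 1L)
    epos <- sort(sample(n, 2L))
    window <- sample(0:4, 1L)
    got <- sllre:::entity_window_candidates(n, epos, window)
    brute <- setdiff(
      which(vapply(seq_len(n), function(w) {
        any(abs(w - epos) <= window)
      }, logical(1))),
      epos)
    expect_identical(got, brute)
  }
})

test_that("global weights average by stem and rank deterministically", {
  recs <- list(
    structure(list(id = "r1",
                   words = c("@DRUG$", "activates", "@DRUG$", "today"),
                   weights = c(0.3, 0.2, 0.3, 0.2),
                   entity_pos = c(1L, 3L)),
              class = "attention_record"),
    structure(list(id = "r2",
                   words = c("x", "@DRUG$", "activation", "@DRUG$"),
                   weights = c(0.1, 0.2, 0.4, 0.3),
                   entity_pos = c(2L, 4L)),
              class = "attention_record"))
  tab <- compute_global_weights(recs, window = 3L)
  activ <- tab[tab$stem == "activ", ]
  expect_identical(activ$count, 2L)
  expect_equal(activ$mean_weight, 0.3, tolerance = 1e-12)
  expect_identical(top_k_stems(tab, 1L), "activ")
  expect_warning(all_stems <- top_k_stems(tab, 50L), "exceeds")
  expect_identical(sort(all_stems), sort(tab$stem))
  expect_error(compute_global_weights(list()), "empty record")

  # ties break lexicographically, stable across calls
  recs_tie <- list(structure(
    list(id = "t", words = c("@DRUG$", "beta", "alpha", "@DRUG$"),
         weights = c(0.3, 0.2, 0.2, 0.3), entity_pos = c(1L, 4L)),
    class = "attention_record"))
  tab_tie <- compute_global_weights(recs_tie)
  expect_identical(top_k_stems(tab_tie, 2L), c("alpha", "beta"))
})

test_that("a single-occurrence stem reports that word's exact weight", {
  rec <- structure(list(id = "s", words = c("@DRUG$", "inhibits", "@DRUG$"),
                        weights = c(0.5, 0.25, 0.25),
                        entity_pos = c(1L, 3L)),
                   class = "attention_record")
  tab <- compute_global_weights(list(rec))
  expect_equal(tab$mean_weight[tab$stem == "inhibit"], 0.25,
               tolerance = 1e-12)
})

test_that("record and table exports are written as documented", {
  corpus <- tiny_corpus(5, seed = 62)
  model <- frozen_attention_model(corpus)
  recs <- extract_records(model, corpus)
  tsv <- withr::local_tempfile(fileext = ".tsv")
  write_record_tsv(recs[[1]], tsv)
  back <- utils::read.delim(tsv)
  expect_identical(back$word, recs[[1]]$words)
  tab <- compute_global_weights(recs)
  write_global_weights(tab, tsv)
  expect_identical(nrow(utils::read.delim(tsv)), nrow(tab))
  html <- withr::local_tempfile(fileext = ".html")
  render_attention_html(recs, html)
  expect_true(any(grepl("rgba", readLines(html))))
})
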