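test_that("sub-domain manifests carry the published retrieval recipes", {
  ppi <- build_subdomain_manifest("PPI")
  expect_identical(ppi$mode, "query")
  expect_identical(ppi$query, "Protein OR Gene")
  ddi <- build_subdomain_manifest("DDI")
  expect_identical(ddi$query, "Drug")
  cp <- build_subdomain_manifest("ChemProt")
  expect_identical(cp$mode, "annotation")
  expect_setequal(cp$entity_types, c("protein/gene", "chemical"))
  expect_error(build_subdomain_manifest("XYZ"))

  path <- withr::local_tempfile(fileext = ".yaml")
  write_manifest(ddi, path)
  back <- read_manifest(path)
  expect_identical(back$query, ddi$query)
  expect_identical(back$mode, ddi$mode)
})

test_that("document files round-trip through the blank-line layout", {
  docs <- generate_document_corpus(7L, 4L, letters_vocab(), seed = 3L)
  path <- withr::local_tempfile(fileext = ".txt")
  write_documents(docs, path)
  expect_identical(read_documents(path), docs)
})

mlm_fixture <- function(piece_len = 4L, seed = 60L, n = 60L) {
  sentences <- random_sentences(n, seed = seed)
  tok <- toy_tokenizer(sentences, piece_len = piece_len)
  list(tok = tok,
       inputs = lapply(sentences, tokenize, tokenizer = tok, max_len = 32L))
}

test_that("subword masking selects round(rate x eligible) positions", {
  fx <- mlm_fixture()
  for (i in seq_along(fx$inputs)) {
    inp <- fx$inputs[[i]]
    ex <- make_mlm_examples(inp, fx$tok, rate = 0.15, mode = "subword",
                            seed = i)
    elig <- sum(inp$mask) - 2L  # [CLS] and [SEP] never selected
    expect_identical(length(ex$positions), as.integer(round(0.15 * elig)))
    expect_identical(ex$labels, inp$ids[ex$positions])
    # untouched outside the selected set
    expect_identical(ex$ids[-ex$positions], inp$ids[-ex$positions])
    expect_false(any(ex$positions %in%
                       c(1L, which(inp$ids == fx$tok$sep),
                         which(!inp$mask))))
  }
})

test_that("whole-word masking never partially selects a word", {
  fx <- mlm_fixture()
  for (i in seq_along(fx$inputs)) {
    inp <- fx$inputs[[i]]
    ex <- make_mlm_examples(inp, fx$tok, rate = 0.15, mode = "whole-word",
                            seed = i)
    sel_words <- unique(inp$word_ids[ex$positions])
    full_span <- which(inp$word_ids %in% sel_words)
    expect_identical(sort(ex$positions), sort(full_span))
    elig <- sum(inp$mask) - 2L
    expect_gte(length(ex$positions), round(0.15 * elig))
  }
})

test_that("a multi-piece word is selected in full once any piece is", {
  tok <- toy_tokenizer("abcdefghijkl xy", piece_len = 4L)
  inp <- tokenize("abcdefghijkl xy", tok, max_len = 8L)
  # rate small enough that one "position" is requested; the long word has 3
  # pieces, so whole-word mode must take all or none of them
  for (s in 1:20) {
    ex <- make_mlm_examples(inp, tok, rate = 0.25, mode = "whole-word",
                            seed = s)
    w <- unique(inp$word_ids[ex$positions])
    expect_identical(sort(ex$positions),
                     sort(which(inp$word_ids %in% w)))
  }
})

test_that("masking respects rate 0 and is deterministic given the seed", {
  fx <- mlm_fixture(n = 5L)
  inp <- fx$inputs[[1]]
  ex0 <- make_mlm_examples(inp, fx$tok, rate = 0, mode = "subword")
  expect_length(ex0$positions, 0L)
  expect_length(ex0$labels, 0L)
  expect_identical(ex0$ids, inp$ids)
  e1 <- make_mlm_examples(inp, fx$tok, rate = 0.3, mode = "whole-word",
                          seed = 4L)
  e2 <- make_mlm_examples(inp, fx$tok, rate = 0.3, mode = "whole-word",
                          seed = 4L)
  expect_identical(e1, e2)
})

test_that("subword and whole-word modes mask statistically equal fractions", {
  fx <- mlm_fixture(n = 500L, seed = 77L)
  frac <- function(mode) {
    sel <- 0L; elig <- 0L
    for (i in seq_along(fx$inputs)) {
      inp <- fx$inputs[[i]]
      ex <- make_mlm_examples(inp, fx$tok, rate = 0.15, mode = mode,
                              seed = i)
      sel <- sel + length(ex$positions)
      elig <- elig + sum(inp$mask) - 2L
    }
    c(sel = sel, elig = elig)
  }
  a <- frac("subword")
  b <- frac("whole-word")
  p <- 0.15
  se <- sqrt(p * (1 - p) / a[["elig"]])
  expect_lt(abs(a[["sel"]] / a[["elig"]] - b[["sel"]] / b[["elig"]]),
            3 * se + 0.01)
})

test_that("NSP pairs are labelled by true adjacency at the target rate", {
  docs <- generate_document_corpus(40L, 6L, letters_vocab(), seed = 19L)
  pairs <- make_nsp_pairs(docs, 400L, seed = 23L)
  expect_identical(pairs, make_nsp_pairs(docs, 400L, seed = 23L))
  expect_lt(abs(mean(pairs$is_next) - 0.5), 3 * sqrt(0.25 / 400))
  # definitional check: every is_next pair is consecutive in some document
  for (i in which(pairs$is_next)) {
    ok <- any(vapply(docs, function(d) {
      j <- which(d == pairs$a[i])
      length(j) > 0 && any(d[pmin(j + 1L, length(d))] == pairs$b[i])
    }, logical(1)))
    expect_true(ok)
  }
  for (i in which(!pairs$is_next)) {
    same_doc_consec <- any(vapply(docs, function(d) {
      j <- which(d == pairs$a[i])
      length(j) > 0 && any(d[pmin(j + 1L, length(d))] == pairs$b[i])
    }, logical(1)))
    expect_false(same_doc_consec)
  }

  one_doc <- list(c("s one", "s two"))
  forced <- make_nsp_pairs(one_doc, 3L, seed = 1L, positive_fraction = 1)
  expect_true(all(forced$is_next))
  expect_true(all(forced$a == "s one" & forced$b == "s two"))
  expect_error(make_nsp_pairs(one_doc, 2L), "two documents")
  expect_error(make_nsp_pairs(list("a", "b"), 2L, positive_fraction = 1),
               "two sentences")
})

test_that("pre-training reduces the masked-token loss and is reproducible", {
  docs <- generate_document_corpus(200L, 6L, letters_vocab(), seed = 11L)
  tok <- toy_tokenizer(unlist(docs), piece_len = 4L)
  enc <- build_tiny_encoder(encoder_config(
    L = 2L, H = 32L, heads = 4L, vocab = vocab_size(tok), max_len = 32L,
    seed = 5L))
  noop <- run_pretraining(enc, tok, docs, steps = 0L, seed = 7L)
  expect_identical(noop$encoder$params, enc$params)

  res <- run_pretraining(enc, tok, docs, steps = 300L, lr = 1e-3,
                         batch_size = 16L, seed = 7L)
  tr <- res$trace
  expect_identical(nrow(tr), 300L)
  expect_lt(mean(tr$mlm_loss[251:300]), mean(tr$mlm_loss[1:50]))

  res2 <- run_pretraining(enc, tok, docs, steps = 20L, seed = 7L)
  res3 <- run_pretraining(enc, tok, docs, steps = 20L, seed = 7L)
  expect_identical(res2$encoder$params, res3$encoder$params)
  expect_identical(res2$trace, res3$trace)

  small_tok <- toy_tokenizer("only these words")
  expect_error(run_pretraining(enc, small_tok, docs, steps = 1L),
               "vocabulary sizes differ")
})
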