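test_that("entity tagging reproduces the standard pre-processed strings", {
  sc_ddi <- task_scheme("DDI")
  raw <- "Cimetidine: Cimetidine increases Theophylline plasma levels."
  # spans: second "Cimetidine" (12..22) and "Theophylline" (33..45)
  co <- relation_corpus("d17", raw, "MECHANISM",
    mentions = data.frame(m1_start = 12L, m1_end = 22L, m1_type = "drug",
                          m2_start = 33L, m2_end = 45L, m2_type = "drug"))
  tagged <- tag_entities(co, sc_ddi)
  expect_identical(tagged$sentence,
                   "Cimetidine: @DRUG$ increases @DRUG$ plasma levels.")

  sc_ppi <- task_scheme("PPI")
  raw2 <- "Nuclear protein NC2 is a coactivator for the transcription factor Sp1."
  co2 <- relation_corpus("p1", raw2, "Positive",
    mentions = data.frame(m1_start = 16L, m1_end = 19L, m1_type = "protein",
                          m2_start = 66L, m2_end = 69L, m2_type = "protein"))
  expect_identical(
    tag_entities(co2, sc_ppi)$sentence,
    "Nuclear protein @PROTEIN$ is a coactivator for the transcription factor @PROTEIN$.")
})

test_that("tagging handles sentence-boundary mentions and rejects bad spans", {
  sc <- task_scheme("DDI")
  co <- relation_corpus("x", "Aspirin potentiates warfarin effects", "EFFECT",
    mentions = data.frame(m1_start = 0L, m1_end = 7L, m1_type = "drug",
                          m2_start = 20L, m2_end = 28L, m2_type = "drug"))
  out <- tag_entities(co, sc)
  expect_identical(out$sentence, "@DRUG$ potentiates @DRUG$ effects")
  expect_true(startsWith(out$sentence, "@DRUG$"))

  bad_overlap <- relation_corpus("y", "abcdef ghij", "EFFECT",
    mentions = data.frame(m1_start = 0L, m1_end = 6L, m1_type = "drug",
                          m2_start = 4L, m2_end = 9L, m2_type = "drug"))
  expect_error(tag_entities(bad_overlap, sc), "overlap")
  bad_range <- relation_corpus("z", "short", "EFFECT",
    mentions = data.frame(m1_start = 0L, m1_end = 3L, m1_type = "drug",
                          m2_start = 4L, m2_end = 9L, m2_type = "drug"))
  expect_error(tag_entities(bad_range, sc), "out-of-range")
})

test_that("tagging an already-tagged instance is rejected, never doubled", {
  sc <- task_scheme("DDI")
  co <- relation_corpus("q", "@DRUG$ affects @DRUG$ here", "EFFECT",
    mentions = data.frame(m1_start = 0L, m1_end = 6L, m1_type = "drug",
                          m2_start = 15L, m2_end = 21L, m2_type = "drug"))
  expect_error(tag_entities(co, sc), "already contains")
})

test_that("detagging recovers original text lengths outside spans", {
  sc <- task_scheme("ChemProt")
  set.seed(42)
  for (i in 1:200) {
    nw <- sample(6:12, 1)
    words <- replicate(nw, paste(sample(letters, sample(3:8, 1),
                                        replace = TRUE), collapse = ""))
    sent <- paste(words, collapse = " ")
    pos <- sort(sample(nw, 2))
    starts <- c(0L, cumsum(nchar(words) + 1L))[pos]
    ends <- starts + nchar(words[pos])
    types <- sample(c("protein", "chemical"), 2, replace = TRUE)
    co <- relation_corpus("r", sent, "CPR:3",
      mentions = data.frame(m1_start = starts[1], m1_end = ends[1],
                            m1_type = types[1], m2_start = starts[2],
                            m2_end = ends[2], m2_type = types[2]))
    tagged <- tag_entities(co, sc)$sentence
    # reverse substitution: tags back to original surface forms
    detag <- sub(sc$tags[[types[1]]], words[pos[1]], tagged, fixed = TRUE)
    detag <- sub(sc$tags[[types[2]]], words[pos[2]], detag, fixed = TRUE)
    expect_identical(detag, sent)
  }
})

test_that("corpus readers validate labels and tag counts with row ids", {
  sc <- tiny_scheme()
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("i1\tx @PROTEIN$ y @PROTEIN$ z\tA",
               "i2\tx @PROTEIN$ y @PROTEIN$ z\tBAD"), path)
  expect_error(read_corpus(path, sc), "BAD.*i2")
  writeLines(c("i1\tx @PROTEIN$ y z\tA"), path)
  expect_error(read_corpus(path, sc), "i1.*1 entity tags")
  writeLines(character(0), path)
  expect_identical(nrow(read_corpus(path, sc)), 0L)
})

test_that("write then load is the identity in both dialects", {
  corpus <- tiny_corpus(50, seed = 3)
  sc <- synthetic_corpus_spec(1L)$scheme
  tsv <- withr::local_tempfile(fileext = ".tsv")
  write_corpus(corpus, tsv, "tagged-tsv")
  back <- read_corpus(tsv, sc, "tagged-tsv")
  expect_identical(back$id, corpus$id)
  expect_identical(back$sentence, corpus$sentence)
  expect_identical(back$label, corpus$label)

  jl <- withr::local_tempfile(fileext = ".jsonl")
  write_corpus(corpus, jl, "span-jsonl")
  back2 <- read_corpus(jl, sc, "span-jsonl")
  expect_identical(back2, corpus)

  # span records round-trip with their mention columns
  sc_ddi <- task_scheme("DDI")
  spans <- relation_corpus(c("a", "b"),
    c("Aspirin blocks warfarin now", "Dose of drugA alters drugB fast"),
    c("EFFECT", "MECHANISM"), group = c("g1", "g1"),
    mentions = data.frame(m1_start = c(0L, 8L), m1_end = c(7L, 13L),
                          m1_type = "drug", m2_start = c(15L, 21L),
                          m2_end = c(23L, 26L), m2_type = "drug"))
  write_corpus(spans, jl, "span-jsonl")
  expect_identical(read_corpus(jl, sc_ddi, "span-jsonl"), spans)
})

test_that("loader/writer round-trip holds on 1,000 random instances", {
  corpus <- tiny_corpus(1000, seed = 17)
  jl <- withr::local_tempfile(fileext = ".jsonl")
  write_corpus(corpus, jl, "span-jsonl")
  expect_identical(read_corpus(jl, synthetic_corpus_spec(1L)$scheme,
                               "span-jsonl"),
                   corpus)
})

test_that("fold assignment partitions instances with balanced sizes", {
  corpus <- tiny_corpus(20, seed = 5)
  f <- make_folds(corpus, k = 10, seed = 1)
  expect_setequal(f$id, corpus$id)
  expect_true(all(table(f$fold) == 2L))

  # leave-one-out
  f1 <- make_folds(corpus, k = 20, seed = 1)
  expect_true(all(table(f1$fold) == 1L))

  # deterministic given seed
  expect_identical(make_folds(corpus, 10, seed = 9),
                   make_folds(corpus, 10, seed = 9))
  expect_error(make_folds(corpus, k = 21), "exceeds")
  expect_error(make_folds(corpus, k = 1), "at least 2")
})

test_that("group-level folds never split a group", {
  corpus <- tiny_corpus(30, seed = 7)  # groups of 5 -> 6 groups
  corpus$group <- sprintf("g%02d", rep(1:12, length.out = 30))
  f <- make_folds(corpus, k = 4, group_level = TRUE, seed = 7)
  by_group <- split(f$fold, corpus$group[match(f$id, corpus$id)])
  # exhaustive check: every group maps to a single fold
  expect_true(all(vapply(by_group, function(x) length(unique(x)) == 1L,
                         logical(1))))
  gf <- vapply(by_group, `[`, integer(1), 1L)
  expect_true(max(table(gf)) - min(table(gf)) <= 1L)
  expect_error(make_folds(corpus, k = 13, group_level = TRUE), "exceeds")
})
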