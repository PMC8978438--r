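# Corpus input/output: relation instances travel as plain data frames with
# columns id, sentence, label, group (all character), plus optional mention
# columns m1_start, m1_end, m1_type, m2_start, m2_end, m2_type for
# span-annotated (not yet entity-tagged) records. Character offsets are
# 0-based, half-open.

#' Construct a relation-instance corpus data frame
#'
#' @param id character instance identifiers (unique).
#' @param sentence sentence text, either entity-tagged (containing exactly
#'   two placeholder tags) or raw (with `mentions` supplied).
#' @param label relation labels, members of `scheme$labels`.
#' @param group document/source identifier used for group-level
#'   cross-validation folding; defaults to `id`.
#' @param mentions optional data frame with columns `m1_start`, `m1_end`,
#'   `m1_type`, `m2_start`, `m2_end`, `m2_type` (0-based half-open character
#'   offsets) for raw sentences.
#' @return a `data.frame` of relation instances.
#' @export
relation_corpus <- function(id, sentence, label, group = id, mentions = NULL) {
  df <- data.frame(id = as.character(id), sentence = as.character(sentence),
                   label = as.character(label), group = as.character(group),
                   stringsAsFactors = FALSE)
  assert_that(!anyDuplicated(df$id), "instance ids must be unique")
  if (!is.null(mentions)) {
    need <- c("m1_start", "m1_end", "m1_type", "m2_start", "m2_end", "m2_type")
    assert_that(all(need %in% names(mentions)),
                "mentions must have columns m1_start..m2_type")
    df <- cbind(df, mentions[, need])
  }
  df
}

validate_corpus <- function(corpus, scheme, tagged = TRUE) {
  bad <- which(!(corpus$label %in% scheme$labels))
  if (length(bad)) {
    stop_sllre(sprintf("unknown label '%s' at instance id '%s'",
                       corpus$label[bad[1]], corpus$id[bad[1]]))
  }
  if (tagged) {
    n_tags <- count_entity_tags(corpus$sentence, scheme)
    off <- which(n_tags != 2L)
    if (length(off)) {
      stop_sllre(sprintf(
        "sentence of instance id '%s' contains %d entity tags (expected 2)",
        corpus$id[off[1]], n_tags[off[1]]))
    }
  }
  invisible(corpus)
}

#' Read a relation-extraction corpus
#'
#' Two dialects are supported. `tagged-tsv` is the common biomedical-RE
#' release layout: UTF-8, no header, one instance per line as
#' `index<TAB>sentence<TAB>label`, with the sentence already entity-tagged.
#' `span-jsonl` holds one JSON object per line with fields `id`, `sentence`,
#' `label`, optional `group`, and optional `spans` (two `[start, end)`
#' 0-based character offset pairs) with parallel `types`.
#'
#' @param path file to read.
#' @param scheme a [label_scheme()]; labels are validated against it and a
#'   tagged sentence must contain exactly two placeholder tags.
#' @param dialect `"tagged-tsv"` or `"span-jsonl"`.
#' @return a relation corpus data frame (see [relation_corpus()]); loading a
#'   file written by [write_corpus()] reproduces the corpus field-by-field.
#' @export
read_corpus <- function(path, scheme, dialect = c("tagged-tsv", "span-jsonl")) {
  dialect <- match.arg(dialect)
  assert_that(file.exists(path), paste("no such file:", path))
  if (dialect == "tagged-tsv") {
    lines <- readLines(path, encoding = "UTF-8")
    lines <- lines[nzchar(lines)]
    if (!length(lines)) return(relation_corpus(character(), character(), character()))
    parts <- strsplit(lines, "\t", fixed = TRUE)
    ok <- lengths(parts) == 3L
    assert_that(all(ok), sprintf("malformed TSV row %d", which(!ok)[1]))
    m <- do.call(rbind, parts)
    corpus <- relation_corpus(m[, 1], m[, 2], m[, 3])
    validate_corpus(corpus, scheme, tagged = TRUE)
  } else {
    lines <- readLines(path, encoding = "UTF-8")
    lines <- lines[nzchar(lines)]
    if (!length(lines)) return(relation_corpus(character(), character(), character()))
    recs <- lapply(lines, jsonlite::fromJSON, simplifyVector = TRUE)
    has_spans <- vapply(recs, function(r) !is.null(r$spans), logical(1))
    assert_that(all(has_spans) || !any(has_spans),
                "span-jsonl file mixes tagged and span records")
    id <- vapply(recs, function(r) as.character(r$id), character(1))
    sentence <- vapply(recs, function(r) as.character(r$sentence), character(1))
    label <- vapply(recs, function(r) as.character(r$label), character(1))
    group <- vapply(recs, function(r) as.character(r$group %||% r$id), character(1))
    mentions <- NULL
    if (all(has_spans) && length(recs)) {
      sp <- lapply(recs, function(r) {
        s <- r$spans
        if (is.list(s)) s <- do.call(rbind, s)
        s
      })
      ty <- lapply(recs, function(r) as.character(r$types))
      mentions <- data.frame(
        m1_start = vapply(sp, function(s) as.integer(s[1, 1]), integer(1)),
        m1_end   = vapply(sp, function(s) as.integer(s[1, 2]), integer(1)),
        m1_type  = vapply(ty, `[`, character(1), 1L),
        m2_start = vapply(sp, function(s) as.integer(s[2, 1]), integer(1)),
        m2_end   = vapply(sp, function(s) as.integer(s[2, 2]), integer(1)),
        m2_type  = vapply(ty, `[`, character(1), 2L))
    }
    corpus <- relation_corpus(id, sentence, label, group, mentions)
    validate_corpus(corpus, scheme, tagged = is.null(mentions))
  }
}

#' Write a relation-extraction corpus
#'
#' @param corpus a relation corpus data frame.
#' @param path destination file.
#' @inheritParams read_corpus
#' @export
write_corpus <- function(corpus, path, dialect = c("tagged-tsv", "span-jsonl")) {
  dialect <- match.arg(dialect)
  if (dialect == "tagged-tsv") {
    lines <- paste(corpus$id, corpus$sentence, corpus$label, sep = "\t")
    writeLines(lines, path, useBytes = TRUE)
  } else {
    has_m <- "m1_start" %in% names(corpus)
    lines <- vapply(seq_len(nrow(corpus)), function(i) {
      rec <- list(id = corpus$id[i], sentence = corpus$sentence[i],
                  label = corpus$label[i], group = corpus$group[i])
      if (has_m) {
        rec$spans <- list(c(corpus$m1_start[i], corpus$m1_end[i]),
                          c(corpus$m2_start[i], corpus$m2_end[i]))
        rec$types <- c(corpus$m1_type[i], corpus$m2_type[i])
      }
      as.character(jsonlite::toJSON(rec, auto_unbox = TRUE))
    }, character(1))
    writeLines(lines, path, useBytes = TRUE)
  }
  invisible(path)
}

#' Replace entity mention spans with placeholder tags
#'
#' Each of the two mention spans of every instance is replaced by the tag of
#' its entity type (for example protein mentions become `@PROTEIN$`),
#' following the standard relation-extraction pre-processing. Text outside
#' the spans is preserved byte-for-byte; the two replacements are applied
#' right-to-left so earlier offsets stay valid. Instances whose sentence
#' already contains a placeholder tag are rejected rather than double-tagged.
#'
#' @param corpus a relation corpus with mention columns (see
#'   [relation_corpus()]).
#' @param scheme a [label_scheme()] supplying the type-to-tag mapping.
#' @return the corpus with tagged sentences and mention columns dropped.
#' @examples
#' sc <- task_scheme("PPI")
#' co <- relation_corpus(
#'   "x1", "Nuclear protein NC2 binds Sp1.", "Positive",
#'   mentions = data.frame(m1_start = 16, m1_end = 19, m1_type = "protein",
#'                         m2_start = 26, m2_end = 29, m2_type = "protein"))
#' tag_entities(co, sc)$sentence
#' @export
tag_entities <- function(corpus, scheme) {
  assert_that("m1_start" %in% names(corpus),
              "corpus has no mention columns; is it already tagged?")
  pre_tagged <- count_entity_tags(corpus$sentence, scheme) > 0L
  if (any(pre_tagged)) {
    stop_sllre(sprintf("instance id '%s' already contains an entity tag",
                       corpus$id[which(pre_tagged)[1]]))
  }
  out <- corpus
  for (i in seq_len(nrow(corpus))) {
    s <- corpus$sentence[i]
    n <- nchar(s)
    sp <- data.frame(start = c(corpus$m1_start[i], corpus$m2_start[i]),
                     end = c(corpus$m1_end[i], corpus$m2_end[i]),
                     type = c(corpus$m1_type[i], corpus$m2_type[i]))
    ok <- all(sp$start >= 0L) && all(sp$start < sp$end) && all(sp$end <= n)
    if (!ok) stop_sllre(sprintf("out-of-range span in instance id '%s'",
                                corpus$id[i]))
    o <- order(sp$start)
    if (sp$end[o[1]] > sp$start[o[2]]) {
      stop_sllre(sprintf("overlapping spans in instance id '%s'", corpus$id[i]))
    }
    if (!all(sp$type %in% names(scheme$tags))) {
      stop_sllre(sprintf("unknown entity type in instance id '%s'", corpus$id[i]))
    }
    # right-to-left replacement keeps the first span's offsets valid
    for (j in order(sp$start, decreasing = TRUE)) {
      tag <- scheme$tags[[sp$type[j]]]
      left <- if (sp$start[j] > 0L) substr(s, 1L, sp$start[j]) else ""
      right <- if (sp$end[j] < nchar(s)) {
        substr(s, sp$end[j] + 1L, nchar(s))
      } else ""
      s <- paste0(left, tag, right)
    }
    out$sentence[i] <- s
  }
  out[c("id", "sentence", "label", "group")]
}

#' Assign cross-validation folds
#'
#' Produces a k-fold assignment over instances, either at instance level
#' (fold sizes differ by at most one) or at group (document) level, where
#' all instances sharing a `group` land in the same fold and per-fold group
#' counts differ by at most one. Group-level folding avoids same-document
#' leakage between training and test folds. The assignment is deterministic
#' given the seed.
#'
#' @param corpus a relation corpus data frame.
#' @param k number of folds (>= 2).
#' @param group_level if `TRUE`, fold whole groups.
#' @param seed integer RNG seed.
#' @return a data frame (`id`, `fold`) with fold indices in `0..k-1` and
#'   attributes `k`, `seed`, `group_level`; class `fold_assignment`.
#' @export
make_folds <- function(corpus, k, group_level = FALSE, seed = 1L) {
  assert_that(k >= 2L, "k must be at least 2")
  n <- nrow(corpus)
  if (group_level) {
    groups <- unique(corpus$group)
    assert_that(length(groups) >= k,
                "k exceeds the number of distinct groups")
    perm <- local_seed(seed, sample.int(length(groups)))
    gfold <- integer(length(groups))
    gfold[perm] <- rep_len(0:(k - 1L), length(groups))
    fold <- gfold[match(corpus$group, groups)]
  } else {
    assert_that(n >= k, "k exceeds the number of instances")
    perm <- local_seed(seed, sample.int(n))
    fold <- integer(n)
    fold[perm] <- rep_len(0:(k - 1L), n)
  }
  structure(data.frame(id = corpus$id, fold = fold, stringsAsFactors = FALSE),
            k = k, seed = seed, group_level = group_level,
            class = c("fold_assignment", "data.frame"))
}

#' @rdname make_folds
#' @param folds a `fold_assignment`.
#' @param path destination TSV (two columns: id, fold; no header).
#' @export
write_folds <- function(folds, path) {
  writeLines(paste(folds$id, folds$fold, sep = "\t"), path, useBytes = TRUE)
  invisible(path)
}
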