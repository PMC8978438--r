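# Sub-domain adaptation support: query manifests describing how the
# task-related PubMed sub-corpora are retrieved, masked-language-model and
# next-sentence-prediction example builders, and a desk-scale continued
# pre-training loop over the tiny encoder.

#' Build a sub-domain retrieval manifest
#'
#' Sub-domain adaptation inserts one more pre-training stage on
#' task-related abstracts between biomedical domain adaptation and
#' fine-tuning. The manifest records how the sub-corpus is defined: the
#' PPI task uses the PubMed query "Protein OR Gene" (about 7.7 million
#' abstracts at full scale), DDI the query "Drug" (about 5.7 million), and
#' ChemProt a PubTator-style annotation filter keeping abstracts that
#' contain both protein/gene and chemical entities (about 3.4 million).
#' Retrieval itself is out of scope: manifests are executed by pointing
#' [read_documents()] at pre-downloaded abstract files.
#'
#' @param task one of `"PPI"`, `"DDI"`, `"ChemProt"`.
#' @return an object of class `subdomain_manifest` with fields `task`,
#'   `mode` (`"query"` or `"annotation"`), `query` or `entity_types`, and
#'   `scale_note`.
#' @export
build_subdomain_manifest <- function(task = c("PPI", "DDI", "ChemProt")) {
  task <- match.arg(task)
  m <- switch(task,
    PPI = list(task = "PPI", mode = "query", query = "Protein OR Gene",
               scale_note = "about 7.7M PubMed abstracts at full scale"),
    DDI = list(task = "DDI", mode = "query", query = "Drug",
               scale_note = "about 5.7M PubMed abstracts at full scale"),
    ChemProt = list(task = "ChemProt", mode = "annotation",
                    entity_types = c("protein/gene", "chemical"),
                    scale_note = "about 3.4M PubMed abstracts at full scale"))
  structure(m, class = "subdomain_manifest")
}

#' @rdname build_subdomain_manifest
#' @param manifest a `subdomain_manifest`.
#' @param path destination / source YAML file.
#' @export
write_manifest <- function(manifest, path) {
  yaml::write_yaml(unclass(manifest), path)
  invisible(path)
}

#' @rdname build_subdomain_manifest
#' @export
read_manifest <- function(path) {
  m <- yaml::read_yaml(path)
  assert_that(m$mode %in% c("query", "annotation"), "unknown manifest mode")
  if (m$mode == "query") {
    assert_that(nzchar(m$query %||% ""), "query manifest needs a query")
  } else {
    assert_that(length(m$entity_types) >= 1L,
                "annotation manifest needs entity types")
  }
  structure(m, class = "subdomain_manifest")
}

#' Read / write document collections
#'
#' Plain-text layout: one sentence per line, a blank line between
#' documents.
#'
#' @param path file path.
#' @return `read_documents()`: a list of character sentence vectors.
#' @export
read_documents <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  docs <- list()
  cur <- character()
  for (ln in lines) {
    if (!nzchar(trimws(ln))) {
      if (length(cur)) docs[[length(docs) + 1L]] <- cur
      cur <- character()
    } else {
      cur <- c(cur, ln)
    }
  }
  if (length(cur)) docs[[length(docs) + 1L]] <- cur
  docs
}

#' @rdname read_documents
#' @param documents list of character sentence vectors.
#' @export
write_documents <- function(documents, path) {
  out <- unlist(lapply(documents, function(d) c(d, "")))
  writeLines(out[-length(out)], path, useBytes = TRUE)
  invisible(path)
}

# Positions eligible for masking: real tokens that are not [CLS]/[SEP]/[PAD].
mlm_eligible <- function(ids, mask, tokenizer) {
  which(mask & !(ids %in% c(tokenizer$cls, tokenizer$sep, tokenizer$pad)))
}

# Core MLM corruption, consuming the caller's RNG stream.
mlm_corrupt <- function(ids, word_ids, mask, rate, mode, tokenizer) {
  elig <- mlm_eligible(ids, mask, tokenizer)
  target <- round(rate * length(elig))
  if (target == 0L || length(elig) == 0L) {
    return(list(ids = ids, labels = integer(0), positions = integer(0)))
  }
  if (mode == "subword") {
    sel <- sort(elig[sample.int(length(elig), target)])
  } else {
    assert_that(!all(is.na(word_ids[elig])),
                "whole-word mode requires word ids")
    wids <- unique(word_ids[elig])
    worder <- sample(wids)
    spans <- lapply(worder, function(wd) {
      elig[!is.na(word_ids[elig]) & word_ids[elig] == wd]
    })
    # take whole words until the target count is covered, preferring words
    # whose piece span fits the remaining budget so the realised fraction
    # tracks the subword rate closely
    sel <- integer(0)
    taken <- logical(length(worder))
    while (length(sel) < target && !all(taken)) {
      remaining <- target - length(sel)
      open <- which(!taken)
      fits <- open[lengths(spans[open]) <= remaining]
      pick <- if (length(fits)) {
        fits[1L]
      } else {
        open[which.min(lengths(spans[open]))]
      }
      sel <- c(sel, spans[[pick]])
      taken[pick] <- TRUE
    }
    sel <- sort(sel)
  }
  labels <- ids[sel]
  pool <- non_special_ids(tokenizer)
  u <- stats::runif(length(sel))
  new_ids <- ids
  new_ids[sel[u < 0.8]] <- tokenizer$mask
  rand_sel <- sel[u >= 0.8 & u < 0.9]
  if (length(rand_sel)) {
    new_ids[rand_sel] <- pool[sample.int(length(pool), length(rand_sel),
                                         replace = TRUE)]
  }
  list(ids = new_ids, labels = labels, positions = sel)
}

#' Build a masked-language-model example
#'
#' Corrupts a tokenized input for MLM training. `subword` mode selects
#' `round(rate x eligible)` positions independently of word boundaries;
#' `whole-word` mode selects complete words (every subword piece of a
#' chosen word) until at least the same count is covered, so no word is
#' ever partially masked. Of the selected positions, 80% are replaced by
#' `[MASK]`, 10% by a random non-special token and 10% left unchanged; all
#' carry labels. `[CLS]`, `[SEP]` and padding are never selected.
#'
#' @param input a [tokenize()] / `tokenize_pair` result (needs `ids`,
#'   `word_ids`, `mask`).
#' @param tokenizer the [toy_tokenizer()] that produced it.
#' @param rate masking rate in `[0, 1]` (0.15 is the usual convention).
#' @param mode `"subword"` or `"whole-word"`.
#' @param seed RNG seed.
#' @return list of class `mlm_example`: corrupted `ids`, `labels`
#'   (original ids at selected positions), `positions`, `mode`, `rate`.
#' @export
make_mlm_examples <- function(input, tokenizer, rate = 0.15,
                              mode = c("subword", "whole-word"), seed = 1L) {
  mode <- match.arg(mode)
  assert_that(rate >= 0 && rate <= 1, "rate must be in [0, 1]")
  out <- local_seed(seed, mlm_corrupt(input$ids, input$word_ids, input$mask,
                                      rate, mode, tokenizer))
  structure(c(out, list(mode = mode, rate = rate)), class = "mlm_example")
}

# Core NSP pair draw, consuming the caller's RNG stream.
nsp_draw <- function(documents, n_pairs, positive_fraction) {
  multi <- which(lengths(documents) >= 2L)
  a <- character(n_pairs); b <- character(n_pairs)
  is_next <- logical(n_pairs)
  for (i in seq_len(n_pairs)) {
    pos <- stats::runif(1) < positive_fraction
    if (pos) {
      d <- if (length(multi) == 1L) multi else sample(multi, 1L)
      s <- sample.int(length(documents[[d]]) - 1L, 1L)
      a[i] <- documents[[d]][s]
      b[i] <- documents[[d]][s + 1L]
      is_next[i] <- TRUE
    } else {
      d1 <- sample.int(length(documents), 1L)
      d2 <- sample(setdiff(seq_along(documents), d1), 1L)
      a[i] <- sample(documents[[d1]], 1L)
      b[i] <- sample(documents[[d2]], 1L)
      is_next[i] <- FALSE
    }
  }
  data.frame(a = a, b = b, is_next = is_next, stringsAsFactors = FALSE)
}

#' Build next-sentence-prediction pairs
#'
#' Draws sentence pairs for the NSP objective: with probability
#' `positive_fraction` a consecutive pair from one document
#' (`is_next = TRUE`), otherwise the second sentence comes from a
#' different document.
#'
#' @param documents list of character sentence vectors.
#' @param n_pairs number of pairs.
#' @param seed RNG seed.
#' @param positive_fraction target fraction of consecutive pairs (set to 1
#'   for positives only, which requires just one document with two
#'   sentences).
#' @return data frame with columns `a`, `b`, `is_next`; deterministic
#'   given `seed`.
#' @export
make_nsp_pairs <- function(documents, n_pairs, seed = 1L,
                           positive_fraction = 0.5) {
  if (positive_fraction < 1) {
    assert_that(length(documents) >= 2L,
                "negatives need at least two documents")
  }
  if (positive_fraction > 0) {
    assert_that(any(lengths(documents) >= 2L),
                "positives need a document with at least two sentences")
  }
  local_seed(seed, nsp_draw(documents, n_pairs, positive_fraction))
}

init_pretrain_head <- function(H, V, seed) {
  local_seed(seed + 1L, list(
    mlm_W = init_mat(H, V), mlm_b = rep(0, V),
    nsp_W = init_mat(H, 2L), nsp_b = rep(0, 2L)))
}

#' Desk-scale continued pre-training
#'
#' Runs `steps` optimiser steps of masked-language-model (and optionally
#' next-sentence-prediction) training on a document collection, updating
#' the encoder end-to-end. This is the desk-scale analogue of the
#' sub-domain adaptation stage; the full-scale recipe (100K steps,
#' sequence length 128, learning rate 2e-5, batch 192) is the
#' `pretrain` block of the configuration presets.
#'
#' @param encoder a [build_tiny_encoder()] result.
#' @param tokenizer the matching [toy_tokenizer()]; its vocabulary size
#'   must equal the encoder's.
#' @param documents list of character sentence vectors.
#' @param steps optimiser steps (0 returns the encoder unchanged).
#' @param lr Adam learning rate.
#' @param batch_size sequences per step.
#' @param seed RNG seed; the run is deterministic given it.
#' @param mlm_rate masking rate.
#' @param mlm_mode `"subword"` (original-BERT convention, used for
#'   BioBERT-style runs) or `"whole-word"` (PubMedBERT-style).
#' @param use_nsp include the NSP objective and pair inputs (switchable
#'   because the whole-word recipe need not use NSP).
#' @param max_len sequence length.
#' @return list with the updated `encoder`, the pre-training `head`
#'   parameters and `trace`, a data frame (step, mlm_loss, nsp_loss).
#' @export
run_pretraining <- function(encoder, tokenizer, documents, steps,
                            lr = 1e-3, batch_size = 16L, seed = 1L,
                            mlm_rate = 0.15,
                            mlm_mode = c("subword", "whole-word"),
                            use_nsp = TRUE, max_len = 32L) {
  mlm_mode <- match.arg(mlm_mode)
  assert_that(vocab_size(tokenizer) == encoder$config$vocab,
              "tokenizer and encoder vocabulary sizes differ")
  head <- init_pretrain_head(encoder$config$H, encoder$config$vocab, seed)
  trace <- data.frame(step = integer(0), mlm_loss = numeric(0),
                      nsp_loss = numeric(0))
  if (steps == 0L) {
    return(list(encoder = encoder, head = head, trace = trace))
  }
  all_sent <- unlist(documents)
  params <- list(enc = encoder$params, head = head)
  opt <- adam_init(params)
  T <- max_len
  trace <- local_seed(seed, {
    rows <- vector("list", steps)
    for (step in seq_len(steps)) {
      if (use_nsp) {
        pairs <- nsp_draw(documents, batch_size, 0.5)
        toks <- Map(function(a, b) tokenize_pair(a, b, tokenizer, max_len),
                    pairs$a, pairs$b)
        nsp_target <- ifelse(pairs$is_next, 1L, 2L)
        segments <- do.call(rbind, lapply(toks, `[[`, "segments"))
      } else {
        sent <- all_sent[sample.int(length(all_sent), batch_size,
                                    replace = TRUE)]
        toks <- lapply(sent, tokenize, tokenizer = tokenizer,
                       max_len = max_len)
        segments <- NULL
      }
      ids <- do.call(rbind, lapply(toks, `[[`, "ids"))
      mask <- do.call(rbind, lapply(toks, `[[`, "mask"))
      ex <- lapply(toks, function(tk) {
        mlm_corrupt(tk$ids, tk$word_ids, tk$mask, mlm_rate, mlm_mode,
                    tokenizer)
      })
      corrupted <- do.call(rbind, lapply(ex, `[[`, "ids"))
      enc_obj <- encoder
      enc_obj$params <- params$enc
      fwd <- encoder_forward(enc_obj, corrupted, mask, segments)
      top <- fwd$acts[[encoder$config$L + 1L]]
      B <- nrow(ids)
      dtop <- matrix(0, B * T, encoder$config$H)
      gh <- params_zero(params$head)
      # masked-token prediction loss at the selected positions
      sel_rows <- unlist(lapply(seq_len(B), function(b) {
        (b - 1L) * T + ex[[b]]$positions
      }))
      mlm_loss <- NA_real_
      if (length(sel_rows)) {
        targets <- unlist(lapply(ex, `[[`, "labels"))
        X <- top[sel_rows, , drop = FALSE]
        logits <- sweep(X %*% params$head$mlm_W, 2L, params$head$mlm_b, `+`)
        ce <- softmax_xent(logits, targets)
        mlm_loss <- ce$loss
        gh$mlm_W <- t(X) %*% ce$dlogits
        gh$mlm_b <- colSums(ce$dlogits)
        dX <- ce$dlogits %*% t(params$head$mlm_W)
        dtop[sel_rows, ] <- dtop[sel_rows, ] + dX
      }
      nsp_loss <- NA_real_
      if (use_nsp) {
        cls_rows <- (seq_len(B) - 1L) * T + 1L
        Xc <- top[cls_rows, , drop = FALSE]
        logits2 <- sweep(Xc %*% params$head$nsp_W, 2L, params$head$nsp_b, `+`)
        ce2 <- softmax_xent(logits2, nsp_target)
        nsp_loss <- ce2$loss
        gh$nsp_W <- t(Xc) %*% ce2$dlogits
        gh$nsp_b <- colSums(ce2$dlogits)
        dtop[cls_rows, ] <- dtop[cls_rows, ] +
          ce2$dlogits %*% t(params$head$nsp_W)
      }
      genc <- encoder_backward(enc_obj, fwd, dtop)
      stepped <- adam_step(params, list(enc = genc, head = gh), opt, lr)
      params <- stepped$params
      opt <- stepped$state
      rows[[step]] <- data.frame(step = step, mlm_loss = mlm_loss,
                                 nsp_loss = nsp_loss)
    }
    do.call(rbind, rows)
  })
  encoder$params <- params$enc
  list(encoder = encoder, head = params$head, trace = trace)
}

#' @rdname run_pretraining
#' @param trace a loss trace as returned in `$trace`.
#' @param path destination CSV (step, mlm_loss, nsp_loss).
#' @export
write_loss_trace <- function(trace, path) {
  utils::write.csv(trace, path, row.names = FALSE)
  invisible(path)
}
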