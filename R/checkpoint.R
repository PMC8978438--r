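# Model checkpoints. Directory layout:
#   model.yaml         encoder + head configuration, scheme, max_len
#   vocab.txt          one vocabulary token per line
#   encoder-params.rds encoder parameter list
#   head-params.rds    SLL head parameter list
# The same encode() contract accepted from the tiny encoder is expected of
# any externally supplied encoder object (the checkpoint adapter): it must
# return all L+1 layers with a correct padding mask, which the shape/mask
# test suite verifies for every encoder plugged in.

#' Save / load an SLL model checkpoint
#'
#' @param model an `sll_model`.
#' @param dir checkpoint directory (created if needed).
#' @export
save_sll_model <- function(model, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  cfg <- model$encoder$config
  yaml::write_yaml(
    list(encoder = list(L = cfg$L, H = cfg$H, heads = cfg$heads,
                        vocab = cfg$vocab, max_len = cfg$max_len,
                        seed = cfg$seed, ffn = cfg$ffn),
         sll = unclass(model$config),
         scheme = list(task = model$scheme$task,
                       positive = model$scheme$positive,
                       negative = model$scheme$negative,
                       tags = as.list(model$scheme$tags)),
         max_len = model$max_len,
         piece_len = model$tokenizer$piece_len),
    file.path(dir, "model.yaml"))
  writeLines(model$tokenizer$vocab, file.path(dir, "vocab.txt"),
             useBytes = TRUE)
  saveRDS(model$encoder$params, file.path(dir, "encoder-params.rds"))
  saveRDS(model$head, file.path(dir, "head-params.rds"))
  invisible(dir)
}

#' @rdname save_sll_model
#' @export
load_sll_model <- function(dir) {
  meta <- yaml::read_yaml(file.path(dir, "model.yaml"))
  vocab <- readLines(file.path(dir, "vocab.txt"), encoding = "UTF-8")
  tags <- unlist(meta$scheme$tags)
  tokenizer <- structure(
    list(vocab = vocab, ids = stats::setNames(seq_along(vocab), vocab),
         pad = 1L, unk = 2L, cls = 3L, sep = 4L, mask = 5L,
         piece_len = meta$piece_len, tags = unname(tags)),
    class = "toy_tokenizer")
  ec <- meta$encoder
  enc <- structure(
    list(config = encoder_config(ec$L, ec$H, ec$heads, ec$vocab,
                                 ec$max_len, ec$seed, ec$ffn),
         params = readRDS(file.path(dir, "encoder-params.rds"))),
    class = "tiny_encoder")
  sc <- meta$sll
  config <- sll_config(sc$summarizer, sc$use_cls, sc$rnn_hidden,
                       sc$max_len, sc$epochs, sc$lr, sc$batch)
  scheme <- label_scheme(unlist(meta$scheme$positive),
                         meta$scheme$negative, meta$scheme$task, tags)
  structure(list(encoder = enc,
                 head = readRDS(file.path(dir, "head-params.rds")),
                 config = config, scheme = scheme, tokenizer = tokenizer,
                 max_len = meta$max_len,
                 metrics = data.frame()),
            class = "sll_model")
}
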