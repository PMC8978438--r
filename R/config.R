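# Run configuration. Two full-scale hyperparameter presets mirror the two
# published recipes (BioBERT-style and PubMedBERT-style); the `tiny` preset
# is the desk-scale configuration used throughout the tests and examples.

config_presets <- function() {
  list(
    "biobert-style" = list(
      encoder = list(L = 12L, H = 768L, heads = 12L, max_len = 128L),
      finetune = list(max_len = 128L, epochs = 10L, lr = 2e-5, batch = 32L),
      probe = list(hidden = 1024L, lr = 2e-5, epochs = 4L),
      pretrain = list(steps = 100000L, lr = 2e-5, batch = 192L,
                      max_len = 128L, mlm_mode = "subword", use_nsp = TRUE),
      rnn_hidden = 768L),
    "pubmedbert-style" = list(
      encoder = list(L = 12L, H = 768L, heads = 12L, max_len = 256L),
      finetune = list(max_len = 256L, epochs = 10L, lr = 2e-5, batch = 16L),
      probe = list(hidden = 1024L, lr = 2e-5, epochs = 4L),
      pretrain = list(steps = 100000L, lr = 2e-5, batch = 192L,
                      max_len = 128L, mlm_mode = "whole-word",
                      use_nsp = TRUE),
      rnn_hidden = 768L),
    tiny = list(
      encoder = list(L = 2L, H = 32L, heads = 4L, max_len = 24L),
      finetune = list(max_len = 24L, epochs = 5L, lr = 1e-3, batch = 32L),
      probe = list(hidden = 64L, lr = 5e-3, epochs = 30L),
      pretrain = list(steps = 300L, lr = 1e-3, batch = 16L, max_len = 32L,
                      mlm_mode = "subword", use_nsp = TRUE),
      rnn_hidden = NULL))
}

config_allowed_keys <- function() {
  list(top = c("task", "preset", "summarizer", "use_cls", "encoder",
               "finetune", "probe", "pretrain", "analysis", "seed",
               "output_dir", "checkpoint"),
       encoder = c("L", "H", "heads", "max_len", "vocab"),
       finetune = c("max_len", "epochs", "lr", "batch"),
       probe = c("hidden", "lr", "epochs", "batch", "heldout"),
       pretrain = c("steps", "lr", "batch", "max_len", "mlm_mode",
                    "use_nsp"),
       analysis = c("window", "k"))
}

#' Load and validate a run configuration
#'
#' Reads a YAML configuration. Unset fields take the preset's defaults
#' (`"biobert-style"` unless `preset` says otherwise): BioBERT-style
#' fine-tuning uses sequence length 128, 10 epochs, learning rate 2e-5,
#' batch 32; the PubMedBERT-style preset sequence length 256 and batch 16;
#' probes use a 1024-unit hidden layer, learning rate 2e-5, 4 epochs;
#' pre-training learning rate 2e-5, batch 192, sequence length 128. A
#' `task` is required. Unknown keys and invalid values are rejected with
#' the offending field path.
#'
#' @param path a YAML file, or a list already parsed.
#' @return object of class `run_config`.
#' @export
load_config <- function(path) {
  raw <- if (is.character(path)) yaml::read_yaml(path) else path
  assert_that(is.list(raw), "config must parse to a mapping")
  allowed <- config_allowed_keys()
  unknown <- setdiff(names(raw), allowed$top)
  assert_that(length(unknown) == 0L,
              paste("unknown config key:", unknown[1]))
  for (blk in c("encoder", "finetune", "probe", "pretrain", "analysis")) {
    if (!is.null(raw[[blk]])) {
      unknown <- setdiff(names(raw[[blk]]), allowed[[blk]])
      assert_that(length(unknown) == 0L,
                  sprintf("unknown config key: %s.%s", blk, unknown[1]))
    }
  }
  assert_that(!is.null(raw$task), "config is missing the required field: task")
  preset_name <- raw$preset %||% "biobert-style"
  assert_that(preset_name %in% names(config_presets()),
              paste("unknown preset:", preset_name))
  preset <- config_presets()[[preset_name]]
  merge_block <- function(name) {
    utils::modifyList(preset[[name]], raw[[name]] %||% list())
  }
  cfg <- list(
    task = raw$task,
    preset = preset_name,
    summarizer = raw$summarizer %||% "attention",
    use_cls = raw$use_cls %||% TRUE,
    encoder = merge_block("encoder"),
    finetune = merge_block("finetune"),
    probe = merge_block("probe"),
    pretrain = merge_block("pretrain"),
    analysis = utils::modifyList(list(window = 3L, k = 10L),
                                 raw$analysis %||% list()),
    seed = raw$seed %||% 1L,
    output_dir = raw$output_dir %||% ".",
    checkpoint = raw$checkpoint)
  check_num <- function(x, field, positive = TRUE) {
    ok <- is.numeric(x) && length(x) == 1L && is.finite(x) &&
      (!positive || x > 0)
    assert_that(ok, paste("invalid value for config field:", field))
  }
  check_num(cfg$finetune$batch, "finetune.batch")
  check_num(cfg$finetune$epochs, "finetune.epochs", positive = FALSE)
  assert_that(cfg$finetune$epochs >= 0,
              "invalid value for config field: finetune.epochs")
  check_num(cfg$finetune$lr, "finetune.lr")
  check_num(cfg$finetune$max_len, "finetune.max_len")
  check_num(cfg$probe$hidden, "probe.hidden")
  check_num(cfg$pretrain$batch, "pretrain.batch")
  assert_that(cfg$summarizer %in% c("attention", "lstm", "bilstm", "none"),
              "invalid value for config field: summarizer")
  assert_that(cfg$pretrain$mlm_mode %in% c("subword", "whole-word"),
              "invalid value for config field: pretrain.mlm_mode")
  if (!is.null(cfg$checkpoint)) {
    assert_that(dir.exists(cfg$checkpoint),
                paste("checkpoint path does not exist:", cfg$checkpoint))
  }
  structure(cfg, class = "run_config")
}

#' @rdname load_config
#' @param config a `run_config`.
#' @export
save_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

# Reproducibility manifest written by every CLI run: config snapshot, seed
# and package version suffice to re-run the stage bit-for-bit in
# deterministic single-threaded mode.
write_run_manifest <- function(out_dir, command, config, seed) {
  yaml::write_yaml(
    list(command = command,
         package = "sllre",
         version = as.character(utils::packageVersion("sllre")),
         seed = seed,
         config = if (is.null(config)) NULL else unclass(config)),
    file.path(out_dir, "run-manifest.yaml"))
}
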