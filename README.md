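# sllre — summarized-last-layer fine-tuning for biomedical relation extraction

Biomedical relation extraction classifies which relation, if any, a
sentence expresses between two tagged entity mentions — protein–protein
interactions, drug–drug interactions (ADVICE / EFFECT / INT / MECHANISM),
chemical–protein interactions (CPR:3/4/5/6/9). Transformer fine-tuning
conventionally classifies from the final-layer `[CLS]` vector alone and
discards every other last-layer token output, even though probing shows
those outputs carry task information the `[CLS]` vector lacks.

`sllre` is an R toolkit for the mechanisms that recover that information,
aimed at text-mining researchers who want to study them on one CPU:

* **SLL fine-tuning.** A summarizer pools the last layer's real-token
  outputs `h^L = {h_1^L … h_N^L}` (separator and padding excluded) and the
  summary is concatenated with the `[CLS]` output before the classifier:

  * additive attention: `α = softmax(h^L K)`, `O = Σ_i α_i h_i^L`, with a
    single trainable `K ∈ R^H`;
  * LSTM: `O` = final-step output; biLSTM: forward final step ⊕ backward
    first-position output;
  * combined output `h = h_CLS^L ⊕ O`, `p = softmax(W_f h + b_f)`; a
    no-`[CLS]` ablation (`h = O`) and the plain `[CLS]`-only baseline are
    both available.

* **Sub-domain adaptation data construction.** PubMed query manifests per
  task ("Protein OR Gene", "Drug", protein/gene + chemical annotation
  filtering), masked-language-model example builders (subword and
  whole-word masking, 15% rate, 80/10/10 corruption), next-sentence-
  prediction pair builders, and a seedable desk-scale continued
  pre-training loop.

* **Scalar-mix edge probing.** Probes over layers 0..l with
  `h_{i,l} = γ_l Σ_k α_l^k h_i^k` feed a two-layer perceptron on frozen
  activations; the knowledge delta `Δ^l = Score(P^l) − Score(P^{l−1})`
  measures what layer l alone contributes, and `Σ_l Δ^l` telescopes to
  `Score(P^L) − Score(P^0)`.

* **Attention-weight analysis.** Per-sentence word-level weight records
  (subword weights summed per word) and a corpus-level table of
  Porter-stemmed mean weights within a 3-word window around the two
  entity tags — the structure in which trigger words like
  "activ(ate)" / "inhibit" surface.

* **Infrastructure.** Entity-tag pre-processing (`@PROTEIN$`, `@DRUG$`,
  `@CHEMICAL$`), tagged-TSV and span-JSONL corpus I/O, instance- and
  document-level cross-validation folding, binary and micro-over-
  non-negative P/R/F evaluation, YAML run configs with full-scale
  (BioBERT-style, PubMedBERT-style) and desk-scale (`tiny`) presets, and
  a CLI (`exec/sllre`).

Everything is testable without downloads: the package ships a tiny
deterministic transformer encoder (hand-written forward and analytic
backward passes, validated against numerical gradients), a synthetic
trigger-word corpus generator whose labels are decidable by a known rule,
and a planted-signal activation generator for the probing series.

## A worked example

```r
library(sllre)

spec <- synthetic_corpus_spec(n = 2000, seed = 13)   # 4 positive classes + negative
corpus <- generate_re_corpus(spec)
set.seed(13); idx <- sort(sample.int(2000, 400))     # 400 held out

tokenizer <- toy_tokenizer(corpus$sentence)
encoder <- build_tiny_encoder(encoder_config(
  L = 2, H = 32, heads = 4, vocab = vocab_size(tokenizer),
  max_len = 24, seed = 13))

model <- fine_tune(encoder, tokenizer, corpus[-idx, ], corpus[idx, ],
                   spec$scheme,
                   sll_config("attention", max_len = 24, epochs = 5,
                              lr = 1e-3, batch = 32), seed = 13)
model$metrics
#>   epoch  train_loss precision recall f1
#> 1     1 1.492782652         0      0  0
#> 2     2 0.585348627         1      1  1
#> 3     3 0.038203260         1      1  1
#> 4     4 0.013649569         1      1  1
#> 5     5 0.008098565         1      1  1

pred <- predict(model, corpus[idx, ])
prf_micro_nonneg(corpus$label[idx], pred$predicted, spec$scheme)
#>   precision recall f1  tp fp fn
#> 1         1      1  1 238  0  0
```

The head learns the task outright (the synthetic corpus is solvable from
its planted trigger words; micro-F1 is computed over the non-negative
classes only). The attention analysis then shows *where* the head looks:

```r
correct <- corpus[idx, ][pred$predicted == corpus$label[idx], ]
records <- extract_records(model, correct)
top_k_stems(compute_global_weights(records, window = 3), 10)
#>  [1] "interfer"  "interact"  "inhibit"   "increas"   "decreas"   "advis"
#>  [7] "recommend" "avoid"     "attenu"    "enhanc"
```

All ten top-ranked stems are stems of planted trigger words
("attenu(ates)", "inhibit(s)", "recommend(ed)" …), and in every correctly
classified positive sentence the trigger word carries the maximum
per-word attention weight — the desk-scale analogue of the qualitative
finding that the attention summarizer concentrates on relation-expressing
words.

The probing side runs the same way from planted activations:

```r
pl <- generate_planted_activations(planted_activations_spec(
  n = 1000, L = 4, H = 32, N = 8, signal_layer = 4, effect = 3, seed = 1))
ser <- probe_series(pl$acts, pl$labels,
                    label_scheme("positive", "negative", task = "planted"),
                    probe_config(hidden = 64, lr = 5e-3, epochs = 30),
                    seed = 1)
ser$table
#>  l     score       delta
#>  0 0.4634146          NA
#>  1 0.4989940 0.035579330
#>  2 0.5079365 0.008942544
#>  3 0.5133470 0.005410515
#>  4 0.7472527 0.233905725
```

A label signal planted only in the last layer shows up only in the last
knowledge delta.

## CLI

```sh
exec/sllre synth      --n 2000 --seed 13 --out-dir runs/synth
exec/sllre preprocess --in runs/synth/corpus.tsv --scheme synthetic --k 10 --seed 1 --out-dir runs/cv
exec/sllre finetune   --train train.tsv --dev dev.tsv --scheme synthetic --summarizer attention --out-dir runs/ft
exec/sllre probe      --n 1000 --effect 3 --signal-layer 4 --out-dir runs/probe
exec/sllre eval       --predictions runs/ft/predictions.tsv --scheme synthetic --out-dir runs/eval
```

Every run writes a `run-manifest.yaml` (command, seed, package version,
config snapshot) sufficient to reproduce it in deterministic
single-threaded mode. See `vignettes/sllre-methods.Rmd` for the model
details, the synthetic study conditions and the design decisions.
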