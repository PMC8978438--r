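Package: sllre
Title: Relation Extraction with Summarized-Last-Layer Fine-Tuning of Transformer Encoders
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A desk-scale toolkit for biomedical relation extraction with
    transformer encoders. Implements the summarize-the-last-layer (SLL)
    fine-tuning head, which pools all last-layer token outputs with an
    additive-attention, LSTM or biLSTM summarizer and concatenates the
    summary with the classification-token output before the softmax
    classifier; sub-domain adaptation data construction (masked-language-model
    and next-sentence-prediction example builders, PubMed sub-domain query
    manifests) with a seedable continued-pre-training loop; scalar-mix edge
    probing with per-layer knowledge deltas; corpus-averaged, Porter-stemmed
    attention-weight analysis within entity windows; entity-tag corpus
    pre-processing and cross-validation folding; and micro precision /
    recall / F1 evaluation over non-negative relation classes. Ships a tiny
    deterministic transformer encoder and a planted-signal synthetic corpus
    generator so every component is testable on one CPU.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    graphics,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
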