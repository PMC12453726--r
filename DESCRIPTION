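Package: currimae
Title: Curriculum-Masked Autoencoder Pretraining and Snapshot Ensembles for
    Multi-Label Chest Radiograph Classification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A desk-scale framework for curriculum-scheduled masked-autoencoder
    (MAE) pretraining of small Vision Transformers on chest-radiograph-like
    images. Pretraining progressively raises the patch masking ratio in fixed
    stages while a cyclic cosine learning-rate schedule with warm restarts
    resets at every stage boundary; a model snapshot is saved at the end of
    each cycle. Snapshots are fine-tuned for multi-label thoracic disease
    classification with a sigmoid head, mean binary cross-entropy, layer-wise
    learning-rate decay, RandAugment and DropPath, then combined by
    score-averaging snapshot ensembling. Includes per-class AUC, sensitivity,
    precision and F1 with support-weighted aggregation for imbalanced label
    sets, a seeded synthetic radiograph generator (thorax-like images,
    co-occurring multi-label findings, strong class imbalance, and a raw
    15-class pediatric label table exercising the class-restructuring rules),
    manifest and augmentation utilities, and a command-line pipeline runner.
    The transformer encoder/decoder, backpropagation and AdamW optimizer are
    implemented in base R so the whole pipeline runs on one CPU.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    png,
    yaml,
    jsonlite,
    EBImage
Suggests:
    testthat (>= 3.0.0),
    withr,
    pROC,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
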