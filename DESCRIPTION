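Package: xairob
Title: Test-Time Augmentation Robustness of Token Attributions for
    SMILES Transformer Toxicity Models
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools to assess how stable explainable-AI token attributions
    are for transformer models that read molecules as SMILES strings.
    Provides molecule ingestion and cleaning, canonicalization and
    randomized SMILES enumeration, character tokenization with masking
    augmentation, structural-alert (SMARTS) matching, an instrumented
    transformer encoder/encoder-decoder with exact attention and gradient
    traces, eight token-attribution methods (attention maps, rollout,
    gradient and attention-gradient families, integrated gradients and
    Shapley values), canonical-atom alignment of attributions across
    enumerated SMILES, cosine-distance/entropy/relative-importance
    robustness metrics, randomized-model controls, and the statistical
    utilities (Mann-Whitney U, test-time bootstrapping) used to compare
    attribution populations.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
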