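# xairob

Robustness analysis of explainable-AI token attributions for SMILES-based
transformer toxicity models, using test-time augmentation.

## The problem

A molecule has many equivalent SMILES strings: `CCO`, `OCC` and `C(O)C` all
encode ethanol. A transformer that predicts Ames mutagenicity from SMILES
should, ideally, explain its prediction the same way no matter which of
those strings it is shown — each heavy atom should receive the same
importance. `xairob` measures how far that ideal is from reality. It
attributes the canonical SMILES and *n* randomized SMILES of each molecule
(test-time augmentation), maps every token attribution back onto the
molecule's canonical atom order, and quantifies the disagreement. Because
attribution variability can come from the architecture and tokenization
rather than from anything the model learned, every analysis is run against
a **randomized-model control**: an identically shaped, Xavier-initialized,
never-trained network.

## What it computes

For a model `f(x) ∈ ℝ²` over a tokenized SMILES `x` of length `S`, eight
attribution methods produce per-token importance vectors `φ ∈ ℝˢ`:

* **Attention Maps** — last-layer attention `α`, head-averaged, key-reduced:
  `φᵢ = (1/S) Σⱼ αᵢⱼ`.
* **Rollout** — layer-wise attention matrices combined by matrix product
  (identity-mixed `½(α+I)` and row-renormalized by default).
* **Grads / AttGrads** — class-activated gradients `∇_α y_c` of the chosen
  class logit w.r.t. attention, alone (last layer) or summed over layers
  as `Σₗ ∇α y_c ⊙ αˡ`.
* **CAT / AttCAT** — gradients w.r.t. the attention-block outputs `hˡ`,
  `Σₗ ∇h y_c ⊙ hˡ`, optionally re-weighted per token by its attention.
* **IG** — integrated gradients along the embedding path from an all-PAD
  baseline; completeness `Σφ = f(x) − f(x̄)` is tracked.
* **SHAP** — Shapley values with tokens as players and PAD as the absent
  background; exact subset enumeration up to 12 tokens, permutation
  sampling beyond.

Attributions are normalized by the absolute sum over the full token string
(`φ̂ᵢ = φᵢ / Σ|φ|`), their atom entries aligned to canonical atom order,
and compared with the cosine distance `1 − u·v/(‖u‖‖v‖)`. The
**robustness score** of a molecule is the mean of the pairwise distance
matrix over its augmentations. Shannon entropy (bits) and the relative
importance assigned to structural-alert (toxicophore) atoms complete the
metric set, with Mann–Whitney U comparisons and test-time bootstrapping of
classification metrics on the statistics side.

The transformer itself (encoder-only and encoder–decoder, auto-translation
pre-training with SMILES enumeration and 15% / 80-10-10 masking,
frozen-encoder transfer learning) is implemented in plain R with exact
reverse-mode gradients, so every attention matrix and every gradient the
attribution equations need is available by construction.

## Worked example

```r
library(xairob)

# a tiny classifier on synthetic molecules with a planted nitro alert
mols <- generateSyntheticMolecules(200, seed = 11, epsilon = 0)
cfg  <- modelConfig(maxLen = 40, embedDim = 32, nHeads = 4, nLayers = 2,
                    ffDim = 64, dropout = 0)
fit  <- transferLearn(randomizeModel(cfg, seed = 4), mols,
                      split = "random", epochs = 60, lr = 3e-3, seed = 6)
fit$metrics$auroc
#> [1] 0.9494949

# attribute one molecule across 1 canonical + 4 randomized SMILES
aligned <- attributeAugmented(fit$model, "CAT", "CC(N)C(=O)O",
                              n_augment = 4, seed = 3)
pairwiseCosineMatrix(aligned)$score
#> [1] 0.4832281
```

An AUROC of 0.95 says the head separates the planted alert almost
perfectly; a robustness score of 0.48 says the CAT explanations for five
equivalent strings of the same molecule still disagree substantially
(0 = identical explanations, 2 = anti-aligned) — the central phenomenon
this package exists to measure. The full demonstration
(`makeDemoConfig()`, or `inst/scripts/xairob demo`) adds the
randomized-model control, all eight methods, entropy, alert importance and
the carbon-count diagnostic.

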