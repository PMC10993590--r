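---
title: "Measuring attribution robustness with SMILES test-time augmentation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring attribution robustness with SMILES test-time augmentation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(xairob)
```

## The question this package answers

Explainable-AI methods assign each input token an importance score for a
prediction. For text-encoded molecules the input admits many equivalent
encodings: every SMILES string of a molecule describes the same graph, so
a faithful explanation should assign each *atom* the same importance
regardless of which string the model was shown. `xairob` operationalizes
that requirement. It enumerates randomized SMILES of a molecule, attributes
each string, re-expresses every attribution in canonical atom order, and
measures the spread. A never-trained, randomly initialized model of the
same architecture is carried through every analysis as a control: if a
trained model's attribution variability looks like the control's, the
variability is telling us about the architecture and tokenization, not
about learning.

## Model and procedure

**Tokenization.** SMILES are tokenized at the character level with one
deliberate deviation from naive character splitting: the two-letter
elements `Cl`/`Br` and whole bracket atoms such as `[N+]` or `[nH]` are
single tokens. This guarantees a bijection between heavy atoms and atom
tokens, which the alignment step needs. The vocabulary is a fixed
68-symbol table (4 specials — BOS, EOS, PAD, MASK — plus elements, ring
labels, punctuation and a closed set of charged/H-annotated bracket
atoms); out-of-vocabulary characters are hard errors rather than silent
drops. Sequences carry BOS/EOS and are padded to a common length; the
maximum is 175 SMILES tokens, i.e. 177 padded positions.

**Canonicalization and enumeration.** The package owns its SMILES
parser, canonical ranking and writer. Ranking is Morgan-style iterative
refinement of graph-invariant atom keys (element, aromaticity, charge,
hydrogen count, ring membership, degree, bond-order sum), with residual
ties resolved by exploring each candidate promotion and keeping the
lexicographically smallest complete string. Every decision depends only on
graph invariants, so all strings of one molecule receive identical
canonical atom ranks — the property that makes aligned attributions
comparable, and the property the test suite checks directly against an
independent toolkit (equivalence classes of our canonical form are in
bijection with RDKit's on fixture corpora). One limitation is deliberate:
aromatic and Kekulé spellings are treated as written and not
inter-normalized. All package-generated structures use a single consistent
style, so this never affects the analyses; mixed-style external data
should be standardized upstream.

**The transformer.** Encoder layers are standard post-layer-norm blocks
(multi-head attention, output projection, position-wise feed-forward),
with learned token and position embeddings, Xavier initialization, AdamW,
and dropout only during training, so attribution always runs on a
deterministic network. The forward pass records, per layer, the per-head
attention matrices and the attention-block output after the output
projection; the backward pass is hand-derived reverse-mode
differentiation and returns the gradients of a chosen class logit with
respect to exactly those tensors, plus the input embeddings. Finite
differences on an independently written forward pass agree with these
gradients to ~1e-9 relative error in the tests — the backward pass is the
implementation, finite differences only ever the oracle. Attention is not
masked at PAD positions: PAD tokens are ordinary learned embeddings, all
positions receive attributions, and the full-string normalization below
includes them, which mirrors how the analyses treat the "full token
string" component.

Pre-training is auto-translation to the canonical string under six
regimens (canonical, randomized or enumerated input, each optionally
masked with the 15% selection / 80-10-10 MASK-random-keep schedule), with
early stopping on validation cross-entropy (patience 5). Transfer learning
freezes the encoder — verified by weight digest, not trust — and trains a
max-pool MLP or TextCNN-with-highway head on binary labels, evaluated on
a scaffold or random split.

**Attribution methods.** Six methods read the traces (raw attention,
rollout, and the four gradient/output combinations), one integrates
gradients along the embedding path from an all-PAD baseline, and one
computes Shapley values with PAD as the absent-token background. PAD is
used as the background because it is the only semantically empty token in
the vocabulary; both choices are configurable. Attention-shaped scores are
reduced over the key axis and embedding-shaped scores over the embedding
axis, always by arithmetic mean, so every method yields one value per
token position. Two printed-formula ambiguities are resolved as explicit
choices: the rollout product's identity factor is implemented as the
standard identity-mix `0.5(α + I)` with row renormalization (a literal
product switch is provided, and the single-layer equivalence with raw
attention maps holds for the literal form); and attention is head-averaged
*before* any Hadamard product, with the AttCAT attention factor further
reduced to a per-token scalar so its shape conforms with the embedding-
shaped gradient term. Under uniform attention AttCAT equals CAT/S and
AttGrads equals Grads/S, which the tests assert.

**Normalization, alignment, metrics.** Attributions are normalized by
the absolute sum over the full padded string, then the atom-token entries
are permuted into canonical atom order. Cosine distance
(`1 − u·v/(‖u‖‖v‖)`, range [0, 2], signed values) compares aligned
vectors; a molecule's in-between-sample robustness score is the mean of
the off-diagonal pairwise distances (self-distances are structurally zero
and would only dilute the mean; the whole-matrix convention is available
as a switch). Zero vectors — possible for zero-gradient controls — have
undefined direction; their pairs are excluded from the mean and counted.
Entropy needs a distribution, so signed values are |·|-renormalized to
sum 1 before `−Σ p log₂ p`; relative component importance defaults to the
`Σ|φ̂|` mass, which keeps fractions in [0, 1] and additive over a disjoint
partition of the string, with the literal signed sum behind a flag.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `n_augment` | 10 | randomized SMILES per molecule (11 vectors with the canonical) |
| `maxLen` | 175 | maximum SMILES tokens; padded length 177 |
| `embedDim`, `nHeads`, `nLayers` | 512, 8, 3 | encoder size; defaults stay under 16.5 M parameters. Depth and head count are package choices at desk scale, overridable |
| `dropout` | 0.1 / 0.3 | pre-training / transfer-learning rates |
| `lr` | 1e-4 / 5e-5 | pre-training / transfer rates; the demo head uses 1e-3–3e-3 because a fresh small head on a frozen encoder needs a larger step at desk scale |
| `steps` (IG) | 64 | Riemann steps; completeness gap is recorded per attribution and warned about above 5% |
| `budget` (SHAP sampled) | 16 | permutations; the demo uses 2 for runtime |
| masking | 0.15, 0.80/0.10/0.10 | selection and MASK/random/keep rates |

## What the synthetic generator emulates — and what it does not

Fixtures are drug-like small molecules drawn from a fragment grammar
(alkyl chains with branches, benzene/pyridine and saturated rings,
ethers, amines, halogens, small polar groups), at most 60 tokens, with a
planted nitro fragment in about half the molecules and binary labels equal
to alert presence XOR 10% noise. This gives a task that is genuinely
learnable from substructure — a frozen random encoder with a trained head
reaches AUROC ≈ 0.9 at ε = 0 — while staying small enough that every
stage runs in seconds to minutes on one CPU. What it does not emulate:
real Ames chemistry (charge states, tautomers, large fused systems,
stereochemistry), label noise structure, class imbalance, or the
scale of corpus pre-training. Passing tests therefore certify the
*machinery* — alignment exactness, axiom satisfaction, control behavior —
not any claim about real-data attribution quality.

## Numerical choices and degenerate inputs

Attention softmax subtracts row maxima; layer norm uses ε = 1e-5; IG uses
the midpoint rule (convergence against a 1024-step oracle is under 1% in
vector norm at 64 steps on toy models); exact Shapley enumerates up to
2¹² subsets and refuses longer inputs rather than silently sampling.
Unparseable SMILES never crash dataset cleaning — records are dropped
with logged reasons; duplicate canonical structures collapse to the first
occurrence and label conflicts drop the record entirely (a conservative
choice; the upstream deduplication rule is not otherwise pinned down).
Salt stripping keeps the largest carbon-containing fragment, ties broken
by canonical string order. The Mann–Whitney test enumerates all group
assignments exactly when both groups have ≤ 8 members (correct under
ties), otherwise uses the tie-corrected normal approximation with
continuity correction; two-sided by default. Degenerate single-class
bootstrap resamples are redrawn, keeping the replicate count fixed, and
the redraw count is reported.

## Design choices where the design was open

* **Gradient class**: gradients default to the predicted class, with an
  explicit override to force the toxic class, since the class of interest
  is application-dependent. Within one molecule's augmentation set the
  canonical string's predicted class is used for every augmentation, so
  all vectors explain the same decision.
* **Max length accounting**: 175 counts SMILES tokens excluding specials;
  padded sequences are 177 long.
* **Vocabulary contents**: the 68-symbol table is pinned in code and
  shipped as a versioned JSON export; the exact membership beyond the
  specials and obvious characters is a package choice.
* **In-between-sample sets include the canonical string** as one of the
  eleven compared representations.

## The desk-scale demonstration and its honest outcomes

`makeDemoConfig()` pins the shipped demonstration: 500 synthetic
molecules, a 2-layer / 64-dimensional encoder, all eight methods on 50
held-out molecules with ten augmentations, trained model and randomized
control. On this demo the in-between-sample distance distributions of the
trained model and the never-trained control overlap substantially
(overlap coefficient ≈ 0.8 at seed 1), and the relative importance given
to the planted alert's atoms is similar for both (≈ 0.17–0.25) — the
package's central cautionary observation: much of what these attribution
methods measure survives removing all learning. Per-molecule robustness
correlates positively with carbon count, consistent with variability
tracking string length and tokenization. One soft expectation is unstable at
this scale: whether averaging aligned vectors over augmentations reduces
the mean in-between-method distance varies in sign with the seed (changes
of roughly ±0.01–0.08 either way on the demo). Two effects compete:
averaging cancels per-representation noise within each method (pushing
methods together), but different methods applied to the same string also
share string-specific structure, and averaging removes that common
component too, exposing method-specific means that can be further apart
in angle on a small, mostly random encoder. The quantity is reported, not
asserted, by the acceptance script; larger models and corpora are the
natural place to revisit it.

Problem sizes throughout (corpus 500, 50 explained molecules, IG at 16
steps and SHAP at 2 permutations inside the demo, full-precision IG/SHAP
in the axiom checks) are the package's chosen desk-scale study
conditions; they keep the complete demonstration in the minutes range on
a single CPU.

## Known limitations

* No kekulé/aromatic inter-normalization, no tautomer or charge
  standardization, no stereochemistry (removed on ingestion, by design).
* The SMARTS matcher implements a documented subset (element, aromaticity,
  charge, H-count, connectivity, degree, ring membership, negation,
  alternation; no recursive SMARTS); the shipped 13-alert toxicophore set
  stays inside it and is cross-checked against an independent
  substructure engine in the tests.
* Encoder-decoder greedy decoding is evaluated for sequence accuracy but
  no beam search is provided.
* Layer/head-specific attribution heuristics are out of scope; Attention
  Maps and Grads always read the last layer averaged over heads (a layer
  override exists for Grads).
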