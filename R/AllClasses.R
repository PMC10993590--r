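#' @import methods
NULL

#' TokenSequence: a tokenized SMILES string
#'
#' Character-level tokenization of one SMILES string with
#' beginning-of-sequence (BOS), end-of-sequence (EOS) and optional padding
#' (PAD) specials.  Two-letter elements (Cl, Br) and bracket atoms count as
#' single tokens so that every heavy atom owns exactly one token position --
#' the bijection the canonical-atom alignment of attributions depends on.
#'
#' @slot tokens character vector of token strings (BOS first, one EOS,
#'   PAD only after EOS).
#' @slot ids integer codes into the fixed 68-symbol vocabulary.
#' @slot atomOfToken integer vector, same length; for atom tokens the
#'   1-based heavy-atom index in string order, NA elsewhere.
#' @slot smiles the SMILES string the sequence was built from.
#' @export
setClass("TokenSequence",
  representation(tokens = "character", ids = "integer",
                 atomOfToken = "integer", smiles = "character"))

setValidity("TokenSequence", function(object) {
  msgs <- character(0)
  tk <- object@tokens
  if (length(tk) != length(object@ids)) msgs <- c(msgs, "tokens/ids length mismatch")
  if (length(tk) != length(object@atomOfToken)) msgs <- c(msgs, "atomOfToken length mismatch")
  if (!length(tk) || tk[1] != BOS_TOKEN) msgs <- c(msgs, "first token must be BOS")
  if (sum(tk == EOS_TOKEN) != 1L) msgs <- c(msgs, "exactly one EOS required")
  eos <- which(tk == EOS_TOKEN)
  if (length(eos) == 1L && any(tk[-seq_len(eos)] != PAD_TOKEN))
    msgs <- c(msgs, "only PAD allowed after EOS")
  atoms <- object@atomOfToken[!is.na(object@atomOfToken)]
  if (anyDuplicated(atoms)) msgs <- c(msgs, "atomOfToken must be injective over atoms")
  if (length(msgs)) msgs else TRUE
})

#' AlertSet: a named collection of structural-alert SMARTS patterns
#'
#' Expert-curated toxicophore substructures used as the human-intuition
#' reference in relative-importance analyses.  Patterns are compiled at
#' construction; invalid SMARTS or duplicate names are errors.
#'
#' @slot name character vector of unique alert names.
#' @slot smarts character vector of SMARTS pattern strings.
#' @slot compiled list of compiled pattern objects (internal form).
#' @export
setClass("AlertSet",
  representation(name = "character", smarts = "character", compiled = "list"))

setValidity("AlertSet", function(object) {
  msgs <- character(0)
  if (length(object@name) != length(object@smarts)) msgs <- c(msgs, "name/smarts length mismatch")
  if (anyDuplicated(object@name)) msgs <- c(msgs, "alert names must be unique")
  if (length(object@compiled) != length(object@smarts))
    msgs <- c(msgs, "compiled patterns missing")
  if (length(msgs)) msgs else TRUE
})

#' MaskingPlan: ground truth of one masking augmentation
#'
#' Records which token positions were selected for corruption and what
#' happened at each (MASK substitution, random token, or kept unchanged),
#' so pre-training corruption statistics can be audited.
#'
#' @slot selected integer vector of selected token positions.
#' @slot action character vector parallel to \code{selected}, each one of
#'   \code{"MASK"}, \code{"RANDOM"}, \code{"KEEP"}.
#' @export
setClass("MaskingPlan",
  representation(selected = "integer", action = "character"))

setValidity("MaskingPlan", function(object) {
  msgs <- character(0)
  if (length(object@selected) != length(object@action))
    msgs <- c(msgs, "selected/action length mismatch")
  if (!all(object@action %in% c("MASK", "RANDOM", "KEEP")))
    msgs <- c(msgs, "unknown action")
  if (anyDuplicated(object@selected)) msgs <- c(msgs, "duplicate positions")
  if (length(msgs)) msgs else TRUE
})

#' ModelConfig: transformer architecture and training hyperparameters
#'
#' Defaults follow the study conditions of the reference setup: maximum
#' sequence length 175 SMILES tokens (177 padded with BOS/EOS), token space
#' 68, embedding dimension 512, AdamW with Xavier initialization, batch 128,
#' learning rate 1e-4 (pre-training) / 5e-5 (transfer), weight decay 0.01,
#' dropout 0.1 / 0.3.  Layer count and head count default to a compact
#' L = 3, h = 8 that keeps the parameter budget under 16.5 M.
#'
#' @slot maxLen maximum SMILES token count (padded length is maxLen + 2).
#' @slot embedDim embedding dimension E.
#' @slot nHeads attention heads h (E must be divisible by h).
#' @slot nLayers encoder layers L.
#' @slot ffDim position-wise feed-forward width.
#' @slot vocabSize token space (68).
#' @slot dropout dropout rate used during training.
#' @slot lr learning rate.
#' @slot weightDecay AdamW weight decay.
#' @slot batchSize minibatch size.
#' @slot architecture "encoder_only" or "encoder_decoder".
#' @slot headType prediction head: "maxpool_mlp" or "textcnn_highway".
#' @export
setClass("ModelConfig",
  representation(maxLen = "integer", embedDim = "integer", nHeads = "integer",
                 nLayers = "integer", ffDim = "integer", vocabSize = "integer",
                 dropout = "numeric", lr = "numeric", weightDecay = "numeric",
                 batchSize = "integer", architecture = "character",
                 headType = "character"))

setValidity("ModelConfig", function(object) {
  msgs <- character(0)
  num_ok <- function(x) length(x) == 1L && is.finite(x) && x > 0
  for (sl in c("maxLen", "embedDim", "nHeads", "nLayers", "ffDim", "vocabSize", "batchSize"))
    if (!num_ok(slot(object, sl))) msgs <- c(msgs, paste(sl, "must be a positive scalar"))
  if (num_ok(object@embedDim) && num_ok(object@nHeads) &&
      object@embedDim %% object@nHeads != 0L)
    msgs <- c(msgs, "embedDim must be divisible by nHeads")
  if (!object@architecture %in% c("encoder_only", "encoder_decoder"))
    msgs <- c(msgs, "architecture must be encoder_only or encoder_decoder")
  if (!object@headType %in% c("maxpool_mlp", "textcnn_highway"))
    msgs <- c(msgs, "headType must be maxpool_mlp or textcnn_highway")
  if (length(msgs)) msgs else TRUE
})

#' AttentionTrace: attention and attention-block outputs of one forward pass
#'
#' Per layer l the head-wise attention matrices (each row a softmax
#' distribution over key positions) and the S x E attention-block output
#' after the output projection, plus the two class logits.  This is the raw
#' material of the transformer-specific attribution methods.
#'
#' @slot alpha list (length L) of h x S x S arrays of attention weights.
#' @slot hOut list (length L) of S x E attention-block outputs.
#' @slot logits numeric length-2 class scores.
#' @slot probs softmax of logits.
#' @slot seqLen padded sequence length S used.
#' @export
setClass("AttentionTrace",
  representation(alpha = "list", hOut = "list", logits = "numeric",
                 probs = "numeric", seqLen = "integer"))

setValidity("AttentionTrace", function(object) {
  msgs <- character(0)
  if (length(object@alpha) != length(object@hOut))
    msgs <- c(msgs, "alpha/hOut layer count mismatch")
  for (l in seq_along(object@alpha)) {
    a <- object@alpha[[l]]
    if (length(dim(a)) != 3L) { msgs <- c(msgs, "alpha must be h x S x S"); break }
    rs <- apply(a, c(1, 2), sum)
    if (max(abs(rs - 1)) > 1e-5) { msgs <- c(msgs, "attention rows must sum to 1"); break }
  }
  if (length(object@logits) != 2L) msgs <- c(msgs, "logits must have length 2")
  if (length(msgs)) msgs else TRUE
})

#' GradientTrace: class-activated gradients of one forward pass
#'
#' Gradients of the selected class logit with respect to each layer's
#' attention weights and attention-block outputs, shapes mirroring
#' \linkS4class{AttentionTrace}.
#'
#' @slot dAlpha list (length L) of h x S x S gradient arrays.
#' @slot dHOut list (length L) of S x E gradient matrices.
#' @slot classIndex the class c the gradients were taken for (1 or 2).
#' @export
setClass("GradientTrace",
  representation(dAlpha = "list", dHOut = "list", classIndex = "integer"))

setValidity("GradientTrace", function(object) {
  msgs <- character(0)
  if (!object@classIndex %in% c(1L, 2L)) msgs <- c(msgs, "classIndex must be 1 or 2")
  allfinite <- all(vapply(object@dAlpha, function(x) all(is.finite(x)), TRUE)) &&
    all(vapply(object@dHOut, function(x) all(is.finite(x)), TRUE))
  if (!allfinite) msgs <- c(msgs, "non-finite gradient entries")
  if (length(object@dAlpha) != length(object@dHOut))
    msgs <- c(msgs, "dAlpha/dHOut layer count mismatch")
  if (length(msgs)) msgs else TRUE
})

#' Attribution: per-token importance for one method/model/input/class
#'
#' A real importance vector with one entry per full-string token position
#' (including BOS/EOS/PAD).  The normalized form divides by the absolute sum
#' over the full string, so sum(|values|) = 1 whenever any entry is nonzero.
#'
#' @slot method one of AttentionMaps, Rollout, Grads, AttGrads, CAT, AttCAT,
#'   IG, SHAP.
#' @slot values numeric vector, padded full-string length.
#' @slot classIndex class the attribution explains (1 or 2).
#' @slot normalized logical; TRUE after \code{normalizeAttribution}.
#' @slot zeroVector flagged TRUE when a normalization met an all-zero vector.
#' @slot provenance named list (model/input digests, free-form).
#' @export
setClass("Attribution",
  representation(method = "character", values = "numeric", classIndex = "integer",
                 normalized = "logical", zeroVector = "logical", provenance = "list"))

ATTRIBUTION_METHODS <- c("AttentionMaps", "Rollout", "Grads", "AttGrads",
                         "CAT", "AttCAT", "IG", "SHAP")

setValidity("Attribution", function(object) {
  msgs <- character(0)
  if (!object@method %in% ATTRIBUTION_METHODS)
    msgs <- c(msgs, paste("unknown method", object@method))
  if (!all(is.finite(object@values))) msgs <- c(msgs, "non-finite attribution values")
  if (isTRUE(object@normalized) && !isTRUE(object@zeroVector)) {
    s <- sum(abs(object@values))
    if (abs(s - 1) > 1e-8) msgs <- c(msgs, "normalized attribution must have unit absolute sum")
  }
  if (length(msgs)) msgs else TRUE
})

#' AlignedAtomAttribution: atom attribution in canonical atom order
#'
#' The atom-token entries of a full-string-normalized attribution, reordered
#' by canonical atom rank so that position k means the same atom for every
#' SMILES of the molecule.  This is the comparable unit of the test-time
#' augmentation robustness analyses.
#'
#' @slot moleculeId identity key (canonical SMILES or dataset id).
#' @slot sourceSmiles the (possibly randomized) string attributed.
#' @slot values numeric vector of length A, canonical atom order.
#' @slot normalizationBase the full-string absolute sum the attribution was
#'   normalized by.
#' @slot method attribution method name.
#' @export
setClass("AlignedAtomAttribution",
  representation(moleculeId = "character", sourceSmiles = "character",
                 values = "numeric", normalizationBase = "numeric",
                 method = "character"))

setValidity("AlignedAtomAttribution", function(object) {
  if (!all(is.finite(object@values))) "non-finite values" else TRUE
})

## ---- show methods ---------------------------------------------------------

setMethod("show", "TokenSequence", function(object) {
  eos <- which(object@tokens == EOS_TOKEN)
  cat(sprintf("TokenSequence: %d tokens (%d padded), %d heavy atoms\n  %s\n",
              eos, length(object@tokens),
              sum(!is.na(object@atomOfToken)),
              paste(utils::head(object@tokens, 12), collapse = " ")))
})

setMethod("show", "AlertSet", function(object) {
  cat(sprintf("AlertSet with %d patterns: %s\n", length(object@name),
              paste(utils::head(object@name, 5), collapse = ", ")))
})

setMethod("show", "ModelConfig", function(object) {
  cat(sprintf("ModelConfig: %s, L=%d E=%d h=%d ff=%d vocab=%d maxLen=%d head=%s\n",
              object@architecture, object@nLayers, object@embedDim, object@nHeads,
              object@ffDim, object@vocabSize, object@maxLen, object@headType))
})

setMethod("show", "AttentionTrace", function(object) {
  cat(sprintf("AttentionTrace: %d layers, S=%d, logits=(%.4f, %.4f)\n",
              length(object@alpha), object@seqLen, object@logits[1], object@logits[2]))
})

setMethod("show", "Attribution", function(object) {
  cat(sprintf("Attribution[%s] length %d (class %d, %s)\n", object@method,
              length(object@values), object@classIndex,
              if (isTRUE(object@normalized)) "normalized" else "raw"))
})

setMethod("show", "AlignedAtomAttribution", function(object) {
  cat(sprintf("AlignedAtomAttribution[%s] %s: %d atoms\n", object@method,
              object@moleculeId, length(object@values)))
})
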