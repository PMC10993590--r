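## The eight token-attribution methods.
##
## Transformer-specific methods read the attention/gradient traces; the
## deep-learning method (integrated gradients) walks the embedding path
## from a PAD baseline; the model-agnostic method (Shapley values) treats
## tokens as players with PAD as the absent-token background.  All methods
## emit one value per full-string token position (BOS/EOS/PAD included);
## attention-shaped scores are reduced over the key axis and
## embedding-shaped scores over the embedding axis, by arithmetic mean.

#' Reduce per-token-per-dimension scores to a per-token vector
#'
#' Arithmetic mean over the second dimension (key positions for
#' attention-shaped S x S scores, embedding dimensions for S x E scores),
#' making attributions comparable across methods.
#'
#' @param raw numeric matrix (S x n, n >= 1).
#' @return numeric vector of length S.
#' @export
reduceEmbedding <- function(raw) {
  if (is.null(dim(raw))) raw <- matrix(raw, ncol = 1L)
  if (ncol(raw) < 1L) .stopf("reduceEmbedding: empty second dimension")
  rowMeans(raw)
}

.head_average <- function(alpha_l) {
  # h x S x S -> S x S
  apply(alpha_l, c(2L, 3L), mean)
}

.new_attribution <- function(method, values, classIndex, provenance = list()) {
  new("Attribution", method = method, values = as.numeric(values),
      classIndex = as.integer(classIndex), normalized = FALSE,
      zeroVector = FALSE, provenance = provenance)
}

#' Raw attention-map attribution
#'
#' The last encoder layer's attention, averaged over heads, reduced over
#' the key axis.
#'
#' @param trace an \linkS4class{AttentionTrace}.
#' @param classIndex class the attribution is reported for (bookkeeping
#'   only; raw attention does not depend on it).  Default 2 (toxic).
#' @return an \linkS4class{Attribution}.
#' @export
attentionMapAttribution <- function(trace, classIndex = 2L) {
  L <- length(trace@alpha)
  A <- .head_average(trace@alpha[[L]])
  .new_attribution("AttentionMaps", reduceEmbedding(A), classIndex)
}

#' Attention rollout attribution
#'
#' Aggregates head-averaged attention across all layers by matrix product.
#' The default follows the standard rollout construction: each layer's
#' matrix is mixed with the identity, 0.5 (A + I), and row-renormalized
#' before multiplying, which models the residual path and keeps every
#' product row-stochastic.  \code{literal = TRUE} instead multiplies the
#' raw attention matrices (whose product with the identity is a no-op).
#'
#' @param trace an \linkS4class{AttentionTrace}.
#' @param literal use the plain attention product without the identity mix.
#' @param classIndex bookkeeping class index (default 2).
#' @return an \linkS4class{Attribution}.
#' @export
rolloutAttribution <- function(trace, literal = FALSE, classIndex = 2L) {
  L <- length(trace@alpha)
  R <- NULL
  for (l in seq_len(L)) {
    A <- .head_average(trace@alpha[[l]])
    if (!literal) {
      A <- 0.5 * (A + diag(nrow(A)))
      A <- A / rowSums(A)
    }
    R <- if (is.null(R)) A else A %*% R
  }
  .new_attribution("Rollout", reduceEmbedding(R), classIndex)
}

#' Attention-gradient (Grads) attribution
#'
#' Class-activated gradient of the selected class logit with respect to
#' the last layer's attention, head-averaged and reduced over the key
#' axis.
#'
#' @param trace an \linkS4class{AttentionTrace}.
#' @param grads a \linkS4class{GradientTrace} from the same forward pass.
#' @param layer which layer to read (default the last).
#' @return an \linkS4class{Attribution}.
#' @export
gradAttribution <- function(trace, grads, layer = NULL) {
  if (length(trace@alpha) != length(grads@dAlpha))
    .stopf("trace/gradient layer count mismatch")
  L <- if (is.null(layer)) length(grads@dAlpha) else as.integer(layer)
  G <- .head_average(grads@dAlpha[[L]])
  .new_attribution("Grads", reduceEmbedding(G), grads@classIndex)
}

#' Attention x gradient (AttGrads) attribution
#'
#' Sums the Hadamard product of head-averaged attention and its class
#' gradient over all layers, reduced over the key axis.
#'
#' @inheritParams gradAttribution
#' @return an \linkS4class{Attribution}.
#' @export
attgradAttribution <- function(trace, grads) {
  if (length(trace@alpha) != length(grads@dAlpha))
    .stopf("trace/gradient layer count mismatch")
  acc <- NULL
  for (l in seq_along(trace@alpha)) {
    M <- .head_average(grads@dAlpha[[l]]) * .head_average(trace@alpha[[l]])
    acc <- if (is.null(acc)) M else acc + M
  }
  .new_attribution("AttGrads", reduceEmbedding(acc), grads@classIndex)
}

#' Class-activation (CAT) attribution from attention-block outputs
#'
#' Sums over layers the Hadamard product of each layer's attention-block
#' output with the class gradient taken with respect to it, reduced over
#' the embedding axis.
#'
#' @inheritParams gradAttribution
#' @return an \linkS4class{Attribution}.
#' @export
catAttribution <- function(trace, grads) {
  if (length(trace@hOut) != length(grads@dHOut))
    .stopf("trace/gradient layer count mismatch")
  acc <- NULL
  for (l in seq_along(trace@hOut)) {
    M <- grads@dHOut[[l]] * trace@hOut[[l]]
    acc <- if (is.null(acc)) M else acc + M
  }
  .new_attribution("CAT", reduceEmbedding(acc), grads@classIndex)
}

#' Attention-weighted CAT (AttCAT) attribution
#'
#' CAT per layer, additionally weighted per query token by its
#' head-averaged, key-reduced attention, then summed over layers and
#' reduced over the embedding axis.  Under uniform attention this equals
#' CAT scaled by 1/S.
#'
#' @inheritParams gradAttribution
#' @return an \linkS4class{Attribution}.
#' @export
attcatAttribution <- function(trace, grads) {
  if (length(trace@hOut) != length(grads@dHOut))
    .stopf("trace/gradient layer count mismatch")
  acc <- NULL
  for (l in seq_along(trace@hOut)) {
    a_tok <- reduceEmbedding(.head_average(trace@alpha[[l]]))
    M <- (grads@dHOut[[l]] * trace@hOut[[l]]) * a_tok
    acc <- if (is.null(acc)) M else acc + M
  }
  .new_attribution("AttCAT", reduceEmbedding(acc), grads@classIndex)
}

#' Integrated gradients attribution
#'
#' Midpoint Riemann approximation of the path integral of the class-logit
#' gradient along the straight embedding path from an all-PAD baseline to
#' the input.  Per-dimension scores are reduced over the embedding axis;
#' the completeness gap |sum(phi) - (f(x) - f(xbar))| is computed on the
#' unreduced scores and reported in the provenance (with a warning when it
#' exceeds \code{gap_warn} of the output difference).
#'
#' @param model a model handle.
#' @param seq a \linkS4class{TokenSequence}.
#' @param steps Riemann steps (default 64).
#' @param classIndex class of interest; default the predicted class.
#' @param baseline_ids optional baseline token ids (default all PAD).
#' @param gap_warn relative completeness-gap warning threshold (default 0.05).
#' @return an \linkS4class{Attribution}; provenance carries
#'   \code{completeness_gap} and \code{output_diff}.
#' @export
integratedGradients <- function(model, seq, steps = 64L, classIndex = NULL,
                                baseline_ids = NULL, gap_warn = 0.05) {
  stopifnot(is(seq, "TokenSequence"))
  ids <- seq@ids
  if (is.null(baseline_ids)) baseline_ids <- rep(match(PAD_TOKEN, VOCABULARY),
                                                 length(ids))
  stopifnot(length(baseline_ids) == length(ids))
  X <- .embed_ids(model, ids)
  Xb <- .embed_ids(model, baseline_ids)
  fw <- .classifier_forward(model, ids, X0 = X)
  if (is.null(classIndex)) classIndex <- which.max(fw$logits)
  classIndex <- as.integer(classIndex)
  dlog <- c(0, 0); dlog[classIndex] <- 1
  acc <- matrix(0, nrow(X), ncol(X))
  for (k in seq_len(steps)) {
    a <- (k - 0.5) / steps
    Xk <- Xb + a * (X - Xb)
    fwk <- .classifier_forward(model, ids, X0 = Xk)
    acc <- acc + .classifier_backward(model, fwk, dlog)$dX0
  }
  phi_mat <- (X - Xb) * (acc / steps)
  f_x <- fw$logits[classIndex]
  f_b <- .classifier_forward(model, ids, X0 = Xb)$logits[classIndex]
  gap <- abs(sum(phi_mat) - (f_x - f_b))
  if (abs(f_x - f_b) > 0 && gap > gap_warn * abs(f_x - f_b))
    warning(sprintf("integrated gradients completeness gap %.3g exceeds %.0f%% of |f(x)-f(baseline)| = %.3g",
                    gap, 100 * gap_warn, abs(f_x - f_b)))
  .new_attribution("IG", reduceEmbedding(phi_mat), classIndex,
                   provenance = list(completeness_gap = gap,
                                     output_diff = f_x - f_b, steps = steps))
}

## exact Shapley values of an np-player game; value(present) takes a
## logical membership vector.  Enumerates all 2^np subsets and applies the
## weighted marginal-contribution formula.
.shapley_exact <- function(value, np) {
  nsub <- 2L^np
  bits <- 2L^(seq_len(np) - 1L)
  vals <- numeric(nsub)
  sizes <- integer(nsub)
  for (s in seq_len(nsub) - 1L) {
    present <- bitwAnd(s, bits) > 0L
    vals[s + 1L] <- value(present)
    sizes[s + 1L] <- sum(present)
  }
  fact <- factorial(0:np)
  phi <- numeric(np)
  for (k in seq_len(np)) {
    bit <- bits[k]
    for (s in seq_len(nsub) - 1L) {
      if (bitwAnd(s, bit) > 0L) next
      w <- fact[sizes[s + 1L] + 1L] * fact[np - sizes[s + 1L]] / fact[np + 1L]
      phi[k] <- phi[k] + w * (vals[s + bit + 1L] - vals[s + 1L])
    }
  }
  phi
}

#' Shapley-value attribution over tokens
#'
#' Tokens are players; a player is "present" when its original token is in
#' place and "absent" when replaced by the PAD background.  The value
#' function is the class logit.  Exact mode enumerates all subsets
#' (non-special token count at most 12); sampled mode averages marginal
#' contributions over random permutations.  Special tokens are never
#' players and receive attribution 0.  The efficiency gap
#' |sum(phi) - (f(x) - f(all-baseline))| is reported in the provenance.
#'
#' @param model a model handle.
#' @param seq a \linkS4class{TokenSequence}.
#' @param mode "exact" or "sampled".
#' @param budget permutations for sampled mode (default 16).
#' @param seed seed for sampled mode.
#' @param classIndex class of interest; default the predicted class.
#' @return an \linkS4class{Attribution}.
#' @export
shapAttribution <- function(model, seq, mode = c("sampled", "exact"),
                            budget = 16L, seed = 1L, classIndex = NULL) {
  stopifnot(is(seq, "TokenSequence"))
  mode <- match.arg(mode)
  ids <- seq@ids
  players <- which(!(seq@tokens %in% SPECIAL_TOKENS))
  np <- length(players)
  pad_id <- match(PAD_TOKEN, VOCABULARY)
  if (is.null(classIndex)) {
    fw <- .classifier_forward(model, ids)
    classIndex <- which.max(fw$logits)
  }
  classIndex <- as.integer(classIndex)
  value <- function(present) {
    v_ids <- ids
    v_ids[players[!present]] <- pad_id
    .classifier_forward(model, v_ids)$logits[classIndex]
  }
  phi_players <- numeric(np)
  if (mode == "exact") {
    if (np > 12L)
      .stopf("exact Shapley needs <= 12 non-special tokens (have %d); use mode='sampled'", np)
    phi_players <- .shapley_exact(value, np)
  } else {
    .with_seed(seed, {
      for (b in seq_len(budget)) {
        perm <- sample(np)
        present <- rep(FALSE, np)
        v_prev <- value(present)
        for (k in perm) {
          present[k] <- TRUE
          v_new <- value(present)
          phi_players[k] <- phi_players[k] + (v_new - v_prev)
          v_prev <- v_new
        }
      }
    })
    phi_players <- phi_players / budget
  }
  v_full <- value(rep(TRUE, np))
  v_none <- value(rep(FALSE, np))
  phi <- numeric(length(ids))
  phi[players] <- phi_players
  .new_attribution("SHAP", phi, classIndex,
                   provenance = list(efficiency_gap = abs(sum(phi_players) - (v_full - v_none)),
                                     mode = mode))
}

#' Normalize an attribution by its full-string absolute sum
#'
#' \eqn{\hat\phi_i = \phi_i / \sum_k |\phi_k|}, so the normalized vector
#' has unit absolute sum.  An all-zero vector passes through unchanged
#' with the \code{zeroVector} flag set.
#'
#' @param att an \linkS4class{Attribution}.
#' @return a normalized \linkS4class{Attribution}; provenance gains
#'   \code{normalization_base}.
#' @export
normalizeAttribution <- function(att) {
  stopifnot(is(att, "Attribution"))
  if (!all(is.finite(att@values))) .stopf("non-finite attribution values")
  s <- sum(abs(att@values))
  if (s == 0) {
    att@zeroVector <- TRUE
    att@normalized <- TRUE
    att@provenance$normalization_base <- 0
    return(att)
  }
  att@values <- att@values / s
  att@normalized <- TRUE
  att@provenance$normalization_base <- s
  att
}

#' Compute one attribution by method name
#'
#' Dispatch helper used by the augmentation pipeline: runs the forward
#' trace (and gradients where needed) and returns the raw attribution.
#'
#' @param model a model handle.
#' @param seq a \linkS4class{TokenSequence}.
#' @param method one of the eight method names (see
#'   \linkS4class{Attribution}).
#' @param classIndex class of interest; default the predicted class.
#' @param steps Riemann steps for IG.
#' @param budget permutation budget for sampled SHAP.
#' @param seed seed for sampled SHAP.
#' @param rollout_literal use the as-printed attention product for Rollout.
#' @return an \linkS4class{Attribution}.
#' @export
attributeMethod <- function(model, seq, method, classIndex = NULL,
                            steps = 64L, budget = 16L, seed = 1L,
                            rollout_literal = FALSE) {
  method <- match.arg(method, ATTRIBUTION_METHODS)
  if (method == "IG")
    return(integratedGradients(model, seq, steps = steps, classIndex = classIndex))
  if (method == "SHAP")
    return(shapAttribution(model, seq, budget = budget, seed = seed,
                           classIndex = classIndex))
  ft <- forwardWithTrace(model, seq)
  if (is.null(classIndex)) classIndex <- ft$prediction$class
  if (method == "AttentionMaps") return(attentionMapAttribution(ft$trace, classIndex))
  if (method == "Rollout")
    return(rolloutAttribution(ft$trace, literal = rollout_literal,
                              classIndex = classIndex))
  gr <- classGradients(model, seq, classIndex)
  switch(method,
         Grads = gradAttribution(ft$trace, gr),
         AttGrads = attgradAttribution(ft$trace, gr),
         CAT = catAttribution(ft$trace, gr),
         AttCAT = attcatAttribution(ft$trace, gr))
}
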