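## Masking augmentation used by the masked pre-training regimens.

#' Corrupt a TokenSequence for masked pre-training
#'
#' Each non-special token position is independently selected with
#' probability 0.15; a selected position is replaced by the MASK token with
#' probability 0.80, by a uniformly random non-special vocabulary token with
#' probability 0.10, and kept unchanged with probability 0.10.  BOS, EOS and
#' PAD are never selected.  The returned \linkS4class{MaskingPlan} records
#' the ground truth of the corruption.
#'
#' @param seq a \linkS4class{TokenSequence}.
#' @param seed integer seed; the corruption is deterministic under it.
#' @param p_select selection probability (default 0.15).
#' @param p_mask,p_random conditional probabilities of the MASK and random
#'   substitutions (defaults 0.80 and 0.10; the remainder keeps the token).
#' @return list with elements \code{corrupted} (a TokenSequence) and
#'   \code{plan} (a MaskingPlan).
#' @export
maskTokens <- function(seq, seed = NULL, p_select = 0.15,
                       p_mask = 0.80, p_random = 0.10) {
  stopifnot(is(seq, "TokenSequence"))
  nonspecial <- which(!(seq@tokens %in% SPECIAL_TOKENS))
  if (!length(nonspecial)) .stopf("maskTokens: sequence has no non-special tokens")
  pool <- setdiff(VOCABULARY, SPECIAL_TOKENS)
  .with_seed(seed, {
    sel <- nonspecial[stats::runif(length(nonspecial)) < p_select]
    action <- character(length(sel))
    toks <- seq@tokens
    if (length(sel)) {
      u <- stats::runif(length(sel))
      action <- ifelse(u < p_mask, "MASK",
                       ifelse(u < p_mask + p_random, "RANDOM", "KEEP"))
      toks[sel[action == "MASK"]] <- MASK_TOKEN
      nrand <- sum(action == "RANDOM")
      if (nrand) toks[sel[action == "RANDOM"]] <- sample(pool, nrand, replace = TRUE)
    }
    corrupted <- new("TokenSequence", tokens = toks,
                     ids = match(toks, VOCABULARY),
                     atomOfToken = seq@atomOfToken, smiles = seq@smiles)
    list(corrupted = corrupted,
         plan = new("MaskingPlan", selected = as.integer(sel), action = action))
  })
}
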