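## Character tokenization of SMILES with a fixed 68-symbol vocabulary.

BOS_TOKEN  <- "<bos>"
EOS_TOKEN  <- "<eos>"
PAD_TOKEN  <- "<pad>"
MASK_TOKEN <- "<mask>"
SPECIAL_TOKENS <- c(BOS_TOKEN, EOS_TOKEN, PAD_TOKEN, MASK_TOKEN)

## The fixed token space (68 codes): 4 specials, the organic-subset and
## aromatic element symbols, ring-closure labels, structural punctuation and
## a closed set of charged/H-annotated bracket atoms legal in cleaned,
## stereo-free SMILES.  Out-of-vocabulary characters are hard errors.
.build_vocabulary <- function() {
  v <- c(
    SPECIAL_TOKENS,
    "Cl", "Br",
    "B", "C", "N", "O", "P", "S", "F", "I",
    "b", "c", "n", "o", "p", "s",
    as.character(1:9), "%10", "%11", "%12",
    "(", ")", "=", "#", "-", ".", ":",
    "[N+]", "[N-]", "[NH+]", "[NH2+]", "[NH3+]", "[NH4+]",
    "[n+]", "[nH]", "[nH+]", "[N]", "[NH]",
    "[O-]", "[O+]", "[OH+]", "[o+]", "[O]",
    "[S-]", "[S+]", "[s+]", "[SH]", "[S]",
    "[C-]", "[C]", "[CH]", "[CH2]", "[c-]", "[cH-]",
    "[P+]", "[PH]"
  )
  stopifnot(length(v) == 68L, !anyDuplicated(v))
  v
}

VOCABULARY <- .build_vocabulary()

ATOM_TOKENS <- c("Cl", "Br", "B", "C", "N", "O", "P", "S", "F", "I",
                 "b", "c", "n", "o", "p", "s",
                 grep("^\\[", VOCABULARY, value = TRUE))

MAX_SEQUENCE_LENGTH <- 175L            # SMILES tokens, specials excluded
PADDED_LENGTH <- MAX_SEQUENCE_LENGTH + 2L

#' The fixed SMILES token vocabulary
#'
#' @return character vector of the 68 token symbols, specials first.
#' @export
tokenVocabulary <- function() VOCABULARY

## split a SMILES string into vocabulary tokens (greedy, atom-aware)
.scan_tokens <- function(smiles) {
  chars <- strsplit(smiles, "", fixed = TRUE)[[1]]
  n <- length(chars)
  out <- character(0)
  i <- 1L
  while (i <= n) {
    ch <- chars[i]
    if (ch == "[") {
      j <- i
      while (j <= n && chars[j] != "]") j <- j + 1L
      if (j > n) .stopf("tokenize: unclosed '[' in '%s'", smiles)
      out <- c(out, paste(chars[i:j], collapse = ""))
      i <- j + 1L
    } else if (ch == "%" ) {
      if (i + 2L > n) .stopf("tokenize: bad ring label in '%s'", smiles)
      out <- c(out, paste(chars[i:(i + 2L)], collapse = ""))
      i <- i + 3L
    } else if (ch %in% c("C", "B") && i < n &&
               paste0(ch, chars[i + 1L]) %in% c("Cl", "Br")) {
      out <- c(out, paste0(ch, chars[i + 1L]))
      i <- i + 2L
    } else {
      out <- c(out, ch)
      i <- i + 1L
    }
  }
  out
}

#' Tokenize a SMILES string
#'
#' Character-level tokenization in which two-letter elements (Cl, Br) and
#' whole bracket atoms are single tokens, so each heavy atom owns exactly
#' one token position.  A BOS token is prepended, an EOS appended, and the
#' sequence is padded with PAD up to \code{pad_to} if given.
#'
#' @param smiles a single SMILES string (at most 175 tokens).
#' @param pad_to optional total padded length (including BOS/EOS).
#' @return a \linkS4class{TokenSequence}.
#' @examples
#' tokenizeSmiles("O=C=O", pad_to = 9)
#' @export
tokenizeSmiles <- function(smiles, pad_to = NULL) {
  toks <- .scan_tokens(smiles)
  bad <- setdiff(toks, VOCABULARY)
  if (length(bad))
    .stopf("tokenize: token(s) outside vocabulary: %s", paste(unique(bad), collapse = " "))
  if (length(toks) > MAX_SEQUENCE_LENGTH)
    .stopf("tokenize: '%s' has %d tokens, exceeding the maximum of %d",
           smiles, length(toks), MAX_SEQUENCE_LENGTH)
  full <- c(BOS_TOKEN, toks, EOS_TOKEN)
  if (!is.null(pad_to)) {
    pad_to <- as.integer(pad_to)
    if (pad_to < length(full))
      .stopf("tokenize: pad_to=%d shorter than sequence length %d", pad_to, length(full))
    full <- c(full, rep(PAD_TOKEN, pad_to - length(full)))
  }
  atom_of <- rep(NA_integer_, length(full))
  is_atom <- full %in% ATOM_TOKENS
  atom_of[is_atom] <- seq_len(sum(is_atom))
  new("TokenSequence", tokens = full, ids = match(full, VOCABULARY),
      atomOfToken = atom_of, smiles = smiles)
}

#' Reconstruct the SMILES string of a TokenSequence
#'
#' Concatenates the tokens between BOS and EOS; exact inverse of
#' \code{\link{tokenizeSmiles}}.
#'
#' @param seq a \linkS4class{TokenSequence}.
#' @return the SMILES string.
#' @export
detokenize <- function(seq) {
  stopifnot(is(seq, "TokenSequence"))
  eos <- which(seq@tokens == EOS_TOKEN)
  paste(seq@tokens[seq(2L, length.out = eos - 2L)], collapse = "")
}

#' Token strings of a TokenSequence
#' @param seq a \linkS4class{TokenSequence}.
#' @return character vector of tokens.
#' @export
tokens <- function(seq) seq@tokens

#' Integer token codes of a TokenSequence
#' @param seq a \linkS4class{TokenSequence}.
#' @return integer vector of vocabulary codes.
#' @export
tokenIds <- function(seq) seq@ids

#' Token-position to heavy-atom map of a TokenSequence
#' @param seq a \linkS4class{TokenSequence}.
#' @return integer vector (NA at non-atom positions).
#' @export
atomOfToken <- function(seq) seq@atomOfToken

#' Write the token vocabulary to a JSON file
#'
#' @param path output file path.
#' @return the path, invisibly.
#' @export
writeVocabulary <- function(path) {
  jsonlite::write_json(list(tokens = VOCABULARY,
                            specials = SPECIAL_TOKENS,
                            size = length(VOCABULARY)),
                       path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}
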