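## Test-time augmentation robustness: canonical-atom alignment of token
## attributions, pairwise cosine-distance matrices and the robustness
## score, attribution entropy, relative component importance, TTA
## averaging and cross-group (in-between model / in-between method)
## distances.

#' Align an attribution's atom entries to canonical atom order
#'
#' Extracts the atom-token entries of a full-string-normalized attribution
#' and permutes them into the molecule's canonical atom order, so that
#' position k refers to the same atom in every SMILES of the molecule.
#' Non-atom tokens are dropped but the full-string normalization base is
#' retained.
#'
#' @param att a normalized \linkS4class{Attribution} computed on \code{seq}.
#' @param seq the \linkS4class{TokenSequence} that was attributed.
#' @param ranks canonical atom ranks of the same source SMILES
#'   (\code{\link{canonicalAtomRanks}}); computed if missing.
#' @param moleculeId identity key; defaults to the canonical SMILES.
#' @return an \linkS4class{AlignedAtomAttribution}.
#' @export
alignAtomAttributions <- function(att, seq, ranks = NULL, moleculeId = NULL) {
  stopifnot(is(att, "Attribution"), is(seq, "TokenSequence"))
  if (!isTRUE(att@normalized))
    .stopf("alignAtomAttributions expects a normalized attribution")
  if (length(att@values) != length(seq@ids))
    .stopf("attribution length %d does not match sequence length %d",
           length(att@values), length(seq@ids))
  if (is.null(ranks)) ranks <- canonicalAtomRanks(seq@smiles)
  atom_pos <- which(!is.na(seq@atomOfToken))
  atom_idx <- seq@atomOfToken[atom_pos]
  if (length(ranks) != length(atom_pos))
    .stopf("atom count mismatch: %d ranks vs %d atom tokens (tokenizer/parser disagreement)",
           length(ranks), length(atom_pos))
  vals <- numeric(length(ranks))
  vals[ranks[atom_idx]] <- att@values[atom_pos]
  if (is.null(moleculeId)) moleculeId <- canonicalSmiles(seq@smiles)
  base <- att@provenance$normalization_base
  new("AlignedAtomAttribution", moleculeId = moleculeId,
      sourceSmiles = seq@smiles, values = vals,
      normalizationBase = if (is.null(base)) NA_real_ else base,
      method = att@method)
}

#' Attribute a molecule across its test-time augmentations
#'
#' Attributes the canonical SMILES plus \code{n_augment} randomized SMILES
#' of one molecule with one method, normalizes each attribution over its
#' full token string, and aligns all of them to canonical atom order.  The
#' default \code{n_augment = 10} gives the canonical + ten randomized
#' strings.
#'
#' @param model a model handle.
#' @param method attribution method name.
#' @param smiles the molecule (any valid SMILES; canonicalized internally).
#' @param n_augment randomized SMILES count (>= 1).
#' @param seed enumeration seed.
#' @param classIndex class of interest (default: class predicted for the
#'   canonical string, so all augmentations explain the same class).
#' @param pad_to common padded length for all augmentations (default:
#'   longest augmentation + 2).
#' @param ... further arguments to \code{\link{attributeMethod}}.
#' @return list of \code{n_augment + 1} \linkS4class{AlignedAtomAttribution}
#'   objects (canonical first).
#' @export
attributeAugmented <- function(model, method, smiles, n_augment = 10L,
                               seed = 1L, classIndex = NULL, pad_to = NULL, ...) {
  if (n_augment < 1L) .stopf("n_augment must be >= 1")
  can <- canonicalSmiles(smiles)
  strs <- c(can, enumerateSmiles(can, n_augment, seed = seed))
  if (is.null(pad_to))
    pad_to <- max(vapply(strs, function(s) length(.scan_tokens(s)), 0L)) + 2L
  if (is.null(classIndex)) {
    fw <- .classifier_forward(model, tokenizeSmiles(can, pad_to = pad_to)@ids)
    classIndex <- which.max(fw$logits)
  }
  lapply(strs, function(s) {
    sq <- tokenizeSmiles(s, pad_to = pad_to)
    att <- normalizeAttribution(attributeMethod(model, sq, method,
                                                classIndex = classIndex, ...))
    alignAtomAttributions(att, sq, moleculeId = can)
  })
}

#' Cosine distance between two vectors
#'
#' \eqn{1 - u.v / (||u||_2 ||v||_2)}; lies in [0, 2].  NA when either
#' vector is all-zero (distance undefined).
#'
#' @param u,v numeric vectors of equal length.
#' @return cosine distance, or NA for a zero vector.
#' @export
cosineDistance <- function(u, v) {
  nu <- sqrt(sum(u^2)); nv <- sqrt(sum(v^2))
  if (nu == 0 || nv == 0) return(NA_real_)
  d <- 1 - sum(u * v) / (nu * nv)
  min(max(d, 0), 2)
}

#' Pairwise cosine-distance matrix and robustness score
#'
#' Computes the full symmetric cosine-distance matrix between aligned
#' attribution vectors of one molecule.  The robustness score is the mean
#' of the off-diagonal entries by default (self-distances are structurally
#' zero; \code{includeDiagonal = TRUE} averages the whole matrix).
#' Zero-vector attributions give undefined (NA) distances; those pairs are
#' excluded from the mean and counted.
#'
#' @param atts list of \linkS4class{AlignedAtomAttribution} (or plain
#'   numeric vectors), equal length, at least 2.
#' @param includeDiagonal include the zero diagonal in the mean.
#' @return list with \code{matrix}, \code{score}, \code{n_undefined}.
#' @export
pairwiseCosineMatrix <- function(atts, includeDiagonal = FALSE) {
  vecs <- lapply(atts, function(a)
    if (is(a, "AlignedAtomAttribution")) a@values else as.numeric(a))
  n <- length(vecs)
  if (n < 2L) .stopf("need at least 2 attributions")
  len <- unique(vapply(vecs, length, 0L))
  if (length(len) != 1L) .stopf("aligned vectors differ in length")
  D <- matrix(0, n, n)
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    D[i, j] <- D[j, i] <- cosineDistance(vecs[[i]], vecs[[j]])
  }
  off <- D[upper.tri(D)]
  n_undef <- sum(is.na(off))
  score <- if (includeDiagonal) {
    vals <- c(off, off, diag(D))
    mean(vals, na.rm = TRUE)
  } else mean(off, na.rm = TRUE)
  list(matrix = D, score = score, n_undefined = n_undef)
}

#' Shannon entropy of an attribution, in bits
#'
#' Signed attributions carry no distribution; the documented convention
#' takes absolute values and renormalizes them to sum 1 before applying
#' \eqn{H = -\sum p_i \log_2 p_i} (with 0 log 0 = 0).  Set
#' \code{renormalize = FALSE} to entropy-score a vector that is already a
#' distribution (negative mass is then an error).
#'
#' @param values numeric vector (aligned atom attribution or component).
#' @param renormalize apply the |values| / sum(|values|) transform
#'   (default TRUE).
#' @return entropy in bits (NA for an all-zero vector).
#' @export
attributionEntropy <- function(values, renormalize = TRUE) {
  if (is(values, "AlignedAtomAttribution")) values <- values@values
  if (renormalize) {
    s <- sum(abs(values))
    if (s == 0) return(NA_real_)
    p <- abs(values) / s
  } else {
    if (any(values < 0)) .stopf("negative mass in a non-renormalized entropy input")
    s <- sum(values)
    if (s == 0) return(NA_real_)
    p <- values / s
  }
  p <- p[p > 0]
  -sum(p * log2(p))
}

#' Relative importance of a token component
#'
#' The fraction of a normalized attribution carried by a component of the
#' token string: \code{"full"} (all positions incl. BOS/EOS/PAD),
#' \code{"smiles"} (all non-special tokens), \code{"atom"} (atom tokens),
#' or \code{"alerts"} (atom tokens of structural-alert atoms).  The
#' default mass is \eqn{\sum |\hat\phi_i|}, which makes importances lie in
#' [0, 1] and sum to 1 over a disjoint partition; \code{signed = TRUE}
#' gives the literal signed sum instead.
#'
#' @param att a normalized \linkS4class{Attribution}.
#' @param seq the attributed \linkS4class{TokenSequence}.
#' @param component one of "full", "smiles", "atom", "alerts".
#' @param alert_atoms heavy-atom indices (string order) of alert matches;
#'   required for the alerts component (empty vector = no match = 0).
#' @param signed use the signed sum instead of the absolute mass.
#' @return a single fraction.
#' @export
relativeImportance <- function(att, seq, component = c("atom", "full", "smiles", "alerts"),
                               alert_atoms = NULL, signed = FALSE) {
  stopifnot(is(att, "Attribution"), is(seq, "TokenSequence"))
  component <- match.arg(component)
  if (!isTRUE(att@normalized)) .stopf("relativeImportance expects a normalized attribution")
  pos <- switch(component,
    full = seq_along(seq@tokens),
    smiles = which(!(seq@tokens %in% SPECIAL_TOKENS)),
    atom = which(!is.na(seq@atomOfToken)),
    alerts = {
      if (is.null(alert_atoms)) .stopf("alerts component requires alert_atoms")
      which(seq@atomOfToken %in% alert_atoms)
    })
  if (!length(pos)) return(0)
  if (signed) sum(att@values[pos]) else sum(abs(att@values[pos]))
}

#' Average aligned attributions over test-time augmentations
#'
#' Arithmetic mean per aligned atom over a set of equal-length aligned
#' attribution vectors (the TTA-averaged explanation).
#'
#' @param atts list of \linkS4class{AlignedAtomAttribution}, equal length.
#' @return an \linkS4class{AlignedAtomAttribution} (source = "tta_average").
#' @export
ttaAverage <- function(atts) {
  if (!length(atts)) .stopf("ttaAverage: empty input")
  vecs <- lapply(atts, function(a)
    if (is(a, "AlignedAtomAttribution")) a@values else as.numeric(a))
  len <- unique(vapply(vecs, length, 0L))
  if (length(len) != 1L) .stopf("ttaAverage: aligned vectors differ in length")
  m <- Reduce(`+`, vecs) / length(vecs)
  proto <- atts[[1]]
  if (is(proto, "AlignedAtomAttribution"))
    new("AlignedAtomAttribution", moleculeId = proto@moleculeId,
        sourceSmiles = "tta_average", values = m,
        normalizationBase = NA_real_, method = proto@method)
  else m
}

#' Cross-group attribution distances (in-between model / method)
#'
#' Given one aligned attribution per molecule for each group (groups being
#' different models for a fixed method, or different methods for a fixed
#' model), computes per molecule all pairwise cosine distances between
#' groups and aggregates them into a tidy long-format table.
#'
#' @param groups named list; each element is a named list (or environment)
#'   mapping molecule id to an \linkS4class{AlignedAtomAttribution} or
#'   numeric vector.
#' @param axis label stored in the output ("model" or "method").
#' @return list with \code{distances} (data.frame: molecule_id, group_a,
#'   group_b, axis, distance), \code{skipped} (molecules missing from some
#'   group), and \code{summary} (per-pair mean distance).
#' @export
crossGroupDistances <- function(groups, axis = c("model", "method")) {
  axis <- match.arg(axis)
  gnames <- names(groups)
  if (is.null(gnames) || any(!nzchar(gnames))) .stopf("groups must be named")
  if (length(groups) < 2L)
    return(list(distances = data.frame(molecule_id = character(0),
                                       group_a = character(0), group_b = character(0),
                                       axis = character(0), distance = numeric(0)),
                skipped = character(0), summary = data.frame()))
  shared <- Reduce(intersect, lapply(groups, names))
  all_ids <- unique(unlist(lapply(groups, names)))
  skipped <- setdiff(all_ids, shared)
  rows <- list()
  for (mol in shared) {
    for (i in seq_len(length(groups) - 1L)) for (j in (i + 1L):length(groups)) {
      a <- groups[[i]][[mol]]; b <- groups[[j]][[mol]]
      va <- if (is(a, "AlignedAtomAttribution")) a@values else as.numeric(a)
      vb <- if (is(b, "AlignedAtomAttribution")) b@values else as.numeric(b)
      rows[[length(rows) + 1L]] <- data.frame(
        molecule_id = mol, group_a = gnames[i], group_b = gnames[j],
        axis = axis, distance = cosineDistance(va, vb),
        stringsAsFactors = FALSE)
    }
  }
  distances <- if (length(rows)) do.call(rbind, rows)
    else data.frame(molecule_id = character(0), group_a = character(0),
                    group_b = character(0), axis = character(0),
                    distance = numeric(0))
  summary <- if (nrow(distances))
    stats::aggregate(distance ~ group_a + group_b, distances, mean,
                     na.action = stats::na.omit)
    else data.frame()
  list(distances = distances, skipped = skipped, summary = summary)
}
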