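## Synthetic drug-like molecule generator.
##
## Fixtures are assembled from a small fragment grammar (alkyl chains,
## benzene/pyridine and saturated rings, ethers, amines, halogens, small
## polar groups) that is valid-by-construction; every draw is additionally
## re-parsed as a safety net.  When a planted alert fragment is given,
## about half the molecules carry it and the binary label equals alert
## presence XOR epsilon-noise -- a separable-by-design toxicity task used
## for classifier and attribution sanity runs.

.SUBSTITUENTS <- c("F", "Cl", "Br", "O", "N", "OC", "C", "CC",
                   "C(C)C", "C(=O)O", "C#N", "OCC")

.random_chain <- function(len, branch_prob, hetero_prob) {
  out <- character(0)
  for (i in seq_len(len)) {
    atom <- if (i > 1L && i < len && stats::runif(1) < hetero_prob)
      sample(c("O", "N"), 1L) else "C"
    piece <- atom
    if (atom == "C" && i < len && stats::runif(1) < branch_prob)
      piece <- paste0(piece, "(", sample(.SUBSTITUENTS, 1L), ")")
    out <- c(out, piece)
  }
  paste(out, collapse = "")
}

.random_ring <- function(hetero_prob, n_subs) {
  aromatic <- stats::runif(1) < 0.7
  if (aromatic) {
    core <- if (stats::runif(1) < hetero_prob) "n" else "c"
    # three in-ring substituent slots plus one attachment after closure
    raw <- sample(.SUBSTITUENTS, 4L, replace = TRUE)
    subs <- rep("", 4L)
    if (n_subs > 0L) {
      slots <- sample(4L, min(n_subs, 4L))
      subs[slots] <- raw[slots]
    }
    wrap <- function(s) if (nzchar(s)) paste0("(", s, ")") else ""
    paste0("c1c", wrap(subs[1]), "c", wrap(subs[2]), core,
           "c", wrap(subs[3]), "c1", subs[4])
  } else {
    subs <- rep("", 4L)
    if (n_subs > 0L) {
      slots <- sample(4L, min(n_subs, 4L))
      subs[slots] <- paste0("(", sample(.SUBSTITUENTS, length(slots), replace = TRUE), ")")
    }
    paste0("C1C", subs[1], "C", subs[2], "C", subs[3], "C", subs[4], "C1")
  }
}

.one_synthetic_smiles <- function(ring_prob, branch_prob, hetero_prob,
                                  alert_fragment) {
  use_ring <- stats::runif(1) < ring_prob
  base <- if (use_ring) {
    .random_ring(hetero_prob, n_subs = sample(0:2, 1L))
  } else {
    .random_chain(sample(2:7, 1L), branch_prob, hetero_prob)
  }
  if (!is.null(alert_fragment)) base <- paste0(base, alert_fragment)
  base
}

#' Generate synthetic molecule records
#'
#' Draws \code{n} valid, cleanable small molecules from a fragment grammar.
#' With a planted alert, roughly half the molecules carry the alert
#' fragment and \code{label = contains(alert) XOR noise(epsilon)}.  The
#' corpus is fully deterministic under \code{seed}.
#'
#' @param n number of molecules (>= 1).
#' @param seed integer seed.
#' @param planted_alert optional SMILES fragment appended to ~50\% of the
#'   molecules (default when \code{plant = TRUE}: a nitro group,
#'   \code{"[N+](=O)[O-]"}); give \code{NULL} for unlabeled fixtures.
#' @param epsilon label-noise rate (default 0.1).
#' @param ring_prob probability a molecule is ring-based (default 0.5).
#' @param branch_prob per-position chain branching probability (default 0.3).
#' @param hetero_prob heteroatom substitution probability (default 0.2).
#' @return data.frame of cleaned molecule records (columns \code{id},
#'   \code{smiles}, \code{label}, \code{source}, \code{has_alert}).
#' @examples
#' generateSyntheticMolecules(5, seed = 1)
#' @export
generateSyntheticMolecules <- function(n, seed = NULL,
                                       planted_alert = "[N+](=O)[O-]",
                                       epsilon = 0.1,
                                       ring_prob = 0.5, branch_prob = 0.3,
                                       hetero_prob = 0.2) {
  if (!is.numeric(n) || length(n) != 1L || n < 1L) .stopf("n must be >= 1")
  n <- as.integer(n)
  .with_seed(seed, {
    smiles <- character(n); has_alert <- logical(n); label <- rep(NA_real_, n)
    for (i in seq_len(n)) {
      ok <- FALSE
      for (try in 1:20) {
        has <- !is.null(planted_alert) && stats::runif(1) < 0.5
        s <- .one_synthetic_smiles(ring_prob, branch_prob, hetero_prob,
                                   if (has) planted_alert else NULL)
        valid <- tryCatch({ parseSmiles(s); TRUE }, error = function(e) FALSE)
        if (valid && length(.scan_tokens(s)) <= 60L) {
          smiles[i] <- s; has_alert[i] <- has; ok <- TRUE; break
        }
      }
      if (!ok) .stopf("fixture grammar failed to produce a valid molecule")
      if (!is.null(planted_alert)) {
        flip <- stats::runif(1) < epsilon
        label[i] <- as.numeric(xor(has_alert[i], flip))
      }
    }
    # canonicalize per record but keep all n rows (a corpus may legitimately
    # repeat a molecule; dataset-level deduplication is cleanStructures' job)
    data.frame(id = sprintf("syn%04d", seq_len(n)),
               smiles = vapply(smiles, canonicalSmiles, "", USE.NAMES = FALSE),
               label = label, source = "synthetic", has_alert = has_alert,
               stringsAsFactors = FALSE)
  })
}
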