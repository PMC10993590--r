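# canonical-atom alignment, cosine robustness, entropy, relative
# importance, TTA averaging and cross-group distances

aligned_from_values <- function(smiles, raw_values, pad_to = 40L) {
  sq <- tokenizeSmiles(smiles, pad_to = pad_to)
  att <- normalizeAttribution(xairob:::.new_attribution("IG", raw_values, 2L))
  alignAtomAttributions(att, sq)
}

test_that("alignment drops non-atom tokens, keeps base, permutes canonically", {
  s <- "CC(N)C(=O)O"
  sq <- tokenizeSmiles(s, pad_to = 20L)
  vals <- seq_along(sq@ids) * 1.0
  att <- normalizeAttribution(xairob:::.new_attribution("IG", vals, 2L))
  al <- alignAtomAttributions(att, sq)
  A <- heavyAtomCount(s)
  expect_length(al@values, A)
  expect_equal(al@normalizationBase, sum(abs(vals)))
  expect_lte(sum(abs(al@values)), 1)
  # canonical input: alignment equals the atom-token subsequence
  can <- canonicalSmiles(s)
  sqc <- tokenizeSmiles(can, pad_to = 20L)
  expect_identical(canonicalAtomRanks(can), seq_len(A))
  attc <- normalizeAttribution(xairob:::.new_attribution("IG",
    seq_along(sqc@ids) * 1.0, 2L))
  alc <- alignAtomAttributions(attc, sqc)
  expect_equal(alc@values,
               attc@values[!is.na(atomOfToken(sqc))])
})

test_that("alignment equivariance: atom-identity attributions align exactly", {
  mols <- generateSyntheticMolecules(15, seed = 31L)
  for (s in mols$smiles) {
    strs <- c(s, enumerateSmiles(s, 6L, seed = 2L))
    aligned <- lapply(strs, function(e) {
      g <- xairob:::parseSmiles(e)
      sq <- tokenizeSmiles(e, pad_to = 64L)
      vals <- numeric(length(sq@ids))
      ap <- which(!is.na(atomOfToken(sq)))
      vals[ap] <- xairob:::ELEMENT_NUMBERS[g$element[atomOfToken(sq)[ap]]]
      aligned_from_values(e, vals, pad_to = 64L)
    })
    pc <- pairwiseCosineMatrix(aligned)
    expect_equal(max(abs(pc$matrix)), 0)
    expect_equal(pc$score, 0)
  }
  # oxygen of ethanol lands at the same aligned index from OCC and CCO
  mark_oxygen <- function(s) {
    g <- xairob:::parseSmiles(s)
    sq <- tokenizeSmiles(s, pad_to = 8L)
    vals <- numeric(length(sq@ids))
    ap <- which(!is.na(atomOfToken(sq)))
    vals[ap] <- as.numeric(g$element[atomOfToken(sq)[ap]] == "O")
    aligned_from_values(s, vals, pad_to = 8L)
  }
  expect_equal(mark_oxygen("OCC")@values, mark_oxygen("CCO")@values)
})

test_that("alignment errors on atom-count mismatch and unnormalized input", {
  sq <- tokenizeSmiles("CCO", pad_to = 8L)
  att <- xairob:::.new_attribution("IG", seq_len(8L) * 1.0, 2L)
  expect_error(alignAtomAttributions(att, sq), "normalized")
  natt <- normalizeAttribution(att)
  expect_error(alignAtomAttributions(natt, sq, ranks = c(1L, 2L)),
               "atom count mismatch")
})

test_that("attributeAugmented returns canonical + n aligned equal-length vectors", {
  m <- tiny_model(seed = 2L, maxLen = 30L)
  out <- attributeAugmented(m, "CAT", "CC(N)C(=O)O", n_augment = 4L, seed = 3L)
  expect_length(out, 5L)
  A <- heavyAtomCount("CC(N)C(=O)O")
  for (al in out) {
    expect_s4_class(al, "AlignedAtomAttribution")
    expect_length(al@values, A)
    expect_identical(al@moleculeId, canonicalSmiles("CC(N)C(=O)O"))
  }
  # single-heavy-atom molecule -> all aligned vectors of length 1
  out1 <- attributeAugmented(m, "AttentionMaps", "C", n_augment = 3L, seed = 1L)
  expect_true(all(vapply(out1, function(a) length(a@values), 0L) == 1L))
})

test_that("cosine distance anchors and bounds", {
  expect_equal(cosineDistance(c(1, 0), c(1, 0)), 0)
  expect_equal(cosineDistance(c(1, 0), c(0, 1)), 1)
  expect_equal(cosineDistance(c(1, 0), c(-1, 0)), 2)
  expect_true(is.na(cosineDistance(c(0, 0), c(1, 0))))
  set.seed(3)
  for (i in 1:50) {
    d <- cosineDistance(rnorm(6), rnorm(6))
    expect_gte(d, 0); expect_lte(d, 2)
  }
})

test_that("pairwise matrix is symmetric, zero-diagonal; score handles zeros", {
  set.seed(4)
  vecs <- lapply(1:4, function(i) rnorm(5))
  pc <- pairwiseCosineMatrix(vecs)
  expect_equal(pc$matrix, t(pc$matrix))
  expect_equal(diag(pc$matrix), rep(0, 4))
  expect_equal(pc$score, mean(pc$matrix[upper.tri(pc$matrix)]))
  # identical vectors -> zero matrix, score 0
  same <- pairwiseCosineMatrix(list(c(1, 2), c(1, 2), c(1, 2)))
  expect_equal(same$score, 0)
  # robustness score invariant to augmentation order
  perm <- sample(4)
  expect_equal(pairwiseCosineMatrix(vecs[perm])$score, pc$score)
  # zero vectors excluded and counted
  withz <- pairwiseCosineMatrix(list(c(1, 0), c(0, 0), c(0, 1)))
  expect_equal(withz$n_undefined, 2L)
  expect_equal(withz$score, 1)
  # diagonal convention switch
  expect_lt(pairwiseCosineMatrix(vecs, includeDiagonal = TRUE)$score, pc$score)
  expect_error(pairwiseCosineMatrix(vecs[1]), "at least 2")
  expect_error(pairwiseCosineMatrix(list(1:2, 1:3)), "length")
})

test_that("entropy anchors, bound, and sign conventions", {
  expect_equal(attributionEntropy(rep(0.25, 4)), 2.0)
  expect_equal(attributionEntropy(c(1, 0, 0, 0)), 0)
  expect_equal(attributionEntropy(c(0.5, 0.25, 0.25)), 1.5)
  # bounded by log2(A)
  set.seed(5)
  for (i in 1:20) {
    v <- rnorm(7)
    expect_lte(attributionEntropy(v), log2(7))
  }
  # signed values use |.|: entropy of (x, -x) equals entropy of (x, x)
  expect_equal(attributionEntropy(c(0.3, -0.7)), attributionEntropy(c(0.3, 0.7)))
  expect_error(attributionEntropy(c(-0.1, 1.1), renormalize = FALSE), "negative")
  expect_true(is.na(attributionEntropy(c(0, 0))))
})

test_that("relative importance partitions the full string under |.| mass", {
  m <- tiny_model(seed = 7L, maxLen = 30L)
  s <- "c1ccc(cc1)[N+](=O)[O-]"
  sq <- tokenizeSmiles(s, pad_to = 20L)
  att <- normalizeAttribution(attributeMethod(m, sq, "CAT", classIndex = 2L))
  expect_equal(relativeImportance(att, sq, "full"), 1.0)
  alert <- matchAlerts(s, alertSet("nitro", "[N+](=O)[O-]"))
  ri_alert <- relativeImportance(att, sq, "alerts", alert_atoms = alert$atoms)
  ri_atom <- relativeImportance(att, sq, "atom")
  ri_smiles <- relativeImportance(att, sq, "smiles")
  expect_lte(ri_alert, ri_atom + 1e-12)
  expect_lte(ri_atom, ri_smiles + 1e-12)
  expect_lte(ri_smiles, 1 + 1e-12)
  # disjoint partition sums to the full mass
  specials_mass <- sum(abs(att@values[tokens(sq) %in% xairob:::SPECIAL_TOKENS]))
  nonatom_mass <- ri_smiles - ri_atom
  expect_equal(specials_mass + nonatom_mass + ri_atom, 1, tolerance = 1e-12)
  # all mass on alert atoms -> importance 1; no match -> 0
  vals <- numeric(length(sq@ids))
  vals[which(atomOfToken(sq) %in% alert$atoms)] <- 1
  att2 <- normalizeAttribution(xairob:::.new_attribution("IG", vals, 2L))
  expect_equal(relativeImportance(att2, sq, "alerts", alert_atoms = alert$atoms), 1)
  expect_equal(relativeImportance(att2, sq, "alerts", alert_atoms = integer(0)), 0)
  # signed switch gives the literal signed sum
  expect_equal(relativeImportance(att, sq, "atom", signed = TRUE),
               sum(att@values[!is.na(atomOfToken(sq))]))
})

test_that("tta averaging is the per-atom mean with its optimality property", {
  set.seed(6)
  vecs <- lapply(1:5, function(i) rnorm(4))
  avg <- ttaAverage(vecs)
  expect_equal(avg, Reduce(`+`, vecs) / 5)
  # mean minimizes total squared distance to the set
  obj <- function(x) sum(vapply(vecs, function(v) sum((v - x)^2), 0))
  expect_lt(obj(avg), obj(avg + c(0.05, 0, 0, 0)))
  expect_lt(obj(avg), obj(rnorm(4)))
  expect_equal(ttaAverage(list(c(1, -1), c(-1, 1))), c(0, 0))
  expect_equal(ttaAverage(vecs[c(1, 1, 1)]), vecs[[1]])
  expect_error(ttaAverage(list(1:2, 1:3)), "length")
})

test_that("cross-group distances cover the in-between-model/method axes", {
  g1 <- list(m1 = c(1, 0), m2 = c(0, 1))
  # one group -> empty distance set
  expect_equal(nrow(crossGroupDistances(list(a = g1))$distances), 0L)
  # duplicated group -> all distances zero
  dup <- crossGroupDistances(list(a = g1, b = g1), axis = "model")
  expect_equal(dup$distances$distance, rep(0, 2))
  # three groups -> 3 pairwise values per molecule
  g2 <- list(m1 = c(0, 1), m2 = c(1, 0))
  g3 <- list(m1 = c(1, 1), m2 = c(1, -1))
  three <- crossGroupDistances(list(a = g1, b = g2, c = g3), axis = "method")
  expect_equal(nrow(three$distances), 6L)
  expect_equal(sum(three$distances$molecule_id == "m1"), 3L)
  # missing molecule skipped and reported
  g4 <- list(m1 = c(1, 0))
  sk <- crossGroupDistances(list(a = g1, b = g4))
  expect_equal(sk$skipped, "m2")
  expect_equal(nrow(sk$distances), 1L)
})
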