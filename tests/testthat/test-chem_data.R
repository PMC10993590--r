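# molecule ingestion, canonicalization, enumeration, tokenization,
# masking, alerts and the fixture generator

test_that("cleaning strips salts and stereo, collapses duplicates, skips bad input", {
  out <- cleanStructures(c("CC(=O)O.[Na+]", "CCO", "OCC", "C(", "C/C=C/C", ""))
  expect_equal(nrow(out), 3L)
  expect_equal(out$smiles[1], canonicalSmiles("CC(=O)O"))
  expect_equal(out$smiles[2], canonicalSmiles("CCO"))
  expect_equal(out$smiles[3], canonicalSmiles("CC=CC"))
  dropped <- attr(out, "dropped")
  expect_equal(nrow(dropped), 2L)
  expect_match(dropped$reason[1], "unmatched")
})

test_that("duplicate label conflicts drop the record; agreeing labels survive", {
  out <- cleanStructures(c("CCO", "OCC", "CCN", "NCC"),
                         label = c(1, 0, 1, 1))
  expect_equal(nrow(out), 1L)
  expect_equal(out$label, 1)
  expect_true(any(grepl("conflicting", attr(out, "dropped")$reason)))
})

test_that("overlap removal subtracts by canonical key", {
  a <- cleanStructures(c("CCO"))
  b <- cleanStructures(c("OCC", "CCN"))
  expect_equal(removeOverlap(a, b)$smiles, canonicalSmiles("CCN"))
  expect_equal(nrow(removeOverlap(b, b)), 0L)
  c_ <- cleanStructures("CCCC")
  expect_equal(removeOverlap(a, c_)$smiles, c_$smiles)
})

test_that("canonicalization is idempotent and representation-invariant", {
  for (s in fixture_smiles) {
    cs <- canonicalSmiles(s)
    expect_identical(canonicalSmiles(cs), cs)
  }
  expect_identical(canonicalSmiles("OCC"), canonicalSmiles("C(O)C"))
  expect_error(canonicalSmiles("C("), "invalid structure")
})

test_that("enumeration round-trips and is deterministic under seed", {
  for (s in fixture_smiles) {
    cs <- canonicalSmiles(s)
    en <- enumerateSmiles(s, 8L, seed = 11L)
    expect_length(en, 8L)
    expect_true(all(vapply(en, canonicalSmiles, "") == cs))
  }
  expect_identical(enumerateSmiles("CC(N)C(=O)O", 5L, seed = 3L),
                   enumerateSmiles("CC(N)C(=O)O", 5L, seed = 3L))
  expect_equal(enumerateSmiles("C", 5L, seed = 1L), rep("C", 5L))
})

test_that("canonical atom ranks are bijective and identity-preserving", {
  for (s in fixture_smiles) {
    r <- canonicalAtomRanks(s)
    expect_setequal(r, seq_along(r))
    # canonical string of the molecule ranks as the identity permutation
    expect_identical(canonicalAtomRanks(canonicalSmiles(s)),
                     seq_along(r))
  }
  # the oxygen lands at the same canonical index in OCC and CCO
  r1 <- canonicalAtomRanks("OCC")  # O C C
  r2 <- canonicalAtomRanks("CCO")  # C C O
  expect_equal(r1[1], r2[3])
  # element identity preserved across enumerations
  for (s in c("CC(N)C(=O)O", "c1ccc(cc1)[N+](=O)[O-]")) {
    ref <- NULL
    for (e in c(s, enumerateSmiles(s, 5L, seed = 2L))) {
      g <- xairob:::parseSmiles(e)
      els <- g$element[order(canonicalAtomRanks(e))]
      if (is.null(ref)) ref <- els else expect_identical(els, ref)
    }
  }
})

test_that("canonical equivalence classes agree with an independent toolkit", {
  mols <- generateSyntheticMolecules(40, seed = 19L)$smiles
  strs <- unlist(lapply(mols, function(s) c(s, enumerateSmiles(s, 3L, seed = 4L))))
  mine <- vapply(strs, canonicalSmiles, "", USE.NAMES = FALSE)
  f <- tempfile(); writeLines(strs, f)
  ref <- rdkit_run(sprintf("
from rdkit import Chem
for line in open('%s'):
    m = Chem.MolFromSmiles(line.strip())
    print('None' if m is None else Chem.MolToSmiles(m))", f))
  expect_false(any(ref == "None"))
  # same my-class <=> same rdkit-class
  expect_true(all(tapply(ref, mine, function(x) length(unique(x))) == 1L))
  expect_equal(length(unique(mine)), length(unique(ref)))
})

test_that("tokenization owns one token per heavy atom and round-trips", {
  ts <- tokenizeSmiles("O=C=O", pad_to = 9L)
  expect_identical(tokens(ts),
                   c("<bos>", "O", "=", "C", "=", "O", "<eos>", "<pad>", "<pad>"))
  expect_identical(which(!is.na(atomOfToken(ts))), c(2L, 4L, 6L))
  ts2 <- tokenizeSmiles("CCl")
  expect_equal(sum(!is.na(atomOfToken(ts2))), heavyAtomCount("CCl"))
  for (s in fixture_smiles) {
    sq <- tokenizeSmiles(s, pad_to = 40L)
    expect_identical(detokenize(sq), s)
    expect_equal(sum(!is.na(atomOfToken(sq))), heavyAtomCount(s))
  }
  expect_length(tokenVocabulary(), 68L)
  expect_error(tokenizeSmiles("CCX"), "outside vocabulary")
  expect_error(tokenizeSmiles(paste(rep("C", 200), collapse = "")), "exceeding")
})

test_that("masking hits the 15% / 80-10-10 schedule and spares specials", {
  sq <- tokenizeSmiles(strrep("C", 100), pad_to = 120L)
  nsel <- 0L; nmask <- 0L; nrand <- 0L; nkeep <- 0L; total <- 0L
  # one RNG stream for all draws: the binomial bound assumes independence
  set.seed(1)
  for (i in 1:1200) {
    mk <- maskTokens(sq)
    expect_false(any(tokens(sq)[mk$plan@selected] %in%
                       c("<bos>", "<eos>", "<pad>", "<mask>")))
    nsel <- nsel + length(mk$plan@selected)
    nmask <- nmask + sum(mk$plan@action == "MASK")
    nrand <- nrand + sum(mk$plan@action == "RANDOM")
    nkeep <- nkeep + sum(mk$plan@action == "KEEP")
    total <- total + 100L
  }
  expect_gt(total, 1e5)
  # within 3 binomial SD of the target rates
  expect_lt(abs(nsel / total - 0.15), 3 * sqrt(0.15 * 0.85 / total))
  expect_lt(abs(nmask / nsel - 0.80), 3 * sqrt(0.80 * 0.20 / nsel))
  expect_lt(abs(nrand / nsel - 0.10), 3 * sqrt(0.10 * 0.90 / nsel))
  expect_lt(abs(nkeep / nsel - 0.10), 3 * sqrt(0.10 * 0.90 / nsel))
  # determinism
  m1 <- maskTokens(sq, seed = 42L); m2 <- maskTokens(sq, seed = 42L)
  expect_identical(tokens(m1$corrupted), tokens(m2$corrupted))
  expect_identical(m1$plan@selected, m2$plan@selected)
})

test_that("alert matching finds substructures with string-order atom indices", {
  nitro <- alertSet("nitro", "[N+](=O)[O-]")
  m <- matchAlerts("c1ccc(cc1)[N+](=O)[O-]", nitro)
  expect_length(m$matches$nitro, 1L)
  expect_setequal(m$matches$nitro[[1]], 7:9)
  expect_length(matchAlerts("CC", nitro)$matches, 0L)
  empty <- alertSet(character(0), character(0))
  expect_length(matchAlerts("CCO", empty)$matches, 0L)
  expect_error(alertSet("bad", "$([N+])"), "not supported")
  expect_error(matchAlerts("C(", nitro), "invalid structure")
})

test_that("shipped alert set agrees with an independent substructure engine", {
  alerts <- readAlerts(system.file("extdata", "alerts.tsv", package = "xairob"))
  mols <- c(fixture_smiles, "CC(=O)C=C", "NNC", "CC=O", "N=NC", "CN=O",
            "C1OC1CC", "C1NC1", "CCCl")
  mine <- lapply(mols, function(s) {
    m <- matchAlerts(s, alerts)
    lapply(m$matches, function(hits) lapply(hits, sort))
  })
  f <- tempfile(); writeLines(mols, f)
  af <- system.file("extdata", "alerts.tsv", package = "xairob")
  ref_lines <- rdkit_run(sprintf("
from rdkit import Chem
import csv
alerts = [(r['name'], Chem.MolFromSmarts(r['smarts']))
          for r in csv.DictReader(open('%s'), delimiter='\\t')]
for line in open('%s'):
    m = Chem.MolFromSmiles(line.strip())
    hits = []
    for name, pat in alerts:
        ms = set(tuple(sorted(x)) for x in m.GetSubstructMatches(pat))
        for t in sorted(ms):
            hits.append(name + ':' + ','.join(str(i + 1) for i in t))
    print(';'.join(sorted(hits)))", af, f))
  for (i in seq_along(mols)) {
    mine_str <- character(0)
    for (nm in names(mine[[i]]))
      for (hit in mine[[i]][[nm]])
        mine_str <- c(mine_str, paste0(nm, ":", paste(hit, collapse = ",")))
    expect_identical(paste(sort(mine_str), collapse = ";"), ref_lines[i],
                     label = sprintf("alerts for %s", mols[i]))
  }
})

test_that("synthetic generator yields valid, cleanable, reproducible corpora", {
  syn <- generateSyntheticMolecules(100, seed = 7L)
  expect_equal(nrow(syn), 100L)
  cleaned <- cleanStructures(syn$smiles, syn$label, syn$id)
  expect_equal(nrow(attr(cleaned, "dropped")[
    !grepl("duplicate|conflict", attr(cleaned, "dropped")$reason), ]), 0L)
  expect_true(all(vapply(syn$smiles, function(s)
    identical(canonicalSmiles(s), s), TRUE)))
  # determinism
  expect_identical(syn, generateSyntheticMolecules(100, seed = 7L))
  # epsilon = 0: label equals alert presence exactly
  syn0 <- generateSyntheticMolecules(80, seed = 8L, epsilon = 0)
  nitro <- alertSet("nitro", "[N+](=O)[O-]")
  found <- vapply(syn0$smiles, function(s)
    length(matchAlerts(s, nitro)$matches) > 0, TRUE, USE.NAMES = FALSE)
  expect_identical(as.numeric(found), syn0$label)
  expect_identical(found, syn0$has_alert)
  # sequence-length bound
  expect_true(all(vapply(syn$smiles, function(s)
    length(xairob:::.scan_tokens(s)), 0L) <= 60L))
})

test_that("smi and csv readers fill defaults", {
  f <- tempfile(fileext = ".smi")
  writeLines(c("CCO mol1", "CCN"), f)
  r <- readSmilesFile(f)
  expect_equal(r$smiles, c("CCO", "CCN"))
  expect_equal(r$id[1], "mol1")
  f2 <- tempfile(fileext = ".csv")
  utils::write.csv(data.frame(smiles = c("CCO"), label = 1), f2, row.names = FALSE)
  r2 <- readSmilesFile(f2)
  expect_equal(r2$label, 1)
})
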