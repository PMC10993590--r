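## Canonical atom ranking, canonical/randomized SMILES writing, enumeration.
##
## Ranking is Morgan-style iterative refinement over graph-invariant atom
## keys, with remaining ties resolved by exploring each candidate promotion
## and keeping the lexicographically smallest complete SMILES.  Because every
## decision depends only on graph invariants (never on input atom order), all
## SMILES of one molecule map to the same canonical string and the same
## per-atom canonical ranks -- the property the attribution-alignment layer
## relies on.

.initial_keys <- function(g) {
  h <- .molgraph_hydrogens(g)
  deg <- tabulate(c(g$bond_a1, g$bond_a2), nbins = .molgraph_natoms(g))
  inring <- .molgraph_in_ring(g)
  bsum <- .molgraph_bondsum(g)
  sprintf("%2s|%d|%+03d|%d|%03d|%d|%04.1f",
          g$element, as.integer(g$aromatic), g$charge, h,
          ifelse(is.na(g$isotope), 0L, g$isotope), as.integer(inring), bsum)
}

.bond_code <- function(order, aromatic) ifelse(aromatic, 4L, order)

.refine_ranks <- function(g, ranks, adj) {
  n <- length(ranks)
  repeat {
    keys <- character(n)
    for (i in seq_len(n)) {
      nb <- adj[[i]]
      nbkeys <- sprintf("%d:%05d", .bond_code(nb$order, nb$aromatic), ranks[nb$nbr])
      keys[i] <- paste0(sprintf("%05d|", ranks[i]),
                        paste(sort(nbkeys), collapse = ","))
    }
    new <- .dense_rank(keys)
    # refinement only ever splits classes; equal class count => fixed point
    if (length(unique(new)) == length(unique(ranks))) return(new)
    ranks <- new
  }
}

## promote atom `a` to strictly precede its tie class, then re-refine
.promote_and_refine <- function(g, ranks, adj, a) {
  r <- ranks * 2L
  r[a] <- r[a] - 1L
  .refine_ranks(g, .dense_rank(sprintf("%06d", r)), adj)
}

## resolve all ties; returns list(priority = complete ranking, smiles)
.canonical_resolve <- function(g, ranks, adj, depth = 0L) {
  n <- length(ranks)
  if (depth > 64L) .stopf("canonical tie resolution exceeded depth limit")
  tab <- table(ranks)
  tied <- as.integer(names(tab)[tab > 1L])
  if (!length(tied)) {
    return(list(priority = ranks, smiles = writeSmilesGraph(g, ranks)))
  }
  cell <- which(ranks == min(tied))
  best <- NULL
  for (a in cell) {
    r2 <- .promote_and_refine(g, ranks, adj, a)
    cand <- .canonical_resolve(g, r2, adj, depth + 1L)
    if (is.null(best) || cand$smiles < best$smiles) best <- cand
  }
  best
}

.canonicalize_graph <- function(g) {
  adj <- .molgraph_adjacency(g)
  ranks <- .refine_ranks(g, .dense_rank(.initial_keys(g)), adj)
  .canonical_resolve(g, ranks, adj)
}

## ---- SMILES writer --------------------------------------------------------

## implied hydrogen count if the atom were written bare (organic subset rule)
.implied_bare_h <- function(g, i, bsum) {
  val <- DEFAULT_VALENCE[[g$element[i]]]
  if (is.null(val)) return(NA_integer_)
  cap <- val[val >= bsum[i]]
  if (!length(cap)) return(NA_integer_)
  as.integer(ceiling(cap[1] - bsum[i]))
}

.atom_token <- function(g, i, bsum, hyd) {
  sym <- g$element[i]
  if (g$aromatic[i]) sym <- tolower(sym)
  bare_ok <- g$element[i] %in% ORGANIC_SUBSET &&
    g$charge[i] == 0L && is.na(g$isotope[i])
  if (bare_ok) {
    implied <- .implied_bare_h(g, i, bsum)
    if (!is.na(implied) && implied == hyd[i]) return(sym)
  }
  h <- hyd[i]
  hstr <- if (h == 0L) "" else if (h == 1L) "H" else paste0("H", h)
  ch <- g$charge[i]
  cstr <- if (ch == 0L) "" else if (ch == 1L) "+" else if (ch == -1L) "-"
          else sprintf("%+d", ch)
  iso <- if (is.na(g$isotope[i])) "" else as.character(g$isotope[i])
  paste0("[", iso, sym, hstr, cstr, "]")
}

.bond_token <- function(g, b) {
  if (g$bond_aromatic[b]) return("")
  ord <- g$bond_order[b]
  if (ord == 2L) return("=")
  if (ord == 3L) return("#")
  # explicit single between two aromatic atoms (e.g. biphenyl link)
  if (g$aromatic[g$bond_a1[b]] && g$aromatic[g$bond_a2[b]]) return("-")
  ""
}

.closure_label <- function(k) if (k <= 9L) as.character(k) else sprintf("%%%02d", k)

#' Write a SMILES string from a molecular graph under an atom priority
#'
#' Depth-first emission: each component starts at its minimum-priority atom
#' and neighbors are visited in increasing priority, so a complete canonical
#' ranking yields the canonical string and a random permutation yields a
#' randomized (but valid and equivalent) string.
#'
#' @keywords internal
writeSmilesGraph <- function(g, priority) {
  n <- .molgraph_natoms(g)
  adj <- .molgraph_adjacency(g)
  bsum <- .molgraph_bondsum(g)
  hyd <- .molgraph_hydrogens(g)
  comp <- .molgraph_components(g)
  visited <- logical(n)
  bond_used <- logical(length(g$bond_a1))

  # discovery pass: tree children + ring-closure (back) edges, per component
  children <- vector("list", n)     # list of (atom, bond)
  closures <- vector("list", n)     # list of (partner, bond, open)
  visit_order <- integer(0)
  dfs <- function(a) {
    visited[a] <<- TRUE
    visit_order <<- c(visit_order, a)
    nb <- adj[[a]]
    ord <- order(priority[nb$nbr])
    for (k in ord) {
      v <- nb$nbr[k]; b <- nb$bond[k]
      if (bond_used[b]) next
      bond_used[b] <<- TRUE
      if (visited[v]) {
        closures[[v]] <<- c(closures[[v]], list(list(partner = a, bond = b, open = TRUE)))
        closures[[a]] <<- c(closures[[a]], list(list(partner = v, bond = b, open = FALSE)))
      } else {
        children[[a]] <<- c(children[[a]], list(list(atom = v, bond = b)))
        dfs(v)
      }
    }
  }
  roots <- integer(0)
  for (cid in seq_len(max(comp))) {
    members <- which(comp == cid)
    roots <- c(roots, members[which.min(priority[members])])
  }
  roots <- roots[order(vapply(roots, function(r) priority[r], numeric(1)))]
  for (r in roots) if (!visited[r]) dfs(r)

  # digit assignment in emission (pre)order
  pos <- match(seq_len(n), visit_order)
  digit_of_bond <- integer(length(g$bond_a1))
  free <- rep(TRUE, 99L)
  for (a in visit_order) {
    for (cl in closures[[a]]) {
      if (cl$open) {
        d <- which(free)[1]
        free[d] <- FALSE
        digit_of_bond[cl$bond] <- d
      } else {
        free[digit_of_bond[cl$bond]] <- TRUE
      }
    }
  }

  emit <- function(a) {
    out <- .atom_token(g, a, bsum, hyd)
    cls <- closures[[a]]
    if (length(cls)) {
      ord <- order(vapply(cls, function(cl) pos[cl$partner], numeric(1)))
      for (cl in cls[ord]) {
        sym <- if (cl$open) "" else .bond_token(g, cl$bond)
        out <- paste0(out, sym, .closure_label(digit_of_bond[cl$bond]))
      }
    }
    ch <- children[[a]]
    if (length(ch)) {
      for (k in seq_along(ch)) {
        sub <- paste0(.bond_token(g, ch[[k]]$bond), emit(ch[[k]]$atom))
        out <- if (k < length(ch)) paste0(out, "(", sub, ")") else paste0(out, sub)
      }
    }
    out
  }
  paste(vapply(roots, emit, character(1)), collapse = ".")
}

## ---- exported operations --------------------------------------------------

#' Canonicalize a SMILES string
#'
#' Produces this package's deterministic canonical form: all SMILES strings
#' of the same molecule (same graph, same aromatic/kekule style) map to one
#' unique string, and the function is idempotent.  Canonical strings are the
#' molecule-identity keys used throughout cleaning, overlap removal and
#' attribution alignment.
#'
#' @param smiles a single SMILES string.
#' @return the canonical SMILES string.
#' @examples
#' canonicalSmiles("OCC")
#' canonicalSmiles("C(O)C")  # same molecule, same output
#' @export
canonicalSmiles <- function(smiles) {
  .canonicalize_graph(parseSmiles(smiles))$smiles
}

#' Canonical atom ranks of a SMILES string
#'
#' For each heavy atom, in the order atoms appear in \emph{this} string,
#' returns its (1-based) position in the molecule's canonical atom order,
#' i.e. the order atoms appear in \code{\link{canonicalSmiles}} output.
#' Ranks form a bijection onto \code{1..A} and are identical for every
#' SMILES of the same molecule, which is what makes attributions from
#' different enumerations comparable atom by atom.
#'
#' @param smiles a single SMILES string.
#' @return integer vector of length A (heavy atoms), a permutation of 1..A.
#' @examples
#' canonicalAtomRanks("OCC")
#' canonicalAtomRanks("CCO")
#' @export
canonicalAtomRanks <- function(smiles) {
  g <- parseSmiles(smiles)
  res <- .canonicalize_graph(g)
  # emission order under the resolved priority
  order <- .emission_order(g, res$priority)
  match(seq_len(.molgraph_natoms(g)), order)
}

## emission (pre)order for a complete priority; mirrors writeSmilesGraph
.emission_order <- function(g, priority) {
  n <- .molgraph_natoms(g)
  adj <- .molgraph_adjacency(g)
  comp <- .molgraph_components(g)
  visited <- logical(n)
  bond_used <- logical(length(g$bond_a1))
  ord_out <- integer(0)
  dfs <- function(a) {
    visited[a] <<- TRUE
    ord_out <<- c(ord_out, a)
    nb <- adj[[a]]
    for (k in order(priority[nb$nbr])) {
      v <- nb$nbr[k]; b <- nb$bond[k]
      if (bond_used[b]) next
      bond_used[b] <<- TRUE
      if (!visited[v]) dfs(v)
    }
  }
  roots <- integer(0)
  for (cid in seq_len(max(comp))) {
    members <- which(comp == cid)
    roots <- c(roots, members[which.min(priority[members])])
  }
  for (r in roots[order(vapply(roots, function(r) priority[r], numeric(1)))])
    if (!visited[r]) dfs(r)
  ord_out
}

#' Enumerate randomized SMILES of a molecule
#'
#' Generates \code{n} alternative SMILES strings by permuting the atom
#' traversal order, the test-time-augmentation unit of this package.  Every
#' output canonicalizes back to \code{canonicalSmiles(smiles)}; duplicates
#' are allowed for molecules that admit few distinct strings.
#'
#' @param smiles a single valid SMILES string.
#' @param n number of randomized strings (>= 1).
#' @param seed integer seed; the output is deterministic under it.
#' @param max_chars resample strings longer than this many characters
#'   (default 175, the model's maximum sequence length); if a molecule
#'   cannot fit, the shortest attempt is kept and flagged via the
#'   \code{"overlength"} attribute.
#' @return character vector of length \code{n}.
#' @examples
#' enumerateSmiles("O=C=O", n = 3, seed = 1)
#' @export
enumerateSmiles <- function(smiles, n, seed = NULL, max_chars = 175L) {
  if (!is.numeric(n) || length(n) != 1L || n < 1L) .stopf("n must be >= 1")
  n <- as.integer(n)
  g <- parseSmiles(smiles)
  natoms <- .molgraph_natoms(g)
  .with_seed(seed, {
    out <- character(n)
    over <- logical(n)
    for (k in seq_len(n)) {
      best <- NULL
      for (try in 1:10) {
        s <- writeSmilesGraph(g, sample.int(natoms))
        if (is.null(best) || nchar(s) < nchar(best)) best <- s
        if (nchar(s) <= max_chars) { best <- s; break }
      }
      out[k] <- best
      over[k] <- nchar(best) > max_chars
    }
    if (any(over)) attr(out, "overlength") <- which(over)
    out
  })
}
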