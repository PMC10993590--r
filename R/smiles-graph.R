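## Molecular graphs parsed from a restricted SMILES dialect.
##
## The dialect covers the chemistry this package works with after cleaning:
## organic-subset atoms (B C N O P S F Cl Br I), their aromatic forms
## (b c n o s p), bracket atoms with explicit hydrogen count and formal
## charge, bond orders - = # :, branches, ring-bond closures (1-9, %nn) and
## dot-separated fragments.  Stereo markers (/ \ @ @@) are accepted on input
## and dropped, matching the cleaning contract; isotope labels are accepted
## and retained.

ORGANIC_SUBSET <- c("B", "C", "N", "O", "P", "S", "F", "Cl", "Br", "I")
AROMATIC_SYMBOLS <- c("b", "c", "n", "o", "p", "s")

## default valences used for implicit-hydrogen bookkeeping; multi-valent
## elements list alternatives in increasing order
DEFAULT_VALENCE <- list(
  B = 3L, C = 4L, N = c(3L, 5L), O = 2L, P = c(3L, 5L),
  S = c(2L, 4L, 6L), F = 1L, Cl = 1L, Br = 1L, I = 1L
)

.new_molgraph <- function() {
  list(
    element  = character(0),
    aromatic = logical(0),
    charge   = integer(0),
    hcount   = integer(0),   # NA_integer_ = implicit (computed on demand)
    isotope  = integer(0),   # NA_integer_ = none
    bond_a1  = integer(0),
    bond_a2  = integer(0),
    bond_order = integer(0), # 1, 2, 3; aromatic bonds carry order 1
    bond_aromatic = logical(0)
  )
}

.molgraph_add_atom <- function(g, element, aromatic = FALSE, charge = 0L,
                               hcount = NA_integer_, isotope = NA_integer_) {
  g$element  <- c(g$element, element)
  g$aromatic <- c(g$aromatic, aromatic)
  g$charge   <- c(g$charge, as.integer(charge))
  g$hcount   <- c(g$hcount, as.integer(hcount))
  g$isotope  <- c(g$isotope, as.integer(isotope))
  g
}

.molgraph_add_bond <- function(g, a1, a2, order = 1L, aromatic = FALSE) {
  g$bond_a1 <- c(g$bond_a1, as.integer(a1))
  g$bond_a2 <- c(g$bond_a2, as.integer(a2))
  g$bond_order <- c(g$bond_order, as.integer(order))
  g$bond_aromatic <- c(g$bond_aromatic, aromatic)
  g
}

.molgraph_natoms <- function(g) length(g$element)

## adjacency as a list of data.frames (nbr, order, aromatic)
.molgraph_adjacency <- function(g) {
  n <- .molgraph_natoms(g)
  adj <- vector("list", n)
  for (i in seq_len(n)) adj[[i]] <- list(nbr = integer(0), order = integer(0),
                                         aromatic = logical(0), bond = integer(0))
  for (b in seq_along(g$bond_a1)) {
    a1 <- g$bond_a1[b]; a2 <- g$bond_a2[b]
    adj[[a1]]$nbr <- c(adj[[a1]]$nbr, a2)
    adj[[a1]]$order <- c(adj[[a1]]$order, g$bond_order[b])
    adj[[a1]]$aromatic <- c(adj[[a1]]$aromatic, g$bond_aromatic[b])
    adj[[a1]]$bond <- c(adj[[a1]]$bond, b)
    adj[[a2]]$nbr <- c(adj[[a2]]$nbr, a1)
    adj[[a2]]$order <- c(adj[[a2]]$order, g$bond_order[b])
    adj[[a2]]$aromatic <- c(adj[[a2]]$aromatic, g$bond_aromatic[b])
    adj[[a2]]$bond <- c(adj[[a2]]$bond, b)
  }
  adj
}

.invalid_structure <- function(smiles, why) {
  stop(sprintf("invalid structure '%s': %s", smiles, why), call. = FALSE)
}

## ---- parsing --------------------------------------------------------------

.parse_bracket_atom <- function(body, smiles) {
  # body is the text between [ and ]
  rest <- body
  isotope <- NA_integer_
  m <- regmatches(rest, regexpr("^[0-9]+", rest))
  if (length(m) && nzchar(m)) {
    isotope <- as.integer(m)
    rest <- substring(rest, nchar(m) + 1L)
  }
  m <- regmatches(rest, regexpr("^([A-Z][a-z]?|[a-z])", rest))
  if (!length(m) || !nzchar(m))
    .invalid_structure(smiles, sprintf("bracket atom '[%s]' has no element symbol", body))
  sym <- m
  rest <- substring(rest, nchar(sym) + 1L)
  aromatic <- sym %in% AROMATIC_SYMBOLS
  element <- if (aromatic) toupper(sym) else sym
  # drop chirality
  rest <- sub("^@@?", "", rest)
  hcount <- 0L
  m <- regmatches(rest, regexpr("^H[0-9]*", rest))
  if (length(m) && nzchar(m)) {
    hcount <- if (nchar(m) == 1L) 1L else as.integer(substring(m, 2L))
    rest <- substring(rest, nchar(m) + 1L)
  }
  charge <- 0L
  m <- regmatches(rest, regexpr("^(\\+[0-9]+|-[0-9]+|\\++|-+)", rest))
  if (length(m) && nzchar(m)) {
    if (grepl("^[+-][0-9]", m)) {
      charge <- as.integer(m)
    } else {
      charge <- nchar(m) * if (substring(m, 1L, 1L) == "+") 1L else -1L
    }
    rest <- substring(rest, nchar(m) + 1L)
  }
  rest <- sub("^:[0-9]+", "", rest)  # atom maps dropped
  if (nzchar(rest))
    .invalid_structure(smiles, sprintf("unparsed bracket content '%s' in '[%s]'", rest, body))
  list(element = element, aromatic = aromatic, charge = charge,
       hcount = hcount, isotope = isotope)
}

#' Parse a SMILES string into a molecular graph
#'
#' Internal workhorse behind canonicalization, enumeration, alert matching
#' and the fixture generator.  Atoms are indexed in order of appearance in
#' the string, which is the numbering every downstream atom-index contract
#' refers to.
#'
#' @param smiles a single SMILES string.
#' @return a molgraph list (atoms + bonds), with atoms in string order.
#' @keywords internal
parseSmiles <- function(smiles) {
  if (!is.character(smiles) || length(smiles) != 1L || is.na(smiles) || !nzchar(smiles))
    .invalid_structure(as.character(smiles)[1], "empty or non-string input")
  g <- .new_molgraph()
  chars <- strsplit(smiles, "", fixed = TRUE)[[1]]
  n <- length(chars)
  i <- 1L
  prev <- 0L                 # previous atom index, 0 = none (fragment start)
  stack <- integer(0)        # branch stack
  pending_bond <- NA_integer_   # bond order forced by symbol, NA = default
  ring <- list()             # closure label -> list(atom, order)
  while (i <= n) {
    ch <- chars[i]
    if (ch %in% c("/", "\\")) { # stereo bond -> plain single
      pending_bond <- 1L; i <- i + 1L; next
    }
    if (ch == "-") { pending_bond <- 1L; i <- i + 1L; next }
    if (ch == "=") { pending_bond <- 2L; i <- i + 1L; next }
    if (ch == "#") { pending_bond <- 3L; i <- i + 1L; next }
    if (ch == ":") { pending_bond <- 4L; i <- i + 1L; next }  # 4 = aromatic
    if (ch == "(") {
      if (prev == 0L) .invalid_structure(smiles, "branch opened before any atom")
      stack <- c(stack, prev); i <- i + 1L; next
    }
    if (ch == ")") {
      if (!length(stack)) .invalid_structure(smiles, "unmatched ')'")
      prev <- stack[length(stack)]; stack <- stack[-length(stack)]
      i <- i + 1L; next
    }
    if (ch == ".") {
      if (!is.na(pending_bond)) .invalid_structure(smiles, "bond before '.'")
      prev <- 0L; i <- i + 1L; next
    }
    if (grepl("^[0-9%]$", ch)) {
      if (ch == "%") {
        if (i + 2L > n || !grepl("^[0-9][0-9]$", paste0(chars[i + 1L], chars[i + 2L])))
          .invalid_structure(smiles, "'%' ring label needs two digits")
        lab <- paste0("%", chars[i + 1L], chars[i + 2L]); i <- i + 3L
      } else {
        lab <- ch; i <- i + 1L
      }
      if (prev == 0L) .invalid_structure(smiles, "ring closure before any atom")
      if (is.null(ring[[lab]])) {
        ring[[lab]] <- list(atom = prev, order = pending_bond)
      } else {
        other <- ring[[lab]]
        ord <- if (!is.na(pending_bond)) pending_bond
               else if (!is.na(other$order)) other$order
               else NA_integer_
        arom <- FALSE
        if (is.na(ord)) {
          arom <- g$aromatic[other$atom] && g$aromatic[prev]
          ord <- 1L
        } else if (ord == 4L) { arom <- TRUE; ord <- 1L }
        if (other$atom == prev) .invalid_structure(smiles, "ring bond to self")
        g <- .molgraph_add_bond(g, other$atom, prev, ord, arom)
        ring[[lab]] <- NULL
      }
      pending_bond <- NA_integer_
      next
    }
    # atoms
    atom <- NULL
    if (ch == "[") {
      j <- i + 1L
      while (j <= n && chars[j] != "]") j <- j + 1L
      if (j > n) .invalid_structure(smiles, "unclosed '['")
      atom <- .parse_bracket_atom(paste(chars[(i + 1L):(j - 1L)], collapse = ""), smiles)
      i <- j + 1L
    } else if (ch %in% c("C", "B") && i < n && chars[i + 1L] %in% c("l", "r")) {
      two <- paste0(ch, chars[i + 1L])
      if (two %in% c("Cl", "Br")) {
        atom <- list(element = two, aromatic = FALSE, charge = 0L,
                     hcount = NA_integer_, isotope = NA_integer_)
        i <- i + 2L
      }
    }
    if (is.null(atom)) {
      if (ch %in% ORGANIC_SUBSET) {
        atom <- list(element = ch, aromatic = FALSE, charge = 0L,
                     hcount = NA_integer_, isotope = NA_integer_)
        i <- i + 1L
      } else if (ch %in% AROMATIC_SYMBOLS) {
        atom <- list(element = toupper(ch), aromatic = TRUE, charge = 0L,
                     hcount = NA_integer_, isotope = NA_integer_)
        i <- i + 1L
      } else {
        .invalid_structure(smiles, sprintf("unexpected character '%s' at position %d", ch, i))
      }
    }
    g <- .molgraph_add_atom(g, atom$element, atom$aromatic, atom$charge,
                            atom$hcount, atom$isotope)
    this <- .molgraph_natoms(g)
    if (prev != 0L) {
      ord <- pending_bond
      arom <- FALSE
      if (is.na(ord)) {
        arom <- g$aromatic[prev] && g$aromatic[this]
        ord <- 1L
      } else if (ord == 4L) { arom <- TRUE; ord <- 1L }
      g <- .molgraph_add_bond(g, prev, this, ord, arom)
    }
    pending_bond <- NA_integer_
    prev <- this
  }
  if (length(stack)) .invalid_structure(smiles, "unmatched '('")
  if (length(ring)) .invalid_structure(smiles, "unclosed ring bond")
  if (!is.na(pending_bond)) .invalid_structure(smiles, "dangling bond symbol")
  if (.molgraph_natoms(g) == 0L) .invalid_structure(smiles, "no atoms")
  .molgraph_check_valence(g, smiles)
  g
}

## bond-order sum per atom; aromatic bonds count 1 each plus one extra unit
## for participating in an aromatic system (benzene carbon: 2 + 1 = 3)
.molgraph_bondsum <- function(g) {
  n <- .molgraph_natoms(g)
  s <- numeric(n)
  for (b in seq_along(g$bond_a1)) {
    o <- if (g$bond_aromatic[b]) 1L else g$bond_order[b]
    s[g$bond_a1[b]] <- s[g$bond_a1[b]] + o
    s[g$bond_a2[b]] <- s[g$bond_a2[b]] + o
  }
  s + as.numeric(g$aromatic)
}

## implicit hydrogen counts (explicit bracket counts honoured verbatim)
.molgraph_hydrogens <- function(g) {
  s <- .molgraph_bondsum(g)
  n <- .molgraph_natoms(g)
  h <- integer(n)
  for (i in seq_len(n)) {
    if (!is.na(g$hcount[i])) { h[i] <- g$hcount[i]; next }
    val <- DEFAULT_VALENCE[[g$element[i]]]
    if (is.null(val)) { h[i] <- 0L; next }
    # simple charge adjustment: +1 raises capacity by 1, -1 lowers it by 1
    cap <- val + g$charge[i]
    cap <- cap[cap >= s[i]]
    h[i] <- if (length(cap)) as.integer(ceiling(cap[1] - s[i])) else 0L
  }
  h
}

.molgraph_check_valence <- function(g, smiles) {
  s <- .molgraph_bondsum(g)
  for (i in seq_len(.molgraph_natoms(g))) {
    val <- DEFAULT_VALENCE[[g$element[i]]]
    if (is.null(val)) next
    cap <- max(val) + abs(g$charge[i]) + (if (!is.na(g$hcount[i])) g$hcount[i] else 0L)
    if (s[i] > cap + 1e-9)
      .invalid_structure(smiles,
        sprintf("atom %d (%s) exceeds valence (bond order sum %.1f)", i, g$element[i], s[i]))
  }
  invisible(TRUE)
}

## connected components, in atom-index order
.molgraph_components <- function(g) {
  n <- .molgraph_natoms(g)
  adj <- .molgraph_adjacency(g)
  comp <- integer(n)
  k <- 0L
  for (start in seq_len(n)) {
    if (comp[start] != 0L) next
    k <- k + 1L
    queue <- start
    comp[start] <- k
    while (length(queue)) {
      a <- queue[1]; queue <- queue[-1]
      for (nb in adj[[a]]$nbr) if (comp[nb] == 0L) { comp[nb] <- k; queue <- c(queue, nb) }
    }
  }
  comp
}

## ring membership per atom (atoms on any cycle), via bond-bridge detection
.molgraph_in_ring <- function(g) {
  n <- .molgraph_natoms(g)
  nb <- length(g$bond_a1)
  if (nb == 0L) return(logical(n))
  adj <- .molgraph_adjacency(g)
  # iterated DFS bridge finding (Tarjan)
  disc <- integer(n); low <- integer(n); timer <- 0L
  bridge <- logical(nb)
  parent_bond <- integer(n)
  for (root in seq_len(n)) {
    if (disc[root] != 0L) next
    stack <- list(list(a = root, pi = 0L, pb = 0L))
    while (length(stack)) {
      fr <- stack[[length(stack)]]
      a <- fr$a
      if (fr$pi == 0L) { timer <- timer + 1L; disc[a] <- low[a] <- timer }
      if (fr$pi < length(adj[[a]]$nbr)) {
        stack[[length(stack)]]$pi <- fr$pi + 1L
        idx <- fr$pi + 1L
        v <- adj[[a]]$nbr[idx]; bidx <- adj[[a]]$bond[idx]
        if (bidx == fr$pb) next
        if (disc[v] == 0L) {
          stack[[length(stack) + 1L]] <- list(a = v, pi = 0L, pb = bidx)
        } else {
          low[a] <- min(low[a], disc[v])
        }
      } else {
        stack[[length(stack)]] <- NULL
        if (length(stack)) {
          p <- stack[[length(stack)]]$a
          low[p] <- min(low[p], low[a])
          if (low[a] > disc[p]) bridge[fr$pb] <- TRUE
        }
      }
    }
  }
  inring <- logical(n)
  for (b in seq_len(nb)) {
    if (!bridge[b]) { inring[g$bond_a1[b]] <- TRUE; inring[g$bond_a2[b]] <- TRUE }
  }
  # degree-1 atoms can never be in a ring even if flagged via shared bond scan
  deg <- tabulate(c(g$bond_a1, g$bond_a2), nbins = n)
  inring & deg >= 2L
}

.molgraph_formula_counts <- function(g) {
  tab <- table(g$element)
  h <- sum(.molgraph_hydrogens(g))
  out <- as.integer(tab); names(out) <- names(tab)
  c(out, H = h)
}
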