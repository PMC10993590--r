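## Structural-alert (toxicophore) matching.
##
## Alerts are SMARTS patterns; this module compiles a restricted but
## well-defined SMARTS subset into pattern graphs and matches them by
## backtracking subgraph isomorphism, returning heavy-atom indices in the
## numbering of the query SMILES string (the numbering the attribution
## layer uses).  Supported primitives: element symbols (aromatic lowercase
## included), wildcards * / A / a, atomic number #n, charge, Hn (total
## hydrogen count), Xn (total connectivity), Dn (explicit degree), R / R0
## (ring membership), '!' negation, ',' alternation and '&'/';'/implicit
## conjunction inside brackets; bonds - = # : ~ and default
## single-or-aromatic; branches and ring closures.  Recursive SMARTS is not
## supported and raises a compile error.

## ---- SMARTS compilation ---------------------------------------------------

.smarts_primitive <- function(txt, smarts) {
  # returns list(field, value) for one primitive, input already '!'-stripped
  if (txt == "*") return(list(kind = "any"))
  if (txt == "a") return(list(kind = "aromatic", value = TRUE))
  if (txt == "A") return(list(kind = "aromatic", value = FALSE))
  if (grepl("^#[0-9]+$", txt))
    return(list(kind = "elemnum", value = as.integer(substring(txt, 2L))))
  if (grepl("^H[0-9]*$", txt))
    return(list(kind = "hcount",
                value = if (nchar(txt) == 1L) 1L else as.integer(substring(txt, 2L))))
  if (grepl("^X[0-9]+$", txt))
    return(list(kind = "connect", value = as.integer(substring(txt, 2L))))
  if (grepl("^D[0-9]+$", txt))
    return(list(kind = "degree", value = as.integer(substring(txt, 2L))))
  if (txt == "R") return(list(kind = "ring", value = TRUE))
  if (txt == "R0") return(list(kind = "ring", value = FALSE))
  if (grepl("^(\\+[0-9]*|-[0-9]*)$", txt)) {
    sign <- if (substring(txt, 1L, 1L) == "+") 1L else -1L
    mag <- substring(txt, 2L)
    return(list(kind = "charge", value = sign * (if (nzchar(mag)) as.integer(mag) else 1L)))
  }
  if (grepl("^[A-Z][a-z]?$", txt) && txt %in% names(ELEMENT_NUMBERS))
    return(list(kind = "element", value = txt, aromatic = FALSE))
  if (grepl("^[a-z]$", txt) && toupper(txt) %in% names(ELEMENT_NUMBERS))
    return(list(kind = "element", value = toupper(txt), aromatic = TRUE))
  .stopf("SMARTS '%s': unsupported primitive '%s'", smarts, txt)
}

ELEMENT_NUMBERS <- c(B = 5L, C = 6L, N = 7L, O = 8L, F = 9L, P = 15L,
                     S = 16L, Cl = 17L, Br = 35L, I = 53L)

## parse the inside of a bracket expression into an OR of ANDs of
## (negated) primitives
.smarts_bracket_expr <- function(body, smarts) {
  if (grepl("\\$", body)) .stopf("SMARTS '%s': recursive SMARTS not supported", smarts)
  ors <- strsplit(body, ",", fixed = TRUE)[[1]]
  lapply(ors, function(conj) {
    txt <- gsub("&", ";", conj, fixed = TRUE)
    parts <- if (grepl(";", txt, fixed = TRUE))
      strsplit(txt, ";", fixed = TRUE)[[1]] else txt
    prims <- list()
    for (p in parts) {
      # juxtaposed primitives within one part, e.g. "NH2" or "!C"
      rest <- p
      while (nzchar(rest)) {
        neg <- FALSE
        if (substring(rest, 1L, 1L) == "!") { neg <- TRUE; rest <- substring(rest, 2L) }
        m <- regmatches(rest, regexpr(
          "^(#[0-9]+|R0|R|H[0-9]*|X[0-9]+|D[0-9]+|\\+[0-9]*|-[0-9]*|[A-Z][a-z]|[A-Za-z]|\\*)",
          rest))
        if (!length(m) || !nzchar(m))
          .stopf("SMARTS '%s': cannot parse '%s'", smarts, rest)
        # prefer one-letter element if two-letter is not a known element
        if (nchar(m) == 2L && grepl("^[A-Z][a-z]$", m) &&
            !(m %in% names(ELEMENT_NUMBERS)))
          m <- substring(m, 1L, 1L)
        pr <- .smarts_primitive(m, smarts)
        pr$neg <- neg
        prims[[length(prims) + 1L]] <- pr
        rest <- substring(rest, nchar(m) + (if (neg) 0L else 0L) + 1L)
      }
    }
    prims
  })
}

## scan a SMARTS string into structural tokens mirroring the SMILES parser
.compile_smarts <- function(smarts) {
  if (grepl("\\$\\(", smarts)) .stopf("SMARTS '%s': recursive SMARTS not supported", smarts)
  chars <- strsplit(smarts, "", fixed = TRUE)[[1]]
  n <- length(chars)
  atoms <- list()       # each: list of OR-of-AND primitive lists
  bond_a1 <- integer(0); bond_a2 <- integer(0); bond_type <- character(0)
  i <- 1L; prev <- 0L; stack <- integer(0)
  pending <- NA_character_
  ring <- list()
  add_atom <- function(expr) {
    atoms[[length(atoms) + 1L]] <<- expr
    this <- length(atoms)
    if (prev != 0L) {
      bond_a1 <<- c(bond_a1, prev); bond_a2 <<- c(bond_a2, this)
      bond_type <<- c(bond_type, if (is.na(pending)) "default" else pending)
    }
    pending <<- NA_character_
    prev <<- this
  }
  while (i <= n) {
    ch <- chars[i]
    if (ch %in% c("-", "=", "#", ":", "~")) {
      pending <- switch(ch, "-" = "single", "=" = "double", "#" = "triple",
                        ":" = "aromatic", "~" = "any")
      i <- i + 1L; next
    }
    if (ch == "(") { stack <- c(stack, prev); i <- i + 1L; next }
    if (ch == ")") {
      if (!length(stack)) .stopf("SMARTS '%s': unmatched ')'", smarts)
      prev <- stack[length(stack)]; stack <- stack[-length(stack)]
      i <- i + 1L; next
    }
    if (grepl("^[0-9]$", ch)) {
      lab <- ch
      if (is.null(ring[[lab]])) {
        ring[[lab]] <- list(atom = prev, type = pending)
      } else {
        other <- ring[[lab]]
        ty <- if (!is.na(pending)) pending
              else if (!is.na(other$type)) other$type else "default"
        bond_a1 <- c(bond_a1, other$atom); bond_a2 <- c(bond_a2, prev)
        bond_type <- c(bond_type, ty)
        ring[[lab]] <- NULL
      }
      pending <- NA_character_
      i <- i + 1L; next
    }
    if (ch == "[") {
      j <- i
      while (j <= n && chars[j] != "]") j <- j + 1L
      if (j > n) .stopf("SMARTS '%s': unclosed '['", smarts)
      add_atom(.smarts_bracket_expr(paste(chars[(i + 1L):(j - 1L)], collapse = ""), smarts))
      i <- j + 1L; next
    }
    # bare atom tokens
    if (ch %in% c("C", "B") && i < n && paste0(ch, chars[i + 1L]) %in% c("Cl", "Br")) {
      add_atom(list(list(list(kind = "element", value = paste0(ch, chars[i + 1L]),
                              aromatic = FALSE, neg = FALSE))))
      i <- i + 2L; next
    }
    if (ch %in% c(names(ELEMENT_NUMBERS), "*", "a", "A") ||
        ch %in% tolower(names(ELEMENT_NUMBERS)[nchar(names(ELEMENT_NUMBERS)) == 1L])) {
      pr <- .smarts_primitive(ch, smarts)
      pr$neg <- FALSE
      add_atom(list(list(pr)))
      i <- i + 1L; next
    }
    .stopf("SMARTS '%s': unexpected character '%s'", smarts, ch)
  }
  if (length(stack)) .stopf("SMARTS '%s': unmatched '('", smarts)
  if (length(ring)) .stopf("SMARTS '%s': unclosed ring bond", smarts)
  if (!length(atoms)) .stopf("SMARTS '%s': no atoms", smarts)
  list(atoms = atoms, bond_a1 = bond_a1, bond_a2 = bond_a2, bond_type = bond_type)
}

## ---- matching -------------------------------------------------------------

.atom_matches <- function(expr, ctx, i) {
  for (conj in expr) {
    ok <- TRUE
    for (pr in conj) {
      val <- switch(pr$kind,
        any      = TRUE,
        aromatic = ctx$aromatic[i] == pr$value,
        elemnum  = ELEMENT_NUMBERS[[ctx$element[i]]] == pr$value,
        element  = ctx$element[i] == pr$value &&
                   (is.null(pr$aromatic) || ctx$aromatic[i] == pr$aromatic),
        hcount   = ctx$h[i] == pr$value,
        connect  = ctx$deg[i] + ctx$h[i] == pr$value,
        degree   = ctx$deg[i] == pr$value,
        ring     = ctx$inring[i] == pr$value,
        charge   = ctx$charge[i] == pr$value,
        FALSE)
      if (isTRUE(pr$neg)) val <- !val
      if (!val) { ok <- FALSE; break }
    }
    if (ok) return(TRUE)
  }
  FALSE
}

.bond_matches <- function(type, order, aromatic) {
  switch(type,
    any      = TRUE,
    default  = (order == 1L && !aromatic) || aromatic,
    single   = order == 1L && !aromatic,
    double   = order == 2L && !aromatic,
    triple   = order == 3L,
    aromatic = aromatic,
    FALSE)
}

.match_pattern <- function(pat, g) {
  n <- .molgraph_natoms(g)
  ctx <- list(element = g$element, aromatic = g$aromatic, charge = g$charge,
              h = .molgraph_hydrogens(g), inring = .molgraph_in_ring(g),
              deg = tabulate(c(g$bond_a1, g$bond_a2), nbins = n))
  np <- length(pat$atoms)
  # adjacency of pattern with bond types
  padj <- vector("list", np)
  for (k in seq_len(np)) padj[[k]] <- list(nbr = integer(0), type = character(0))
  for (b in seq_along(pat$bond_a1)) {
    a1 <- pat$bond_a1[b]; a2 <- pat$bond_a2[b]; ty <- pat$bond_type[b]
    padj[[a1]]$nbr <- c(padj[[a1]]$nbr, a2); padj[[a1]]$type <- c(padj[[a1]]$type, ty)
    padj[[a2]]$nbr <- c(padj[[a2]]$nbr, a1); padj[[a2]]$type <- c(padj[[a2]]$type, ty)
  }
  madj <- .molgraph_adjacency(g)
  bond_between <- function(i, j) {
    k <- which(madj[[i]]$nbr == j)
    if (!length(k)) return(NULL)
    list(order = madj[[i]]$order[k[1]], aromatic = madj[[i]]$aromatic[k[1]])
  }
  matches <- list()
  assign_vec <- integer(np)
  used <- logical(n)
  bt <- function(k) {
    if (k > np) {
      matches[[length(matches) + 1L]] <<- assign_vec
      return(invisible(NULL))
    }
    for (cand in seq_len(n)) {
      if (used[cand]) next
      if (!.atom_matches(pat$atoms[[k]], ctx, cand)) next
      ok <- TRUE
      for (e in seq_along(padj[[k]]$nbr)) {
        other <- padj[[k]]$nbr[e]
        if (other >= k) next  # only check edges to already-assigned atoms
        mb <- bond_between(cand, assign_vec[other])
        if (is.null(mb) || !.bond_matches(padj[[k]]$type[e], mb$order, mb$aromatic)) {
          ok <- FALSE; break
        }
      }
      if (!ok) next
      assign_vec[k] <<- cand; used[cand] <<- TRUE
      bt(k + 1L)
      used[cand] <<- FALSE
    }
  }
  bt(1L)
  # unique as unordered atom sets
  if (!length(matches)) return(list())
  key <- vapply(matches, function(m) paste(sort(m), collapse = ","), "")
  matches[!duplicated(key)]
}

## ---- exported interface ---------------------------------------------------

#' Compile an alert set from names and SMARTS patterns
#'
#' @param name character vector of unique alert names.
#' @param smarts character vector of SMARTS patterns (restricted subset; see
#'   package vignette).  Every pattern must compile.
#' @return an \linkS4class{AlertSet}.
#' @export
alertSet <- function(name, smarts) {
  compiled <- lapply(seq_along(smarts), function(i) {
    tryCatch(.compile_smarts(smarts[i]), error = function(e)
      .stopf("alert '%s': %s", name[i], conditionMessage(e)))
  })
  new("AlertSet", name = as.character(name), smarts = as.character(smarts),
      compiled = compiled)
}

#' Read an alert set from a TSV file (name TAB smarts)
#'
#' @param path TSV file with two columns: alert name and SMARTS pattern.
#' @return an \linkS4class{AlertSet}.
#' @export
readAlerts <- function(path) {
  df <- utils::read.delim(path, header = TRUE, stringsAsFactors = FALSE,
                          comment.char = "#")
  if (ncol(df) < 2L) .stopf("alert file must have name<TAB>smarts columns")
  alertSet(df[[1]], df[[2]])
}

#' Match structural alerts against a molecule
#'
#' Finds all substructure matches of every alert in the molecule and
#' reports heavy-atom indices in the numbering of \emph{this} SMILES string
#' (atoms in order of appearance), the numbering token attributions use.
#'
#' @param smiles a single valid SMILES string.
#' @param alerts an \linkS4class{AlertSet}.
#' @return list with \code{matches} (named list per matched alert, each a
#'   list of integer atom-index vectors) and \code{atoms} (sorted union of
#'   all matched atom indices).
#' @examples
#' nitro <- alertSet("nitro", "[N+](=O)[O-]")
#' matchAlerts("c1ccc(cc1)[N+](=O)[O-]", nitro)
#' @export
matchAlerts <- function(smiles, alerts) {
  stopifnot(is(alerts, "AlertSet"))
  g <- parseSmiles(smiles)
  out <- list()
  for (i in seq_along(alerts@name)) {
    m <- .match_pattern(alerts@compiled[[i]], g)
    if (length(m)) out[[alerts@name[i]]] <- m
  }
  list(matches = out,
       atoms = as.integer(sort(unique(unlist(out)))))
}
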