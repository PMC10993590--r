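## Molecule ingestion and cleaning: stereo removal, salt stripping,
## canonicalization, duplicate collapse and dataset overlap removal.

## strip stereo annotations textually before parsing; the parser drops any
## that remain inside brackets
.strip_stereo <- function(smiles) {
  s <- gsub("@{1,2}", "", smiles)
  s <- gsub("[/\\\\]", "", s)
  s
}

#' Clean raw SMILES into canonical molecule records
#'
#' Applies the dataset-preparation contract: stereochemistry annotations are
#' removed, the largest organic fragment is kept (salt stripping), the
#' structure is sanitized and canonicalized, and exact duplicate canonical
#' SMILES are collapsed to the first occurrence.  Duplicates whose labels
#' conflict are dropped entirely.  Unparseable inputs are skipped, never
#' fatal; all drops are recorded in the \code{"dropped"} attribute.
#'
#' @param smiles character vector of raw SMILES strings.
#' @param label optional numeric/integer binary labels (toxic = 1).
#' @param id optional record identifiers; defaults to seq position.
#' @param source free-text provenance stored on each record.
#' @return data.frame with columns \code{id}, \code{smiles} (canonical),
#'   \code{label}, \code{source}; attribute \code{"dropped"} is a data.frame
#'   of discarded inputs and reasons.
#' @examples
#' cleanStructures(c("CC(=O)O.[Na+]", "CCO", "OCC", "C("))
#' @export
cleanStructures <- function(smiles, label = NULL, id = NULL, source = "") {
  n <- length(smiles)
  if (!n) .stopf("cleanStructures: no input structures")
  if (is.null(label)) label <- rep(NA_real_, n)
  if (is.null(id)) id <- as.character(seq_len(n))
  stopifnot(length(label) == n, length(id) == n)
  dropped <- list()
  note <- function(s, why) dropped[[length(dropped) + 1L]] <<-
    data.frame(smiles = s, reason = why, stringsAsFactors = FALSE)

  canon <- character(n); ok <- logical(n)
  for (i in seq_len(n)) {
    raw <- smiles[i]
    if (is.na(raw) || !nzchar(raw)) { note(as.character(raw), "empty input"); next }
    res <- tryCatch({
      frag <- .largest_organic_fragment(.strip_stereo(raw))
      canonicalSmiles(frag)
    }, error = function(e) e)
    if (inherits(res, "error")) { note(raw, conditionMessage(res)); next }
    canon[i] <- res; ok[i] <- TRUE
  }

  out <- data.frame(id = id[ok], smiles = canon[ok], label = label[ok],
                    source = source, stringsAsFactors = FALSE)
  # duplicate collapse (first occurrence wins), label-conflict drop
  if (nrow(out)) {
    drop <- logical(nrow(out))
    for (s in unique(out$smiles[duplicated(out$smiles)])) {
      idx <- which(out$smiles == s)
      labs <- unique(out$label[idx][!is.na(out$label[idx])])
      if (length(labs) > 1L) {
        drop[idx] <- TRUE
        note(s, "conflicting labels among duplicates")
      } else {
        drop[idx[-1L]] <- TRUE
        if (length(labs) == 1L) out$label[idx[1L]] <- labs
      }
    }
    out <- out[!drop, , drop = FALSE]
    rownames(out) <- NULL
  }
  attr(out, "dropped") <- if (length(dropped)) do.call(rbind, dropped)
    else data.frame(smiles = character(0), reason = character(0))
  out
}

## keep the largest fragment that contains carbon (falling back to the
## largest fragment of any kind); ties broken by canonical SMILES order
.largest_organic_fragment <- function(smiles) {
  frags <- strsplit(smiles, ".", fixed = TRUE)[[1]]
  frags <- frags[nzchar(frags)]
  if (!length(frags)) .stopf("empty structure")
  if (length(frags) == 1L) return(frags)
  info <- lapply(frags, function(f) {
    g <- parseSmiles(f)
    list(natoms = .molgraph_natoms(g), carbon = any(g$element == "C"))
  })
  natoms <- vapply(info, `[[`, 0L, "natoms")
  carbon <- vapply(info, `[[`, TRUE, "carbon")
  pool <- if (any(carbon)) which(carbon) else seq_along(frags)
  pool <- pool[natoms[pool] == max(natoms[pool])]
  if (length(pool) > 1L) {
    cs <- vapply(frags[pool], canonicalSmiles, "")
    pool <- pool[order(cs)][1L]
  }
  frags[pool]
}

#' Remove records of one dataset that occur in another
#'
#' Returns \code{b} minus all records whose canonical SMILES occur in
#' \code{a} (both cleaned first if not already canonical keys).  Used to
#' remove pre-training/fine-tuning overlap between corpora.
#'
#' @param a,b cleaned molecule data.frames (as from
#'   \code{\link{cleanStructures}}).
#' @return \code{b} without the overlapping records.
#' @export
removeOverlap <- function(a, b) {
  stopifnot(is.data.frame(a), is.data.frame(b), "smiles" %in% names(a),
            "smiles" %in% names(b))
  out <- b[!(b$smiles %in% a$smiles), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Read molecules from a CSV or .smi file
#'
#' CSV files need a \code{smiles} column and may carry \code{label} and
#' \code{id} columns; \code{.smi} files hold one SMILES per line with an
#' optional whitespace-separated id.
#'
#' @param path file path.
#' @return data.frame with columns \code{smiles}, \code{label}, \code{id}.
#' @export
readSmilesFile <- function(path) {
  if (!file.exists(path)) .stopf("no such file: %s", path)
  if (grepl("\\.smi$", path, ignore.case = TRUE)) {
    lines <- readLines(path, warn = FALSE)
    lines <- lines[nzchar(trimws(lines))]
    parts <- strsplit(trimws(lines), "[ \t]+")
    data.frame(smiles = vapply(parts, `[[`, "", 1L),
               label = NA_real_,
               id = vapply(seq_along(parts), function(i)
                 if (length(parts[[i]]) > 1L) parts[[i]][2L] else as.character(i), ""),
               stringsAsFactors = FALSE)
  } else {
    df <- utils::read.csv(path, stringsAsFactors = FALSE)
    if (!"smiles" %in% names(df)) .stopf("CSV must have a 'smiles' column")
    data.frame(smiles = df$smiles,
               label = if ("label" %in% names(df)) as.numeric(df$label) else NA_real_,
               id = if ("id" %in% names(df)) as.character(df$id)
                    else as.character(seq_len(nrow(df))),
               stringsAsFactors = FALSE)
  }
}

#' Number of heavy atoms of a SMILES string
#' @param smiles a single SMILES string.
#' @return integer heavy-atom count.
#' @export
heavyAtomCount <- function(smiles) .molgraph_natoms(parseSmiles(smiles))

#' Number of carbon atoms of a SMILES string
#' @param smiles a single SMILES string.
#' @return integer carbon count.
#' @export
carbonCount <- function(smiles) sum(parseSmiles(smiles)$element == "C")
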