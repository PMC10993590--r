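## Statistical comparison utilities: Mann-Whitney U with exact small-sample
## p-values, test-time bootstrapping of classification metrics, and the
## carbon-count dependence diagnostic.

#' Mann-Whitney U test
#'
#' Rank-sum U with midrank tie handling.  For small samples (both groups at
#' most \code{exact_max}) the p-value is exact, computed by enumerating all
#' group assignments of the pooled sample (which remains correct under
#' ties); larger samples use the normal approximation with tie correction
#' and continuity correction.  Two-sided by default.
#'
#' @param popA,popB numeric vectors (each non-empty).
#' @param alternative "two.sided" (default), "less" or "greater"
#'   (\code{popA} shifted below/above \code{popB}).
#' @param exact_max exact-enumeration threshold per group (default 8).
#' @return list with \code{U} (statistic for popA), \code{p}, and
#'   \code{method}.
#' @examples
#' mannWhitneyU(c(1, 2), c(3, 4))
#' @export
mannWhitneyU <- function(popA, popB, alternative = "two.sided", exact_max = 8L) {
  if (!length(popA) || !length(popB)) .stopf("mannWhitneyU: empty population")
  alternative <- match.arg(alternative, c("two.sided", "less", "greater"))
  nA <- length(popA); nB <- length(popB)
  pooled <- c(popA, popB)
  r <- rank(pooled)
  U <- sum(r[seq_len(nA)]) - nA * (nA + 1) / 2
  if (nA <= exact_max && nB <= exact_max) {
    combs <- utils::combn(nA + nB, nA)
    Us <- apply(combs, 2L, function(ix) sum(r[ix])) - nA * (nA + 1) / 2
    p <- switch(alternative,
      two.sided = {
        mu <- nA * nB / 2
        mean(abs(Us - mu) >= abs(U - mu) - 1e-9)
      },
      less = mean(Us <= U + 1e-9),
      greater = mean(Us >= U - 1e-9))
    return(list(U = U, p = min(1, p), method = "exact enumeration"))
  }
  mu <- nA * nB / 2
  ties <- table(pooled)
  tiecor <- sum(ties^3 - ties) / ((nA + nB) * (nA + nB - 1))
  sigma <- sqrt(nA * nB / 12 * (nA + nB + 1 - tiecor))
  if (sigma == 0) return(list(U = U, p = 1, method = "normal approximation"))
  p <- switch(alternative,
    two.sided = min(1, 2 * stats::pnorm(-max((abs(U - mu) - 0.5) / sigma, 0))),
    less = stats::pnorm((U - mu + 0.5) / sigma),
    greater = stats::pnorm((U - mu - 0.5) / sigma, lower.tail = FALSE))
  list(U = U, p = min(1, p), method = "normal approximation")
}

#' Threshold-based and ranking classification metrics
#'
#' AUROC is the rank statistic (probability a random positive scores above
#' a random negative, ties counted half); the remaining metrics threshold
#' the scores at \code{threshold}.
#'
#' @param scores predicted probabilities of the positive class.
#' @param labels binary labels (0/1), both classes present.
#' @param threshold classification threshold (default 0.5).
#' @return named list: auroc, accuracy, f1, mcc, precision, recall.
#' @export
classificationMetrics <- function(scores, labels, threshold = 0.5) {
  stopifnot(length(scores) == length(labels))
  labels <- as.integer(labels)
  if (length(unique(labels)) < 2L)
    .stopf("classificationMetrics: labels contain a single class")
  pos <- scores[labels == 1L]; neg <- scores[labels == 0L]
  r <- rank(c(pos, neg))
  auroc <- (sum(r[seq_along(pos)]) - length(pos) * (length(pos) + 1) / 2) /
    (length(pos) * length(neg))
  pred <- as.integer(scores >= threshold)
  tp <- sum(pred == 1L & labels == 1L); fp <- sum(pred == 1L & labels == 0L)
  fn <- sum(pred == 0L & labels == 1L); tn <- sum(pred == 0L & labels == 0L)
  prec <- if (tp + fp > 0) tp / (tp + fp) else 0
  rec <- if (tp + fn > 0) tp / (tp + fn) else 0
  f1 <- if (prec + rec > 0) 2 * prec * rec / (prec + rec) else 0
  mcc_den <- sqrt(prod(c(tp + fp, tp + fn, tn + fp, tn + fn)))
  mcc <- if (mcc_den > 0) (tp * tn - fp * fn) / mcc_den else 0
  list(auroc = auroc, accuracy = (tp + tn) / length(labels),
       f1 = f1, mcc = mcc, precision = prec, recall = rec)
}

#' Test-time bootstrap of classification metrics
#'
#' Resamples (score, label) pairs with replacement to the full test length,
#' \code{reps} times, and computes all classification metrics per
#' replicate, giving a variance indication from the single held-out split.
#' Degenerate single-class resamples are redrawn (count reported).
#'
#' @param scores predicted probabilities.
#' @param labels binary labels, both classes present.
#' @param reps replicates (default 1000).
#' @param seed integer seed; replicate vectors are reproducible under it.
#' @param threshold classification threshold.
#' @return list of per-metric lists, each with \code{metric},
#'   \code{estimate} (point estimate on the full set), \code{replicates},
#'   \code{reps}, \code{seed}; plus \code{redrawn}, the number of
#'   degenerate resamples that were redrawn.
#' @export
bootstrapMetrics <- function(scores, labels, reps = 1000L, seed = 1L,
                             threshold = 0.5) {
  stopifnot(length(scores) == length(labels))
  labels <- as.integer(labels)
  if (length(unique(labels)) < 2L)
    .stopf("bootstrapMetrics: labels contain a single class")
  n <- length(scores)
  point <- classificationMetrics(scores, labels, threshold)
  metric_names <- names(point)
  mat <- matrix(NA_real_, reps, length(metric_names),
                dimnames = list(NULL, metric_names))
  redrawn <- 0L
  .with_seed(seed, {
    for (r in seq_len(reps)) {
      repeat {
        ix <- sample.int(n, n, replace = TRUE)
        if (length(unique(labels[ix])) == 2L) break
        redrawn <- redrawn + 1L
      }
      mat[r, ] <- unlist(classificationMetrics(scores[ix], labels[ix], threshold))
    }
  })
  out <- lapply(metric_names, function(m)
    list(metric = m, estimate = point[[m]], replicates = mat[, m],
         reps = reps, seed = seed))
  names(out) <- metric_names
  out$redrawn <- redrawn
  out
}

#' Carbon-count dependence of robustness scores
#'
#' Groups per-molecule in-between-sample robustness scores by carbon count
#' and reports per-group median/IQR plus the Spearman rank correlation
#' between carbon count and score -- the diagnostic for whether attribution
#' variability tracks tokenization (string length) rather than learning.
#'
#' @param scores numeric per-molecule robustness scores.
#' @param smiles the molecules' SMILES (same order).
#' @return list with \code{by_count} (data.frame: carbons, n, median, q25,
#'   q75) and \code{spearman} (NA with a flag when undefined).
#' @export
carbonDependence <- function(scores, smiles) {
  stopifnot(length(scores) == length(smiles))
  cc <- vapply(smiles, carbonCount, 0L, USE.NAMES = FALSE)
  grp <- split(scores, cc)
  by_count <- data.frame(
    carbons = as.integer(names(grp)),
    n = vapply(grp, length, 0L),
    median = vapply(grp, stats::median, 0),
    q25 = vapply(grp, function(x) unname(stats::quantile(x, 0.25)), 0),
    q75 = vapply(grp, function(x) unname(stats::quantile(x, 0.75)), 0),
    row.names = NULL)
  rho <- if (length(unique(cc)) < 2L || length(unique(scores)) < 2L) NA_real_
         else suppressWarnings(stats::cor(cc, scores, method = "spearman"))
  list(by_count = by_count, spearman = rho,
       undefined = !is.finite(rho) || is.na(rho))
}
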