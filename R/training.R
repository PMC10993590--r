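## Pre-training (auto-translation to canonical SMILES) and frozen-encoder
## transfer learning, with the scaffold/random splits and early stopping.

## ---- decoder (encoder-decoder architecture) -------------------------------

.decoder_forward <- function(model, ids_dec, M, train = FALSE) {
  cfg <- model$config
  rate <- if (train) cfg@dropout else 0
  X <- .embed_ids(model, ids_dec)
  layers <- vector("list", cfg@nLayers)
  for (l in seq_len(cfg@nLayers)) {
    lay <- model$params$pre$dec[[l]]
    satt <- .attention_forward(X, lay, cfg@nHeads, causal = TRUE)
    dp1 <- .dropout_forward(satt$hout, rate, train)
    ln1 <- .layernorm_forward(X + dp1$out, lay$ln1g, lay$ln1b)
    X1 <- ln1$out
    catt <- .attention_forward(X1, lay, cfg@nHeads, Xkv = M, cross = TRUE)
    dp3 <- .dropout_forward(catt$hout, rate, train)
    ln3 <- .layernorm_forward(X1 + dp3$out, lay$ln3g, lay$ln3b)
    X2 <- ln3$out
    A1 <- sweep(X2 %*% lay$W1, 2L, lay$b1, `+`)
    H1 <- .relu(A1)
    F2 <- sweep(H1 %*% lay$W2, 2L, lay$b2, `+`)
    dp2 <- .dropout_forward(F2, rate, train)
    ln2 <- .layernorm_forward(X2 + dp2$out, lay$ln2g, lay$ln2b)
    layers[[l]] <- list(satt = satt, dp1 = dp1$mask, ln1 = ln1$cache, X1 = X1,
                        catt = catt, dp3 = dp3$mask, ln3 = ln3$cache, X2 = X2,
                        A1 = A1, H1 = H1, F2 = F2, dp2 = dp2$mask, ln2 = ln2$cache)
    X <- ln2$out
  }
  logits <- sweep(X %*% model$params$pre$Wout, 2L, model$params$pre$bout, `+`)
  list(logits = logits, out = X, layers = layers, ids = ids_dec)
}

.decoder_backward <- function(model, cache, dLogits) {
  cfg <- model$config
  L <- cfg@nLayers
  pre <- model$params$pre
  Xfin <- cache$out
  gWout <- t(Xfin) %*% dLogits
  gbout <- colSums(dLogits)
  dX <- dLogits %*% t(pre$Wout)
  gDec <- vector("list", L)
  dM <- NULL
  for (l in rev(seq_len(L))) {
    lay <- pre$dec[[l]]
    cc <- cache$layers[[l]]
    ln2b <- .layernorm_backward(cc$ln2, dX)
    dF2 <- .dropout_backward(cc$dp2, ln2b$dx)
    dH1 <- dF2 %*% t(lay$W2)
    dA1 <- dH1 * (cc$A1 > 0)
    dX2 <- ln2b$dx + dA1 %*% t(lay$W1)
    ln3b <- .layernorm_backward(cc$ln3, dX2)
    dcatt <- .dropout_backward(cc$dp3, ln3b$dx)
    cb <- .attention_backward(cc$catt$cache, lay, dcatt)
    dM <- if (is.null(dM)) cb$dXkv else dM + cb$dXkv
    dX1 <- ln3b$dx + cb$dX
    ln1b <- .layernorm_backward(cc$ln1, dX1)
    dsatt <- .dropout_backward(cc$dp1, ln1b$dx)
    sb <- .attention_backward(cc$satt$cache, lay, dsatt)
    gDec[[l]] <- c(sb$grads,
                   list(ln1g = ln1b$dgamma, ln1b = ln1b$dbeta,
                        W1 = t(cc$X2) %*% dA1, b1 = colSums(dA1),
                        W2 = t(cc$H1) %*% dF2, b2 = colSums(dF2),
                        ln2g = ln2b$dgamma, ln2b = ln2b$dbeta),
                   stats::setNames(cb$grads, c("Wq2", "bq2", "Wk2", "bk2",
                                               "Wv2", "bv2", "Wo2", "bo2")),
                   list(ln3g = ln3b$dgamma, ln3b = ln3b$dbeta))
    gDec[[l]] <- gDec[[l]][names(lay)]
    dX <- ln1b$dx + sb$dX
  }
  # decoder input embedding grads
  dtok <- matrix(0, nrow(model$params$tok), ncol(model$params$tok))
  for (i in seq_along(cache$ids)) dtok[cache$ids[i], ] <- dtok[cache$ids[i], ] + dX[i, ]
  dpos <- matrix(0, nrow(model$params$pos), ncol(model$params$pos))
  dpos[seq_along(cache$ids), ] <- dX
  list(gDec = gDec, gWout = gWout, gbout = gbout, dM = dM,
       dtok = dtok, dpos = dpos)
}

## greedy decode a canonical SMILES from an encoder memory
.greedy_decode <- function(model, M, max_steps) {
  bos <- match(BOS_TOKEN, VOCABULARY)
  eos <- match(EOS_TOKEN, VOCABULARY)
  ids <- bos
  for (t in seq_len(max_steps)) {
    dec <- .decoder_forward(model, ids, M)
    nxt <- which.max(dec$logits[length(ids), ])
    ids <- c(ids, nxt)
    if (nxt == eos) break
  }
  ids
}

## ---- pre-training ---------------------------------------------------------

.regimen_parts <- function(regimen) {
  regimen <- match.arg(regimen, c("C2C", "R2C", "E2C", "MC2C", "MR2C", "ME2C"))
  list(masked = startsWith(regimen, "M"),
       input = sub("^M", "", substr(regimen, nchar(regimen) - 2L, nchar(regimen) - 2L)))
}

## training pairs for one epoch: list of (in_ids, tgt_ids) padded to S
.pretrain_pairs <- function(corpus, regimen, S, epoch_seed, n_enum = 10L) {
  parts <- .regimen_parts(regimen)
  pairs <- list()
  .with_seed(epoch_seed, {
    for (i in seq_len(nrow(corpus))) {
      can <- corpus$smiles[i]
      ins <- switch(parts$input,
        C = can,
        R = enumerateSmiles(can, 1L, seed = sample.int(1e6, 1)),
        E = c(enumerateSmiles(can, n_enum, seed = sample.int(1e6, 1)), can))
      for (s in ins) {
        inseq <- tokenizeSmiles(s, pad_to = S)
        if (parts$masked)
          inseq <- maskTokens(inseq, seed = sample.int(1e6, 1))$corrupted
        tgt <- tokenizeSmiles(can, pad_to = S)
        pairs[[length(pairs) + 1L]] <- list(in_ids = inseq@ids, tgt_ids = tgt@ids)
      }
    }
    pairs
  })
}

## per-sample loss + gradient subtree for the pretrain objective
.pretrain_sample_pass <- function(model, in_ids, tgt_ids, train = TRUE) {
  cfg <- model$config
  pad <- match(PAD_TOKEN, VOCABULARY)
  if (cfg@architecture == "encoder_only") {
    enc <- .encoder_forward(model, .embed_ids(model, in_ids), train = train)
    pre <- model$params$pre
    A <- sweep(enc$out %*% pre$Wp1, 2L, pre$bp1, `+`)
    H <- .relu(A)
    logits <- sweep(H %*% pre$Wp2, 2L, pre$bp2, `+`)
    w <- as.numeric(tgt_ids != pad)
    ce <- .cross_entropy(logits, tgt_ids, w)
    pred <- max.col(logits)
    acc <- sum((pred == tgt_ids) * w) / sum(w)
    seq_ok <- all(pred[w > 0] == tgt_ids[w > 0])
    if (!train) return(list(loss = ce$loss, acc = acc, seq_ok = seq_ok))
    dH <- ce$dlogits %*% t(pre$Wp2)
    dA <- dH * (A > 0)
    dX <- dA %*% t(pre$Wp1)
    eb <- .encoder_backward(model, enc, dX)
    dtok <- matrix(0, nrow(model$params$tok), ncol(model$params$tok))
    for (i in seq_along(in_ids)) dtok[in_ids[i], ] <- dtok[in_ids[i], ] + eb$dX0[i, ]
    dpos <- matrix(0, nrow(model$params$pos), ncol(model$params$pos))
    dpos[seq_along(in_ids), ] <- eb$dX0
    grads <- list(tok = dtok, pos = dpos, enc = eb$gEnc,
                  pre = list(Wp1 = t(enc$out) %*% dA, bp1 = colSums(dA),
                             Wp2 = t(H) %*% ce$dlogits, bp2 = colSums(ce$dlogits)))
    list(loss = ce$loss, acc = acc, seq_ok = seq_ok, grads = grads)
  } else {
    # teacher forcing: decoder input is the target shifted right
    eos_pos <- which(tgt_ids == match(EOS_TOKEN, VOCABULARY))[1]
    dec_in <- tgt_ids[seq_len(eos_pos - 1L)]       # BOS t1..tn
    dec_tgt <- tgt_ids[2:eos_pos]                  # t1..tn EOS
    enc <- .encoder_forward(model, .embed_ids(model, in_ids), train = train)
    dec <- .decoder_forward(model, dec_in, enc$out, train = train)
    ce <- .cross_entropy(dec$logits, dec_tgt)
    pred <- max.col(dec$logits)
    acc <- mean(pred == dec_tgt)
    seq_ok <- all(pred == dec_tgt)
    if (!train) return(list(loss = ce$loss, acc = acc, seq_ok = seq_ok))
    db <- .decoder_backward(model, dec, ce$dlogits)
    eb <- .encoder_backward(model, enc, db$dM)
    dtok <- db$dtok
    for (i in seq_along(in_ids)) dtok[in_ids[i], ] <- dtok[in_ids[i], ] + eb$dX0[i, ]
    dpos <- db$dpos
    dpos[seq_along(in_ids), ] <- dpos[seq_along(in_ids), ] + eb$dX0
    grads <- list(tok = dtok, pos = dpos, enc = eb$gEnc,
                  pre = list(dec = db$gDec, Wout = db$gWout, bout = db$gbout))
    list(loss = ce$loss, acc = acc, seq_ok = seq_ok, grads = grads)
  }
}

#' Pre-train a transformer by auto-translation to canonical SMILES
#'
#' The six training regimens combine the input form (C = canonical, R =
#' one randomized SMILES, E = enumerated: up to \code{n_enum} randomized
#' plus the canonical) with optional masking (prefix M), always decoding to
#' the canonical string.  Early stopping monitors validation cross-entropy
#' with the given patience.  The history records per-epoch character and
#' sequence accuracy (teacher-forced; greedy-search sequence accuracy is
#' reported for the encoder-decoder at the end).
#'
#' @param model a model handle from \code{\link{buildModel}}.
#' @param corpus cleaned molecule data.frame (column \code{smiles}).
#' @param regimen one of C2C, R2C, E2C, MC2C, MR2C, ME2C.
#' @param epochs maximum epochs.
#' @param valFraction fraction of the corpus held out for validation.
#' @param patience early-stopping patience in epochs (default 5).
#' @param seed integer seed controlling shuffling, enumeration and masking.
#' @param n_enum enumerations per molecule for the E regimens (default 10).
#' @param greedyEval evaluate greedy-search sequence accuracy on the
#'   validation set after training (encoder-decoder only).
#' @return list with the trained \code{model} and a \code{history}
#'   data.frame (epoch, train_loss, val_loss, char_acc, seq_acc).
#' @export
pretrain <- function(model, corpus, regimen = "C2C", epochs = 20L,
                     valFraction = 0.1, patience = 5L, seed = 1L,
                     n_enum = 10L, greedyEval = FALSE) {
  if (!nrow(corpus)) .stopf("pretrain: empty corpus")
  cfg <- model$config
  S <- min(cfg@maxLen + 2L,
           max(vapply(corpus$smiles, function(s) length(.scan_tokens(s)), 0L)) + 2L)
  nval <- floor(valFraction * nrow(corpus))
  idx <- .with_seed(seed, sample(nrow(corpus)))
  if (nval >= 1L && nval < nrow(corpus)) {
    val <- corpus[idx[seq_len(nval)], , drop = FALSE]
    trn <- corpus[idx[-seq_len(nval)], , drop = FALSE]
  } else {
    # valFraction = 0: monitor the training set itself (memorization runs)
    trn <- corpus; val <- corpus
  }
  upd_names <- c("tok", "pos", "enc", "pre")
  opt <- .adamw_init(model$params[upd_names])
  hist <- data.frame()
  best_val <- Inf; best_params <- model$params; bad <- 0L
  for (ep in seq_len(epochs)) {
    pairs <- .pretrain_pairs(trn, regimen, S, epoch_seed = seed + 1000L * ep,
                             n_enum = n_enum)
    ord <- .with_seed(seed + ep, sample(length(pairs)))
    losses <- c()
    bs <- min(cfg@batchSize, length(pairs))
    for (start in seq(1L, length(pairs), by = bs)) {
      batch <- pairs[ord[start:min(start + bs - 1L, length(pairs))]]
      acc_g <- NULL
      bl <- 0
      .with_seed(seed + 7L * ep + start, {
        for (p in batch) {
          r <- .pretrain_sample_pass(model, p$in_ids, p$tgt_ids, train = TRUE)
          bl <- bl + r$loss
          acc_g <- if (is.null(acc_g)) r$grads else .tree_map2(`+`, acc_g, r$grads)
        }
      })
      acc_g <- .tree_map(function(x) x / length(batch), acc_g)
      st <- .adamw_step(model$params[upd_names], acc_g, opt, cfg@lr, cfg@weightDecay)
      model$params[upd_names] <- st$params
      opt <- st$state
      losses <- c(losses, bl / length(batch))
    }
    # validation (canonical input, no masking: measures the translation task)
    vstats <- lapply(seq_len(nrow(val)), function(i) {
      tgt <- tokenizeSmiles(val$smiles[i], pad_to = S)@ids
      .pretrain_sample_pass(model, tgt, tgt, train = FALSE)
    })
    vl <- mean(vapply(vstats, `[[`, 0, "loss"))
    hist <- rbind(hist, data.frame(epoch = ep, train_loss = mean(losses),
                                   val_loss = vl,
                                   char_acc = mean(vapply(vstats, `[[`, 0, "acc")),
                                   seq_acc = mean(vapply(vstats, `[[`, TRUE, "seq_ok"))))
    if (vl < best_val) { best_val <- vl; best_params <- model$params; bad <- 0L }
    else bad <- bad + 1L
    if (bad >= patience) break
  }
  model$params <- best_params
  out <- list(model = model, history = hist)
  if (greedyEval && cfg@architecture == "encoder_decoder") {
    eos <- match(EOS_TOKEN, VOCABULARY)
    ok <- vapply(seq_len(nrow(val)), function(i) {
      tgt <- tokenizeSmiles(val$smiles[i], pad_to = S)@ids
      enc <- .encoder_forward(model, .embed_ids(model, tgt))
      dec_ids <- .greedy_decode(model, enc$out, S)
      ref <- tgt[2:which(tgt == eos)[1]]
      length(dec_ids) - 1L == length(ref) && all(dec_ids[-1L] == ref)
    }, TRUE)
    out$greedy_seq_acc <- mean(ok)
  }
  out
}

## ---- splits ---------------------------------------------------------------

## ring-system framework: iteratively strip degree-1 atoms; acyclic
## molecules share one bucket
.scaffold_key <- function(smiles) {
  g <- parseSmiles(smiles)
  keep <- rep(TRUE, .molgraph_natoms(g))
  repeat {
    deg <- integer(length(keep))
    for (b in seq_along(g$bond_a1)) {
      if (keep[g$bond_a1[b]] && keep[g$bond_a2[b]]) {
        deg[g$bond_a1[b]] <- deg[g$bond_a1[b]] + 1L
        deg[g$bond_a2[b]] <- deg[g$bond_a2[b]] + 1L
      }
    }
    drop <- keep & deg <= 1L
    if (!any(drop)) break
    keep[drop] <- FALSE
  }
  if (!any(keep)) return("<acyclic>")
  map <- cumsum(keep)
  sub <- .new_molgraph()
  sub$element <- g$element[keep]; sub$aromatic <- g$aromatic[keep]
  sub$charge <- g$charge[keep]; sub$hcount <- rep(NA_integer_, sum(keep))
  sub$isotope <- g$isotope[keep]
  bk <- keep[g$bond_a1] & keep[g$bond_a2]
  sub$bond_a1 <- map[g$bond_a1[bk]]; sub$bond_a2 <- map[g$bond_a2[bk]]
  sub$bond_order <- g$bond_order[bk]; sub$bond_aromatic <- g$bond_aromatic[bk]
  .canonicalize_graph(sub)$smiles
}

#' Split molecules by scaffold or at random
#'
#' The scaffold split groups molecules by their ring-system framework and
#' assigns whole groups (largest first) to train, then validation, then
#' test, so test molecules are structurally out-of-domain.
#'
#' @param data molecule data.frame with a \code{smiles} column.
#' @param method "scaffold" or "random".
#' @param frac numeric length-3 train/validation/test fractions.
#' @param seed seed for the random split (and scaffold group tie shuffling).
#' @return list of three data.frames: \code{train}, \code{valid},
#'   \code{test}.
#' @export
splitDataset <- function(data, method = c("scaffold", "random"),
                         frac = c(0.8, 0.1, 0.1), seed = 1L) {
  method <- match.arg(method)
  n <- nrow(data)
  if (method == "random") {
    idx <- .with_seed(seed, sample(n))
    ntr <- floor(frac[1] * n); nva <- floor(frac[2] * n)
    return(list(train = data[idx[seq_len(ntr)], , drop = FALSE],
                valid = data[idx[ntr + seq_len(nva)], , drop = FALSE],
                test = data[idx[(ntr + nva + 1L):n], , drop = FALSE]))
  }
  keys <- vapply(data$smiles, .scaffold_key, "", USE.NAMES = FALSE)
  groups <- split(seq_len(n), keys)
  groups <- groups[order(-vapply(groups, length, 0L), names(groups))]
  ntr <- floor(frac[1] * n); nva <- floor(frac[2] * n)
  tr <- integer(0); va <- integer(0); te <- integer(0)
  for (gidx in groups) {
    if (length(tr) < ntr) tr <- c(tr, gidx)
    else if (length(va) < nva) va <- c(va, gidx)
    else te <- c(te, gidx)
  }
  list(train = data[tr, , drop = FALSE],
       valid = data[va, , drop = FALSE],
       test = data[te, , drop = FALSE])
}

## ---- transfer learning ----------------------------------------------------

#' Transfer-learn a toxicity classifier on a (frozen) encoder
#'
#' Attaches a prediction head (max-pool MLP or TextCNN + highway) to the
#' given encoder and trains it on binary labels with AdamW.  With
#' \code{freeze = TRUE} (the default, the reference procedure) the encoder
#' weights are bitwise untouched -- verified by digest -- and its outputs
#' are cached, so only the head trains.  Returns held-out metrics (AUROC,
#' accuracy, F1, MCC, precision, recall).
#'
#' @param encoder a model handle (pre-trained or randomized).
#' @param data labeled molecule data.frame (\code{smiles}, \code{label}).
#' @param headType "maxpool_mlp" or "textcnn_highway"; defaults to the
#'   encoder's configured head.
#' @param freeze freeze the encoder (default TRUE).
#' @param split "scaffold" or "random".
#' @param epochs training epochs (head converges quickly when frozen).
#' @param lr learning rate (default the transfer-learning 5e-5 is often too
#'   slow for a fresh head at desk scale; default here 1e-3, configurable).
#' @param seed integer seed.
#' @param frac split fractions.
#' @return list with \code{model}, \code{metrics}, \code{split},
#'   \code{history}, and \code{encoderUnchanged} (digest check result).
#' @export
transferLearn <- function(encoder, data, headType = NULL, freeze = TRUE,
                          split = c("scaffold", "random"), epochs = 30L,
                          lr = 1e-3, seed = 1L, frac = c(0.8, 0.1, 0.1)) {
  split <- match.arg(split)
  data <- data[!is.na(data$label), , drop = FALSE]
  if (length(unique(data$label)) < 2L)
    .stopf("transferLearn: training data must contain both classes")
  model <- encoder
  if (!is.null(headType) && headType != model$headType) {
    cfgh <- model$config; cfgh@headType <- headType
    hp <- .with_seed(seed, .init_head(cfgh))
    model$headType <- hp$type; model$headFilters <- hp$nf
    hp$type <- NULL; hp$nf <- NULL
    model$params$head <- hp
    model$nParams <- .tree_count(model$params)
  }
  parts <- splitDataset(data, split, frac, seed)
  if (length(unique(parts$train$label)) < 2L)
    .stopf("transferLearn: single-class training split")
  digest_before <- encoderDigest(model)
  S <- min(model$config@maxLen + 2L,
           max(vapply(data$smiles, function(s) length(.scan_tokens(s)), 0L)) + 2L)
  seqs <- lapply(parts$train$smiles, tokenizeSmiles, pad_to = S)
  y <- as.integer(parts$train$label) + 1L   # class 1 = non-toxic, 2 = toxic
  enc_cache <- NULL
  if (freeze)
    enc_cache <- lapply(seqs, function(sq)
      .encoder_forward(model, .embed_ids(model, sq@ids))$out)
  upd <- if (freeze) "head" else c("tok", "pos", "enc", "head")
  opt <- .adamw_init(model$params[upd])
  hist <- data.frame()
  cfg <- model$config
  for (ep in seq_len(epochs)) {
    ord <- .with_seed(seed + ep, sample(length(seqs)))
    bs <- min(cfg@batchSize, length(seqs))
    losses <- c()
    for (start in seq(1L, length(seqs), by = bs)) {
      bidx <- ord[start:min(start + bs - 1L, length(seqs))]
      acc_g <- NULL; bl <- 0
      for (i in bidx) {
        if (freeze) {
          X <- enc_cache[[i]]
          head <- .head_forward(model, X)
          ce <- .cross_entropy(matrix(head$logits, 1L), y[i])
          hb <- .head_backward(model, X, head$cache, as.numeric(ce$dlogits))
          g <- list(head = hb$grads)
        } else {
          fw <- .classifier_forward(model, seqs[[i]]@ids, train = TRUE)
          ce <- .cross_entropy(matrix(fw$logits, 1L), y[i])
          bw <- .classifier_backward(model, fw, as.numeric(ce$dlogits))
          g <- bw$grads[upd]
        }
        bl <- bl + ce$loss
        acc_g <- if (is.null(acc_g)) g else .tree_map2(`+`, acc_g, g)
      }
      acc_g <- .tree_map(function(x) x / length(bidx), acc_g)
      st <- .adamw_step(model$params[upd], acc_g, opt, lr, cfg@weightDecay)
      model$params[upd] <- st$params
      opt <- st$state
      losses <- c(losses, bl / length(bidx))
    }
    hist <- rbind(hist, data.frame(epoch = ep, train_loss = mean(losses)))
  }
  scores <- predictToxicity(model, parts$test$smiles, pad_to = S)
  metrics <- classificationMetrics(scores, parts$test$label)
  list(model = model, metrics = metrics, split = parts, history = hist,
       encoderUnchanged = identical(encoderDigest(model), digest_before))
}
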