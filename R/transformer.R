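## Instrumented transformer encoder (and encoder-decoder) in plain R.
##
## The forward pass caches every intermediate the attribution equations
## need: per-layer, per-head attention matrices alpha and per-layer
## attention-block outputs h (after the output projection), plus class
## logits.  The backward pass is exact reverse-mode differentiation and can
## report gradients of a chosen class logit with respect to alpha, h and
## the input embeddings.  Post-layer-norm residual blocks, Xavier
## initialization, AdamW training; dropout is active only in training mode
## so attribution always runs deterministically.

#' Construct a transformer model configuration
#'
#' Defaults are the reference training setup (sequence length 175, token
#' space 68, embedding 512, batch 128, AdamW, Xavier) with a compact
#' 3-layer, 8-head encoder that stays under the 16.5 M parameter budget.
#'
#' @param maxLen maximum SMILES token count (padded length = maxLen + 2).
#' @param embedDim embedding dimension E.
#' @param nHeads attention heads h; E must be divisible by h.
#' @param nLayers encoder layers L.
#' @param ffDim feed-forward width (default 4 * embedDim).
#' @param vocabSize token space (default 68).
#' @param dropout dropout rate during training (0.1 pre-training, 0.3
#'   transfer learning in the reference setup).
#' @param lr learning rate (1e-4 pre-training, 5e-5 transfer).
#' @param weightDecay AdamW weight decay.
#' @param batchSize minibatch size.
#' @param architecture "encoder_only" or "encoder_decoder".
#' @param headType classification head: "maxpool_mlp" or "textcnn_highway".
#' @return a \linkS4class{ModelConfig}.
#' @export
modelConfig <- function(maxLen = 175L, embedDim = 512L, nHeads = 8L,
                        nLayers = 3L, ffDim = NULL, vocabSize = 68L,
                        dropout = 0.1, lr = 1e-4, weightDecay = 0.01,
                        batchSize = 128L, architecture = "encoder_only",
                        headType = "maxpool_mlp") {
  if (is.null(ffDim)) ffDim <- 4L * as.integer(embedDim)
  new("ModelConfig", maxLen = as.integer(maxLen), embedDim = as.integer(embedDim),
      nHeads = as.integer(nHeads), nLayers = as.integer(nLayers),
      ffDim = as.integer(ffDim), vocabSize = as.integer(vocabSize),
      dropout = dropout, lr = lr, weightDecay = weightDecay,
      batchSize = as.integer(batchSize), architecture = architecture,
      headType = headType)
}

.init_encoder_layer <- function(E, FF) {
  list(Wq = .xavier(E, E), bq = numeric(E),
       Wk = .xavier(E, E), bk = numeric(E),
       Wv = .xavier(E, E), bv = numeric(E),
       Wo = .xavier(E, E), bo = numeric(E),
       ln1g = rep(1, E), ln1b = numeric(E),
       W1 = .xavier(E, FF), b1 = numeric(FF),
       W2 = .xavier(FF, E), b2 = numeric(E),
       ln2g = rep(1, E), ln2b = numeric(E))
}

.init_decoder_layer <- function(E, FF) {
  c(.init_encoder_layer(E, FF),
    list(Wq2 = .xavier(E, E), bq2 = numeric(E),
         Wk2 = .xavier(E, E), bk2 = numeric(E),
         Wv2 = .xavier(E, E), bv2 = numeric(E),
         Wo2 = .xavier(E, E), bo2 = numeric(E),
         ln3g = rep(1, E), ln3b = numeric(E)))
}

.init_head <- function(config) {
  E <- config@embedDim
  if (config@headType == "maxpool_mlp") {
    list(type = "maxpool_mlp",
         Wh1 = .xavier(E, E), bh1 = numeric(E),
         Wh2 = .xavier(E, 2L), bh2 = numeric(2L))
  } else {
    nf <- max(8L, min(100L, 2L * E))  # filters per kernel size
    list(type = "textcnn_highway", nf = nf,
         Wc3 = .xavier(3L * E, nf), bc3 = numeric(nf),
         Wc4 = .xavier(4L * E, nf), bc4 = numeric(nf),
         Wc5 = .xavier(5L * E, nf), bc5 = numeric(nf),
         Wt = .xavier(3L * nf, 3L * nf), bt = numeric(3L * nf),
         Wg = .xavier(3L * nf, 3L * nf), bg = numeric(3L * nf),
         Wout = .xavier(3L * nf, 2L), bout = numeric(2L))
  }
}

#' Build a transformer model
#'
#' Xavier-initialized and deterministic under \code{seed}.  The model
#' carries an encoder, a classification head (per \code{headType}) and the
#' pre-training head matching the architecture (a position-wise MLP for
#' encoder-only, a full causal/cross-attention decoder for
#' encoder-decoder).
#'
#' @param config a \linkS4class{ModelConfig}.
#' @param seed integer seed for the initialization.
#' @return a model handle (list with \code{config}, \code{params} and
#'   \code{nParams}).
#' @export
buildModel <- function(config, seed = NULL) {
  validObject(config)
  E <- config@embedDim; FF <- config@ffDim; V <- config@vocabSize
  S <- config@maxLen + 2L
  .with_seed(seed, {
    params <- list(
      tok = .xavier(V, E),
      pos = .xavier(S, E),
      enc = lapply(seq_len(config@nLayers), function(l) .init_encoder_layer(E, FF)),
      head = .init_head(config))
    params$pre <- if (config@architecture == "encoder_only") {
      list(Wp1 = .xavier(E, FF), bp1 = numeric(FF),
           Wp2 = .xavier(FF, V), bp2 = numeric(V))
    } else {
      list(dec = lapply(seq_len(config@nLayers), function(l) .init_decoder_layer(E, FF)),
           Wout = .xavier(E, V), bout = numeric(V))
    }
    # head$type / head$nf are metadata, not parameters
    meta <- params$head$type
    nf <- params$head$nf
    params$head$type <- NULL; params$head$nf <- NULL
    model <- list(config = config, params = params,
                  headType = meta, headFilters = nf)
    model$nParams <- .tree_count(params)
    model
  })
}

#' Build a never-trained randomized model
#'
#' Xavier random weights under \code{seed}; the randomization control used
#' in every robustness analysis.
#'
#' @inheritParams buildModel
#' @return a model handle.
#' @export
randomizeModel <- function(config, seed = NULL) buildModel(config, seed)

#' Number of trainable parameters of a model
#' @param model a model handle from \code{\link{buildModel}}.
#' @return integer parameter count.
#' @export
parameterCount <- function(model) model$nParams

## ---- attention block ------------------------------------------------------

.attention_forward <- function(X, layer, nHeads, causal = FALSE,
                               Xkv = NULL, cross = FALSE) {
  W <- if (cross) list(Wq = layer$Wq2, bq = layer$bq2, Wk = layer$Wk2,
                       bk = layer$bk2, Wv = layer$Wv2, bv = layer$bv2,
                       Wo = layer$Wo2, bo = layer$bo2)
       else layer[c("Wq", "bq", "Wk", "bk", "Wv", "bv", "Wo", "bo")]
  if (is.null(Xkv)) Xkv <- X
  S <- nrow(X); Sk <- nrow(Xkv); E <- ncol(X)
  d <- E %/% nHeads
  Q <- sweep(X %*% W$Wq, 2L, W$bq, `+`)
  K <- sweep(Xkv %*% W$Wk, 2L, W$bk, `+`)
  V <- sweep(Xkv %*% W$Wv, 2L, W$bv, `+`)
  alpha <- array(0, c(nHeads, S, Sk))
  ctx <- matrix(0, S, E)
  for (k in seq_len(nHeads)) {
    idx <- ((k - 1L) * d + 1L):(k * d)
    scores <- Q[, idx, drop = FALSE] %*% t(K[, idx, drop = FALSE]) / sqrt(d)
    if (causal) scores[upper.tri(scores)] <- -1e30
    a <- .softmax_rows(scores)
    alpha[k, , ] <- a
    ctx[, idx] <- a %*% V[, idx, drop = FALSE]
  }
  hout <- sweep(ctx %*% W$Wo, 2L, W$bo, `+`)
  list(hout = hout, cache = list(X = X, Xkv = Xkv, Q = Q, K = K, V = V,
                                 alpha = alpha, ctx = ctx, d = d,
                                 nHeads = nHeads, cross = cross))
}

## returns dX, dXkv, parameter grads and dAlpha (gradient at the alpha node)
.attention_backward <- function(cache, layer, dhout) {
  X <- cache$X; Xkv <- cache$Xkv; d <- cache$d; nH <- cache$nHeads
  W <- if (cache$cross) list(Wq = layer$Wq2, Wk = layer$Wk2, Wv = layer$Wv2,
                             Wo = layer$Wo2)
       else layer[c("Wq", "Wk", "Wv", "Wo")]
  S <- nrow(X); Sk <- nrow(Xkv)
  dWo <- t(cache$ctx) %*% dhout
  dbo <- colSums(dhout)
  dctx <- dhout %*% t(W$Wo)
  dQ <- matrix(0, S, ncol(X)); dK <- matrix(0, Sk, ncol(X)); dV <- matrix(0, Sk, ncol(X))
  dAlpha <- array(0, c(nH, S, Sk))
  for (k in seq_len(nH)) {
    idx <- ((k - 1L) * d + 1L):(k * d)
    a <- cache$alpha[k, , , drop = TRUE]
    if (S == 1L || Sk == 1L) a <- matrix(a, S, Sk)
    dctx_h <- dctx[, idx, drop = FALSE]
    da <- dctx_h %*% t(cache$V[, idx, drop = FALSE])
    dAlpha[k, , ] <- da
    dV[, idx] <- t(a) %*% dctx_h
    ds <- .softmax_rows_backward(a, da)
    dQ[, idx] <- ds %*% cache$K[, idx, drop = FALSE] / sqrt(d)
    dK[, idx] <- t(ds) %*% cache$Q[, idx, drop = FALSE] / sqrt(d)
  }
  grads <- list(Wq = t(X) %*% dQ, bq = colSums(dQ),
                Wk = t(Xkv) %*% dK, bk = colSums(dK),
                Wv = t(Xkv) %*% dV, bv = colSums(dV),
                Wo = dWo, bo = dbo)
  dX <- dQ %*% t(W$Wq)
  dXkv <- dK %*% t(W$Wk) + dV %*% t(W$Wv)
  if (!cache$cross) { dX <- dX + dXkv; dXkv <- NULL }
  list(dX = dX, dXkv = dXkv, grads = grads, dAlpha = dAlpha)
}

## ---- encoder --------------------------------------------------------------

.embed_ids <- function(model, ids) {
  S <- length(ids)
  if (S > nrow(model$params$pos))
    .stopf("sequence length %d exceeds model maximum %d", S, nrow(model$params$pos))
  model$params$tok[ids, , drop = FALSE] + model$params$pos[seq_len(S), , drop = FALSE]
}

.encoder_forward <- function(model, X0, train = FALSE) {
  cfg <- model$config
  rate <- if (train) cfg@dropout else 0
  X <- X0
  layers <- vector("list", cfg@nLayers)
  for (l in seq_len(cfg@nLayers)) {
    lay <- model$params$enc[[l]]
    att <- .attention_forward(X, lay, cfg@nHeads)
    dp1 <- .dropout_forward(att$hout, rate, train)
    ln1 <- .layernorm_forward(X + dp1$out, lay$ln1g, lay$ln1b)
    X1 <- ln1$out
    A1 <- sweep(X1 %*% lay$W1, 2L, lay$b1, `+`)
    H1 <- .relu(A1)
    F2 <- sweep(H1 %*% lay$W2, 2L, lay$b2, `+`)
    dp2 <- .dropout_forward(F2, rate, train)
    ln2 <- .layernorm_forward(X1 + dp2$out, lay$ln2g, lay$ln2b)
    layers[[l]] <- list(att = att, dp1 = dp1$mask, ln1 = ln1$cache, X1 = X1,
                        A1 = A1, H1 = H1, dp2 = dp2$mask, ln2 = ln2$cache)
    X <- ln2$out
  }
  list(out = X, layers = layers, X0 = X0)
}

## backward through the encoder; dOut is the gradient at the final output.
## Returns parameter grads, dX0, and per-layer dAlpha / dHOut traces.
.encoder_backward <- function(model, cache, dOut) {
  cfg <- model$config
  L <- cfg@nLayers
  dX <- dOut
  gEnc <- vector("list", L)
  dAlpha <- vector("list", L)
  dHOut <- vector("list", L)
  for (l in rev(seq_len(L))) {
    lay <- model$params$enc[[l]]
    cc <- cache$layers[[l]]
    ln2b <- .layernorm_backward(cc$ln2, dX)
    dr2 <- ln2b$dx
    dF2 <- .dropout_backward(cc$dp2, dr2)
    dH1 <- dF2 %*% t(lay$W2)
    dW2 <- t(cc$H1) %*% dF2
    db2 <- colSums(dF2)
    dA1 <- dH1 * (cc$A1 > 0)
    dW1 <- t(cc$X1) %*% dA1
    db1 <- colSums(dA1)
    dX1 <- dr2 + dA1 %*% t(lay$W1)
    ln1b <- .layernorm_backward(cc$ln1, dX1)
    dr1 <- ln1b$dx
    dhout <- .dropout_backward(cc$dp1, dr1)
    dHOut[[l]] <- dhout
    ab <- .attention_backward(cc$att$cache, lay, dhout)
    dAlpha[[l]] <- ab$dAlpha
    gEnc[[l]] <- c(ab$grads,
                   list(ln1g = ln1b$dgamma, ln1b = ln1b$dbeta,
                        W1 = dW1, b1 = db1, W2 = dW2, b2 = db2,
                        ln2g = ln2b$dgamma, ln2b = ln2b$dbeta))
    # reorder to match parameter layout
    gEnc[[l]] <- gEnc[[l]][names(model$params$enc[[l]])]
    dX <- dr1 + ab$dX
  }
  list(gEnc = gEnc, dX0 = dX, dAlpha = dAlpha, dHOut = dHOut)
}

## ---- classification heads -------------------------------------------------

.head_forward <- function(model, X) {
  hp <- model$params$head
  if (model$headType == "maxpool_mlp") {
    amax <- apply(X, 2L, which.max)
    pooled <- X[cbind(amax, seq_len(ncol(X)))]
    a1 <- as.numeric(pooled %*% hp$Wh1) + hp$bh1
    h1 <- .relu(a1)
    logits <- as.numeric(h1 %*% hp$Wh2) + hp$bh2
    list(logits = logits, cache = list(amax = amax, pooled = pooled, a1 = a1, h1 = h1))
  } else {
    E <- ncol(X); S <- nrow(X); nf <- model$headFilters
    conv <- function(kk, W, b) {
      npos <- S - kk + 1L
      win <- matrix(0, npos, kk * E)
      for (i in seq_len(npos)) win[i, ] <- as.numeric(t(X[i:(i + kk - 1L), , drop = FALSE]))
      Z <- sweep(win %*% W, 2L, b, `+`)
      Zr <- .relu(Z)
      amax <- apply(Zr, 2L, which.max)
      list(win = win, Z = Z, amax = amax,
           pooled = Zr[cbind(amax, seq_len(nf))])
    }
    c3 <- conv(3L, hp$Wc3, hp$bc3)
    c4 <- conv(4L, hp$Wc4, hp$bc4)
    c5 <- conv(5L, hp$Wc5, hp$bc5)
    z <- c(c3$pooled, c4$pooled, c5$pooled)
    tpre <- as.numeric(z %*% hp$Wt) + hp$bt
    tg <- 1 / (1 + exp(-tpre))
    gpre <- as.numeric(z %*% hp$Wg) + hp$bg
    gg <- .relu(gpre)
    hw <- tg * gg + (1 - tg) * z
    logits <- as.numeric(hw %*% hp$Wout) + hp$bout
    list(logits = logits,
         cache = list(c3 = c3, c4 = c4, c5 = c5, z = z, tpre = tpre, tg = tg,
                      gpre = gpre, gg = gg, hw = hw, S = S, E = E))
  }
}

.head_backward <- function(model, X, cache, dlogits) {
  hp <- model$params$head
  if (model$headType == "maxpool_mlp") {
    dWh2 <- outer(cache$h1, dlogits)
    dbh2 <- dlogits
    dh1 <- as.numeric(hp$Wh2 %*% dlogits)
    da1 <- dh1 * (cache$a1 > 0)
    dWh1 <- outer(cache$pooled, da1)
    dbh1 <- da1
    dpooled <- as.numeric(hp$Wh1 %*% da1)
    dX <- matrix(0, nrow(X), ncol(X))
    dX[cbind(cache$amax, seq_len(ncol(X)))] <- dpooled
    list(grads = list(Wh1 = dWh1, bh1 = dbh1, Wh2 = dWh2, bh2 = dbh2), dX = dX)
  } else {
    cc <- cache
    dWout <- outer(cc$hw, dlogits)
    dbout <- dlogits
    dhw <- as.numeric(hp$Wout %*% dlogits)
    dtg <- dhw * (cc$gg - cc$z)
    dgg <- dhw * cc$tg
    dz <- dhw * (1 - cc$tg)
    dtpre <- dtg * cc$tg * (1 - cc$tg)
    dgpre <- dgg * (cc$gpre > 0)
    dWt <- outer(cc$z, dtpre); dbt <- dtpre
    dWg <- outer(cc$z, dgpre); dbg <- dgpre
    dz <- dz + as.numeric(hp$Wt %*% dtpre) + as.numeric(hp$Wg %*% dgpre)
    nf <- model$headFilters
    dX <- matrix(0, cc$S, cc$E)
    back <- function(kk, W, conv, dpool) {
      dZr <- matrix(0, nrow(conv$Z), nf)
      dZr[cbind(conv$amax, seq_len(nf))] <- dpool
      dZ <- dZr * (conv$Z > 0)
      dW <- t(conv$win) %*% dZ
      db <- colSums(dZ)
      dwin <- dZ %*% t(W)
      for (i in seq_len(nrow(dwin)))
        dX[i:(i + kk - 1L), ] <<- dX[i:(i + kk - 1L), ] +
          matrix(dwin[i, ], kk, cc$E, byrow = TRUE)
      list(dW = dW, db = db)
    }
    g3 <- back(3L, hp$Wc3, cc$c3, dz[seq_len(nf)])
    g4 <- back(4L, hp$Wc4, cc$c4, dz[nf + seq_len(nf)])
    g5 <- back(5L, hp$Wc5, cc$c5, dz[2L * nf + seq_len(nf)])
    list(grads = list(Wc3 = g3$dW, bc3 = g3$db, Wc4 = g4$dW, bc4 = g4$db,
                      Wc5 = g5$dW, bc5 = g5$db, Wt = dWt, bt = dbt,
                      Wg = dWg, bg = dbg, Wout = dWout, bout = dbout),
         dX = dX)
  }
}

## ---- full classifier passes ----------------------------------------------

.classifier_forward <- function(model, ids, train = FALSE, X0 = NULL) {
  if (is.null(X0)) X0 <- .embed_ids(model, ids)
  enc <- .encoder_forward(model, X0, train = train)
  head <- .head_forward(model, enc$out)
  list(logits = head$logits, enc = enc, head = head, ids = ids)
}

.classifier_backward <- function(model, fw, dlogits) {
  hb <- .head_backward(model, fw$enc$out, fw$head$cache, dlogits)
  eb <- .encoder_backward(model, fw$enc, hb$dX)
  # embedding grads
  dtok <- matrix(0, nrow(model$params$tok), ncol(model$params$tok))
  for (i in seq_along(fw$ids)) dtok[fw$ids[i], ] <- dtok[fw$ids[i], ] + eb$dX0[i, ]
  dpos <- matrix(0, nrow(model$params$pos), ncol(model$params$pos))
  dpos[seq_along(fw$ids), ] <- eb$dX0
  grads <- list(tok = dtok, pos = dpos, enc = eb$gEnc, head = hb$grads)
  list(grads = grads, dAlpha = eb$dAlpha, dHOut = eb$dHOut, dX0 = eb$dX0)
}

## ---- exported instrumentation --------------------------------------------

#' Forward pass with a full attention trace
#'
#' Runs the classifier in evaluation mode (dropout off) and returns the
#' class prediction together with an \linkS4class{AttentionTrace}: all
#' per-layer, per-head attention matrices and per-layer attention-block
#' outputs.
#'
#' @param model a model handle.
#' @param seq a \linkS4class{TokenSequence}.
#' @return list with \code{prediction} (logits, probs, class) and
#'   \code{trace} (an AttentionTrace).
#' @export
forwardWithTrace <- function(model, seq) {
  stopifnot(is(seq, "TokenSequence"))
  fw <- .classifier_forward(model, seq@ids, train = FALSE)
  probs <- .softmax_vec(fw$logits)
  trace <- new("AttentionTrace",
               alpha = lapply(fw$enc$layers, function(l) l$att$cache$alpha),
               hOut = lapply(fw$enc$layers, function(l) l$att$hout),
               logits = fw$logits, probs = probs, seqLen = length(seq@ids))
  list(prediction = list(logits = fw$logits, probs = probs,
                         class = which.max(fw$logits)),
       trace = trace, .forward = fw)
}

#' Class-activated gradients with respect to attention traces
#'
#' Computes exact gradients of the selected class logit with respect to
#' every layer's attention matrix and attention-block output, by
#' reverse-mode differentiation of the same forward pass the trace came
#' from.
#'
#' @param model a model handle.
#' @param seq a \linkS4class{TokenSequence}.
#' @param classIndex class of interest: 1 or 2; default the predicted class.
#' @return a \linkS4class{GradientTrace}.
#' @export
classGradients <- function(model, seq, classIndex = NULL) {
  stopifnot(is(seq, "TokenSequence"))
  fw <- .classifier_forward(model, seq@ids, train = FALSE)
  if (is.null(classIndex)) classIndex <- which.max(fw$logits)
  classIndex <- as.integer(classIndex)
  if (!classIndex %in% c(1L, 2L)) .stopf("classIndex must be 1 or 2")
  dlogits <- c(0, 0); dlogits[classIndex] <- 1
  bw <- .classifier_backward(model, fw, dlogits)
  for (l in seq_along(bw$dAlpha)) {
    if (!all(is.finite(bw$dAlpha[[l]])) || !all(is.finite(bw$dHOut[[l]])))
      .stopf("non-finite gradients at layer %d", l)
  }
  new("GradientTrace", dAlpha = bw$dAlpha, dHOut = bw$dHOut,
      classIndex = classIndex)
}

#' Predicted class probabilities for a batch of SMILES
#'
#' @param model a model handle.
#' @param smiles character vector of SMILES.
#' @param pad_to optional common padded length.
#' @return numeric vector of toxic-class (class 2) probabilities.
#' @export
predictToxicity <- function(model, smiles, pad_to = NULL) {
  vapply(smiles, function(s) {
    fw <- .classifier_forward(model, tokenizeSmiles(s, pad_to = pad_to)@ids)
    .softmax_vec(fw$logits)[2L]
  }, numeric(1), USE.NAMES = FALSE)
}

## weight digest used to verify the frozen-encoder guarantee
#' Digest of the encoder weights (frozen-encoder check)
#' @param model a model handle.
#' @return md5 string over embedding + encoder parameters.
#' @export
encoderDigest <- function(model) {
  .object_digest(list(model$params$tok, model$params$pos, model$params$enc))
}
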