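# shared fixtures: tiny models, corpora, and an independent forward pass
# used as the finite-difference oracle for trace gradients

tiny_config <- function(...) {
  defaults <- list(maxLen = 20L, embedDim = 16L, nHeads = 2L, nLayers = 2L,
                   ffDim = 24L, dropout = 0)
  do.call(modelConfig, utils::modifyList(defaults, list(...)))
}

tiny_model <- function(seed = 1L, ...) buildModel(tiny_config(...), seed = seed)

fixture_smiles <- c("CCO", "CC(C)CO", "c1ccccc1", "c1ccc(cc1)[N+](=O)[O-]",
                    "CC(N)C(=O)O", "C1CCCCC1", "O=C=O", "ClCCBr",
                    "c1ccc2ccccc2c1", "CC(C)(C)c1ccc(O)cc1")

rdkit_available <- local({
  ok <- NULL
  function() {
    if (is.null(ok)) {
      res <- tryCatch(system2("python", c("-c", "import rdkit"),
                              stdout = FALSE, stderr = FALSE),
                      error = function(e) 1L)
      ok <<- identical(res, 0L)
    }
    ok
  }
})

# run a python/RDKit snippet and return stdout lines
rdkit_run <- function(code) {
  f <- tempfile(fileext = ".py")
  writeLines(code, f)
  on.exit(unlink(f))
  system2("python", f, stdout = TRUE)
}

# Independent re-implementation of the encoder classifier forward pass that
# can inject additive perturbations at the attention (post-softmax) and
# attention-output nodes.  Used only as the finite-difference oracle for
# GradientTrace; it shares no code with the package's backward pass.
oracle_logits <- function(model, ids, alpha_bump = NULL, hout_bump = NULL) {
  cfg <- model$config
  E <- cfg@embedDim; nH <- cfg@nHeads; d <- E / nH
  X <- model$params$tok[ids, , drop = FALSE] +
    model$params$pos[seq_along(ids), , drop = FALSE]
  softmax_r <- function(m) {
    e <- exp(m - apply(m, 1, max)); e / rowSums(e)
  }
  ln <- function(x, g, b) {
    mu <- rowMeans(x); xc <- x - mu
    xh <- xc / sqrt(rowMeans(xc^2) + 1e-5)
    sweep(sweep(xh, 2, g, `*`), 2, b, `+`)
  }
  for (l in seq_len(cfg@nLayers)) {
    lay <- model$params$enc[[l]]
    Q <- sweep(X %*% lay$Wq, 2, lay$bq, `+`)
    K <- sweep(X %*% lay$Wk, 2, lay$bk, `+`)
    V <- sweep(X %*% lay$Wv, 2, lay$bv, `+`)
    ctx <- matrix(0, nrow(X), E)
    for (h in seq_len(nH)) {
      ix <- ((h - 1) * d + 1):(h * d)
      a <- softmax_r(Q[, ix, drop = FALSE] %*% t(K[, ix, drop = FALSE]) / sqrt(d))
      if (!is.null(alpha_bump)) a <- a + alpha_bump[[l]][h, , ]
      ctx[, ix] <- a %*% V[, ix, drop = FALSE]
    }
    hout <- sweep(ctx %*% lay$Wo, 2, lay$bo, `+`)
    if (!is.null(hout_bump)) hout <- hout + hout_bump[[l]]
    X1 <- ln(X + hout, lay$ln1g, lay$ln1b)
    FF <- sweep(pmax(sweep(X1 %*% lay$W1, 2, lay$b1, `+`), 0) %*% lay$W2,
                2, lay$b2, `+`)
    X <- ln(X1 + FF, lay$ln2g, lay$ln2b)
  }
  hp <- model$params$head
  pooled <- apply(X, 2, max)
  as.numeric(pmax(as.numeric(pooled %*% hp$Wh1) + hp$bh1, 0) %*% hp$Wh2) + hp$bh2
}

zero_bumps <- function(model, S) {
  cfg <- model$config
  list(alpha = lapply(seq_len(cfg@nLayers), function(l)
         array(0, c(cfg@nHeads, S, S))),
       hout = lapply(seq_len(cfg@nLayers), function(l)
         matrix(0, S, cfg@embedDim)))
}

# synthetic attention/gradient traces for identity checks
uniform_trace <- function(S, E, h, L = 1L, seed = 1L) {
  set.seed(seed)
  new("AttentionTrace",
      alpha = replicate(L, array(1 / S, c(h, S, S)), simplify = FALSE),
      hOut = replicate(L, matrix(stats::rnorm(S * E), S, E), simplify = FALSE),
      logits = c(0, 0), probs = c(0.5, 0.5), seqLen = as.integer(S))
}

random_gradient_trace <- function(S, E, h, L = 1L, classIndex = 2L, seed = 2L) {
  set.seed(seed)
  new("GradientTrace",
      dAlpha = replicate(L, array(stats::rnorm(h * S * S), c(h, S, S)),
                         simplify = FALSE),
      dHOut = replicate(L, matrix(stats::rnorm(S * E), S, E), simplify = FALSE),
      classIndex = as.integer(classIndex))
}
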