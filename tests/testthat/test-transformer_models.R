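# instrumented transformer: construction, traces, gradient exactness,
# pre-training regimens and frozen-encoder transfer learning

test_that("model construction is deterministic, validated and parameter-counted", {
  m1 <- tiny_model(seed = 5L)
  m2 <- tiny_model(seed = 5L)
  expect_identical(m1$params, m2$params)
  m3 <- tiny_model(seed = 6L)
  expect_false(identical(m1$params, m3$params))
  expect_error(modelConfig(embedDim = 510L, nHeads = 8L), "divisible")
  cfg <- modelConfig(embedDim = 512L, nHeads = 8L)
  expect_equal(cfg@embedDim / cfg@nHeads, 64)
  # parameter count monotone in depth/width, default under the 16.5 M budget
  count <- function(...) parameterCount(buildModel(tiny_config(...), seed = 1L))
  expect_gt(count(nLayers = 3L), count(nLayers = 2L))
  expect_gt(count(embedDim = 32L, ffDim = 48L), count(embedDim = 16L, ffDim = 48L))
  expect_lt(parameterCount(buildModel(modelConfig(), seed = 1L)), 16.5e6)
})

test_that("forward traces have stochastic attention rows and consistent shapes", {
  m <- tiny_model(seed = 2L)
  sq <- tokenizeSmiles("CC(N)C(=O)O", pad_to = 14L)
  ft <- forwardWithTrace(m, sq)
  tr <- ft$trace
  expect_length(tr@alpha, 2L)
  expect_length(tr@hOut, 2L)
  for (l in 1:2) {
    a <- tr@alpha[[l]]
    expect_equal(dim(a), c(2L, 14L, 14L))
    expect_true(max(abs(apply(a, c(1, 2), sum) - 1)) < 1e-5)
    expect_equal(dim(tr@hOut[[l]]), c(14L, 16L))
  }
  expect_length(ft$prediction$logits, 2L)
  expect_equal(sum(ft$prediction$probs), 1, tolerance = 1e-12)
  # duplicate call -> identical trace (eval mode is deterministic)
  ft2 <- forwardWithTrace(m, sq)
  expect_identical(ft$trace@alpha, ft2$trace@alpha)
  expect_identical(ft$prediction$logits, ft2$prediction$logits)
  # over-length input errors
  expect_error(forwardWithTrace(m, tokenizeSmiles(strrep("C", 30))), "exceeds")
})

test_that("trace gradients match central finite differences on a toy model", {
  m <- tiny_model(seed = 3L)
  sq <- tokenizeSmiles("CC(O)CN", pad_to = 10L)
  S <- 10L
  gt <- classGradients(m, sq, classIndex = 1L)
  base <- oracle_logits(m, sq@ids)
  expect_equal(base, forwardWithTrace(m, sq)$prediction$logits, tolerance = 1e-10)
  eps <- 1e-5
  set.seed(4)
  for (rep in 1:12) {
    l <- sample(2L, 1L); h <- sample(2L, 1L)
    i <- sample(S, 1L); j <- sample(S, 1L)
    bp <- zero_bumps(m, S); bm <- zero_bumps(m, S)
    bp$alpha[[l]][h, i, j] <- eps; bm$alpha[[l]][h, i, j] <- -eps
    fd <- (oracle_logits(m, sq@ids, alpha_bump = bp$alpha)[1] -
           oracle_logits(m, sq@ids, alpha_bump = bm$alpha)[1]) / (2 * eps)
    an <- gt@dAlpha[[l]][h, i, j]
    expect_equal(an, fd, tolerance = 1e-3 * max(abs(fd), 1e-4))
  }
  for (rep in 1:12) {
    l <- sample(2L, 1L); i <- sample(S, 1L); e <- sample(16L, 1L)
    bp <- zero_bumps(m, S); bm <- zero_bumps(m, S)
    bp$hout[[l]][i, e] <- eps; bm$hout[[l]][i, e] <- -eps
    fd <- (oracle_logits(m, sq@ids, hout_bump = bp$hout)[1] -
           oracle_logits(m, sq@ids, hout_bump = bm$hout)[1]) / (2 * eps)
    an <- gt@dHOut[[l]][i, e]
    expect_equal(an, fd, tolerance = 1e-3 * max(abs(fd), 1e-4))
  }
})

test_that("gradient traces mirror trace shapes and detect a constant head", {
  m <- tiny_model(seed = 7L)
  sq <- tokenizeSmiles("CCO", pad_to = 6L)
  gt <- classGradients(m, sq, 2L)
  ft <- forwardWithTrace(m, sq)
  for (l in 1:2) {
    expect_equal(dim(gt@dAlpha[[l]]), dim(ft$trace@alpha[[l]]))
    expect_equal(dim(gt@dHOut[[l]]), dim(ft$trace@hOut[[l]]))
  }
  # constant output head (all-zero head weights) -> zero trace gradients
  m0 <- m
  m0$params$head <- rapply(m0$params$head, function(x) x * 0, how = "replace")
  g0 <- classGradients(m0, sq, 2L)
  expect_true(all(vapply(g0@dAlpha, function(x) all(x == 0), TRUE)))
  expect_true(all(vapply(g0@dHOut, function(x) all(x == 0), TRUE)))
})

test_that("randomized models are seed-reproducible and run all methods", {
  cfg <- tiny_config()
  expect_identical(randomizeModel(cfg, seed = 9L)$params,
                   randomizeModel(cfg, seed = 9L)$params)
  expect_false(identical(randomizeModel(cfg, seed = 9L)$params,
                         randomizeModel(cfg, seed = 10L)$params))
  # every attribution method runs on the randomized control
  rm_ <- randomizeModel(cfg, seed = 11L)
  sq <- tokenizeSmiles("CC(C)CO", pad_to = 10L)
  for (meth in xairob:::ATTRIBUTION_METHODS) {
    att <- suppressWarnings(attributeMethod(rm_, sq, meth, steps = 8L, budget = 2L))
    expect_s4_class(att, "Attribution")
    expect_true(all(is.finite(att@values)))
    expect_length(att@values, 10L)
  }
})

test_that("encoder-only pre-training memorizes a toy corpus", {
  syn <- generateSyntheticMolecules(50, seed = 5L, planted_alert = NULL)
  cfg <- modelConfig(maxLen = 40L, embedDim = 32L, nHeads = 4L, nLayers = 1L,
                     ffDim = 64L, dropout = 0, lr = 2e-3, batchSize = 16L)
  mod <- buildModel(cfg, seed = 2L)
  pt <- pretrain(mod, syn, "C2C", epochs = 50L, seed = 3L,
                 valFraction = 0, patience = 50L)
  expect_equal(tail(pt$history$seq_acc, 1L), 1.0)
  expect_equal(tail(pt$history$char_acc, 1L), 1.0)
})

test_that("masked and enumerated regimens train and early stopping halts", {
  syn <- generateSyntheticMolecules(12, seed = 6L, planted_alert = NULL)
  cfg <- modelConfig(maxLen = 40L, embedDim = 16L, nHeads = 2L, nLayers = 1L,
                     ffDim = 24L, dropout = 0, lr = 2e-3, batchSize = 12L)
  mod <- buildModel(cfg, seed = 2L)
  pt <- pretrain(mod, syn, "ME2C", epochs = 3L, seed = 3L, n_enum = 2L,
                 valFraction = 0.25)
  expect_lt(tail(pt$history$train_loss, 1L), pt$history$train_loss[1L])
  # early stopping: loss made strictly worse every epoch by a zero-lr
  # model never improving past epoch 1 -> halts after patience epochs
  cfg0 <- modelConfig(maxLen = 40L, embedDim = 16L, nHeads = 2L, nLayers = 1L,
                      ffDim = 24L, dropout = 0, lr = 0, batchSize = 12L)
  mod0 <- buildModel(cfg0, seed = 2L)
  pt0 <- pretrain(mod0, syn, "C2C", epochs = 50L, seed = 3L,
                  valFraction = 0.25, patience = 3L)
  expect_lte(nrow(pt0$history), 4L)
})

test_that("encoder-decoder pre-training translates and greedy-decodes", {
  syn <- generateSyntheticMolecules(8, seed = 7L, planted_alert = NULL)
  syn <- syn[!duplicated(syn$smiles), , drop = FALSE]
  cfg <- modelConfig(maxLen = 40L, embedDim = 32L, nHeads = 4L, nLayers = 1L,
                     ffDim = 64L, dropout = 0, lr = 2e-3, batchSize = 8L,
                     architecture = "encoder_decoder")
  mod <- buildModel(cfg, seed = 2L)
  pt <- pretrain(mod, syn, "C2C", epochs = 80L, seed = 3L,
                 valFraction = 0, patience = 80L, greedyEval = TRUE)
  expect_equal(tail(pt$history$seq_acc, 1L), 1.0)  # teacher-forced memorization
  expect_gt(pt$greedy_seq_acc, 0.7)                # greedy decode recovers most
})

test_that("frozen-encoder transfer keeps weights bitwise and separates a planted alert", {
  syn <- generateSyntheticMolecules(200, seed = 11L, epsilon = 0)
  cfg <- modelConfig(maxLen = 40L, embedDim = 32L, nHeads = 4L, nLayers = 2L,
                     ffDim = 64L, dropout = 0)
  enc <- randomizeModel(cfg, seed = 4L)
  tl <- transferLearn(enc, syn, split = "random", epochs = 60L, seed = 6L,
                      lr = 3e-3)
  expect_true(tl$encoderUnchanged)
  expect_identical(encoderDigest(tl$model), encoderDigest(enc))
  expect_gt(tl$metrics$auroc, 0.9)
  # untrained variant: a raw randomized model still yields valid probabilities
  p <- predictToxicity(randomizeModel(cfg, seed = 12L), syn$smiles[1:5])
  expect_true(all(p >= 0 & p <= 1))
  # single-class data errors
  bad <- syn; bad$label <- 1
  expect_error(transferLearn(enc, bad), "both classes")
})

test_that("scaffold split separates ring frameworks; random split partitions", {
  syn <- generateSyntheticMolecules(120, seed = 13L)
  sp <- splitDataset(syn, "scaffold", seed = 1L)
  expect_equal(nrow(sp$train) + nrow(sp$valid) + nrow(sp$test), nrow(syn))
  key <- function(df) unique(vapply(df$smiles, xairob:::.scaffold_key, ""))
  expect_length(intersect(key(sp$train), key(sp$test)), 0L)
  sp2 <- splitDataset(syn, "random", seed = 1L)
  expect_equal(sort(c(sp2$train$id, sp2$valid$id, sp2$test$id)), sort(syn$id))
})

test_that("textcnn-highway head trains end to end", {
  syn <- generateSyntheticMolecules(80, seed = 21L, epsilon = 0)
  cfg <- modelConfig(maxLen = 40L, embedDim = 16L, nHeads = 2L, nLayers = 1L,
                     ffDim = 24L, dropout = 0, headType = "textcnn_highway")
  enc <- randomizeModel(cfg, seed = 4L)
  tl <- transferLearn(enc, syn, split = "random", epochs = 15L, seed = 6L,
                      lr = 3e-3)
  expect_true(tl$encoderUnchanged)
  expect_true(is.finite(tl$metrics$auroc))
})
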