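# the eight attribution methods: reductions, structural limits, naive-loop
# oracles, integrated-gradients axioms and Shapley axioms

test_that("embedding reduction is a per-row mean", {
  expect_equal(reduceEmbedding(matrix(3, 4, 5)), rep(3, 4))
  set.seed(1)
  M <- matrix(rnorm(30), 5, 6)
  expect_equal(reduceEmbedding(M), apply(M, 1, mean))
  expect_equal(reduceEmbedding(matrix(1:4, 4, 1)), as.numeric(1:4))
  expect_error(reduceEmbedding(matrix(0, 3, 0)), "empty")
})

test_that("attention maps behave on uniform and hand-computed traces", {
  S <- 4L
  tr <- uniform_trace(S, 8L, 2L)
  expect_equal(attentionMapAttribution(tr)@values, rep(1 / S, S))
  # hand-computed 3x3 single-head case
  A <- matrix(c(0.5, 0.3, 0.2,
                0.1, 0.8, 0.1,
                0.2, 0.2, 0.6), 3, 3, byrow = TRUE)
  tr3 <- new("AttentionTrace", alpha = list(array(A, c(1, 3, 3))),
             hOut = list(matrix(0, 3, 8)), logits = c(0, 0),
             probs = c(.5, .5), seqLen = 3L)
  expect_equal(attentionMapAttribution(tr3)@values, rowMeans(A))
  expect_true(all(attentionMapAttribution(tr3)@values >= 0 &
                  attentionMapAttribution(tr3)@values <= 1))
})

test_that("rollout limits: single layer, identity layers, stochastic closure", {
  m <- tiny_model(seed = 1L, nLayers = 1L)
  sq <- tokenizeSmiles("CC(N)O", pad_to = 8L)
  tr <- forwardWithTrace(m, sq)$trace
  expect_equal(rolloutAttribution(tr, literal = TRUE)@values,
               attentionMapAttribution(tr)@values)
  # identity attention at every layer -> rollout matrix stays identity-derived
  ident <- array(0, c(1, 2, 2)); ident[1, , ] <- diag(2)
  tr2 <- new("AttentionTrace", alpha = list(ident, ident),
             hOut = list(matrix(0, 2, 4), matrix(0, 2, 4)),
             logits = c(0, 0), probs = c(.5, .5), seqLen = 2L)
  expect_equal(rolloutAttribution(tr2)@values, rep(0.5, 2))
  expect_equal(rolloutAttribution(tr2, literal = TRUE)@values, rep(0.5, 2))
  # (A+I)/2 convention keeps rows stochastic at any depth
  m3 <- tiny_model(seed = 2L, nLayers = 3L)
  tr3 <- forwardWithTrace(m3, tokenizeSmiles("CCOC", pad_to = 8L))$trace
  expect_equal(sum(rolloutAttribution(tr3)@values), 1, tolerance = 1e-9)
})

test_that("gradient-family methods match naive-loop oracles on random traces", {
  S <- 5L; E <- 6L; h <- 2L; L <- 2L
  tr <- new("AttentionTrace",
            alpha = lapply(1:L, function(l) {
              a <- array(abs(stats::rnorm(h * S * S)), c(h, S, S))
              for (k in 1:h) a[k, , ] <- a[k, , ] / rowSums(a[k, , ])
              a
            }),
            hOut = lapply(1:L, function(l) matrix(stats::rnorm(S * E), S, E)),
            logits = c(0, 0), probs = c(.5, .5), seqLen = S)
  gt <- random_gradient_trace(S, E, h, L, seed = 3L)
  # naive loops written independently of the implementation's vector code
  havg <- function(a) {
    out <- matrix(0, S, S)
    for (i in 1:S) for (j in 1:S) out[i, j] <- mean(a[, i, j])
    out
  }
  grads_oracle <- numeric(S)
  GL <- havg(gt@dAlpha[[L]])
  for (i in 1:S) grads_oracle[i] <- mean(GL[i, ])
  expect_equal(gradAttribution(tr, gt)@values, grads_oracle)
  attg_oracle <- numeric(S)
  for (i in 1:S) {
    tot <- 0
    for (l in 1:L) for (j in 1:S)
      tot <- tot + havg(gt@dAlpha[[l]])[i, j] * havg(tr@alpha[[l]])[i, j]
    attg_oracle[i] <- tot / S
  }
  expect_equal(attgradAttribution(tr, gt)@values, attg_oracle)
  cat_oracle <- numeric(S)
  for (i in 1:S) {
    tot <- 0
    for (l in 1:L) for (e in 1:E)
      tot <- tot + gt@dHOut[[l]][i, e] * tr@hOut[[l]][i, e]
    cat_oracle[i] <- tot / E
  }
  expect_equal(catAttribution(tr, gt)@values, cat_oracle)
  attcat_oracle <- numeric(S)
  for (i in 1:S) {
    tot <- 0
    for (l in 1:L) {
      ai <- mean(havg(tr@alpha[[l]])[i, ])
      for (e in 1:E)
        tot <- tot + ai * gt@dHOut[[l]][i, e] * tr@hOut[[l]][i, e]
    }
    attcat_oracle[i] <- tot / E
  }
  expect_equal(attcatAttribution(tr, gt)@values, attcat_oracle)
  # layer mismatch is an error
  gt1 <- random_gradient_trace(S, E, h, 1L)
  expect_error(catAttribution(tr, gt1), "mismatch")
})

test_that("grads attribution agrees with finite differences through the model", {
  m <- tiny_model(seed = 3L, nLayers = 1L)
  sq <- tokenizeSmiles("CCO", pad_to = 6L)
  tr <- forwardWithTrace(m, sq)$trace
  gt <- classGradients(m, sq, 1L)
  phi <- gradAttribution(tr, gt)@values
  S <- 6L
  eps <- 1e-5
  fd_phi <- numeric(S)
  for (i in 1:S) {
    tot <- 0
    for (j in 1:S) for (h in 1:2) {
      bp <- zero_bumps(m, S); bm <- zero_bumps(m, S)
      bp$alpha[[1]][h, i, j] <- eps; bm$alpha[[1]][h, i, j] <- -eps
      tot <- tot + (oracle_logits(m, sq@ids, alpha_bump = bp$alpha)[1] -
                    oracle_logits(m, sq@ids, alpha_bump = bm$alpha)[1]) / (2 * eps) / 2
    }
    fd_phi[i] <- tot / S
  }
  expect_equal(phi, fd_phi, tolerance = 1e-3)
})

test_that("integrated gradients satisfies completeness and converges in steps", {
  m <- tiny_model(seed = 5L)
  sq <- tokenizeSmiles("CC(C)CO", pad_to = 10L)
  ig <- integratedGradients(m, sq, steps = 256L, classIndex = 2L)
  gap <- ig@provenance$completeness_gap
  diff <- abs(ig@provenance$output_diff)
  expect_lt(gap, 0.01 * diff)
  # PAD positions sit exactly at the baseline -> zero attribution
  pad_pos <- which(tokens(sq) == "<pad>")
  expect_equal(ig@values[pad_pos], rep(0, length(pad_pos)))
  # coarse vs dense-step oracle within 5% relative (vector norm)
  ig64 <- integratedGradients(m, sq, steps = 64L, classIndex = 2L)
  ig1024 <- integratedGradients(m, sq, steps = 1024L, classIndex = 2L)
  expect_lt(sqrt(sum((ig64@values - ig1024@values)^2)) /
            sqrt(sum(ig1024@values^2)), 0.05)
})

test_that("exact Shapley reproduces the closed-form toy game", {
  # v({}) = 0, v({1}) = 1, v({2}) = 2, v({1,2}) = 4  =>  phi = (1.5, 2.5)
  v <- function(present) {
    if (!any(present)) 0
    else if (present[1] && present[2]) 4
    else if (present[1]) 1 else 2
  }
  expect_equal(xairob:::.shapley_exact(v, 2L), c(1.5, 2.5))
  # brute-force oracle over permutations for a random 4-player game
  set.seed(9)
  vals <- stats::rnorm(16)
  v4 <- function(present) vals[sum(2^(which(present) - 1)) + 1]
  phi <- xairob:::.shapley_exact(v4, 4L)
  perms <- rbind(1:4)
  perms <- do.call(rbind, combinat_perms <- {
    pp <- list()
    rec <- function(pre, rest) {
      if (!length(rest)) pp[[length(pp) + 1L]] <<- pre
      else for (r in rest) rec(c(pre, r), setdiff(rest, r))
    }
    rec(integer(0), 1:4)
    pp
  })
  phi_or <- numeric(4)
  for (p in seq_len(nrow(perms))) {
    present <- rep(FALSE, 4)
    vprev <- v4(present)
    for (k in perms[p, ]) {
      present[k] <- TRUE
      vnew <- v4(present)
      phi_or[k] <- phi_or[k] + (vnew - vprev)
      vprev <- vnew
    }
  }
  expect_equal(phi, phi_or / nrow(perms))
})

test_that("token Shapley satisfies efficiency, symmetry and null-player axioms", {
  m <- tiny_model(seed = 6L)
  sq <- tokenizeSmiles("CCO", pad_to = 6L)
  sh <- shapAttribution(m, sq, mode = "exact", classIndex = 2L)
  expect_equal(sh@provenance$efficiency_gap, 0, tolerance = 1e-10)
  # specials carry zero
  expect_equal(sh@values[tokens(sq) %in% c("<bos>", "<eos>", "<pad>")],
               rep(0, 3))
  # symmetry: identical tokens in a permutation-equivariant model (no
  # positional embedding) have identical marginal contributions
  msym <- tiny_model(seed = 6L)
  msym$params$pos[] <- 0
  sq2 <- tokenizeSmiles("CC", pad_to = 4L)
  sh2 <- shapAttribution(msym, sq2, mode = "exact", classIndex = 2L)
  expect_equal(sh2@values[2], sh2@values[3], tolerance = 1e-10)
  # exact mode refuses long inputs
  long <- tokenizeSmiles(strrep("C", 15))
  expect_error(shapAttribution(m <- tiny_model(seed = 6L, maxLen = 18L), long,
                               mode = "exact"), "sampled")
  # sampled mode is seed-reproducible
  s1 <- shapAttribution(tiny_model(seed = 6L), sq, mode = "sampled",
                        budget = 4L, seed = 3L, classIndex = 2L)
  s2 <- shapAttribution(tiny_model(seed = 6L), sq, mode = "sampled",
                        budget = 4L, seed = 3L, classIndex = 2L)
  expect_identical(s1@values, s2@values)
})

test_that("normalization yields unit absolute sum, preserves signs, flags zeros", {
  a <- xairob:::.new_attribution("IG", c(2, -1, 1), 2L)
  n <- normalizeAttribution(a)
  expect_equal(n@values, c(0.5, -0.25, 0.25))
  expect_equal(sum(abs(n@values)), 1)
  z <- normalizeAttribution(xairob:::.new_attribution("IG", c(0, 0), 2L))
  expect_true(z@zeroVector)
  expect_equal(z@values, c(0, 0))
  bad <- xairob:::.new_attribution("IG", c(1, 2), 2L)
  bad@values[1] <- NA_real_
  expect_error(normalizeAttribution(bad), "finite")
})

test_that("attributeAllMethods matches per-method calls", {
  m <- tiny_model(seed = 8L)
  sq <- tokenizeSmiles("CC(O)C", pad_to = 8L)
  all8 <- suppressWarnings(
    attributeAllMethods(m, sq, classIndex = 2L, ig_steps = 32L,
                        shap_budget = 3L, seed = 5L))
  for (meth in c("AttentionMaps", "Rollout", "Grads", "AttGrads", "CAT", "AttCAT")) {
    single <- attributeMethod(m, sq, meth, classIndex = 2L)
    expect_equal(all8[[meth]]@values, single@values, label = meth)
  }
  ig <- suppressWarnings(attributeMethod(m, sq, "IG", classIndex = 2L, steps = 32L))
  expect_equal(all8$IG@values, ig@values)
  sh <- attributeMethod(m, sq, "SHAP", classIndex = 2L, budget = 3L, seed = 5L)
  expect_equal(all8$SHAP@values, sh@values)
})
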