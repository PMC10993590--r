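# Mann-Whitney U, bootstrap metrics, classification metrics, carbon
# dependence

test_that("Mann-Whitney matches exhaustive enumeration for all n <= 6", {
  # independent oracle: enumerate all group relabelings of the pooled data
  perm_oracle <- function(a, b) {
    nA <- length(a); r <- rank(c(a, b))
    Uobs <- sum(r[seq_len(nA)]) - nA * (nA + 1) / 2
    mu <- nA * length(b) / 2
    combs <- utils::combn(length(r), nA)
    Us <- apply(combs, 2, function(ix) sum(r[ix])) - nA * (nA + 1) / 2
    mean(abs(Us - mu) >= abs(Uobs - mu) - 1e-9)
  }
  set.seed(11)
  for (rep in 1:30) {
    nA <- sample(1:6, 1); nB <- sample(1:6, 1)
    # draw from a small integer range so ties occur often
    a <- sample(1:4, nA, replace = TRUE)
    b <- sample(1:4, nB, replace = TRUE)
    r <- mannWhitneyU(a, b)
    expect_equal(r$p, perm_oracle(a, b), label = sprintf("nA=%d nB=%d", nA, nB))
    expect_equal(r$method, "exact enumeration")
  }
  # tie-free exact case cross-checked against the stock implementation
  for (rep in 1:10) {
    a <- rnorm(5); b <- rnorm(6)
    expect_equal(mannWhitneyU(a, b)$p,
                 stats::wilcox.test(a, b, exact = TRUE)$p.value)
    expect_equal(mannWhitneyU(a, b)$U,
                 unname(stats::wilcox.test(a, b)$statistic))
  }
})

test_that("Mann-Whitney anchors: separation, identity, sidedness", {
  r <- mannWhitneyU(c(1, 2), c(3, 4))
  expect_equal(r$U, 0)
  expect_equal(mannWhitneyU(c(1, 2), c(3, 4), alternative = "less")$p, 1 / 6)
  x <- c(1, 2, 3, 4)
  expect_gte(mannWhitneyU(x, x)$p, 0.99)
  set.seed(2)
  a <- rnorm(20); b <- a + 100
  expect_lt(mannWhitneyU(a, b)$p, 0.05)
  expect_error(mannWhitneyU(numeric(0), 1), "empty")
  # large-sample approximation close to the stock normal-approx p
  a <- rnorm(30); b <- rnorm(25) + 0.4
  expect_equal(mannWhitneyU(a, b)$p,
               stats::wilcox.test(a, b, exact = FALSE)$p.value,
               tolerance = 1e-10)
})

test_that("classification metrics reproduce confusion arithmetic", {
  m <- classificationMetrics(c(.9, .8, .2, .1), c(1, 1, 0, 0))
  expect_true(all(unlist(m) == 1))
  # TP=2, FP=1, FN=1, TN=2
  m2 <- classificationMetrics(c(.9, .8, .3, .7, .2, .1), c(1, 1, 1, 0, 0, 0))
  expect_equal(m2$precision, 2 / 3)
  expect_equal(m2$recall, 2 / 3)
  expect_equal(m2$accuracy, 2 / 3)
  expect_equal(m2$f1, 2 / 3)
  mcc_hand <- (2 * 2 - 1 * 1) / sqrt(3 * 3 * 3 * 3)
  expect_equal(m2$mcc, mcc_hand)
  # constant scores -> AUROC 0.5 (ties count half)
  m3 <- classificationMetrics(rep(0.7, 6), c(1, 0, 1, 0, 1, 0))
  expect_equal(m3$auroc, 0.5)
  expect_error(classificationMetrics(c(.1, .2), c(1, 1)), "single class")
})

test_that("bootstrap: perfect separation, reproducibility, consistency", {
  scores <- c(rep(0.9, 10), rep(0.1, 10))
  labels <- c(rep(1, 10), rep(0, 10))
  bs <- bootstrapMetrics(scores, labels, reps = 1000L, seed = 7L)
  expect_length(bs$auroc$replicates, 1000L)
  expect_true(all(bs$auroc$replicates == 1.0))
  bs2 <- bootstrapMetrics(scores, labels, reps = 1000L, seed = 7L)
  expect_identical(bs$accuracy$replicates, bs2$accuracy$replicates)
  # replicate mean within 2 bootstrap SE of the point estimate
  set.seed(8)
  sc <- runif(60); lb <- rbinom(60, 1, plogis(3 * (sc - 0.5)))
  bs3 <- bootstrapMetrics(sc, lb, reps = 1000L, seed = 9L)
  se <- stats::sd(bs3$auroc$replicates)
  expect_lt(abs(mean(bs3$auroc$replicates) - bs3$auroc$estimate), 2 * se)
  expect_error(bootstrapMetrics(c(.2, .3), c(1, 1)), "single class")
  # degenerate resamples are redrawn, keeping reps fixed
  small <- bootstrapMetrics(c(.9, .1, .2), c(1, 0, 0), reps = 200L, seed = 1L)
  expect_gt(small$redrawn, 0L)
  expect_length(small$auroc$replicates, 200L)
})

test_that("carbon dependence tracks rank correlation and groups", {
  smis <- c("C", "CC", "CCC", "CCCC", "CCCCC")
  # scores equal to carbon count -> perfect rank correlation
  cd <- carbonDependence(1:5, smis)
  expect_equal(cd$spearman, 1)
  expect_equal(cd$by_count$carbons, 1:5)
  # constant scores -> zero correlation (flagged undefined by sd = 0)
  cd0 <- carbonDependence(rep(1, 5), smis)
  expect_true(cd0$undefined || cd0$spearman == 0)
  # single group -> undefined, flagged
  cd1 <- carbonDependence(c(1, 2), c("CC", "CCO"))
  expect_true(is.data.frame(cd1$by_count))
  cd2 <- carbonDependence(c(1, 2), c("CC", "CC"))
  expect_true(cd2$undefined)
})
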